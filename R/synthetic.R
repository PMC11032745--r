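#' Parameters for the synthetic drug-market generator
#'
#' Bundles everything the generator needs to emit seizure and death record
#' sets with known ground truth: per-drug annual seizure intensities
#' (availability), the polydrug mixing process, per-drug lethality, and the
#' death model linking annual totals to the true lethality index.
#'
#' @param drugs Character vector of drug categories.
#' @param years Integer vector of calendar years.
#' @param seizure_intensity Expected seizure counts: a long data frame with
#'   columns `drug`, `year`, `intensity`, or a named numeric vector (one
#'   constant intensity per drug across all years).
#' @param true_lethality Named numeric vector: per-drug probability that a
#'   single-drug seizure's worth of market activity produces one
#'   single-drug death (the ground-truth lethality ratio, in \[0, 1\]).
#' @param p_mixed Probability a seizure involves two or more drugs.
#' @param p_third Probability a mixed seizure involves a third drug.
#' @param mix_weights Named non-negative co-occurrence weights; a partner
#'   drug is drawn with probability proportional to
#'   `mix_weights[d] * intensity[d, year]`, so co-occurrence tracks
#'   availability. Default: equal weights.
#' @param deaths_model `"mechanistic"` (deaths are exactly the binomial
#'   single-drug deaths) or `"linear_sqrt"` (multi-drug death records are
#'   appended so annual totals follow
#'   `round((a + b * SALI_true(y) + e_y)^2)`, `e_y ~ N(0, noise_sd)`).
#' @param a,b,noise_sd Coefficients of the `linear_sqrt` death model, on
#'   the square-root-deaths scale.
#' @param rng_seed Integer seed; identical parameters and seed give
#'   bit-identical output.
#' @return A validated list of class `"market_params"`.
#' @export
market_params <- function(drugs, years, seizure_intensity, true_lethality,
                          p_mixed = 0.3, p_third = 0.15, mix_weights = NULL,
                          deaths_model = c("mechanistic", "linear_sqrt"),
                          a = 12, b = 0.0095, noise_sd = 0.3, rng_seed = 1L) {
  deaths_model <- arg_match(deaths_model)
  drugs <- tolower(drugs)
  years <- as.integer(sort(unique(years)))
  if (length(drugs) == 0 || anyDuplicated(drugs)) {
    abort_config("`drugs` must be a non-empty set of unique labels.")
  }
  if (is.numeric(seizure_intensity) && !is.null(names(seizure_intensity))) {
    seizure_intensity <- tidyr::expand_grid(drug = names(seizure_intensity),
                                            year = years) |>
      mutate(intensity = seizure_intensity[.data$drug])
  }
  seizure_intensity <- as_tibble(seizure_intensity) |>
    mutate(drug = tolower(.data$drug), year = as.integer(.data$year))
  if (!all(c("drug", "year", "intensity") %in% names(seizure_intensity))) {
    abort_config("`seizure_intensity` needs columns drug, year, intensity.")
  }
  grid <- tidyr::expand_grid(drug = drugs, year = years) |>
    left_join(seizure_intensity, by = c("drug", "year")) |>
    mutate(intensity = dplyr::coalesce(.data$intensity, 0))
  if (any(grid$intensity < 0)) abort_config("Intensities must be >= 0.")
  if (is.null(mix_weights)) mix_weights <- setNames(rep(1, length(drugs)), drugs)
  names(mix_weights) <- tolower(names(mix_weights))
  mix_weights <- mix_weights[drugs]
  if (anyNA(mix_weights) || any(mix_weights < 0)) {
    abort_config("`mix_weights` must be non-negative and cover every drug.")
  }
  names(true_lethality) <- tolower(names(true_lethality))
  theta <- true_lethality[drugs]
  if (anyNA(theta) || any(theta < 0 | theta > 1)) {
    abort_config("`true_lethality` must give a probability in [0, 1] for every drug.")
  }
  for (p in c(p_mixed, p_third)) {
    if (!is.numeric(p) || p < 0 || p > 1) abort_config("Probabilities must be in [0, 1].")
  }
  if (noise_sd < 0) abort_config("`noise_sd` must be >= 0.")
  structure(
    list(drugs = drugs, years = years, seizure_intensity = grid,
         true_lethality = theta, p_mixed = p_mixed, p_third = p_third,
         mix_weights = mix_weights, deaths_model = deaths_model,
         a = a, b = b, noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
    class = "market_params"
  )
}

#' Ohio-2017-like parameter preset
#'
#' A ready-made [market_params()] whose 2017 expected single-drug seizure
#' counts and per-drug lethality match the magnitudes of the published
#' reference-year summary table (e.g. roughly 3,800 pure fentanyl seizures
#' with lethality 0.393), with plausible availability trends over
#' 2009-2018: fentanyl surging after 2013, prescription opioids slowly
#' declining, amphetamines rising, heroin rising then falling.
#'
#' @param rng_seed Integer seed stored in the preset.
#' @return A `"market_params"` object.
#' @export
ohio2017_like <- function(rng_seed = 1L) {
  years <- 2009:2018
  intens <- tibble(
    drug = rep(analytic_drugs(), each = length(years)),
    year = rep(years, times = 6),
    intensity = c(
      # fentanyl: rare before 2013, surging to the 2017 peak
      50, 80, 150, 300, 600, 1200, 2200, 3600, 5446, 6200,
      # cocaine: large and resurgent
      5200, 5000, 4800, 4700, 4900, 5300, 6100, 7200, 8259, 8900,
      # prescription opioids: slow decline
      7200, 7000, 6700, 6300, 6000, 5700, 5500, 5350, 5214, 5100,
      # heroin: rise then fall as fentanyl displaces it
      1300, 1700, 2200, 2700, 3200, 3600, 3750, 3700, 3551, 2900,
      # amphetamines: steep rise
      1500, 1900, 2400, 3100, 4100, 5400, 7200, 9800, 12874, 14500,
      # benzodiazepines: steady
      7000, 7100, 7200, 7300, 7400, 7500, 7600, 7700, 7767, 7800
    )
  )
  market_params(
    drugs = analytic_drugs(), years = years,
    seizure_intensity = intens,
    true_lethality = c(fentanyl = 0.393, cocaine = 0.044,
                       prescription_opioids = 0.059, heroin = 0.044,
                       amphetamines = 0.009, benzodiazepines = 0.005),
    p_mixed = 0.3, p_third = 0.15,
    mix_weights = c(fentanyl = 2, cocaine = 1, prescription_opioids = 1,
                    heroin = 1, amphetamines = 1, benzodiazepines = 1),
    deaths_model = "linear_sqrt", a = 20, b = 0.0095, noise_sd = 0.3,
    rng_seed = rng_seed
  )
}

random_dates <- function(year, n) {
  start <- as.Date(paste0(year, "-01-01"))
  ndays <- as.integer(as.Date(paste0(year, "-12-31")) - start) + 1L
  start + sample.int(ndays, n, replace = TRUE) - 1L
}

# Sample one partner per mixed seizure, availability-weighted, excluding
# the drugs already present. `present` is a list of character vectors.
sample_partners <- function(present, drugs, avail) {
  vapply(present, function(p) {
    cand <- setdiff(drugs, p)
    w <- avail[cand]
    if (length(cand) == 0 || sum(w) == 0) return(NA_character_)
    if (length(cand) == 1) return(cand)
    sample(cand, 1, prob = w)
  }, character(1))
}

#' Generate a synthetic seizure and death record set
#'
#' Draws, for each drug and year, a Poisson number of seizure events at the
#' stated intensity; each event is mixed with probability `p_mixed`, in
#' which case one (and with probability `p_third` two) partner drugs are
#' added, drawn with probability proportional to co-occurrence weight times
#' that year's availability. Single-drug deaths are drawn binomially from
#' each drug-year's single-drug seizure count at the drug's true lethality.
#' Under the `linear_sqrt` death model, additional multi-drug death records
#' (always at least two toxicology substances, so they never enter
#' single-drug counts) are appended until each year's total matches
#' `round((a + b * SALI_true + e)^2)`.
#'
#' All ICD-10 codes are drawn uniformly from X40-X44 and dates uniformly
#' within the year. The generator keeps an event-level tally as it goes,
#' returned as the log; the log is the ground-truth bookkeeping that
#' downstream estimates are validated against.
#'
#' @param params A [market_params()] object.
#' @param seed Optional integer overriding `params$rng_seed`. The caller's
#'   RNG state is preserved.
#' @return A list of class `"market_sim"` with elements `seizures` and
#'   `deaths` (record tibbles in the [read_seizures()] / [read_deaths()]
#'   shape), `log` (list of `drug_year` and `year` tally tibbles) and
#'   `params`.
#' @export
generate_market <- function(params, seed = NULL) {
  stopifnot(inherits(params, "market_params"))
  seed <- seed %||% params$rng_seed
  with_preserved_seed(seed, generate_market_impl(params))
}

generate_market_impl <- function(params) {
  drugs <- params$drugs
  years <- params$years
  theta <- params$true_lethality
  icd_codes <- paste0("X4", 0:4)

  seiz_acc <- list()
  death_acc <- list()
  tally <- tidyr::expand_grid(drug = drugs, year = years) |>
    mutate(single_seizures = 0L, mixed_seizures = 0L, single_deaths = 0L)
  tkey <- paste(tally$drug, tally$year)
  sid <- 0L
  did <- 0L

  for (y in years) {
    intens_y <- params$seizure_intensity |>
      filter(.data$year == y)
    avail <- setNames(intens_y$intensity[match(drugs, intens_y$drug)], drugs) *
      params$mix_weights

    for (d in drugs) {
      lam <- intens_y$intensity[intens_y$drug == d]
      n <- rpois(1, lam)
      if (n == 0) next
      mixed <- if (length(drugs) > 1) runif(n) < params$p_mixed else rep(FALSE, n)
      subs <- rep(list(d), n)
      n_mix <- sum(mixed)
      if (n_mix > 0) {
        p1 <- sample_partners(subs[mixed], drugs, avail)
        subs[mixed] <- Map(c, subs[mixed], p1)
        third <- runif(n_mix) < params$p_third
        if (any(third)) {
          idx <- which(mixed)[third]
          p2 <- sample_partners(subs[idx], drugs, avail)
          ok <- !is.na(p2)
          subs[idx[ok]] <- Map(c, subs[idx[ok]], p2[ok])
        }
        subs[mixed] <- lapply(subs[mixed], function(s) sort(unique(s)))
      }
      seiz_acc[[length(seiz_acc) + 1L]] <- tibble(
        seizure_id = sprintf("S%07d", sid + seq_len(n)),
        date = random_dates(y, n),
        county = "synthetic",
        substances = subs
      )
      sid <- sid + n

      # tallies: pure events for the primary drug, appearance counts for all
      n_single <- n - n_mix
      tally$single_seizures[tkey == paste(d, y)] <-
        tally$single_seizures[tkey == paste(d, y)] + n_single
      if (n_mix > 0) {
        app <- table(unlist(subs[mixed]))
        k <- match(paste(names(app), y), tkey)
        tally$mixed_seizures[k] <- tally$mixed_seizures[k] + as.integer(app)
      }

      m <- rbinom(1, n_single, theta[[d]])
      tally$single_deaths[tkey == paste(d, y)] <- m
      if (m > 0) {
        death_acc[[length(death_acc) + 1L]] <- tibble(
          death_id = sprintf("D%07d", did + seq_len(m)),
          date_of_death = random_dates(y, m),
          icd10_underlying = sample(icd_codes, m, replace = TRUE),
          tox_substances = rep(list(d), m)
        )
        did <- did + m
      }
    }
  }

  tally <- mutate(tally, all_seizures = .data$single_seizures + .data$mixed_seizures)
  year_log <- tally |>
    mutate(sdli_true = theta[.data$drug] * .data$all_seizures) |>
    group_by(.data$year) |>
    summarise(sali_true = sum(.data$sdli_true),
              mechanistic_deaths = sum(.data$single_deaths),
              .groups = "drop")

  if (params$deaths_model == "linear_sqrt") {
    eps <- rnorm(length(years), 0, params$noise_sd)
    total <- as.integer(round(pmax(0, params$a + params$b * year_log$sali_true + eps)^2))
    extra <- total - year_log$mechanistic_deaths
    if (any(extra < 0)) {
      abort_config(paste0(
        "Infeasible death totals in year(s) ",
        paste(year_log$year[extra < 0], collapse = ", "),
        ": linear_sqrt total below mechanistic single-drug deaths. ",
        "Increase `a` or lower `true_lethality`."
      ))
    }
    for (i in seq_along(years)) {
      k <- extra[i]
      if (k == 0) next
      y <- year_log$year[i]
      intens_y <- filter(params$seizure_intensity, .data$year == y)
      avail <- setNames(intens_y$intensity[match(drugs, intens_y$drug)], drugs) *
        params$mix_weights
      first <- if (length(drugs) > 1 && sum(avail) > 0) {
        sample(drugs, k, replace = TRUE, prob = avail)
      } else rep(drugs[1], k)
      second <- sample_partners(as.list(first), drugs, avail)
      second[is.na(second)] <- "other:polydrug"
      tox <- Map(function(a1, a2) sort(unique(c(a1, a2))), first, second)
      death_acc[[length(death_acc) + 1L]] <- tibble(
        death_id = sprintf("D%07d", did + seq_len(k)),
        date_of_death = random_dates(y, k),
        icd10_underlying = sample(icd_codes, k, replace = TRUE),
        tox_substances = unname(tox)
      )
      did <- did + k
    }
    year_log$total_deaths <- total
  } else {
    year_log$total_deaths <- year_log$mechanistic_deaths
  }

  seizures <- if (length(seiz_acc)) bind_rows(seiz_acc) else
    tibble(seizure_id = character(), date = as.Date(character()),
           county = character(), substances = list())
  deaths <- if (length(death_acc)) bind_rows(death_acc) else
    tibble(death_id = character(), date_of_death = as.Date(character()),
           icd10_underlying = character(), tox_substances = list())

  structure(
    list(seizures = arrange(seizures, .data$seizure_id),
         deaths = arrange(deaths, .data$death_id),
         log = list(drug_year = tally, year = year_log),
         params = params),
    class = "market_sim"
  )
}

#' Ground-truth SALI series of a simulated market
#'
#' Computes the Summed Annual Lethality Index from the generator's true
#' per-drug lethality and the realized all-seizure tallies — not from
#' estimated lethality ratios — for use as ground truth in parameter
#' recovery checks.
#'
#' @param params The [market_params()] used for generation.
#' @param log The `log` element of a [generate_market()] result.
#' @return Tibble with columns `year` and `sali`.
#' @export
true_sali <- function(params, log) {
  log$drug_year |>
    mutate(sdli = params$true_lethality[.data$drug] * .data$all_seizures) |>
    group_by(.data$year) |>
    summarise(sali = sum(.data$sdli), .groups = "drop") |>
    arrange(.data$year)
}

#' Write a simulated market to disk
#'
#' Emits the exact CSV dialects consumed by [read_seizures()] and
#' [read_deaths()], plus the generator's tally log and a YAML echo of the
#' parameters for provenance.
#'
#' @param sim A `"market_sim"` from [generate_market()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_market <- function(sim, dir) {
  stopifnot(inherits(sim, "market_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    seizures = file.path(dir, "seizures.csv"),
    deaths = file.path(dir, "deaths.csv"),
    log_drug_year = file.path(dir, "generator_log.csv"),
    log_year = file.path(dir, "generator_log_year.csv"),
    params = file.path(dir, "params.yml")
  )
  write_seizures(sim$seizures, paths[["seizures"]])
  write_deaths(sim$deaths, paths[["deaths"]])
  readr::write_csv(sim$log$drug_year, paths[["log_drug_year"]])
  readr::write_csv(sim$log$year, paths[["log_year"]])
  p <- sim$params
  yaml::write_yaml(
    list(drugs = p$drugs, years = p$years,
         seizure_intensity = as.data.frame(p$seizure_intensity),
         true_lethality = as.list(p$true_lethality),
         p_mixed = p$p_mixed, p_third = p$p_third,
         mix_weights = as.list(p$mix_weights),
         deaths_model = p$deaths_model,
         a = p$a, b = p$b, noise_sd = p$noise_sd, rng_seed = p$rng_seed),
    paths[["params"]]
  )
  invisible(paths)
}
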