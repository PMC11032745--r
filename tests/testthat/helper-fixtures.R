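# Fixture builders shared across the suite. All fixtures are constructed in
# code; nothing is read from disk except files the tests write themselves.

make_seizures <- function(substances, years = 2017, ids = NULL,
                          county = "Franklin") {
  n <- length(substances)
  years <- rep_len(years, n)
  tibble::tibble(
    seizure_id = ids %||% sprintf("S%04d", seq_len(n)),
    date = as.Date(paste0(years, "-06-15")),
    county = rep_len(county, n),
    substances = lapply(substances, function(s) sort(unique(s)))
  )
}

make_deaths <- function(substances, years = 2017, icd = "X42", ids = NULL) {
  n <- length(substances)
  years <- rep_len(years, n)
  tibble::tibble(
    death_id = ids %||% sprintf("D%04d", seq_len(n)),
    date_of_death = as.Date(paste0(years, "-06-15")),
    icd10_underlying = rep_len(icd, n),
    tox_substances = lapply(substances, function(s) sort(unique(s)))
  )
}

`%||%` <- rlang::`%||%`

# Published reference-year summary counts: single-drug deaths and
# single-drug seizures per category in 2017.
reference_counts <- function() {
  tibble::tibble(
    drug = c("fentanyl", "cocaine", "prescription_opioids",
             "heroin", "amphetamines", "benzodiazepines"),
    single_deaths = c(1497L, 254L, 217L, 110L, 85L, 28L),
    single_seizures = c(3812L, 5781L, 3650L, 2486L, 9012L, 5437L)
  )
}

# Record sets whose 2017 single-drug counts equal reference_counts().
reference_records <- function() {
  rc <- reference_counts()
  seiz <- make_seizures(
    as.list(rep(rc$drug, rc$single_seizures)),
    ids = sprintf("S%06d", seq_len(sum(rc$single_seizures)))
  )
  icd <- paste0("X4", 0:4)
  nd <- sum(rc$single_deaths)
  deaths <- make_deaths(
    as.list(rep(rc$drug, rc$single_deaths)),
    icd = rep_len(icd, nd),
    ids = sprintf("D%06d", seq_len(nd))
  )
  list(seizures = seiz, deaths = deaths)
}

# Small three-drug market with a linear-sqrt death model; intensities rise
# linearly so SALI spans a modest range over 12 years.
small_market <- function(seed = 1L, deaths_model = "linear_sqrt") {
  drugs <- c("fentanyl", "cocaine", "heroin")
  years <- 2007:2018
  grid <- expand.grid(drug = drugs, year = years, stringsAsFactors = FALSE)
  grid$intensity <- rep(seq(250 / 3, 500 / 3, length.out = length(years)), each = 3)
  market_params(
    drugs = drugs, years = years, seizure_intensity = grid,
    true_lethality = c(fentanyl = 0.3, cocaine = 0.3, heroin = 0.3),
    p_mixed = 0.45, p_third = 0.15,
    deaths_model = deaths_model,
    a = 12, b = 0.0095, noise_sd = 0.3, rng_seed = seed
  )
}

# Exhaustive per-record scan used as the independent counting oracle.
brute_count <- function(records, subst_col, date_col, drug, year,
                        single_only = FALSE) {
  n <- 0L
  for (i in seq_len(nrow(records))) {
    s <- records[[subst_col]][[i]]
    y <- as.integer(format(records[[date_col]][i], "%Y"))
    if (y != year) next
    hit <- if (single_only) length(s) == 1L && s == drug else drug %in% s
    if (hit) n <- n + 1L
  }
  n
}
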