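#' Count single-drug deaths for one drug and year
#'
#' A single-drug death is an unintentional overdose death whose toxicology
#' lists exactly one drug category — the numerator of the lethality ratio.
#' Single-drug status is judged after category normalization and
#' deduplication, so two raw names mapping to the same category still count
#' as single-drug. With `ignore_other_substances = TRUE`, `"other:"`
#' categories (e.g. alcohol) are disregarded when judging single-drug
#' status.
#'
#' @param deaths Tibble of death records, already filtered with
#'   [filter_unintentional()].
#' @param drug A drug category label.
#' @param year Calendar year.
#' @param ignore_other_substances Ignore `"other:"` categories when
#'   determining single-drug status? Default `FALSE`: a fentanyl + alcohol
#'   death is not a single-drug fentanyl death.
#' @return Non-negative integer count.
#' @export
count_single_drug_deaths <- function(deaths, drug, year,
                                     ignore_other_substances = FALSE) {
  count_single(deaths$tox_substances, year_of(deaths$date_of_death),
               drug, year, ignore_other_substances)
}

#' Count single-drug seizures for one drug and year
#'
#' A single-drug (pure) seizure is a seizure event in which lab analysis
#' identified exactly one drug category — the denominator of the lethality
#' ratio.
#'
#' @param seizures Tibble of seizure records (see [read_seizures()]).
#' @inheritParams count_single_drug_deaths
#' @return Non-negative integer count.
#' @export
count_single_drug_seizures <- function(seizures, drug, year,
                                       ignore_other_substances = FALSE) {
  count_single(seizures$substances, year_of(seizures$date),
               drug, year, ignore_other_substances)
}

count_single <- function(substances, years, drug, year, ignore_other) {
  in_year <- years == year
  if (!any(in_year)) return(0L)
  sum(vapply(substances[in_year], function(s) {
    if (ignore_other) s <- s[!is_other_category(s)]
    length(s) == 1L && s == drug
  }, logical(1)))
}

# Vectorized one-pass tallies used by the table/series builders; equivalent
# to looping the scalar counters over every (drug, year) cell.
single_drug_tally <- function(substances, years, ignore_other = FALSE) {
  if (ignore_other) {
    substances <- lapply(substances, function(s) s[!is_other_category(s)])
  }
  one <- lengths(substances) == 1L
  tibble(drug = unlist(substances[one]), year = years[one]) |>
    count(.data$drug, .data$year, name = "n")
}

appearance_tally <- function(substances, years) {
  tibble(drug = unlist(substances), year = rep(years, lengths(substances))) |>
    count(.data$drug, .data$year, name = "n")
}

#' Count all seizures (single + mixed) of a drug in a year
#'
#' Counts every seizure event in which the drug was identified, whether
#' alone or alongside other substances. A mixed seizure containing k
#' analytic drugs contributes 1 to each of the k drugs' totals, so this
#' count is always at least the single-drug seizure count.
#'
#' @inheritParams count_single_drug_seizures
#' @return Non-negative integer count.
#' @export
count_all_seizures <- function(seizures, drug, year) {
  in_year <- year_of(seizures$date) == year
  if (!any(in_year)) return(0L)
  sum(vapply(seizures$substances[in_year], function(s) drug %in% s, logical(1)))
}

#' Lethality ratio
#'
#' Deaths per seizure for one drug in the reference year: single-drug
#' deaths divided by single-drug seizures. The quotient is kept at full
#' floating precision; reporting layers round to 3 decimals,
#' half-away-from-zero (see [format_lethality_table()]).
#'
#' @param single_deaths Non-negative integer count of single-drug deaths.
#' @param single_seizures Positive integer count of single-drug seizures.
#' @param drug Optional drug label used in the error message when
#'   `single_seizures` is zero.
#' @return Non-negative real, deaths per seizure.
#' @export
#' @examples
#' lethality_ratio(1497, 3812) # 0.3927... -> prints as 0.393
lethality_ratio <- function(single_deaths, single_seizures, drug = NULL) {
  if (any(single_seizures <= 0)) {
    abort_degenerate(paste0(
      "Lethality ratio undefined: zero single-drug seizures",
      if (!is.null(drug)) paste0(" for ", paste(drug[single_seizures <= 0], collapse = ", ")),
      "."
    ))
  }
  if (any(single_deaths < 0)) abort_data("Negative death count.")
  single_deaths / single_seizures
}

#' Build the per-drug lethality table for a reference year
#'
#' Computes, for each requested drug, the reference-year single-drug death
#' count, single-drug seizure count and lethality ratio. Drugs with zero
#' single-drug seizures in the reference year are excluded with a warning
#' rather than assigned a ratio, since no lethality can be estimated for
#' them.
#'
#' @param deaths Tibble of death records, already filtered with
#'   [filter_unintentional()].
#' @param seizures Tibble of seizure records.
#' @param reference_year Calendar year on which ratios are computed
#'   (the published analysis uses 2017, the peak mortality year).
#' @param drugs Character vector of drug categories to index; defaults to
#'   the six of [analytic_drugs()].
#' @param ignore_other_substances Passed to the single-drug counters.
#' @return A tibble with columns `drug`, `single_deaths`, `single_seizures`
#'   and `lr`, one row per retained drug, carrying the reference year as
#'   attribute `reference_year` and class `"lethality_table"`.
#' @export
build_lethality_table <- function(deaths, seizures, reference_year,
                                  drugs = analytic_drugs(),
                                  ignore_other_substances = FALSE) {
  if (length(drugs) == 0) abort_config("`drugs` must name at least one category.")
  if (anyDuplicated(tolower(drugs))) abort_config("`drugs` contains duplicates.")
  drugs <- tolower(drugs)

  dtal <- single_drug_tally(deaths$tox_substances, year_of(deaths$date_of_death),
                            ignore_other_substances)
  stal <- single_drug_tally(seizures$substances, year_of(seizures$date),
                            ignore_other_substances)
  lookup <- function(tal, d) {
    n <- tal$n[tal$drug == d & tal$year == reference_year]
    if (length(n) == 0) 0L else n
  }
  tab <- tibble(
    drug = drugs,
    single_deaths = unname(vapply(drugs, lookup, integer(1), tal = dtal)),
    single_seizures = unname(vapply(drugs, lookup, integer(1), tal = stal))
  )
  zero <- tab$single_seizures == 0
  if (any(zero)) {
    warn(paste0(
      "Excluding drug(s) with zero single-drug seizures in ", reference_year,
      ": ", paste(tab$drug[zero], collapse = ", ")
    ))
    tab <- tab[!zero, ]
  }
  if (nrow(tab) == 0) {
    abort_degenerate(paste0("No drug has single-drug seizures in ", reference_year, "."))
  }
  tab$lr <- lethality_ratio(tab$single_deaths, tab$single_seizures, tab$drug)
  structure(tab, reference_year = as.integer(reference_year),
            class = c("lethality_table", class(tab)))
}

#' Format a lethality table for reporting
#'
#' Returns the table with ratios rounded to 3 decimals, half away from
#' zero, matching how published summary tables present them (e.g.
#' 254/5781 = 0.0439... prints as 0.044). The pipeline itself always uses
#' full-precision ratios.
#'
#' @param table A `lethality_table` from [build_lethality_table()].
#' @param digits Decimal places (default 3).
#' @return Tibble with `lr` rounded.
#' @export
format_lethality_table <- function(table, digits = 3) {
  mutate(as_tibble(table), lr = round_half_away(.data$lr, digits))
}

#' Per-drug-year Street-Drug Lethality Index (SDLI)
#'
#' For each drug in the lethality table and each requested year, multiplies
#' the drug's reference-year lethality ratio by its total annual seizure
#' count (single + mixed). Frequency of seizure acts as a proxy for
#' street-level availability, so SDLI scales each drug's availability by
#' its lethality.
#'
#' @param table A `lethality_table` from [build_lethality_table()].
#' @param seizures Tibble of seizure records covering the analysis years.
#' @param years Integer vector of calendar years.
#' @return Long tibble with columns `drug`, `year`, `all_seizures`, `sdli`.
#' @export
compute_sdli <- function(table, seizures, years) {
  if (length(years) == 0) abort_config("`years` must be non-empty.")
  if (nrow(table) == 0) abort_config("Lethality table is empty.")
  tal <- appearance_tally(seizures$substances, year_of(seizures$date))
  grid <- tidyr::expand_grid(drug = table$drug, year = as.integer(sort(unique(years)))) |>
    left_join(tal, by = c("drug", "year")) |>
    mutate(all_seizures = as.integer(dplyr::coalesce(.data$n, 0L))) |>
    select(-"n")
  grid$sdli <- table$lr[match(grid$drug, table$drug)] * grid$all_seizures
  grid
}

#' Summed Annual Lethality Index (SALI) series
#'
#' Sums the per-drug SDLI values within each year to produce the annual
#' index used as the regression predictor. Only drugs present in the
#' lethality table contribute; deaths enter only through the
#' reference-year ratios, so year-to-year variation in SALI reflects the
#' seizure record alone.
#'
#' @inheritParams compute_sdli
#' @return Tibble with columns `year` and `sali`, one row per year, with
#'   the per-drug SDLI detail in attribute `sdli`, the contributing drugs
#'   in `drugs_included`, and class `"sali_series"`.
#' @export
#' @examples
#' # one drug, lr = 0.5, 10 seizures in the year -> SALI = 5
compute_sali_series <- function(table, seizures, years) {
  sdli <- compute_sdli(table, seizures, years)
  out <- sdli |>
    group_by(.data$year) |>
    summarise(sali = sum(.data$sdli), .groups = "drop") |>
    arrange(.data$year)
  structure(out,
            sdli = sdli,
            drugs_included = table$drug,
            reference_year = attr(table, "reference_year"),
            class = c("sali_series", class(out)))
}

#' Annual unintentional overdose death totals
#'
#' Counts death records per calendar year. Records should already be
#' filtered with [filter_unintentional()]. With
#' `scope = "indexed_drugs_only"`, only deaths whose toxicology involves at
#' least one of `drugs` are counted; the default counts all unintentional
#' overdose deaths regardless of substance.
#'
#' @param deaths Tibble of death records (filtered).
#' @param years Integer vector of calendar years to report (zero-filled
#'   when no deaths occurred).
#' @param scope `"all_unintentional"` (default) or `"indexed_drugs_only"`.
#' @param drugs Drug categories defining the indexed scope.
#' @return Tibble with columns `year` and `deaths`.
#' @export
annual_deaths <- function(deaths, years,
                          scope = c("all_unintentional", "indexed_drugs_only"),
                          drugs = analytic_drugs()) {
  scope <- arg_match(scope)
  if (scope == "indexed_drugs_only") {
    keep <- vapply(deaths$tox_substances,
                   function(s) any(s %in% drugs), logical(1))
    deaths <- deaths[keep, ]
  }
  yr <- year_of(deaths$date_of_death)
  years <- as.integer(sort(unique(years)))
  tibble(
    year = years,
    deaths = vapply(years, function(y) sum(yr == y), integer(1))
  )
}
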