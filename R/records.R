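#' Build a substance mapping
#'
#' A substance mapping translates raw substance names as they appear in
#' seizure lab results or toxicology reports (e.g. `"Oxycodone"`,
#' `"methamphetamine"`) into the analytic drug categories of
#' [analytic_drugs()]. Lookups are case-insensitive and whitespace-trimmed.
#' Names absent from the table are handled by `unmapped_policy`:
#' `"keep_as_other"` carries them as `"other:<name>"` categories,
#' `"drop"` discards them, and `"error"` fails naming the offending string.
#'
#' @param x Path to a two-column CSV (`raw_name,category`) or a data frame
#'   with those columns. `NULL` (default) loads the mapping shipped with the
#'   package, which covers common street and pharmaceutical names.
#' @param unmapped_policy How to treat raw names not in the table.
#' @return A tibble with columns `raw_name`, `category` and class
#'   `"substance_mapping"`; the policy is stored as an attribute.
#' @export
#' @examples
#' m <- substance_mapping()
#' normalize_substance(c("Fentanyl ", "oxycodone"), m)
substance_mapping <- function(x = NULL,
                              unmapped_policy = c("keep_as_other", "drop", "error")) {
  unmapped_policy <- arg_match(unmapped_policy)
  if (is.null(x)) {
    x <- system.file("extdata", "substance_mapping.csv", package = "sdli")
  }
  if (is.character(x)) {
    if (!file.exists(x)) abort_config(paste0("Mapping file not found: ", x))
    x <- readr::read_csv(x, col_types = readr::cols(.default = readr::col_character()))
  }
  x <- as_tibble(x)
  missing_cols <- setdiff(c("raw_name", "category"), names(x))
  if (length(missing_cols) > 0) {
    abort_format(paste0(
      "Substance mapping must have columns raw_name, category; missing: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  x <- x |>
    mutate(
      raw_name = tolower(trimws(.data$raw_name)),
      category = tolower(trimws(.data$category))
    )
  dup <- x$raw_name[duplicated(x$raw_name)]
  if (length(dup) > 0) {
    abort_format(paste0(
      "Raw names map to more than one category: ",
      paste(unique(dup), collapse = ", ")
    ))
  }
  bad <- setdiff(unique(x$category), c(.analytic_drugs)) |>
    (\(v) v[!is_other_category(v)])()
  if (length(bad) > 0) {
    abort_format(paste0(
      "Unknown target categories in mapping: ", paste(bad, collapse = ", ")
    ))
  }
  structure(x, unmapped_policy = unmapped_policy,
            class = c("substance_mapping", class(x)))
}

#' Normalize raw substance names to drug categories
#'
#' Case-insensitive, whitespace-trimmed lookup of raw substance names in a
#' [substance_mapping()]. Unmapped names are resolved per the mapping's
#' policy: kept as `"other:<name>"`, dropped (returned as `NA`), or raised
#' as a configuration error.
#'
#' @param raw Character vector of raw substance names.
#' @param mapping A [substance_mapping()].
#' @return Character vector of category labels; `NA` marks dropped names.
#' @export
normalize_substance <- function(raw, mapping) {
  if (!inherits(mapping, "substance_mapping")) {
    abort_config("`mapping` must be created with substance_mapping().")
  }
  if (any(!nzchar(trimws(raw)))) {
    abort_data("Empty substance name encountered.")
  }
  key <- tolower(trimws(raw))
  idx <- match(key, mapping$raw_name)
  out <- mapping$category[idx]
  unmapped <- is.na(idx)
  # Already-normalized tokens pass through regardless of the mapping table,
  # so category-level files round-trip under any mapping.
  passthrough <- unmapped & (key %in% .analytic_drugs | is_other_category(key))
  out[passthrough] <- key[passthrough]
  unmapped <- unmapped & !passthrough
  if (any(unmapped)) {
    policy <- attr(mapping, "unmapped_policy")
    if (policy == "error") {
      abort_config(paste0(
        "Unmapped substance name(s): ",
        paste(unique(key[unmapped]), collapse = ", ")
      ))
    } else if (policy == "keep_as_other") {
      out[unmapped] <- paste0("other:", gsub("\\s+", "_", key[unmapped]))
    } # "drop": leave NA
  }
  out
}

# Shared reader for the two record dialects. `substances` raw names are
# pipe-delimited within the field.
read_records <- function(path, mapping, id_col, date_col, subst_col, extra_cols) {
  if (!file.exists(path)) abort_data(paste0("File not found: ", path))
  required <- c(id_col, date_col, subst_col, extra_cols)
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols()))
  missing_cols <- setdiff(setdiff(required, "county"), header)
  if (length(missing_cols) > 0) {
    abort_format(paste0(
      "Missing required column(s) in ", basename(path), ": ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  n_in <- nrow(raw)

  dates <- as.Date(raw[[date_col]], format = "%Y-%m-%d")
  bad <- which(is.na(dates))
  if (length(bad) > 0) {
    abort_rows(
      paste0("Unparseable ", date_col, " in row(s): ",
             paste(head(bad, 20), collapse = ", "),
             if (length(bad) > 20) " ..." else ""),
      rows = bad
    )
  }

  pieces <- strsplit(raw[[subst_col]] %|% "", "|", fixed = TRUE)
  flat <- trimws(unlist(pieces))
  row_idx <- rep(seq_along(pieces), lengths(pieces))
  keep <- nzchar(flat)
  flat <- flat[keep]
  row_idx <- row_idx[keep]
  norm <- normalize_substance(flat, mapping)
  ok <- !is.na(norm)
  grouped <- split(norm[ok], factor(row_idx[ok], levels = seq_along(pieces)))
  subst <- lapply(unname(grouped), function(s) sort(unique(s)))

  out <- tibble(
    !!id_col := raw[[id_col]],
    !!date_col := dates
  )
  for (col in extra_cols) {
    out[[col]] <- if (col %in% names(raw)) raw[[col]] else NA_character_
  }
  out[[subst_col]] <- subst

  empty <- n_categories(out[[subst_col]]) == 0
  if (any(empty)) {
    warn(paste0(sum(empty), " record(s) dropped: empty substance set after mapping."))
    out <- out[!empty, ]
  }

  if (anyDuplicated(out[[id_col]])) {
    warn(paste0("Duplicate ", id_col, " rows merged into single records."))
    out <- out |>
      group_by(across(all_of(id_col))) |>
      summarise(
        across(all_of(c(date_col, extra_cols)), ~ .x[1]),
        !!subst_col := list(sort(unique(unlist(.data[[subst_col]])))),
        .groups = "drop"
      )
  }
  out <- arrange(out, .data[[id_col]])
  inform(paste0("Read ", n_in, " row(s) from ", basename(path), "; kept ",
                nrow(out), " record(s)."))
  out
}

`%|%` <- function(x, y) ifelse(is.na(x), y, x)

#' Read seizure records
#'
#' Reads a case-level seizure CSV (columns `seizure_id`, `date`, `county`,
#' `substances`; `substances` pipe-delimited raw names, dates ISO-8601) and
#' normalizes raw substance names to drug categories via the mapping.
#' Substance sets are deduplicated per record, so a seizure listing two raw
#' names that map to the same category is a single-drug seizure. Duplicate
#' `seizure_id` rows are merged (union of substances) with a warning;
#' records whose substance set is empty after mapping are dropped with a
#' warning.
#'
#' @param path Path to the seizure CSV.
#' @param mapping A [substance_mapping()]; default mapping if omitted.
#' @return Tibble with columns `seizure_id` (character), `date` (Date),
#'   `county` (character) and `substances` (list-column of sorted category
#'   vectors), one row per seizure event.
#' @export
read_seizures <- function(path, mapping = substance_mapping()) {
  read_records(path, mapping,
               id_col = "seizure_id", date_col = "date",
               subst_col = "substances", extra_cols = "county")
}

#' Read overdose death records
#'
#' Reads a case-level death-record CSV (columns `death_id`, `date_of_death`,
#' `icd10_underlying`, `tox_substances`) and normalizes toxicology substance
#' names to drug categories. No cause-of-death filtering is applied at read
#' time; use [filter_unintentional()] for the ICD-10 X40-X44 filter.
#'
#' @inheritParams read_seizures
#' @return Tibble with columns `death_id`, `date_of_death` (Date),
#'   `icd10_underlying` (character) and `tox_substances` (list-column),
#'   one row per decedent.
#' @export
read_deaths <- function(path, mapping = substance_mapping()) {
  read_records(path, mapping,
               id_col = "death_id", date_col = "date_of_death",
               subst_col = "tox_substances", extra_cols = "icd10_underlying")
}

#' Write seizure or death records
#'
#' Inverse of [read_seizures()] / [read_deaths()]: serializes the
#' list-column of substances back to pipe-delimited fields so that a write
#' followed by a read reproduces the records field-for-field.
#'
#' @param records Tibble as returned by the corresponding reader.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_seizures <- function(records, path) {
  out <- records |>
    mutate(substances = vapply(.data$substances, paste, "", collapse = "|")) |>
    select(all_of(c("seizure_id", "date", "county", "substances")))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_seizures
#' @export
write_deaths <- function(records, path) {
  out <- records |>
    mutate(tox_substances = vapply(.data$tox_substances, paste, "", collapse = "|")) |>
    select(all_of(c("death_id", "date_of_death", "icd10_underlying", "tox_substances")))
  readr::write_csv(out, path)
  invisible(path)
}

#' Filter deaths to unintentional drug overdoses
#'
#' Retains exactly the death records whose underlying cause of death is an
#' ICD-10 accidental drug poisoning code X40-X44. Matching is on the first
#' three characters, case-insensitive, so registry exports with decimal
#' suffixes (`"X42.1"`) are accepted. The operation is idempotent and its
#' output is always a subset of its input.
#'
#' @param deaths Tibble of death records (see [read_deaths()]).
#' @return The subset of `deaths` with unintentional-overdose underlying
#'   cause.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   death_id = c("D1", "D2"),
#'   date_of_death = as.Date(c("2017-06-01", "2017-06-02")),
#'   icd10_underlying = c("X42", "X60"),
#'   tox_substances = list("heroin", "fentanyl")
#' )
#' filter_unintentional(d)
filter_unintentional <- function(deaths) {
  code3 <- toupper(substr(trimws(deaths$icd10_underlying), 1, 3))
  deaths[code3 %in% paste0("X4", 0:4), ]
}
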