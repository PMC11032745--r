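#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis in one validated object
#' that round-trips losslessly through YAML (see [read_config()] /
#' [write_config()]).
#'
#' @param seizures,deaths Paths to the seizure and death record CSVs.
#' @param out_dir Directory for all outputs (created if needed).
#' @param mapping Optional path to a substance-mapping CSV; `NULL` uses the
#'   mapping shipped with the package.
#' @param reference_year Year on which lethality ratios are computed.
#' @param years Analysis years for the SALI series and regression; `NULL`
#'   uses every year present in the seizure records.
#' @param drugs Drug categories to index.
#' @param ci_level Confidence level for slope inference.
#' @param unmapped_policy Policy for substances missing from the mapping.
#' @param ignore_other_substances Ignore `"other:"` categories when judging
#'   single-drug status?
#' @param deaths_scope Count `"all_unintentional"` deaths as the dependent
#'   variable, or only `"indexed_drugs_only"` deaths.
#' @return A list of class `"sdli_config"`.
#' @export
sdli_config <- function(seizures, deaths, out_dir, mapping = NULL,
                        reference_year = 2017, years = NULL,
                        drugs = analytic_drugs(), ci_level = 0.95,
                        unmapped_policy = "keep_as_other",
                        ignore_other_substances = FALSE,
                        deaths_scope = c("all_unintentional", "indexed_drugs_only")) {
  deaths_scope <- arg_match(deaths_scope)
  if (!is.numeric(ci_level) || ci_level <= 0 || ci_level >= 1) {
    abort_config("`ci_level` must be in (0, 1).")
  }
  structure(
    list(seizures = seizures, deaths = deaths, out_dir = out_dir,
         mapping = mapping, reference_year = as.integer(reference_year),
         years = if (!is.null(years)) as.integer(years),
         drugs = tolower(drugs), ci_level = ci_level,
         unmapped_policy = unmapped_policy,
         ignore_other_substances = isTRUE(ignore_other_substances),
         deaths_scope = deaths_scope),
    class = "sdli_config"
  )
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file path.
#' @return `read_config()` returns an `"sdli_config"`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("Config file not found: ", path))
  x <- yaml::read_yaml(path)
  do.call(sdli_config, x[!vapply(x, is.null, logical(1))])
}

#' @rdname read_config
#' @param config An `"sdli_config"` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sdli_config"))
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

with_stage <- function(stage, expr) {
  withCallingHandlers(
    expr,
    error = function(e) {
      abort(
        paste0("Pipeline stage '", stage, "' failed: ", conditionMessage(e)),
        class = c("sdli_stage_error", class(e)[startsWith(class(e), "sdli_")]),
        stage = stage, parent = e
      )
    }
  )
}

#' Run the full lethality-index pipeline
#'
#' Executes read, ICD-10 filtering, lethality-table construction, SALI
#' computation, regression fitting, diagnostics and report rendering from a
#' single configuration, persisting every intermediate so each reported
#' number is traceable to a CSV. The pipeline is a pure function of the
#' configuration and input files: identical inputs give identical tabular
#' outputs.
#'
#' Outputs written to `out_dir`: `lethality_table.csv`, `sdli.csv`,
#' `sali.csv`, `fit_summary.csv`, `diagnostics.csv`,
#' `predicted_observed.csv` (figure data sidecar), `predicted_observed.png`,
#' three residual plot PNGs, and `run_log.txt`.
#'
#' @param config An [sdli_config()] (or path to a YAML config).
#' @return Invisibly, a list with the fitted objects (`table`, `sali`,
#'   `fit`, `diagnostics`) and `paths` (named vector of output files).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "sdli_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log_lines <- character()
  note <- function(...) {
    msg <- paste0(...)
    inform(msg)
    log_lines <<- c(log_lines, msg)
  }

  mapping <- with_stage("mapping", substance_mapping(
    config$mapping, unmapped_policy = config$unmapped_policy))

  seizures <- with_stage("read_seizures", read_seizures(config$seizures, mapping))
  deaths_all <- with_stage("read_deaths", read_deaths(config$deaths, mapping))
  note("Read ", nrow(seizures), " seizure and ", nrow(deaths_all), " death records.")

  deaths <- with_stage("filter_unintentional", filter_unintentional(deaths_all))
  note("Retained ", nrow(deaths), " unintentional overdose deaths (ICD-10 X40-X44) of ",
       nrow(deaths_all), ".")

  years <- config$years %||% sort(unique(year_of(seizures$date)))

  table <- with_stage("build_lethality_table", build_lethality_table(
    deaths, seizures, config$reference_year, config$drugs,
    ignore_other_substances = config$ignore_other_substances))
  note("Lethality table (reference year ", config$reference_year, "): ",
       nrow(table), " drug(s).")

  sali <- with_stage("compute_sali_series",
                     compute_sali_series(table, seizures, years))
  obs <- with_stage("annual_deaths", annual_deaths(
    deaths, years, scope = config$deaths_scope, drugs = config$drugs))

  fit_data <- left_join(as_tibble(sali), obs, by = "year")
  fit <- with_stage("fit_sali_regression",
                    fit_sali_regression(fit_data, ci_level = config$ci_level))
  note(sprintf("Fit: slope %.6f, r^2 %.3f, Durbin-Watson %.3f over %d years.",
               fit$slope, fit$r_squared, fit$durbin_watson, nrow(fit$data)))

  diag <- with_stage("residual_diagnostics", residual_diagnostics(fit, dir = out))
  aug <- augment(fit)

  paths <- c(
    lethality_table = file.path(out, "lethality_table.csv"),
    sdli = file.path(out, "sdli.csv"),
    sali = file.path(out, "sali.csv"),
    fit_summary = file.path(out, "fit_summary.csv"),
    diagnostics = file.path(out, "diagnostics.csv"),
    prediction_data = file.path(out, "predicted_observed.csv"),
    prediction_figure = file.path(out, "predicted_observed.png"),
    diag$paths,
    run_log = file.path(out, "run_log.txt")
  )
  readr::write_csv(format_lethality_table(table), paths[["lethality_table"]])
  readr::write_csv(attr(sali, "sdli"), paths[["sdli"]])
  readr::write_csv(as_tibble(sali), paths[["sali"]])
  readr::write_csv(tidy(fit), paths[["fit_summary"]])
  readr::write_csv(aug, paths[["diagnostics"]])

  with_stage("render_prediction_figure", render_prediction_figure(
    tibble(year = aug$year, deaths = aug$observed_deaths),
    setNames(aug$predicted_deaths, aug$year),
    paths[["prediction_figure"]],
    sidecar = paths[["prediction_data"]]
  ))
  writeLines(log_lines, paths[["run_log"]])
  invisible(list(table = table, sali = sali, fit = fit,
                 diagnostics = diag, paths = paths))
}

#' Plot observed vs model-predicted annual deaths
#'
#' @param observed Data frame with columns `year`, `deaths`.
#' @param predicted Data frame with columns `year`, `predicted`.
#' @return A ggplot with paired bars per year.
#' @export
plot_predicted_observed <- function(observed, predicted) {
  df <- tibble(
    year = rep(observed$year, 2),
    series = rep(c("Observed", "Predicted"), each = nrow(observed)),
    deaths = c(observed$deaths, predicted$predicted)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$year), y = .data$deaths,
                                   fill = .data$series)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::scale_fill_manual(values = c(Observed = "grey30", Predicted = "steelblue")) +
    ggplot2::labs(x = "Year", y = "Unintentional overdose deaths", fill = NULL,
                  title = "Predicted and observed unintentional overdose deaths")
}

#' Render the predicted-vs-observed figure with its data sidecar
#'
#' Writes a paired observed/predicted bar chart and a sidecar CSV holding
#' exactly the numbers plotted, so downstream checks never need to read
#' pixels.
#'
#' @param observed Data frame with columns `year`, `deaths`.
#' @param predicted Named numeric vector (names = years) or data frame with
#'   columns `year`, `predicted`.
#' @param path PNG output path.
#' @param sidecar CSV output path; default replaces the image extension.
#' @return `path`, invisibly.
#' @export
render_prediction_figure <- function(observed, predicted, path,
                                     sidecar = sub("\\.[a-z]+$", ".csv", path)) {
  if (is.numeric(predicted)) {
    predicted <- tibble(year = as.integer(names(predicted)), predicted = unname(predicted))
  }
  if (!setequal(observed$year, predicted$year)) {
    abort_data("Observed and predicted year sets do not match.")
  }
  df <- left_join(as_tibble(observed), as_tibble(predicted), by = "year") |>
    arrange(.data$year)
  readr::write_csv(df, sidecar)
  p <- plot_predicted_observed(df, df)
  ggplot2::ggsave(path, p, width = 7, height = 4.5, dpi = 120)
  invisible(path)
}
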