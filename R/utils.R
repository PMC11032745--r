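# Internal helpers shared across modules.

# Round half away from zero (report-layer rounding; base round() is banker's).
round_half_away <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Calendar year of a Date vector.
year_of <- function(date) {
  as.integer(format(date, "%Y"))
}

# Number of drug categories a record involves, optionally ignoring
# "other:" categories. `substances` is a list-column of character vectors.
n_categories <- function(substances, ignore_other = FALSE) {
  vapply(substances, function(s) {
    if (ignore_other) s <- s[!is_other_category(s)]
    length(s)
  }, integer(1))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so simulation calls do not perturb user code.
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Structured error helpers: condition classes let the CLI map failures to
# exit codes and let tests assert on the failure mode, not the message.
abort_format <- function(msg, ...) abort(msg, class = "sdli_format_error", ...)
abort_rows <- function(msg, ...) abort(msg, class = "sdli_row_error", ...)
abort_config <- function(msg, ...) abort(msg, class = "sdli_config_error", ...)
abort_data <- function(msg, ...) abort(msg, class = "sdli_data_error", ...)
abort_degenerate <- function(msg, ...) abort(msg, class = "sdli_degenerate_error", ...)
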