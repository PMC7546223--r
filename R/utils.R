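#' Round half away from zero
#'
#' Rounds to the nearest integer (or to `digits` decimal places) with halves
#' rounded away from zero, the convention used for percentage presentation in
#' clinical validation reports (e.g. 91.5 -> 92).  Base `round()` uses
#' round-half-even, which would turn 92.5 into 92.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep (default 0).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' round_half_up(c(0.5, 1.5, 2.5))
#' round_half_up(91.95, 1)
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Integer-percent label used in report tables: "92%" style.
percent_label <- function(x) {
  paste0(round_half_up(x), "%")
}

# Checks that a data frame carries the required columns; aborts otherwise.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), class = "panelval_column_error")
  }
  invisible(df)
}

# Validates that a named numeric vector is a proper probability distribution.
check_distribution <- function(p, what, tol = 1e-9) {
  if (is.null(names(p)) || any(!nzchar(names(p)))) {
    abort(sprintf("%s must be a named numeric vector", what),
          class = "panelval_config_error")
  }
  if (any(p < 0) || abs(sum(p) - 1) > tol) {
    abort(sprintf("%s must be non-negative and sum to 1 (got %.6f)",
                  what, sum(p)),
          class = "panelval_config_error")
  }
  invisible(p)
}
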