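# Shared helpers: validation and the quantile positivity rule used by both
# the immune score and the HRDPS call.

MB <- 1e6
DAYS_PER_MONTH <- 30.44

#' Flag values strictly above an empirical quantile
#'
#' Positivity rule shared by the immune score ("highest 25%") and the HRDPS
#' call: a sample is positive iff its score lies strictly above the
#' linear-interpolation (type 7) quantile of the cohort. With all-tied scores
#' nothing is positive.
#'
#' @param scores Numeric vector of per-sample scores.
#' @param quantile Fraction in (0, 1); default 0.75 marks the top quartile.
#' @return Logical vector, `NA` where `scores` is `NA`.
#' @export
call_quantile_positive <- function(scores, quantile = 0.75) {
  stopifnot(is.numeric(scores), length(quantile) == 1L,
            quantile > 0, quantile < 1)
  if (sum(!is.na(scores)) < 4L) {
    stop("need at least 4 non-missing scores for a quantile positivity call")
  }
  cut <- stats::quantile(scores, probs = quantile, na.rm = TRUE,
                         names = FALSE, type = 7)
  scores > cut
}

# internal: stop with the offending field named
.check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single fraction in [0, 1]", name))
  }
  invisible(x)
}

.check_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x) &&
    (if (positive) x > 0 else x >= 0)
  if (!ok) stop(sprintf("'%s' must be a %s integer", name,
                        if (positive) "positive" else "non-negative"))
  invisible(as.integer(x))
}

.check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")))
  }
  invisible(df)
}
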