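#' Round to significant figures, the way the source tables print rates
#'
#' Thin wrapper around [base::signif()] used at the reporting layer only;
#' estimators never round internally.
#'
#' @param x numeric vector.
#' @param digits significant figures (default 2, matching the printed tables).
#' @return numeric vector rounded to `digits` significant figures.
#' @export
report_signif <- function(x, digits = 2) signif(x, digits = digits)

#' Population variance (divide by n)
#'
#' Fluctuation-test summary tables in this field use the population
#' convention, not the n - 1 sample estimator.
#'
#' @param x numeric vector.
#' @return mean squared deviation from the mean.
#' @export
pop_var <- function(x) mean((x - mean(x))^2)

# run `expr` under a fixed seed when one is supplied, untouched otherwise
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

assert_columns <- function(data, cols, call = rlang::caller_env()) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("missing required column(s): ", paste(missing, collapse = ", ")),
      call = call
    )
  }
  invisible(data)
}
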