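#' Predicted plasmid-bearing frequency across serial transfers
#'
#' Forward model of a pairwise competition under serial transfer: the
#' frequency `q` of plasmid-bearing cells obeys
#' \eqn{dq/dt = -q(1-q)s} with time in generations, whose closed-form
#' solution is linear on the logit scale,
#' \eqn{\mathrm{logit}(q_n) = \mathrm{logit}(q_0) - s\,g\,n} after `n`
#' transfers of `g` generations each. By the sign convention used
#' throughout, `s > 0` means the plasmid-bearing competitor is at a
#' disadvantage (its frequency falls). The endpoints `q0 = 0` and `q0 = 1`
#' are absorbing.
#'
#' @param q0 starting frequency in \[0, 1\].
#' @param s selection coefficient per generation.
#' @param n_transfers number of serial transfers.
#' @param gens_per_transfer generations per transfer; the default 6.64 is
#'   log2(100), i.e. regrowth after a 1/100 dilution.
#' @return a tibble with columns `transfer` (0..`n_transfers`) and `q`.
#' @examples
#' predict_frequency(0.5, s = 0.05, n_transfers = 5)
#' @export
predict_frequency <- function(q0, s, n_transfers,
                              gens_per_transfer = log2(100)) {
  if (q0 < 0 || q0 > 1) abort("`q0` must be in [0, 1]")
  if (n_transfers < 0) abort("`n_transfers` must be >= 0")
  transfers <- seq(0L, as.integer(n_transfers))
  q <- if (q0 == 0 || q0 == 1 || s == 0) {
    rep(q0, length(transfers)) # absorbing endpoints; exact neutrality
  } else {
    plogis(qlogis(q0) - s * gens_per_transfer * transfers)
  }
  tibble(transfer = transfers, q = q)
}

#' Estimate a selection coefficient from a competition trajectory
#'
#' Inverts the forward model of [predict_frequency()]: ordinary
#' least-squares regression of logit(q) on cumulative generations, with the
#' selection coefficient taken as minus the slope. Frequencies of exactly 0
#' or 1 have no logit and are dropped with a warning. The fit is classified
#' as `"neutral"` when |s| falls below `neutral_threshold` or the 95%
#' confidence interval spans zero, `"cost"` when s > 0 (plasmid-bearing
#' cells declining) and `"advantage"` when s < 0.
#'
#' @param traj data frame with columns `transfer` and `q`, or with
#'   `transfer`, `total` and `plasmid_bearing` colony counts (then
#'   `q = plasmid_bearing / total`).
#' @param gens_per_transfer generations per transfer (default log2(100)).
#' @param neutral_threshold |s| below which a fit is called neutral even
#'   with a tight confidence interval (default 0.01 per generation).
#' @return an object of class `selection_fit`; see [tidy.selection_fit()]
#'   and [glance.selection_fit()].
#' @examples
#' traj <- predict_frequency(0.5, s = 0.05, n_transfers = 5)
#' estimate_s(traj)
#' @export
estimate_s <- function(traj, gens_per_transfer = log2(100),
                       neutral_threshold = 0.01) {
  assert_columns(traj, "transfer")
  if (!"q" %in% names(traj)) {
    assert_columns(traj, c("total", "plasmid_bearing"))
    traj <- mutate(traj, q = .data$plasmid_bearing / .data$total)
  }
  if (any(traj$q < 0 | traj$q > 1)) abort("`q` must be in [0, 1]")
  if (is.unsorted(traj$transfer, strictly = TRUE)) {
    abort("`transfer` must be strictly increasing")
  }
  interior <- traj$q > 0 & traj$q < 1
  if (any(!interior)) {
    warn("dropping frequencies of exactly 0 or 1 (logit undefined)")
  }
  kept <- traj[interior, ]
  if (nrow(kept) < 2) {
    abort("need at least 2 transfer points with q strictly inside (0, 1)")
  }
  gens <- kept$transfer * gens_per_transfer
  fit <- lm(qlogis(kept$q) ~ gens)
  est <- summary(fit)$coefficients
  s_hat <- -est["gens", "Estimate"]
  se <- est["gens", "Std. Error"]
  ci <- s_hat + c(-1, 1) * stats::qt(0.975, fit$df.residual) * se
  classification <- if (abs(s_hat) <= neutral_threshold ||
                          (is.finite(se) && ci[1] < 0 && ci[2] > 0)) {
    "neutral"
  } else if (s_hat > 0) {
    "cost"
  } else {
    "advantage"
  }
  structure(
    list(
      s_hat = s_hat, se = se, ci = ci, classification = classification,
      gens_per_transfer = gens_per_transfer,
      neutral_threshold = neutral_threshold,
      n_points = nrow(kept), n_dropped = sum(!interior),
      data = as_tibble(kept), lm_fit = fit
    ),
    class = "selection_fit"
  )
}

#' @export
print.selection_fit <- function(x, ...) {
  cat(sprintf(
    "Selection coefficient: s = %.4g per generation (SE %.3g), %s\n",
    x$s_hat, x$se, x$classification
  ))
  cat(sprintf(
    "  %d transfer points, %.3g generations per transfer\n",
    x$n_points, x$gens_per_transfer
  ))
  invisible(x)
}

#' Tidy a selection-coefficient fit
#'
#' @param x a `selection_fit` from [estimate_s()].
#' @param ... unused.
#' @return `tidy()`: one-row tibble with the estimate, its standard error
#'   and confidence interval, and the classification. `glance()`: one-row
#'   tibble of fit-level summaries.
#' @export
tidy.selection_fit <- function(x, ...) {
  tibble(
    term = "s", estimate = x$s_hat, std.error = x$se,
    conf.low = x$ci[1], conf.high = x$ci[2],
    classification = x$classification
  )
}

#' @rdname tidy.selection_fit
#' @export
glance.selection_fit <- function(x, ...) {
  tibble(
    s_hat = x$s_hat, se = x$se, classification = x$classification,
    n_points = x$n_points, n_dropped = x$n_dropped,
    gens_per_transfer = x$gens_per_transfer,
    r.squared = summary(x$lm_fit)$r.squared
  )
}
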