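#' Flag jackpot replicates in a fluctuation series
#'
#' A "jackpot" is a replicate whose mutant (here, transconjugant) count is
#' inflated by a mutation that occurred unusually early during clonal
#' expansion. Counts greater than `multiplier` times the series median are
#' flagged. The median-multiple rule is a pragmatic screen; the multiplier is
#' exposed because no universal convention exists.
#'
#' @param counts non-empty numeric vector of per-replicate counts (>= 0).
#' @param multiplier threshold multiple of the median (default 4).
#' @return integer vector of flagged positions (possibly empty).
#' @examples
#' detect_jackpot(c(167, 193, 80, 107, 207, 213, 907, 380, 127, 80))
#' @export
detect_jackpot <- function(counts, multiplier = 4) {
  if (length(counts) == 0) abort("`counts` must be non-empty")
  which(counts > multiplier * median(counts))
}

#' Summary statistics of a fluctuation experiment
#'
#' Mean, median, population variance (divide by n) and variance/mean ratio of
#' per-replicate transconjugant counts. Under the Luria-Delbruck argument,
#' counts from independently grown cultures are overdispersed
#' (variance/mean much greater than 1) when the underlying mutants pre-exist
#' and arise at random times during growth, whereas aliquots of a single
#' culture show near-Poisson dispersion. The population-variance convention
#' is the one used in printed fluctuation tables.
#'
#' @param data data frame with a numeric `transconjugants` column and,
#'   optionally, a `design` column; rows are summarised per design. A bare
#'   numeric vector is also accepted.
#' @param exclude_jackpot drop replicates flagged by [detect_jackpot()]
#'   before summarising (default `FALSE`).
#' @param jackpot_multiplier passed to [detect_jackpot()].
#' @return tibble with one row per design and columns `design`, `n`,
#'   `n_jackpot`, `mean`, `median`, `variance`, `variance_mean_ratio`.
#'   Ratios are exact; round at the reporting layer.
#' @export
fluctuation_summary <- function(data, exclude_jackpot = FALSE,
                                jackpot_multiplier = 4) {
  if (is.numeric(data)) {
    data <- tibble(design = "series", transconjugants = data)
  }
  assert_columns(data, "transconjugants")
  if (!"design" %in% names(data)) data$design <- "series"
  if (nrow(data) == 0) abort("no counts to summarise")
  if (any(!is.finite(data$transconjugants) | data$transconjugants < 0)) {
    abort("`transconjugants` must be finite and >= 0")
  }
  summarise_one <- function(counts, design) {
    jack <- detect_jackpot(counts, jackpot_multiplier)
    kept <- if (exclude_jackpot && length(jack) > 0) counts[-jack] else counts
    if (length(kept) == 0) abort("no replicates left after jackpot exclusion")
    m <- mean(kept)
    v <- pop_var(kept)
    tibble(
      design = design, n = length(kept), n_jackpot = length(jack),
      mean = m, median = median(kept), variance = v,
      variance_mean_ratio = if (m > 0) v / m else 0
    )
  }
  data |>
    group_by(.data$design) |>
    dplyr::group_map(~ summarise_one(.x$transconjugants, .y$design)) |>
    bind_rows()
}

#' Simulate a fluctuation experiment of CRISPR-loss and plasmid receipt
#'
#' Semi-stochastic model of the random generation of CRISPR-negative
#' recipients during clonal growth, followed by plasmid transfer in a filter
#' mating. Each culture grows from `n0` to about `n_final` cells by discrete
#' doublings; at every generation the cohort of newly produced cells acquires
#' CRISPR-loss mutations as a Poisson draw with mean `mu_g` times the
#' post-doubling population, while pre-existing mutants double
#' deterministically (the classic Luria-Delbruck approximation). At mating,
#' each mutant cell receives the plasmid independently with probability
#' `p_transfer`, so per-replicate transconjugant counts are binomial draws
#' from the mutant count.
#'
#' Under `design = "independent_cultures"` every replicate grows its own
#' culture (mutant counts fluctuate between replicates); under
#' `design = "aliquots"` a single culture is grown and its mutant count is
#' shared by all replicates before independent mating draws, which is the
#' experimental control for induced (rather than pre-existing) mutation.
#'
#' `n_final` is rounded to the nearest power-of-two multiple of `n0` so that
#' growth is a whole number of doublings; the realised value is reported in
#' the `recipients` column.
#'
#' @param mu_g CRISPR-loss mutation probability per cell per generation.
#' @param n0 founding cells per culture (default 100).
#' @param n_final cells at mating (default 1e7).
#' @param p_transfer per-mutant plasmid-receipt probability during mating.
#'   The default 1e-4 is the order of the permissive conjugation frequency
#'   T/R observed in mating tables.
#' @param n_replicates number of matings (default 10, the usual design).
#' @param design `"independent_cultures"` or `"aliquots"`.
#' @param seed optional integer; fixed seed gives bit-reproducible output.
#' @return tibble with columns `replicate`, `design`, `recipients`,
#'   `mutants`, `transconjugants`.
#' @export
simulate_fluctuation <- function(mu_g, n0 = 100, n_final = 1e7,
                                 p_transfer = 1e-4, n_replicates = 10,
                                 design = c("independent_cultures", "aliquots"),
                                 seed = NULL) {
  design <- arg_match(design)
  if (mu_g < 0 || mu_g > 1) abort("`mu_g` must be in [0, 1]")
  if (p_transfer < 0 || p_transfer > 1) abort("`p_transfer` must be in [0, 1]")
  if (n0 < 1 || n_final < n0) abort("need `n_final` >= `n0` >= 1")
  gens <- max(1L, as.integer(round(log2(n_final / n0))))
  n_end <- n0 * 2^gens
  grow_mutants <- function() {
    m <- 0
    for (g in seq_len(gens)) {
      m <- 2 * m + rpois(1L, mu_g * n0 * 2^g)
    }
    min(m, n_end)
  }
  with_seed_if(seed, {
    mutants <- if (design == "independent_cultures") {
      vapply(seq_len(n_replicates), function(i) grow_mutants(), numeric(1))
    } else {
      rep(grow_mutants(), n_replicates)
    }
    trans <- rbinom(n_replicates, size = as.integer(mutants), prob = p_transfer)
    tibble(
      replicate = seq_len(n_replicates), design = design,
      recipients = n_end, mutants = mutants, transconjugants = trans
    )
  })
}

expected_transconjugants <- function(mu_g, n0, n_final, p_transfer) {
  gens <- max(1L, as.integer(round(log2(n_final / n0))))
  mu_g * (n0 * 2^gens) * gens * p_transfer
}

#' Estimate the CRISPR-loss mutation rate from fluctuation counts
#'
#' Mean-matching estimator: searches for the per-generation mutation
#' probability `mu_g` whose simulated mean transconjugant count (under
#' [simulate_fluctuation()] with the same known mating parameters) matches
#' the observed mean. A fixed log-spaced grid of candidate rates is
#' simulated once under the given seed, and the estimate is interpolated
#' between the two grid points whose simulated means bracket the observed
#' mean; because the grid depends only on the known parameters and the
#' seed, the estimate is monotone non-decreasing in the observed mean. When
#' all observed counts are zero no point estimate exists and only an upper
#' bound is returned (the rate at which about three transconjugants would
#' have been expected across the whole experiment).
#'
#' @param data numeric vector of per-replicate transconjugant counts, or a
#'   data frame with a `transconjugants` column.
#' @param p_transfer,n0,n_final known mating parameters (see
#'   [simulate_fluctuation()]); `p_transfer` must be supplied explicitly.
#' @param n_sim simulated replicates per grid point (default 200).
#' @param mu_range candidate-rate range searched (default `c(1e-8, 1e-2)`).
#' @param grid_len grid points across `mu_range` (default 25, about four
#'   points per decade).
#' @param seed optional integer seed for the simulation grid.
#' @return one-row tibble with columns `mu_hat`, `mu_lower`, `mu_upper`
#'   (the bracketing grid points), `observed_mean` and `method`
#'   (`"mean_matching"`, `"edge"` when the observed mean falls outside the
#'   simulated range, or `"upper_bound"` for all-zero counts).
#' @export
estimate_mu <- function(data, p_transfer, n0 = 100, n_final = 1e7,
                        n_sim = 200, mu_range = c(1e-8, 1e-2),
                        grid_len = 25, seed = NULL) {
  counts <- if (is.data.frame(data)) {
    assert_columns(data, "transconjugants")
    data$transconjugants
  } else {
    data
  }
  if (length(counts) == 0) abort("no counts supplied")
  if (missing(p_transfer)) abort("`p_transfer` must be supplied")
  obs <- mean(counts)
  gens <- max(1L, as.integer(round(log2(n_final / n0))))
  n_end <- n0 * 2^gens
  if (obs == 0) {
    # about 3 expected transconjugants over all replicates would likely have
    # been seen; the rate giving that expectation bounds mu from above
    mu_up <- 3 / (length(counts) * p_transfer * n_end * gens)
    return(tibble(
      mu_hat = NA_real_, mu_lower = 0, mu_upper = min(mu_up, 1),
      observed_mean = 0, method = "upper_bound"
    ))
  }
  grid <- 10^seq(log10(mu_range[1]), log10(mu_range[2]), length.out = grid_len)
  sim_mean <- function(mu) {
    mean(simulate_fluctuation(
      mu_g = mu, n0 = n0, n_final = n_final, p_transfer = p_transfer,
      n_replicates = n_sim, design = "independent_cultures"
    )$transconjugants)
  }
  with_seed_if(seed, {
    means <- cummax(vapply(grid, sim_mean, numeric(1))) # enforce monotone
    if (obs <= means[1]) {
      warn("observed mean below the simulated range; reporting lower edge")
      return(tibble(
        mu_hat = grid[1], mu_lower = 0, mu_upper = grid[1],
        observed_mean = obs, method = "edge"
      ))
    }
    if (obs >= means[grid_len]) {
      warn("observed mean above the simulated range; reporting upper edge")
      return(tibble(
        mu_hat = grid[grid_len], mu_lower = grid[grid_len], mu_upper = Inf,
        observed_mean = obs, method = "edge"
      ))
    }
    i <- findInterval(obs, means, all.inside = TRUE)
    lo <- grid[i]
    hi <- grid[i + 1]
    mu_hat <- if (means[i + 1] > means[i]) {
      lo + (obs - means[i]) * (hi - lo) / (means[i + 1] - means[i])
    } else {
      (lo + hi) / 2
    }
    tibble(
      mu_hat = mu_hat, mu_lower = lo, mu_upper = hi,
      observed_mean = obs, method = "mean_matching"
    )
  })
}
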