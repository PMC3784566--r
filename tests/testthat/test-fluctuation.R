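test_that("summary reproduces the printed variance/mean ratios", {
  s <- fluctuation_summary(table3)
  ind <- s[s$design == "independent_cultures", ]
  ali <- s[s$design == "aliquots", ]
  expect_equal(round(ind$variance_mean_ratio), 226)
  expect_equal(round(ali$variance_mean_ratio), 4)
  expect_equal(round(ind$mean), 246)
  expect_equal(ind$median, 180)
  expect_equal(round(ali$mean), 133)
  expect_equal(ali$median, 128)
  woj <- fluctuation_summary(table3, exclude_jackpot = TRUE)
  woj_ind <- woj[woj$design == "independent_cultures", ]
  expect_equal(round(woj_ind$variance_mean_ratio), 45)
  expect_equal(woj_ind$n, 9L)
  expect_equal(round(woj_ind$mean), 173)
  expect_equal(woj_ind$median, 167)
  # the aliquot control has no jackpot, so exclusion leaves it untouched
  expect_equal(
    woj[woj$design == "aliquots", ]$variance_mean_ratio,
    ali$variance_mean_ratio
  )
})

test_that("jackpot detection flags only the outlying replicate", {
  expect_identical(detect_jackpot(counts_independent), which(counts_independent == 907))
  expect_identical(detect_jackpot(rep(5, 8)), integer(0))
  expect_identical(detect_jackpot(c(10, 10, 10, 41), multiplier = 4), 4L)
  expect_identical(detect_jackpot(c(10, 10, 10, 41), multiplier = 5), integer(0))
  expect_error(detect_jackpot(numeric(0)), "non-empty")
})

test_that("degenerate and invalid count series are handled", {
  s <- fluctuation_summary(c(5, 5, 5, 5))
  expect_identical(s$variance, 0)
  expect_identical(s$variance_mean_ratio, 0)
  expect_error(fluctuation_summary(tibble::tibble(transconjugants = -1)), ">= 0")
  expect_error(
    fluctuation_summary(tibble::tibble(transconjugants = numeric())),
    "no counts"
  )
})

test_that("summary is permutation-invariant", {
  withr::with_seed(5, {
    shuffled <- sample(counts_independent)
  })
  expect_equal(
    fluctuation_summary(counts_independent)[-1],
    fluctuation_summary(shuffled)[-1]
  )
})

test_that("fluctuation simulator is seeded and respects trivial limits", {
  a <- simulate_fluctuation(3e-4, fluc_n0, fluc_nf, 0.05, seed = 7)
  b <- simulate_fluctuation(3e-4, fluc_n0, fluc_nf, 0.05, seed = 7)
  expect_identical(a, b)
  zero <- simulate_fluctuation(0, fluc_n0, fluc_nf, 0.05, seed = 7)
  expect_true(all(zero$transconjugants == 0))
  ali <- simulate_fluctuation(3e-4, fluc_n0, fluc_nf, 0.05,
    design = "aliquots", seed = 8
  )
  # aliquots share one culture: identical mutant pools across replicates
  expect_equal(length(unique(ali$mutants)), 1L)
  expect_error(simulate_fluctuation(-0.1, fluc_n0, fluc_nf, 0.05), "mu_g")
  expect_error(simulate_fluctuation(1e-4, 100, 10, 0.05), "n_final")
})

test_that("mean mutant yield follows the Luria-Delbruck expectation", {
  # expected mutants per culture: mu * n_final * generations
  mu <- 3e-4
  expected <- mu * fluc_nf * fluc_gens
  sims <- simulate_fluctuation(mu, fluc_n0, fluc_nf,
    p_transfer = 1, n_replicates = 1000, seed = 21
  )
  expect_lt(abs(mean(sims$mutants) - expected) / expected, 0.10)
})

test_that("independent cultures are overdispersed relative to aliquots", {
  ratio_of <- function(design, seed) {
    d <- simulate_fluctuation(3e-4, fluc_n0, fluc_nf, 0.05,
      n_replicates = 10, design = design, seed = seed
    )
    s <- fluctuation_summary(d)
    s$variance_mean_ratio
  }
  wins <- withr::with_seed(31, {
    seeds <- sample.int(1e6, 400)
    vapply(1:200, function(i) {
      ratio_of("independent_cultures", seeds[2 * i - 1]) >
        ratio_of("aliquots", seeds[2 * i])
    }, logical(1))
  })
  expect_gte(mean(wins), 0.95)
})

test_that("mutation-rate estimation recovers the simulated truth", {
  mu_true <- 3e-4
  hits <- vapply(1:5, function(i) {
    obs <- simulate_fluctuation(mu_true, fluc_n0, fluc_nf, 0.05,
      n_replicates = 10, seed = 400 + i
    )
    est <- estimate_mu(obs,
      p_transfer = 0.05, n0 = fluc_n0, n_final = fluc_nf,
      n_sim = 200, seed = 500 + i
    )
    est$mu_hat
  }, numeric(1))
  expect_true(all(hits > mu_true / 3 & hits < mu_true * 3))
})

test_that("all-zero counts yield an upper bound, not an estimate", {
  est <- estimate_mu(rep(0, 10),
    p_transfer = 0.05, n0 = fluc_n0, n_final = fluc_nf, seed = 6
  )
  expect_true(is.na(est$mu_hat))
  expect_identical(est$method, "upper_bound")
  expect_gt(est$mu_upper, 0)
  expect_identical(est$mu_lower, 0)
})

test_that("estimated rate is monotone in the observed mean", {
  mus <- vapply(c(5, 20, 80, 320, 1280), function(m) {
    estimate_mu(rep(m, 10),
      p_transfer = 0.05, n0 = fluc_n0, n_final = fluc_nf,
      n_sim = 100, seed = 77
    )$mu_hat
  }, numeric(1))
  expect_true(all(diff(mus) >= 0))
})
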