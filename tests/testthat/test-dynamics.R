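params0 <- dynamics_params()

test_that("Monod growth rate has the right limits", {
  expect_identical(monod_psi(0, params0), 0)
  expect_equal(monod_psi(params0$k, params0), params0$nu_max / 2)
  expect_equal(monod_psi(100 * params0$k, params0), params0$nu_max,
    tolerance = 0.01
  )
  expect_error(monod_psi(-1, params0), ">= 0")
})

test_that("parameter and state validation", {
  expect_error(dynamics_params(gamma = -1), ">= 0")
  expect_error(dynamics_params(dt = 0), "dt")
  expect_error(initial_state(CP = -5), ">= 0")
  expect_error(scenario_preset("Z"), "unknown scenario")
})

test_that("deterministic field conserves resource plus biomass", {
  withr::with_seed(12, {
    for (i in 1:20) {
      state <- initial_state(
        R_res = runif(1, 0, 2500), CP = runif(1, 0, 1e9),
        CN = runif(1, 0, 1e6), D1 = runif(1, 0, 1e9),
        D2 = runif(1, 0, 1e6), T1 = runif(1, 0, 1e3), T2 = runif(1, 0, 1e3)
      )
      d <- plasmid_derivatives(state, params0)
      expect_equal(params0$e * sum(d[-1]) + d[["R_res"]], 0,
        tolerance = 1e-10 * max(abs(d))
      )
    }
  })
  expect_equal(
    unname(plasmid_derivatives(initial_state(2500, 0, 0, 0, 0, 0, 0), params0)),
    rep(0, 7)
  )
})

test_that("without conjugation the field reduces to pure Monod growth", {
  p <- dynamics_params(gamma = 0)
  s <- initial_state(R_res = 1000, CP = 5e8, D1 = 0)
  d <- plasmid_derivatives(s, p)
  psi <- monod_psi(1000, p)
  expect_equal(d[["CP"]], psi * 5e8)
  expect_true(all(d[c("CN", "D1", "D2", "T1", "T2")] == 0))
})

test_that("batch culture reaches the closed-form final density", {
  # with e*sum(N) + R conserved and R -> 0, N_inf = N0 + R0/e
  p <- dynamics_params(gamma = 0, mu = 0, nu_pl = 0)
  init <- initial_state(R_res = 2500, CP = 200, D1 = 0)
  traj <- simulate_plasmid_dynamics(p, init, record_every = 24)
  final <- traj[nrow(traj), ]
  expect_equal(final$CP, 200 + 2500 / p$e, tolerance = 1e-3)
  expect_lt(final$R_res, 1e-3 * 2500)
})

test_that("mutation events are Poisson with the stated mean", {
  p <- dynamics_params(mu = 1e-3, nu_pl = 0)
  s <- initial_state(R_res = 2500, CP = 1e6)
  moved <- withr::with_seed(88, {
    vapply(1:2000, function(i) {
      1e6 - apply_mutations(s, p, dt = 0.1)[["CP"]]
    }, numeric(1))
  })
  lambda <- 1e-3 * 1e6 * 0.1 # = 100 expected events
  expect_lt(abs(mean(moved) - lambda), 3 * sqrt(lambda / 2000))
  # trivial limits
  p0 <- dynamics_params(mu = 0, nu_pl = 0)
  expect_identical(apply_mutations(s, p0, 0.1), s)
  no_cp <- initial_state(R_res = 2500, CP = 0, D1 = 0)
  expect_identical(apply_mutations(no_cp, p, 0.1), no_cp)
})

test_that("closed compartments stay empty without mutation or transfer", {
  p <- dynamics_params(gamma = 0, mu = 0, nu_pl = 0)
  traj <- simulate_plasmid_dynamics(p, initial_state(), record_every = 1)
  expect_true(all(traj$CN == 0 & traj$D2 == 0 & traj$T1 == 0 & traj$T2 == 0))
  expect_true(all(as.matrix(traj[-1]) >= 0))
})

test_that("compiled and reference R engines produce identical trajectories", {
  p <- scenario_preset("C")$params
  p$dt <- 0.05 # short run is enough to exercise every code path
  a <- simulate_plasmid_dynamics(p, seed = 19, record_every = 1)
  b <- simulate_plasmid_dynamics(p, seed = 19, record_every = 1, engine = "R")
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-12)
})

test_that("deterministic solution is converged in the step size", {
  base <- dynamics_params(mu = 0, nu_pl = 0)
  halved <- dynamics_params(mu = 0, nu_pl = 0, dt = 0.005)
  f1 <- as.numeric(simulate_plasmid_dynamics(base, record_every = 24)[2, -1])
  f2 <- as.numeric(simulate_plasmid_dynamics(halved, record_every = 24)[2, -1])
  expect_true(all(abs(f1 - f2) / pmax(abs(f2), 1) < 0.01))
  # RK4 agrees with fine Euler
  rk <- dynamics_params(mu = 0, nu_pl = 0, method = "rk4")
  f3 <- as.numeric(simulate_plasmid_dynamics(rk, record_every = 24)[2, -1])
  expect_true(all(abs(f3 - f2) / pmax(abs(f2), 1) < 0.01))
})

test_that("resource-biomass conservation holds along stochastic runs", {
  p <- scenario_preset("B")$params
  traj <- simulate_plasmid_dynamics(p, seed = 23, record_every = 1)
  tot <- p$e * rowSums(traj[, c("CP", "CN", "D1", "D2", "T1", "T2")]) +
    traj$R_res
  expect_equal(tot, rep(tot[1], length(tot)), tolerance = 1e-9)
  expect_true(all(as.matrix(traj[-1]) >= 0))
})

test_that("ensembles are reproducible and summarised correctly", {
  p <- scenario_preset("B")$params
  e1 <- run_ensemble(p, n_runs = 3, seed = 14)
  e2 <- run_ensemble(p, n_runs = 3, seed = 14)
  expect_identical(e1$final, e2$final)
  single <- run_ensemble(p, n_runs = 1, seed = 14)
  expect_true(all(tidy(single)$sd == 0))
  g <- glance(e1)
  expect_named(
    g, c("n_runs", "t_end", "mean_T1", "sd_T1", "mean_T2", "sd_T2")
  )
  s <- tidy(e1)
  expect_true(all(s$mean >= s$min & s$mean <= s$max))
  expect_error(run_ensemble(p, n_runs = 0), "n_runs")
})

test_that("scenario presets carry the published standard parameters", {
  b <- scenario_preset("B")
  expect_equal(b$params$mu, 1e-7)
  expect_equal(b$params$nu_pl, 3e-4)
  a <- scenario_preset("A")
  expect_equal(a$params$mu, 1e-7)
  expect_equal(a$params$nu_pl, 1e-7)
  cc <- scenario_preset("C")
  expect_equal(cc$params$mu, 3e-4)
  expect_equal(cc$params$nu_pl, 1e-7)
  for (sc in list(a, b, cc)) {
    expect_equal(sc$params$nu_max, 1.4)
    expect_equal(sc$params$e, 5e-7)
    expect_equal(sc$params$k, 1)
    expect_equal(sc$params$gamma, 1e-14)
    expect_equal(sc$params$t_end, 24)
    expect_identical(
      unname(sc$init),
      c(2500, 200, 0, 100, 0, 0, 0)
    )
  }
})

test_that("transconjugant yields increase with the relevant mutation rate", {
  mean_final <- function(rate, who, seed) {
    base <- scenario_preset("A")$params
    if (who == "T1") base$mu <- rate else base$nu_pl <- rate
    ens <- run_ensemble(base, n_runs = 50, seed = seed)
    ens$summary$mean[ens$summary$population == who]
  }
  t1 <- vapply(
    c(1e-7, 1e-5, 3e-4),
    function(r) mean_final(r, "T1", 61), numeric(1)
  )
  t2 <- vapply(
    c(1e-7, 1e-5, 3e-4),
    function(r) mean_final(r, "T2", 62), numeric(1)
  )
  expect_true(all(diff(t1) > 0))
  expect_true(all(diff(t2) > 0))
})
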