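test_that("schedules evaluate correctly in every mode", {
  sch <- param_schedule("L", "linear", 150, 0, duration = 2000)
  expect_equal(schedule_value(sch, c(0, 1000, 2000, 5000)), c(150, 75, 0, 0))
  expect_equal(schedule_value(constant_schedule("beta", -0.5), c(0, 10)), c(-0.5, -0.5))
  st <- param_schedule("L", "step", 200, 0, duration = 5)
  expect_equal(schedule_value(st, c(4.9, 5, 6)), c(200, 0, 0))
  expect_error(param_schedule("L", "linear", 1, 0, duration = -1), "duration")
  expect_error(sim_config(10, dt = 0.5, record_interval = 0.2), "dt")
})

test_that("Euler-Maruyama with sigma = 0 matches an adaptive ODE oracle", {
  m <- toy_model(toy_params(sigma = 0))
  cfg <- sim_config(50, 1e-3, 1, seed = 3)
  tr <- euler_maruyama(m, c(2, 0), cfg)
  oracle <- rk4_integrate(function(x) toy_drift(x, m$params), c(2, 0), 50, dt = 5e-3)
  expect_equal(unname(tr$states[nrow(tr$states), ]), oracle, tolerance = 1e-3)
  # x1 has relaxed onto the positive-well root (x2 decays only algebraically)
  roots <- toy_x1_roots(m$params)
  expect_equal(unname(tr$states[nrow(tr$states), 1]), max(roots), tolerance = 1e-3)
})

test_that("identical seeds give bit-identical trajectories", {
  m <- toy_model()
  cfg <- sim_config(5, 1e-3, 0.1, seed = 42)
  expect_identical(euler_maruyama(m, c(1, 0), cfg), euler_maruyama(m, c(1, 0), cfg))
  net <- dev_network(dev_params(L = 50))
  cfg2 <- sim_config(100, record_interval = 5, seed = 42)
  expect_identical(
    ssa_gillespie(net, c(70, 10, 100, 1), cfg2),
    ssa_gillespie(net, c(70, 10, 100, 1), cfg2)
  )
  cfg3 <- sim_config(10, 0.01, 1, seed = 42)
  expect_identical(
    cle_integrate(net, c(70, 10, 100, 1), cfg3),
    cle_integrate(net, c(70, 10, 100, 1), cfg3)
  )
})

test_that("drift-suppressed first-step increments follow the Wiener law", {
  m <- toy_model()
  n <- 2e4 # reduced from 1e5; Monte Carlo error ~1% against a 5% band
  dt <- 1e-3
  inc <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    tr <- euler_maruyama(m, c(0, 0), sim_config(dt, dt, dt, seed = i),
      drift_scale = 0)
    inc[i, ] <- tr$states[2, ]
  }
  v <- apply(inc, 2, stats::var)
  expect_equal(unname(v), rep(m$params$sigma^2 * dt, 2), tolerance = 0.05)
})

test_that("generic R-level Euler-Maruyama integrates custom models", {
  lin <- list(id = "lin", labels = "y", drift = function(x, t) -x, sigma = 0)
  tr <- euler_maruyama(lin, 1, sim_config(1, 1e-3, 0.1, seed = 1))
  expect_equal(unname(tr$states[nrow(tr$states), 1]), exp(-1), tolerance = 1e-3)
})

test_that("SSA with no enabled reactions stays constant, states stay integer", {
  p0 <- dev_params(
    k0 = 0, k1 = 0, k2 = 0, k3 = 0, k6 = 0, k7 = 0, k9 = 0, k10 = 0,
    k11 = 0, k12 = 0, k14 = 0, L = 0
  )
  tr <- ssa_gillespie(dev_network(p0), c(0, 0, 0, 0),
    sim_config(50, record_interval = 5, seed = 1))
  expect_true(all(tr$states == 0))
  expect_equal(tr$times, seq(0, 50, by = 5))

  net <- dev_network(dev_params(L = 50))
  tr2 <- ssa_gillespie(net, c(70, 10, 100, 1),
    sim_config(200, record_interval = 1, seed = 9))
  expect_true(all(tr2$states >= 0))
  expect_true(all(tr2$states == round(tr2$states)))
  expect_true(all(is.finite(tr2$states)))
  expect_equal(tr2$times, seq(0, 200, by = 1))
  expect_error(ssa_gillespie(net, c(1.5, 0, 0, 0), sim_config(1, record_interval = 1)),
    "integer")
})

test_that("SSA pure-death ensemble matches the exponential closed form", {
  p0 <- dev_params(
    k0 = 0, k1 = 0, k2 = 0, k3 = 0, k6 = 0, k7 = 0, k9 = 0, k10 = 0,
    k11 = 0, k12 = 0, k14 = 0, kd = 0.01, L = 0
  )
  net <- dev_network(p0)
  t_end <- 100
  n <- 400
  fin <- vapply(seq_len(n), function(i) {
    ssa_gillespie(net, c(100, 0, 0, 0),
      sim_config(t_end, record_interval = t_end, seed = i))$states[2, 1]
  }, numeric(1))
  expected <- 100 * exp(-p0$kd * t_end)
  se <- stats::sd(fin) / sqrt(n)
  expect_lt(abs(mean(fin) - expected), 3 * se)
})

test_that("CLE is stationary at a fixed point with noise disabled", {
  p <- dev_params(L = 50)
  fp <- find_fixed_points(dev_model(p), seed = 1)
  stem <- dev_fp_by_branch(fp, "stem-cell")
  tr <- cle_integrate(dev_network(p), stem, sim_config(10, 0.01, 1, seed = 1),
    noise = FALSE)
  drifted <- sqrt(rowSums((tr$states - matrix(stem, nrow(tr$states), 4,
    byrow = TRUE))^2))
  expect_lt(max(drifted), 1e-6)
})

test_that("CLE one-step increment covariance matches S diag(a) S^T dt", {
  p <- dev_params(L = 50)
  net <- dev_network(p)
  x0 <- c(70, 10, 100, 1)
  dt <- 0.01
  n <- 2e4 # reduced from 1e5; MC error ~1% against the 5% band
  inc <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    tr <- cle_integrate(net, x0, sim_config(dt, dt, dt, seed = i))
    inc[i, ] <- tr$states[2, ] - x0
  }
  a <- dev_propensities(x0, p)
  expect_equal(unname(apply(inc, 2, stats::var)), (a[1:4] + a[5:8]) * dt,
    tolerance = 0.05)
  # clamp policy: no recorded state below zero even near the boundary
  low <- cle_integrate(net, c(0, 0, 1, 1), sim_config(5, 0.01, 0.5, seed = 2))
  expect_true(all(low$states >= 0))
  expect_true(is.numeric(low$diagnostics$clamped))
})

test_that("ensembles are reproducible and member seeds are index-derived", {
  m <- toy_model()
  sim <- function(x0, cfg, sch) euler_maruyama(m, x0, cfg, sch)
  cfg <- sim_config(1, 1e-3, 0.1, seed = 77)
  e1 <- run_ensemble(sim, c(1, 0), cfg, 5)
  e2 <- run_ensemble(sim, c(1, 0), cfg, 5)
  expect_identical(e1, e2)
  expect_equal(e1$seeds, vapply(1:5, function(i) bitwXor(77L, i), integer(1)))
  # member 3 run standalone with its seed reproduces its path
  cfg3 <- cfg
  cfg3$seed <- e1$seeds[3]
  expect_equal(unname(e1$states[, , 3]), unname(euler_maruyama(m, c(1, 0), cfg3)$states))
  expect_error(run_ensemble(sim, c(1, 0), cfg, 1), "n >= 2")
})

test_that("sample_box respects ranges, seeds and uniform moments", {
  r <- list(N = c(60, 100), G = c(0, 16))
  s1 <- sample_box(r, 100, seed = 5)
  s2 <- sample_box(r, 100, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(s1[, "N"] >= 60 & s1[, "N"] <= 100))
  expect_true(all(s1[, "G"] >= 0 & s1[, "G"] <= 16))
  big <- sample_box(r, 1e4, seed = 6)
  for (nm in names(r)) {
    mid <- mean(r[[nm]])
    se <- diff(r[[nm]]) / sqrt(12) / sqrt(1e4)
    expect_lt(abs(mean(big[, nm]) - mid), 3 * se)
  }
  si <- sample_box(r, 50, seed = 7, integer_valued = TRUE)
  expect_true(all(si == round(si)))
  expect_error(sample_box(list(N = c(10, 5)), 10), "low <= high")
})

test_that("SSA and CLE moments agree at the (stable) differentiated state", {
  # The stationary high-L comparison uses the differentiated attractor: the
  # stem state is metastable and rare escapes would dominate the moments.
  p <- dev_params(L = 200)
  net <- dev_network(p)
  x0 <- c(0, 0, 100, 100)
  n <- 1000
  es <- run_ensemble(function(x, c2, s) ssa_gillespie(net, x, c2, s), x0,
    sim_config(500, record_interval = 500, seed = 10), n)
  ec <- run_ensemble(function(x, c2, s) cle_integrate(net, x, c2, s), x0,
    sim_config(500, 0.1, 500, seed = 11), n)
  fs <- ensemble_states(es, "final")
  fc <- ensemble_states(ec, "final")
  for (sp in c("F", "G")) {
    expect_equal(mean(fc[, sp]), mean(fs[, sp]), tolerance = 0.10)
    expect_equal(stats::var(fc[, sp]), stats::var(fs[, sp]), tolerance = 0.25)
  }
  # near-extinct species compared on an absolute scale (2 copies)
  for (sp in c("N", "O")) {
    expect_lt(abs(mean(fc[, sp]) - mean(fs[, sp])), 2)
  }
})
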