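test_that("histogram normalization, degenerate cases and overflow accounting", {
  set.seed(1)
  s <- cbind(x1 = rnorm(500), x2 = rnorm(500))
  g <- histogram_density(s, c("x1", "x2"), bins = 20,
    limits = list(x1 = c(-2, 2), x2 = c(-2, 2)))
  expect_equal(sum(g$mass), 1, tolerance = 1e-12)
  expect_equal(g$n_overflow, sum(abs(s[, 1]) > 2 | abs(s[, 2]) > 2))

  same <- cbind(x1 = rep(0.5, 40), x2 = rep(-0.5, 40))
  g1 <- histogram_density(same, c("x1", "x2"), bins = 10,
    limits = list(x1 = c(-1, 1), x2 = c(-1, 1)))
  expect_equal(sum(g1$counts > 0), 1L)
  expect_error(histogram_density(s[0, , drop = FALSE], c("x1", "x2")), "at least one")
  expect_error(histogram_density(s, c("x1", "nope")), "unknown axis")
})

test_that("potential is a capped negative log with consistent extrema", {
  set.seed(2)
  s <- cbind(x1 = rnorm(2000, 1), x2 = rnorm(2000))
  g <- histogram_density(s, c("x1", "x2"), bins = 15,
    limits = list(x1 = c(-3, 4), x2 = c(-3, 3)))
  expect_equal(which.min(g$potential), which.max(g$mass))
  # potential differences between occupied bins are invariant to sample size
  # scaling (the -ln ratio identity), pseudocount set to zero for exactness
  g0 <- potential_from_density(g, 0)
  occ <- which(g0$counts >= 20)[1:2]
  dU <- g0$potential[occ[1]] - g0$potential[occ[2]]
  expect_equal(dU, -log(g0$mass[occ[1]] / g0$mass[occ[2]]))
  # empty bins at the finite cap, above every occupied bin
  gp <- potential_from_density(g, 1e-6)
  expect_equal(max(gp$potential), -log(1e-6 + 0), tolerance = 1e-9)
  expect_true(all(gp$potential[gp$counts > 0] < -log(1e-6)))
  expect_error(potential_from_density(g, -1), "non-negative")
  # round trip: renormalized exp(-U) recovers the mass on occupied bins
  back <- exp(-g0$potential[g0$counts > 0])
  expect_equal(back / sum(exp(-g0$potential[is.finite(g0$potential)])),
    g0$mass[g0$counts > 0] / sum(g0$mass[g0$counts > 0]),
    tolerance = 1e-12)
})

test_that("marginals agree with direct 1D histograms and sum to one", {
  set.seed(3)
  s <- cbind(x1 = rnorm(3000), x2 = runif(3000, -1, 1))
  g2 <- histogram_density(s, c("x1", "x2"), bins = c(24, 16),
    limits = list(x1 = c(-3, 3), x2 = c(-1, 1)))
  m1 <- marginalize(g2, "x1")
  expect_equal(sum(m1$mass), 1, tolerance = 1e-12)
  direct <- histogram_density(s, "x1", bins = 24, limits = list(x1 = c(-3, 3)))
  expect_equal(as.vector(m1$mass), as.vector(direct$mass), tolerance = 1e-12)
  expect_error(marginalize(g2, "zz"), "unknown axis")
})

test_that("stationary toy marginals switch between bimodal and unimodal", {
  for (case in list(list(beta = 0, modes = 2), list(beta = -0.5, modes = 1),
    list(beta = 0.5, modes = 1))) {
    m <- toy_model(toy_params(beta = case$beta))
    tr <- euler_maruyama(m, c(1, 0), sim_config(800, 1e-3, 0.1, seed = 21))
    mg <- marginalize(tr$states, "x1", bins = 24, limits = list(x1 = c(-2, 2)))
    expect_equal(nrow(landscape_modes(mg)), case$modes,
      info = sprintf("beta = %g", case$beta))
  }
})

test_that("long-run toy histogram has exactly the two well modes", {
  tr <- euler_maruyama(toy_model(), c(1, 0), sim_config(5000, 1e-3, 0.2, seed = 31))
  # coarse transverse bins: the quartic well's flat top makes finer x2 bins
  # noise-dominated for local-maximum detection
  g <- histogram_density(tr$states, c("x1", "x2"), bins = c(40, 8),
    limits = list(x1 = c(-2, 2), x2 = c(-2, 2)))
  modes <- landscape_modes(g)
  expect_equal(nrow(modes), 2L)
  roots <- toy_x1_roots()
  wells <- c(min(roots), max(roots))
  for (w in wells) {
    j <- findInterval(w, g$edges$x1)
    expect_true(any(modes$i == j))
  }
  expect_true(all(abs(modes$center2) < 0.5))
})

test_that("ensemble variance matches a two-pass oracle and edge cases", {
  set.seed(4)
  arr <- array(rnorm(20 * 3 * 7), dim = c(20, 3, 7),
    dimnames = list(NULL, c("a", "b", "c"), NULL))
  ens <- structure(list(times = 1:20, states = arr, base_seed = 1L,
    seeds = 1:7, model_id = "x"), class = "eland_ensemble")
  v <- variance_timeseries(ens)
  for (j in 1:3) {
    two_pass <- apply(arr[, j, ], 1, function(z) sum((z - mean(z))^2) / (length(z) - 1))
    expect_equal(v[[j + 1]], two_pass, tolerance = 1e-12)
  }
  same <- arr
  for (k in 1:7) same[, , k] <- same[, , 1]
  ens2 <- ens
  ens2$states <- same
  expect_true(all(as.matrix(variance_timeseries(ens2)[, -1]) == 0))
  ens1 <- ens
  ens1$states <- arr[, , 1, drop = FALSE]
  expect_error(variance_timeseries(ens1), "at least 2")
})

test_that("tv_distance is a metric-like comparison on shared edges", {
  set.seed(6)
  s1 <- cbind(x1 = rnorm(1000), x2 = rnorm(1000))
  s2 <- cbind(x1 = rnorm(1000, 0.2), x2 = rnorm(1000))
  lim <- list(x1 = c(-3, 3), x2 = c(-3, 3))
  g1 <- histogram_density(s1, c("x1", "x2"), bins = 10, limits = lim)
  g2 <- histogram_density(s2, c("x1", "x2"), bins = 10, limits = lim)
  expect_equal(tv_distance(g1, g1), 0)
  expect_equal(tv_distance(g1, g2), tv_distance(g2, g1))
  expect_gt(tv_distance(g1, g2), 0)
  g3 <- histogram_density(s2, c("x1", "x2"), bins = 12, limits = lim)
  expect_error(tv_distance(g1, g3), "edges")
})
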