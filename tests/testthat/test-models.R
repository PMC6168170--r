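test_that("toy potential matches hand-computed values and symmetry", {
  p <- toy_params()
  expect_identical(toy_potential(c(0, 0), p), 0)
  # lambda - alpha + beta = 0.25 - 0.5 - 0.05
  expect_equal(toy_potential(c(1, 0), p), -0.30)
  set.seed(5)
  for (i in 1:50) {
    x <- runif(2, -2, 2)
    expect_equal(toy_potential(x, p), toy_potential(c(x[1], -x[2]), p))
  }
  expect_error(toy_potential(c(1, 2, 3), p), "two-dimensional")
})

test_that("toy decomposition is orthogonal and sums to the printed drift", {
  p <- toy_params()
  d0 <- toy_decomposition(c(0, 0), toy_params(beta = 0))
  expect_equal(d0$gradient_part, c(0, 0))
  expect_equal(d0$curl_part, c(0, 0))
  d1 <- toy_decomposition(c(1, 0), p)
  expect_equal(d1$gradient_part, c(0.05, 0))
  expect_equal(d1$curl_part, c(0, 0.025))
  set.seed(7)
  for (i in 1:100) {
    x <- runif(2, -2, 2)
    d <- toy_decomposition(x, p)
    expect_lt(abs(sum(d$gradient_part * d$curl_part)), 1e-10)
    expect_equal(toy_drift(x, p), d$gradient_part + d$curl_part)
    expect_equal(toy_drift(x, p), toy_drift_oracle(x, p), tolerance = 1e-12)
  }
})

test_that("toy parameter validation rejects invalid values", {
  expect_error(toy_params(lambda = 0), "lambda")
  expect_error(toy_params(sigma = -1), "sigma")
  expect_error(toy_params(alpha = Inf), "finite")
})

test_that("developmental propensities match the zero-state reduction and scale", {
  p <- dev_params(set = "paper-printed", L = 0)
  a <- dev_propensities(c(0, 0, 0, 0), p)
  expect_equal(a, c(0, p$k6, p$k9, p$k11, 0, 0, 0, 0))
  # first-order degradation: doubling the state doubles a5..a8 exactly
  set.seed(11)
  for (i in 1:20) {
    x <- runif(4, 0, 150)
    a1 <- dev_propensities(x, p)
    a2 <- dev_propensities(2 * x, p)
    expect_equal(a2[5:8], 2 * a1[5:8])
  }
  expect_error(dev_propensities(c(-1, 0, 0, 0), p), "non-negative")
  expect_error(dev_params(k2 = -0.1), "non-negative")
})

test_that("propensities are non-negative and respect the analytic envelopes", {
  for (set in c("calibrated", "paper-printed")) {
    p <- dev_params(set = set, L = 50)
    set.seed(13)
    for (i in 1:200) {
      x <- runif(4, 0, 200)
      a <- dev_propensities(x, p)
      expect_true(all(a >= 0))
      expect_lt(a[1], 1 + p$k1 * p$k0 * x[2])
      expect_lte(a[2], p$k6 + 1)
      expect_lte(a[3], p$k9 + 1)
      expect_lte(a[4], p$k11 + 1)
    }
  }
})

test_that("stoichiometry has the birth/death block structure", {
  S <- dev_stoichiometry()
  expect_identical(dim(S), c(4L, 8L))
  expect_identical(unname(S[1, 1]), 1L)
  expect_identical(unname(S[1, 5]), -1L)
  expect_true(all(rowSums(S) == 0))
  for (i in 1:4) {
    expect_identical(unname(S[i, ]), as.integer(seq_len(8) == i) - as.integer(seq_len(8) == i + 4))
  }
})

test_that("developmental drift is S a and reduces to pure decay", {
  p <- dev_params(L = 50)
  S <- dev_stoichiometry()
  set.seed(17)
  for (i in 1:50) {
    x <- runif(4, 0, 150)
    a <- dev_propensities(x, p)
    expect_equal(unname(dev_drift(x, p)), as.numeric(S %*% a))
    expect_equal(unname(dev_drift(x, p)), a[1:4] - a[5:8])
  }
  # all production switched off -> drift = -kd * state
  p0 <- dev_params(
    k0 = 0, k1 = 0, k2 = 0, k3 = 0, k6 = 0, k7 = 0, k9 = 0, k10 = 0,
    k11 = 0, k12 = 0, k14 = 0, L = 0
  )
  x <- c(30, 20, 10, 5)
  expect_equal(unname(dev_drift(x, p0)), -p0$kd * x)
})

test_that("noise covariance is the diagonal Gram form", {
  p <- dev_params(L = 50)
  S <- dev_stoichiometry()
  set.seed(19)
  for (i in 1:50) {
    x <- runif(4, 0, 150)
    a <- dev_propensities(x, p)
    A <- dev_noise_covariance(x, p)
    expect_equal(A, unname(S %*% diag(a) %*% t(S))) # explicit Gram oracle
    expect_equal(diag(A), a[1:4] + a[5:8])
    expect_true(all(A[upper.tri(A)] == 0))
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-12))
  }
  pz <- dev_params(
    k0 = 0, k1 = 0, k2 = 0, k3 = 0, k6 = 0, k7 = 0, k9 = 0, k10 = 0,
    k11 = 0, k12 = 0, k14 = 0, kd = 0, L = 0
  )
  expect_equal(dev_noise_covariance(c(1, 2, 3, 4), pz), matrix(0, 4, 4))
})

test_that("parameter config round-trips through JSON", {
  p <- dev_params_from_config("calibrated")
  expect_equal(p$kd, 0.01)
  expect_equal(p$k11, 0.05)
  p2 <- dev_params_from_config("paper-printed")
  expect_equal(p2$kd, 1)
  expect_equal(p2$k11, 5)
})

test_that("batched model evaluation agrees with pointwise evaluation", {
  set.seed(23)
  tm <- toy_model()
  X <- matrix(runif(20, -2, 2), ncol = 2)
  bt <- epiland:::model_batch(tm, X, need_jac = TRUE)
  for (i in seq_len(nrow(X))) {
    expect_equal(bt$F[i, ], unname(toy_drift(X[i, ])))
    expect_equal(bt$Jf[i, , ], unname(jacobian_at(tm, X[i, ])))
  }
  dm <- dev_model(dev_params(L = 50))
  X <- matrix(runif(40, 0, 120), ncol = 4)
  bt <- epiland:::model_batch(dm, X, need_jac = TRUE)
  for (i in seq_len(nrow(X))) {
    a <- dev_propensities(X[i, ], dm$params)
    expect_equal(bt$F[i, ], unname(a[1:4] - a[5:8]))
    expect_equal(bt$A[i, ], a[1:4] + a[5:8])
    expect_equal(bt$Jf[i, , ], unname(jacobian_at(dm, X[i, ])), tolerance = 1e-12)
  }
})
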