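test_that("toy fixed points match the cubic-root oracle", {
  # beta = 0: the x1 equation is x1^3 = x1 exactly
  fp0 <- find_fixed_points(toy_model(toy_params(beta = 0)), seed = 1)
  expect_equal(nrow(fp0), 3L)
  expect_equal(sort(fp0$x1), c(-1, 0, 1), tolerance = 1e-6)
  expect_true(all(abs(fp0$x2) < 1e-4))
  # defaults: roots of x1^3 - x1 - 0.05
  fp <- find_fixed_points(toy_model(), seed = 1)
  expect_equal(sort(fp$x1), toy_x1_roots(), tolerance = 1e-3)
  expect_true(all(fp$residual < 1e-9))
  # drift vanishes at every reported root (independent re-evaluation)
  for (i in seq_len(nrow(fp))) {
    expect_lt(sqrt(sum(toy_drift(c(fp$x1[i], fp$x2[i]))^2)), 1e-9)
  }
  # middle root is a saddle with the structurally-zero transverse direction
  mid <- fp[which.min(abs(fp$x1)), ]
  expect_identical(mid$classification, "saddle")
  expect_gte(mid$n_marginal, 1L)
})

test_that("toy Jacobian matches the closed form and central differences", {
  m <- toy_model(toy_params(beta = 0))
  J0 <- jacobian_at(m, c(0, 0))
  p <- m$params
  expect_equal(J0, matrix(c(2 * p$alpha, 2 * p$c * p$alpha, 0, 0), 2, 2))
  ev <- eigen(J0, only.values = TRUE)$values
  expect_equal(sort(Re(ev)), c(0, 2 * p$alpha))
  set.seed(9)
  for (i in 1:20) {
    x <- runif(2, -2, 2)
    expect_equal(jacobian_at(m, x, "central"), jacobian_at(m, x, "analytic"),
      tolerance = 1e-6)
  }
  # alpha = 0.4 at fixed alpha/lambda ratio: saddle eigenvalue = 2 alpha = 0.8
  m2 <- toy_model(toy_params(alpha = 0.4, lambda = 0.2, beta = 0))
  ev2 <- eigen(jacobian_at(m2, c(0, 0)), only.values = TRUE)$values
  expect_equal(max(Re(ev2)), 0.8, tolerance = 1e-12)
})

test_that("developmental Jacobian agrees with central differences", {
  m <- dev_model(dev_params(L = 50))
  set.seed(10)
  for (i in 1:20) {
    x <- runif(4, 0, 120)
    expect_equal(jacobian_at(m, x, "central"), unname(jacobian_at(m, x, "analytic")),
      tolerance = 1e-6)
  }
})

test_that("classification follows the eigenvalue sign rule", {
  expect_identical(classify_fixed_point(c(-1, -2))$classification, "stable")
  expect_identical(classify_fixed_point(c(0.5, -1))$classification, "saddle")
  cl <- classify_fixed_point(c(1, 0))
  expect_identical(cl$classification, "saddle")
  expect_identical(cl$n_marginal, 1L)
  expect_identical(classify_fixed_point(complex(real = c(-1, -1),
    imaginary = c(2, -2)))$classification, "stable")
  expect_error(classify_fixed_point(numeric(0)), "empty")
})

test_that("calibrated developmental model has the three named states at L = 50", {
  fp <- find_fixed_points(dev_model(dev_params(L = 50)), seed = 1)
  expect_gte(nrow(fp), 3L)
  stem <- dev_fp_by_branch(fp, "stem-cell")
  diffd <- dev_fp_by_branch(fp, "differentiated")
  trans <- dev_fp_by_branch(fp, "transition")
  expect_gt(stem["N"], stem["G"]) # N >> G
  expect_gt(stem["N"], 40)
  expect_gt(diffd["G"], diffd["N"]) # G >> N
  expect_gt(diffd["G"], 40)
  expect_lt(trans["N"], stem["N"]) # transition below the stem state
  expect_lt(trans["G"], 40)
  expect_true(all(fp$residual < 1e-9))
  # every root satisfies the drift equation independently of the solver
  p <- dev_params(L = 50)
  for (i in seq_len(nrow(fp))) {
    expect_lt(sqrt(sum(dev_drift(unlist(fp[i, c("N", "O", "F", "G")]), p)^2)), 1e-8)
  }
})

test_that("paper-printed set fails the structural gate; calibrated passes", {
  gate_bad <- dev_structure_gate(dev_params(set = "paper-printed"),
    L_values = c(0, 100, 200), seed = 1)
  expect_false(gate_bad$pass)
  gate_ok <- dev_structure_gate(dev_params(set = "calibrated"),
    L_values = c(0, 100, 200), seed = 1)
  expect_true(gate_ok$pass)
})

test_that("L sweep tracks three branches with the reported character", {
  L_values <- c(0, 50, 100, 150, 200)
  sweep <- sweep_parameter(dev_model(dev_params()), "L", L_values,
    seed = 1, n_starts = 120)
  counts <- table(sweep$value)
  expect_true(all(counts >= 3))
  stem <- sweep[sweep$branch == "stem-cell", ]
  stem <- stem[order(stem$value), ]
  expect_equal(nrow(stem), length(L_values))
  # stem branch: Nanog non-decreasing in L, stable throughout
  expect_false(is.unsorted(stem$N))
  expect_true(all(Re(stem$ev1) < 0))
  # differentiated branch: location nearly unchanged (residual Oct4 coupling
  # moves it by O(0.01) copies; see the methods vignette), stable throughout
  diffd <- sweep[sweep$branch == "differentiated", ]
  expect_equal(nrow(diffd), length(L_values))
  loc <- as.matrix(diffd[, c("N", "O", "F", "G")])
  expect_lt(max(dist(loc)), 0.1)
  expect_true(all(Re(diffd$ev1) < 0))
  # transition branch: unstable at every L
  trans <- sweep[sweep$branch == "transition", ]
  expect_equal(nrow(trans), length(L_values))
  expect_true(all(Re(trans$ev1) > 1e-8))
})

test_that("an empty search region yields a diagnostic, not an error", {
  # search box far away from any root of the toy drift
  box <- matrix(c(5, 6, 5, 6), 2, 2, byrow = TRUE)
  fp <- find_fixed_points(toy_model(), box = box, n_starts = 10, seed = 1)
  expect_equal(nrow(fp), 0L)
  expect_match(attr(fp, "diagnostic"), "no roots")
})
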