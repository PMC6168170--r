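# Shared helpers: independent oracles kept deliberately simple so they do not
# share code paths with the implementation under test.

# Real roots of the x1 drift cubic 4*lambda*x^3 - 2*alpha*x + beta = 0,
# via polyroot (the toy fixed points all lie on the x2 = 0 axis).
toy_x1_roots <- function(params = toy_params()) {
  z <- polyroot(c(params$beta, -2 * params$alpha, 0, 4 * params$lambda))
  sort(Re(z[abs(Im(z)) < 1e-9]))
}

# Classical RK4 integration oracle for deterministic flows.
rk4_integrate <- function(drift, x0, t_end, dt = 1e-3) {
  x <- x0
  steps <- round(t_end / dt)
  for (s in seq_len(steps)) {
    k1 <- drift(x)
    k2 <- drift(x + dt / 2 * k1)
    k3 <- drift(x + dt / 2 * k2)
    k4 <- drift(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

# Hand-expanded drift polynomial of the governing equations (independent of
# toy_decomposition): f1 = 2 a x1 - 4 l x1^3 - b + 4 c l x2^3,
# f2 = 2 c a x1 - 4 c l x1^3 - c b - 4 l x2^3.
toy_drift_oracle <- function(x, p) {
  c(
    2 * p$alpha * x[1] - 4 * p$lambda * x[1]^3 - p$beta + 4 * p$c * p$lambda * x[2]^3,
    2 * p$c * p$alpha * x[1] - 4 * p$c * p$lambda * x[1]^3 - p$c * p$beta -
      4 * p$lambda * x[2]^3
  )
}

# Classify a critical point of a scalar potential by sampling a small ring
# around it (robust to the quartic's vanishing transverse curvature).
ring_classify <- function(potential_fn, x, radius = 0.15, n = 24) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  vals <- vapply(th, function(a) {
    potential_fn(x + radius * c(cos(a), sin(a)))
  }, numeric(1))
  u0 <- potential_fn(x)
  if (all(vals > u0)) "minimum" else if (all(vals < u0)) "maximum" else "saddle"
}

dev_fp_by_branch <- function(fp, branch) {
  row <- fp[fp$branch == branch, c("N", "O", "F", "G")]
  stopifnot(nrow(row) >= 1)
  unlist(row[1, ])
}

reverse_path_states <- function(path) {
  path$states[rev(seq_len(nrow(path$states))), , drop = FALSE]
}
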