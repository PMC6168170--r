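#' Parameters of the two-dimensional bistable toy system
#'
#' The toy system is driven by the quartic double-well potential
#' \deqn{U(x_1, x_2) = \lambda (x_1^4 + x_2^4) - \alpha x_1^2 + \beta x_1,}
#' with drift \eqn{f = -\nabla U + f_U}, where the curl component
#' \eqn{f_U = c\,(4\lambda x_2^3,\; 2\alpha x_1 - 4\lambda x_1^3 - \beta)}
#' is everywhere orthogonal to \eqn{\nabla U}. Isotropic additive noise of
#' amplitude \code{sigma} completes the SDE.
#'
#' @param alpha quadratic-well coefficient (dimensionless, sets the positive
#'   eigenvalue \eqn{2\alpha} at the saddle).
#' @param lambda quartic coefficient, must be positive.
#' @param beta tilt coefficient; \eqn{\beta = 0} gives the symmetric double well,
#'   \eqn{|\beta|} beyond the fold value removes one well.
#' @param c curl magnitude, the constant value of the scalar field \eqn{C(X)}.
#' @param sigma noise amplitude (standard deviation scale), non-negative.
#' @return An object of class \code{toy_params}.
#' @examples
#' p <- toy_params()
#' toy_potential(c(1, 0), p)
#' @export
toy_params <- function(alpha = 0.5, lambda = 0.25, beta = -0.05, c = 0.5,
                       sigma = 0.4) {
  p <- list(alpha = alpha, lambda = lambda, beta = beta, c = c, sigma = sigma)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("toy parameter '%s' must be a finite scalar", nm))
    }
  }
  if (lambda <= 0) stop("'lambda' must be positive")
  if (sigma < 0) stop("'sigma' must be non-negative")
  structure(p, class = "toy_params")
}

check_toy_point <- function(x) {
  if (!is.numeric(x) || length(x) != 2L) {
    stop("toy-model states are two-dimensional (x1, x2)")
  }
  as.numeric(x)
}

#' Evaluate the toy potential
#'
#' @param x numeric length-2 state \code{c(x1, x2)}.
#' @param params a [toy_params()] object.
#' @return Scalar potential energy.
#' @export
toy_potential <- function(x, params = toy_params()) {
  x <- check_toy_point(x)
  params$lambda * (x[1]^4 + x[2]^4) - params$alpha * x[1]^2 + params$beta * x[1]
}

#' Gradient/curl decomposition of the toy drift
#'
#' Splits the deterministic forcing into \eqn{-\nabla U} (the landscape part)
#' and the orthogonal curl part \eqn{f_U}; their dot product vanishes
#' identically.
#'
#' @inheritParams toy_potential
#' @return List with components \code{gradient_part} and \code{curl_part},
#'   each a length-2 numeric vector.
#' @export
toy_decomposition <- function(x, params = toy_params()) {
  x <- check_toy_point(x)
  g1 <- 2 * params$alpha * x[1] - 4 * params$lambda * x[1]^3 - params$beta
  g2 <- -4 * params$lambda * x[2]^3
  list(
    gradient_part = c(g1, g2),
    curl_part = params$c * c(4 * params$lambda * x[2]^3, g1)
  )
}

#' Deterministic drift of the toy system
#'
#' Equals \code{gradient_part + curl_part} of [toy_decomposition()].
#'
#' @inheritParams toy_potential
#' @return Length-2 velocity vector.
#' @export
toy_drift <- function(x, params = toy_params()) {
  d <- toy_decomposition(x, params)
  d$gradient_part + d$curl_part
}

toy_jacobian <- function(x, params) {
  x <- check_toy_point(x)
  # d g1/dx1 = 2*alpha - 12*lambda*x1^2 ; g2 depends on x2 only
  dg1 <- 2 * params$alpha - 12 * params$lambda * x[1]^2
  dg2 <- -12 * params$lambda * x[2]^2
  cc <- params$c
  matrix(c(
    dg1, cc * dg1,
    -cc * dg2, dg2
  ), nrow = 2) # column-major: [ [dg1, c*dg1], [12 c lam x2^2, dg2] ]
}

#' Construct the toy model object
#'
#' Bundles drift, diffusion and analytic Jacobian for use by the simulators,
#' fixed-point tools and action functionals. The diffusion matrix is
#' \eqn{\sigma^2 I}.
#'
#' @param params a [toy_params()] object.
#' @return An object of class \code{c("toy_model", "eland_model")}.
#' @export
toy_model <- function(params = toy_params()) {
  stopifnot(inherits(params, "toy_params"))
  structure(
    list(
      id = "toy2d",
      labels = c("x1", "x2"),
      dim = 2L,
      params = params,
      schedulable = "beta"
    ),
    class = c("toy_model", "eland_model")
  )
}

#' @export
print.eland_model <- function(x, ...) {
  cat(sprintf("<%s model> variables: %s\n", x$id, paste(x$labels, collapse = ", ")))
  invisible(x)
}

# Generic model accessors used across modules ---------------------------------

model_drift <- function(model, x, params = model$params) UseMethod("model_drift")
model_jacobian <- function(model, x, params = model$params) UseMethod("model_jacobian")
# Diagonal of the diffusion (noise covariance) matrix; both shipped models have
# exactly diagonal covariance, which the action functional exploits.
model_noise_diag <- function(model, x, params = model$params) UseMethod("model_noise_diag")
model_noise_jacobian <- function(model, x, params = model$params) UseMethod("model_noise_jacobian")

#' @export
model_drift.toy_model <- function(model, x, params = model$params) {
  toy_drift(x, params)
}

#' @export
model_jacobian.toy_model <- function(model, x, params = model$params) {
  toy_jacobian(x, params)
}

#' @export
model_noise_diag.toy_model <- function(model, x, params = model$params) {
  rep(params$sigma^2, 2L)
}

#' @export
model_noise_jacobian.toy_model <- function(model, x, params = model$params) {
  matrix(0, 2, 2)
}

# Batched model evaluation over a matrix of states (rows). Returns drift F
# (n x d), diffusion diagonal A (n x d) and, when need_jac, the drift and
# diffusion-diagonal Jacobians as n x d x d arrays (entry [i, l, k] =
# d f_l / d x_k at row i). Used by the action functional, where per-point R
# dispatch would dominate the runtime.
model_batch <- function(model, X, need_jac = FALSE) UseMethod("model_batch")

#' @export
model_batch.toy_model <- function(model, X, need_jac = FALSE) {
  p <- model$params
  x1 <- X[, 1]; x2 <- X[, 2]
  g1 <- 2 * p$alpha * x1 - 4 * p$lambda * x1^3 - p$beta
  g2 <- -4 * p$lambda * x2^3
  Fm <- cbind(g1 - p$c * g2, p$c * g1 + g2)
  A <- matrix(p$sigma^2, nrow(X), 2)
  out <- list(F = Fm, A = A)
  if (need_jac) {
    n <- nrow(X)
    dg1 <- 2 * p$alpha - 12 * p$lambda * x1^2
    dg2 <- -12 * p$lambda * x2^2
    Jf <- array(0, c(n, 2, 2))
    Jf[, 1, 1] <- dg1
    Jf[, 1, 2] <- -p$c * dg2
    Jf[, 2, 1] <- p$c * dg1
    Jf[, 2, 2] <- dg2
    out$Jf <- Jf
    out$JA <- array(0, c(n, 2, 2))
  }
  out
}

# Parameter override used by schedules: returns params with one field replaced.
params_with <- function(params, name, value) {
  if (!name %in% names(params)) {
    stop(sprintf("unknown scheduled parameter '%s'", name))
  }
  params[[name]] <- value
  params
}
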