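#' Kinetic parameters of the four-gene developmental network
#'
#' The network tracks copy numbers of Nanog (N), the Oct4-Sox2 complex (O),
#' Fgf4 (F) and Gata6 (G); the LIF concentration \code{L} is an externally
#' controlled parameter. Two canonical parameter sets ship with the package:
#'
#' \describe{
#'   \item{\code{"calibrated"}}{(default) the printed kinetic constants with the
#'     degradation rate set to \code{kd = 0.01} and the Nanog/Gata6 coupling
#'     rebalanced (\code{k2 = 0.45}, \code{k11 = 0.05}, \code{k13 = 0.5},
#'     \code{k14 = 0.1}) so that the system has the three-fixed-point bistable
#'     structure (stem cell, transition, differentiated) across
#'     \code{L} in \code{[0, 200]}. Selected by the structural calibration gate
#'     [dev_structure_gate()].}
#'   \item{\code{"paper-printed"}}{the literal published constants
#'     (\code{kd = 1}); retained for reference, but monostable: it fails the
#'     structural gate at every LIF level.}
#' }
#'
#' @param set character, \code{"calibrated"} or \code{"paper-printed"}; ignored
#'   when individual constants are supplied via \code{...}.
#' @param L LIF concentration (external control), in \code{[0, 200]} for all
#'   shipped experiments.
#' @param ... named overrides for individual constants (\code{k0} ... \code{k14},
#'   \code{kd}).
#' @return An object of class \code{dev_params}: named list \code{k0..k14},
#'   \code{kd}, \code{L}.
#' @export
dev_params <- function(set = c("calibrated", "paper-printed"), L = 50, ...) {
  set <- match.arg(set)
  p <- list(
    k0 = 0.005, k1 = 0.01, k2 = 0.4, k3 = 1, k4 = 0.1, k5 = 0.00135,
    k6 = 0.01, k7 = 0.01, k8 = 1, k9 = 1, k10 = 0.01, k11 = 5, k12 = 1,
    k13 = 0.005, k14 = 1, kd = 1
  )
  if (set == "calibrated") {
    p$kd <- 0.01
    p$k2 <- 0.45
    p$k11 <- 0.05
    p$k13 <- 0.5
    p$k14 <- 0.1
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown developmental parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  p$L <- L
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("developmental parameter '%s' must be a finite non-negative scalar", nm))
    }
  }
  structure(p, class = "dev_params", set = set)
}

#' Load a developmental parameter set from a packaged or user config file
#'
#' Config files are flat key-value JSON; the two canonical sets ship under
#' \code{inst/extdata/params/}.
#'
#' @param path path to a JSON file, or one of the shorthand names
#'   \code{"calibrated"} / \code{"paper-printed"}.
#' @return A \code{dev_params} object.
#' @export
dev_params_from_config <- function(path) {
  if (path %in% c("calibrated", "paper-printed")) {
    path <- system.file("extdata", "params",
      paste0("dev-", path, ".json"),
      package = "epiland", mustWork = TRUE
    )
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  keys <- intersect(names(cfg), c(paste0("k", 0:14), "kd", "L"))
  args <- cfg[keys]
  do.call(dev_params, c(list(set = "paper-printed"), args))
}

dev_species <- c("N", "O", "F", "G")

check_dev_state <- function(x) {
  if (!is.numeric(x) || length(x) != 4L) {
    stop("developmental states are four-dimensional (N, O, F, G)")
  }
  if (any(!is.finite(x))) stop("developmental state contains non-finite values")
  if (any(x < 0)) stop("developmental state coordinates must be non-negative")
  as.numeric(x)
}

#' Reaction propensities of the developmental network
#'
#' Eight reactions: one effective birth process per species (Hill-type
#' quasi-equilibrium lumping of the regulatory interactions) and one first-order
#' degradation per species with rate \code{kd}.
#'
#' @param x non-negative numeric length-4 state \code{c(N, O, F, G)}.
#' @param params a [dev_params()] object.
#' @return Numeric vector of 8 non-negative rates \code{a1..a8}.
#' @export
dev_propensities <- function(x, params = dev_params()) {
  x <- check_dev_state(x)
  N <- x[1]; O <- x[2]; F_ <- x[3]; G <- x[4]
  p <- params
  a1 <- p$k0 * O * (p$k1 + p$k2 * N^2 + p$k0 * O + p$k3 * p$L) /
    (1 + p$k0 * O * (p$k2 * N^2 + p$k0 * O + p$k3 * p$L + p$k4 * F_^2) +
      p$k5 * O * G^2)
  a2 <- (p$k6 + p$k7 * O) / (1 + p$k7 * O + p$k8 * G^2)
  a3 <- (p$k9 + p$k10 * O) / (1 + p$k10 * O)
  a4 <- (p$k11 + p$k12 * G^2 + p$k14 * O) /
    (1 + p$k12 * G^2 + p$k13 * N^2 + p$k14 * O)
  c(a1, a2, a3, a4, p$kd * N, p$kd * O, p$kd * F_, p$kd * G)
}

#' Stoichiometry matrix of the developmental network
#'
#' Row i (species i) carries +1 in column i (birth) and -1 in column i + 4
#' (degradation).
#'
#' @return Integer 4 x 8 matrix with rownames N, O, F, G.
#' @export
dev_stoichiometry <- function() {
  S <- matrix(0L, nrow = 4, ncol = 8, dimnames = list(dev_species, NULL))
  for (i in 1:4) {
    S[i, i] <- 1L
    S[i, i + 4L] <- -1L
  }
  S
}

#' Deterministic drift (rate equations) of the developmental network
#'
#' \eqn{f(X) = S a(X)}; component i equals birth minus death propensity.
#'
#' @inheritParams dev_propensities
#' @return Named numeric length-4 vector.
#' @export
dev_drift <- function(x, params = dev_params()) {
  a <- dev_propensities(x, params)
  stats::setNames(a[1:4] - a[5:8], dev_species)
}

#' Diffusion (noise covariance) matrix of the chemical Langevin approximation
#'
#' \eqn{A(X) = S\,\mathrm{diag}(a)\,S^\top}; for this network the result is
#' diagonal with entry i equal to \eqn{a_i + a_{i+4}}.
#'
#' @inheritParams dev_propensities
#' @return 4 x 4 numeric matrix.
#' @export
dev_noise_covariance <- function(x, params = dev_params()) {
  a <- dev_propensities(x, params)
  diag(a[1:4] + a[5:8], nrow = 4)
}

# Analytic Jacobian of the birth propensities (4 x 4, d a_birth / d state);
# cross-checked against central differences in the test-suite.
dev_propensity_jacobian <- function(x, params) {
  x <- check_dev_state(x)
  N <- x[1]; O <- x[2]; F_ <- x[3]; G <- x[4]
  p <- params
  J <- matrix(0, 4, 4, dimnames = list(dev_species, dev_species))

  P <- p$k1 + p$k2 * N^2 + p$k0 * O + p$k3 * p$L
  R <- p$k2 * N^2 + p$k0 * O + p$k3 * p$L + p$k4 * F_^2
  Q <- 1 + p$k0 * O * R + p$k5 * O * G^2
  kOP <- p$k0 * O * P
  J[1, 1] <- 2 * p$k2 * N * p$k0 * O * (Q - kOP) / Q^2
  J[1, 2] <- (p$k0 * (P + p$k0 * O) * Q -
    kOP * (p$k0 * (R + p$k0 * O) + p$k5 * G^2)) / Q^2
  J[1, 3] <- -kOP * (p$k0 * O * 2 * p$k4 * F_) / Q^2
  J[1, 4] <- -kOP * (2 * p$k5 * O * G) / Q^2

  D2 <- 1 + p$k7 * O + p$k8 * G^2
  n2 <- p$k6 + p$k7 * O
  J[2, 2] <- (p$k7 * D2 - n2 * p$k7) / D2^2
  J[2, 4] <- -n2 * 2 * p$k8 * G / D2^2

  D3 <- 1 + p$k10 * O
  J[3, 2] <- p$k10 * (1 - p$k9) / D3^2

  D4 <- 1 + p$k12 * G^2 + p$k13 * N^2 + p$k14 * O
  n4 <- p$k11 + p$k12 * G^2 + p$k14 * O
  J[4, 1] <- -n4 * 2 * p$k13 * N / D4^2
  J[4, 2] <- (p$k14 * D4 - n4 * p$k14) / D4^2
  J[4, 4] <- (2 * p$k12 * G * D4 - n4 * 2 * p$k12 * G) / D4^2

  J
}

dev_jacobian <- function(x, params) {
  dev_propensity_jacobian(x, params) - diag(params$kd, 4)
}

#' Construct the developmental model object
#'
#' @param params a [dev_params()] object (carries the LIF level \code{L}).
#' @return Object of class \code{c("dev_model", "eland_model")}.
#' @export
dev_model <- function(params = dev_params()) {
  stopifnot(inherits(params, "dev_params"))
  structure(
    list(
      id = "dev4g",
      labels = dev_species,
      dim = 4L,
      params = params,
      schedulable = "L"
    ),
    class = c("dev_model", "eland_model")
  )
}

#' @export
model_drift.dev_model <- function(model, x, params = model$params) {
  dev_drift(x, params)
}

#' @export
model_jacobian.dev_model <- function(model, x, params = model$params) {
  dev_jacobian(x, params)
}

#' @export
model_noise_diag.dev_model <- function(model, x, params = model$params) {
  a <- dev_propensities(x, params)
  a[1:4] + a[5:8]
}

#' @export
model_noise_jacobian.dev_model <- function(model, x, params = model$params) {
  # d(diag A)/dx = d a_birth/dx + kd * I (death propensities are kd * x)
  dev_propensity_jacobian(x, params) + diag(params$kd, 4)
}

#' @export
model_batch.dev_model <- function(model, X, need_jac = FALSE) {
  p <- model$params
  N <- X[, 1]; O <- X[, 2]; F_ <- X[, 3]; G <- X[, 4]
  P <- p$k1 + p$k2 * N^2 + p$k0 * O + p$k3 * p$L
  R <- p$k2 * N^2 + p$k0 * O + p$k3 * p$L + p$k4 * F_^2
  Q <- 1 + p$k0 * O * R + p$k5 * O * G^2
  a1 <- p$k0 * O * P / Q
  D2 <- 1 + p$k7 * O + p$k8 * G^2
  n2 <- p$k6 + p$k7 * O
  a2 <- n2 / D2
  D3 <- 1 + p$k10 * O
  a3 <- (p$k9 + p$k10 * O) / D3
  D4 <- 1 + p$k12 * G^2 + p$k13 * N^2 + p$k14 * O
  n4 <- p$k11 + p$k12 * G^2 + p$k14 * O
  a4 <- n4 / D4
  births <- cbind(a1, a2, a3, a4, deparse.level = 0)
  dimnames(births) <- NULL
  deaths <- unname(p$kd * X)
  out <- list(F = births - deaths, A = births + deaths)
  if (need_jac) {
    n <- nrow(X)
    kOP <- p$k0 * O * P
    Jb <- array(0, c(n, 4, 4))
    Jb[, 1, 1] <- 2 * p$k2 * N * p$k0 * O * (Q - kOP) / Q^2
    Jb[, 1, 2] <- (p$k0 * (P + p$k0 * O) * Q -
      kOP * (p$k0 * (R + p$k0 * O) + p$k5 * G^2)) / Q^2
    Jb[, 1, 3] <- -kOP * (p$k0 * O * 2 * p$k4 * F_) / Q^2
    Jb[, 1, 4] <- -kOP * (2 * p$k5 * O * G) / Q^2
    Jb[, 2, 2] <- (p$k7 * D2 - n2 * p$k7) / D2^2
    Jb[, 2, 4] <- -n2 * 2 * p$k8 * G / D2^2
    Jb[, 3, 2] <- p$k10 * (1 - p$k9) / D3^2
    Jb[, 4, 1] <- -n4 * 2 * p$k13 * N / D4^2
    Jb[, 4, 2] <- (p$k14 * D4 - n4 * p$k14) / D4^2
    Jb[, 4, 4] <- (2 * p$k12 * G * D4 - n4 * 2 * p$k12 * G) / D4^2
    Jf <- Jb
    JA <- Jb
    for (k in 1:4) {
      Jf[, k, k] <- Jf[, k, k] - p$kd
      JA[, k, k] <- JA[, k, k] + p$kd
    }
    out$Jf <- Jf
    out$JA <- JA
  }
  out
}

#' The developmental reaction network
#'
#' Bundles species labels, the propensity evaluator and the stoichiometry
#' matrix for the exact stochastic simulation algorithm and the chemical
#' Langevin integrator.
#'
#' @inheritParams dev_model
#' @return Object of class \code{reaction_network}.
#' @export
dev_network <- function(params = dev_params()) {
  stopifnot(inherits(params, "dev_params"))
  structure(
    list(
      species = dev_species,
      n_reactions = 8L,
      params = params,
      propensities = function(x, p = params) dev_propensities(x, p),
      stoichiometry = dev_stoichiometry()
    ),
    class = "reaction_network"
  )
}
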