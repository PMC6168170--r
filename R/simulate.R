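#' Simulation configuration
#'
#' @param t_end simulation horizon (time units of the model).
#' @param dt integrator step for SDE/CLE integration; ignored by the exact SSA.
#' @param record_interval output sampling period; defaults to \code{dt}.
#' @param seed integer RNG seed; together with the configuration it fully
#'   determines every sample path.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(t_end, dt = NULL, record_interval = NULL, seed = 1L) {
  if (!is.numeric(t_end) || t_end <= 0) stop("'t_end' must be positive")
  if (is.null(record_interval)) record_interval <- if (is.null(dt)) t_end / 100 else dt
  if (!is.null(dt)) {
    if (dt <= 0 || dt > record_interval + 1e-12) {
      stop("need 0 < dt <= record_interval")
    }
    ratio <- record_interval / dt
    if (abs(ratio - round(ratio)) > 1e-8) {
      stop("'record_interval' must be an integer multiple of 'dt'")
    }
  }
  if (record_interval > t_end + 1e-12) stop("'record_interval' must not exceed 't_end'")
  structure(
    list(t_end = t_end, dt = dt, record_interval = record_interval,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

new_trajectory <- function(times, states, model_id, labels, seed,
                           schedule = NULL, config = NULL, diagnostics = list()) {
  colnames(states) <- labels
  structure(
    list(times = times, states = states, model_id = model_id, seed = seed,
         schedule = schedule, config = config, diagnostics = diagnostics),
    class = "eland_trajectory"
  )
}

#' @export
print.eland_trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory: %s> %d records over t = [%g, %g], seed %d\n",
    x$model_id, length(x$times), min(x$times), max(x$times), x$seed
  ))
  invisible(x)
}

#' Euler-Maruyama integration of a model SDE
#'
#' Fixed-step Euler-Maruyama integration. For the shipped models a compiled
#' kernel is used; any other model may be supplied as a list with fields
#' \code{drift(x, t)} (vector) and \code{sigma(x, t)} (per-coordinate noise
#' amplitude), plus \code{labels}.
#'
#' With \code{sigma = 0} the scheme reduces to explicit-Euler ODE integration.
#' Identical seed and configuration give bit-identical output.
#'
#' @param model a [toy_model()], or a generic list model (see Details).
#' @param x0 initial state.
#' @param config a [sim_config()] with non-null \code{dt}.
#' @param schedule optional [param_schedule()] applied to one model parameter.
#' @param drift_scale test hook: scales the drift (0 suppresses it, leaving
#'   pure Wiener increments).
#' @return An \code{eland_trajectory}.
#' @export
euler_maruyama <- function(model, x0, config, schedule = NULL, drift_scale = 1) {
  stopifnot(inherits(config, "sim_config"), !is.null(config$dt))
  set.seed(config$seed)
  if (inherits(model, "toy_model")) {
    x0 <- check_toy_point(x0)
    sch <- resolve_schedule(model, schedule)
    p <- model$params
    out <- em_toy_cpp(
      x0, p$alpha, p$lambda, p$beta, p$c, p$sigma,
      config$t_end, config$dt, config$record_interval,
      sch$mode, sch$from, sch$to, sch$duration, drift_scale
    )
    return(new_trajectory(out$times, out$states, model$id, model$labels,
      config$seed, schedule, config))
  }
  # Generic R-level integrator (used for custom drifts in tests).
  if (!is.list(model) || is.null(model$drift)) {
    stop("unsupported model for euler_maruyama()")
  }
  labels <- if (!is.null(model$labels)) model$labels else paste0("x", seq_along(x0))
  d <- length(x0)
  n_steps <- round(config$t_end / config$dt)
  rec_every <- round(config$record_interval / config$dt)
  n_rec <- n_steps %/% rec_every + 1
  states <- matrix(NA_real_, n_rec, d)
  times <- (0:(n_rec - 1)) * rec_every * config$dt
  x <- as.numeric(x0)
  states[1, ] <- x
  irec <- 2L
  sqdt <- sqrt(config$dt)
  for (s in seq_len(n_steps)) {
    t <- (s - 1) * config$dt
    f <- model$drift(x, t)
    sg <- if (is.function(model$sigma)) model$sigma(x, t) else model$sigma
    x <- x + drift_scale * f * config$dt + sg * sqdt * stats::rnorm(d)
    if (any(!is.finite(x))) {
      stop(sprintf("Euler-Maruyama integration produced a non-finite state at step %d", s))
    }
    if (s %% rec_every == 0) {
      states[irec, ] <- x
      irec <- irec + 1L
    }
  }
  new_trajectory(times, states, if (!is.null(model$id)) model$id else "custom",
    labels, config$seed, schedule, config)
}

#' Exact stochastic simulation (Gillespie) of a reaction network
#'
#' Exact sample path of the jump process, recorded on a uniform output grid.
#' When the LIF level is scheduled, propensities are frozen on a sub-grid of
#' width 1% of the ramp duration (documented piecewise-constant approximation).
#'
#' @param network a [dev_network()].
#' @param x0 non-negative integer initial copy numbers \code{c(N, O, F, G)}.
#' @param config a [sim_config()] (\code{dt} is ignored).
#' @param schedule optional [param_schedule()] for \code{"L"}.
#' @return An \code{eland_trajectory} with integer-valued states.
#' @export
ssa_gillespie <- function(network, x0, config, schedule = NULL) {
  stopifnot(inherits(network, "reaction_network"), inherits(config, "sim_config"))
  x0 <- check_dev_state(x0)
  if (any(abs(x0 - round(x0)) > 1e-9)) stop("SSA initial state must be integer copy numbers")
  p <- network$params
  if (!is.null(schedule) && schedule$parameter != "L") {
    stop("only the LIF level 'L' can be scheduled in the SSA")
  }
  sch <- resolve_schedule(dev_model(p), schedule)
  kvec <- unlist(p[c(paste0("k", 0:14), "kd")], use.names = FALSE)
  set.seed(config$seed)
  out <- ssa_dev_cpp(
    x0, kvec, config$t_end, config$record_interval,
    sch$mode, sch$from, sch$to, sch$duration, p$L
  )
  new_trajectory(out$times, out$states, "dev4g-ssa", network$species,
    config$seed, schedule, config)
}

#' Chemical Langevin integration of a reaction network
#'
#' Euler-Maruyama integration of the diffusion approximation
#' \eqn{dX = S a\,dt + S\,\mathrm{diag}(\sqrt{a})\,dW} with per-reaction noise
#' amplitude \eqn{\sqrt{a_j}} (the amplitude that reproduces the jump-process
#' increment covariance \eqn{S\,\mathrm{diag}(a)\,S^\top dt}). Coordinates are
#' clamped at zero after each step; the clamp count is recorded in
#' \code{diagnostics$clamped}.
#'
#' @inheritParams ssa_gillespie
#' @param config a [sim_config()] with non-null \code{dt}.
#' @param noise logical; \code{FALSE} integrates the deterministic rate
#'   equations (drift only).
#' @return An \code{eland_trajectory}.
#' @export
cle_integrate <- function(network, x0, config, schedule = NULL, noise = TRUE) {
  stopifnot(inherits(network, "reaction_network"), inherits(config, "sim_config"),
    !is.null(config$dt))
  x0 <- check_dev_state(x0)
  p <- network$params
  sch <- resolve_schedule(dev_model(p), schedule)
  kvec <- unlist(p[c(paste0("k", 0:14), "kd")], use.names = FALSE)
  set.seed(config$seed)
  out <- cle_dev_cpp(
    x0, kvec, config$t_end, config$dt, config$record_interval,
    sch$mode, sch$from, sch$to, sch$duration, p$L, noise
  )
  new_trajectory(out$times, out$states, "dev4g-cle", network$species,
    config$seed, schedule, config, diagnostics = list(clamped = out$clamped))
}

#' Uniform-box sampling of initial states
#'
#' Independent uniform draws per coordinate; used to emulate the printed
#' initial-condition regions (e.g. N in [60, 100], G in [0, 16]).
#'
#' @param ranges named list of length-2 numeric ranges, one per coordinate.
#' @param n number of samples.
#' @param seed integer seed.
#' @param integer_valued round to nearest integer (for SSA initial conditions).
#' @return Numeric matrix \code{n x d} with column names from \code{ranges}.
#' @export
sample_box <- function(ranges, n, seed = 1L, integer_valued = FALSE) {
  stopifnot(is.list(ranges), length(ranges) >= 1, n >= 1)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1] > r[2]) {
      stop(sprintf("range for '%s' must be c(low, high) with low <= high", nm))
    }
  }
  set.seed(seed)
  out <- vapply(ranges, function(r) stats::runif(n, r[1], r[2]), numeric(n))
  out <- matrix(out, nrow = n, dimnames = list(NULL, names(ranges)))
  if (integer_valued) out <- round(out)
  out
}

member_seed <- function(base_seed, index) {
  # Per-member streams derived by XOR so the ensemble is order-independent.
  bitwXor(as.integer(base_seed), as.integer(index))
}

#' Run a seeded ensemble of trajectories
#'
#' Launches \code{n} independent trajectories on a common record grid; member
#' i uses the seed \code{xor(base_seed, i)}, so members are reproducible
#' individually and the ensemble as a whole.
#'
#' @param simulator function \code{(x0, config, schedule) -> eland_trajectory},
#'   e.g. a partially applied [euler_maruyama()] / [ssa_gillespie()].
#' @param x0_sampler function \code{(n, seed) -> n x d matrix} of initial
#'   states (see [sample_box()]), or a fixed numeric state used for all members.
#' @param config a [sim_config()]; \code{config$seed} is the ensemble base seed.
#' @param n number of members, at least 2.
#' @param schedule optional [param_schedule()] shared by all members.
#' @return Object of class \code{eland_ensemble}: list with \code{times},
#'   \code{states} (array time x variable x member), \code{seeds}.
#' @export
run_ensemble <- function(simulator, x0_sampler, config, n, schedule = NULL) {
  stopifnot(n >= 2, inherits(config, "sim_config"))
  base_seed <- config$seed
  if (is.numeric(x0_sampler)) {
    x0_fixed <- x0_sampler
    x0s <- matrix(rep(x0_fixed, each = n), nrow = n)
  } else {
    x0s <- x0_sampler(n, base_seed)
  }
  seeds <- vapply(seq_len(n), function(i) member_seed(base_seed, i), integer(1))
  first <- NULL
  states <- NULL
  times <- NULL
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    tr <- tryCatch(
      simulator(x0s[i, ], cfg_i, schedule),
      error = function(e) {
        stop(sprintf("ensemble member %d (seed %d) failed: %s",
          i, seeds[i], conditionMessage(e)))
      }
    )
    if (is.null(states)) {
      times <- tr$times
      states <- array(NA_real_, dim = c(length(times), ncol(tr$states), n),
        dimnames = list(NULL, colnames(tr$states), NULL))
      first <- tr
    }
    states[, , i] <- tr$states
  }
  structure(
    list(times = times, states = states, base_seed = base_seed, seeds = seeds,
         model_id = first$model_id, schedule = schedule, config = config),
    class = "eland_ensemble"
  )
}

#' @export
print.eland_ensemble <- function(x, ...) {
  cat(sprintf(
    "<ensemble: %s> %d members, %d records over t = [%g, %g], base seed %d\n",
    x$model_id, dim(x$states)[3], length(x$times), min(x$times), max(x$times),
    x$base_seed
  ))
  invisible(x)
}

#' Extract member states from an ensemble
#'
#' @param ensemble an \code{eland_ensemble}.
#' @param time \code{"final"} for the last record, \code{"all"} to pool every
#'   record, or a numeric time (nearest record used).
#' @return Matrix with one row per pooled state.
#' @export
ensemble_states <- function(ensemble, time = "final") {
  st <- ensemble$states
  if (identical(time, "all")) {
    out <- apply(st, 2, rbind)
    return(matrix(out, ncol = dim(st)[2], dimnames = list(NULL, dimnames(st)[[2]])))
  }
  idx <- if (identical(time, "final")) length(ensemble$times) else which.min(abs(ensemble$times - time))
  t(st[idx, , , drop = TRUE])
}
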