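#' Discretized transition path
#'
#' Fixed-duration uniform time grid: \code{M} segments (\code{M + 1} states)
#' over total duration \code{T}, endpoints pinned.
#'
#' @param from,to endpoint states.
#' @param M number of segments (at least 8).
#' @param T_total total path duration.
#' @param states optional explicit (M + 1) x d state matrix (defaults to the
#'   straight line).
#' @return Object of class \code{discretized_path}.
#' @export
discretized_path <- function(from, to, M = 100, T_total = 20, states = NULL) {
  if (M < 8) stop("need at least M = 8 segments")
  from <- as.numeric(from); to <- as.numeric(to)
  d <- length(from)
  if (length(to) != d) stop("endpoint dimensionality mismatch")
  if (is.null(states)) {
    w <- seq(0, 1, length.out = M + 1)
    states <- outer(1 - w, from) + outer(w, to)
  }
  stopifnot(nrow(states) == M + 1, ncol(states) == d)
  if (any(!is.finite(states))) stop("path states must be finite")
  structure(
    list(from = from, to = to, M = as.integer(M), T_total = T_total,
         states = states),
    class = "discretized_path"
  )
}

#' @export
print.discretized_path <- function(x, ...) {
  cat(sprintf("<path> %d segments, duration %g, dim %d\n",
    x$M, x$T_total, ncol(x$states)))
  invisible(x)
}

# Conditioning-triggered regularization of the diffusion diagonals
# (epsilon = 1e-6 trace/d where cond > 1e8). Returns the regularized matrix
# plus the number of regularized midpoints.
regularize_noise_diag <- function(A) {
  d <- ncol(A)
  mx <- apply(A, 1, max)
  mn <- apply(A, 1, min)
  bad <- mx <= 0 | mx / pmax(mn, .Machine$double.xmin) > 1e8
  if (any(bad)) {
    A[bad, ] <- A[bad, , drop = FALSE] +
      1e-6 * rowSums(A[bad, , drop = FALSE]) / d + 1e-12
  }
  list(A = A, n_reg = sum(bad))
}

#' Freidlin-Wentzell action of a discretized path
#'
#' Midpoint-rule discretization of
#' \deqn{S[\phi] = \tfrac12 \int_0^T (\dot\phi - f(\phi))^\top A(\phi)^{-1}
#'   (\dot\phi - f(\phi))\, dt,}
#' where \eqn{A} is the model diffusion matrix (\eqn{\sigma^2 I} for the toy
#' system; \eqn{S\,\mathrm{diag}(a)\,S^\top} — diagonal — for the
#' developmental network, regularized where ill-conditioned).
#'
#' @param path a [discretized_path()].
#' @param model an \code{eland_model}.
#' @return Scalar action (non-negative).
#' @export
fw_action <- function(path, model) {
  stopifnot(inherits(path, "discretized_path"))
  action_core(path$states, path$T_total, model)$action
}

action_core <- function(X, T_total, model, need_jac = FALSE) {
  M <- nrow(X) - 1L
  h <- T_total / M
  mids <- (X[-1, , drop = FALSE] + X[-(M + 1), , drop = FALSE]) / 2
  V <- (X[-1, , drop = FALSE] - X[-(M + 1), , drop = FALSE]) / h
  bt <- model_batch(model, clamp_state(model, mids), need_jac = need_jac)
  nd <- regularize_noise_diag(bt$A)
  R <- V - bt$F
  list(
    action = 0.5 * h * sum(R^2 / nd$A),
    mids = mids, V = V, Fm = bt$F, A = nd$A, R = R, h = h, n_reg = nd$n_reg,
    Jf = bt$Jf, JA = bt$JA
  )
}

clamp_state <- function(model, x) {
  if (inherits(model, "dev_model")) pmax(x, 0) else x
}

# Action and analytic gradient with respect to the interior states.
action_with_grad <- function(free, from, to, M, T_total, model) {
  d <- length(from)
  X <- rbind(from, matrix(free, nrow = M - 1, ncol = d, byrow = TRUE), to)
  core <- action_core(X, T_total, model, need_jac = TRUE)
  h <- core$h
  RA <- core$R / core$A          # segment x d
  RA2 <- core$R^2 / core$A^2
  # per-midpoint contractions q[i, k] = sum_l Jf[i, l, k] * RA[i, l]
  q <- matrix(0, M, d)
  pA <- matrix(0, M, d)
  for (k in seq_len(d)) {
    q[, k] <- rowSums(core$Jf[, , k, drop = FALSE][, , 1] * RA)
    pA[, k] <- rowSums(core$JA[, , k, drop = FALSE][, , 1] * RA2)
  }
  j <- seq_len(M - 1)
  G <- RA[j, , drop = FALSE] - RA[j + 1, , drop = FALSE] -
    (h / 2) * (q[j, , drop = FALSE] + q[j + 1, , drop = FALSE]) -
    (h / 4) * (pA[j, , drop = FALSE] + pA[j + 1, , drop = FALSE])
  list(value = core$action, gradient = as.numeric(t(G)), n_reg = core$n_reg)
}

#' Minimize the Freidlin-Wentzell action between two fixed points
#'
#' Quasi-Newton (L-BFGS-B) minimization over the interior path states with
#' pinned endpoints and an analytic gradient. The total duration is selected
#' over a logarithmic grid (finite-duration paths approach the infinite-time
#' minimum action path as the duration grows); several seeded starts
#' (straight line, a via-point detour, and jittered copies) guard against
#' local minima, and the best action is kept.
#'
#' @param model an \code{eland_model}.
#' @param from,to endpoint states (validated fixed points).
#' @param M number of segments.
#' @param T_grid candidate total durations.
#' @param via optional via point (e.g. the transition state) used by one of
#'   the starts.
#' @param init optional state matrix (any resolution) used as an additional
#'   start after arc-length resampling, e.g. a reference path or a previous
#'   solution.
#' @param n_starts number of optimization starts per duration (default 5).
#' @param seed RNG seed for the jittered starts.
#' @param maxit L-BFGS-B iteration cap per start.
#' @return Object of class \code{action_result}: fields \code{path},
#'   \code{action}, \code{T_total}, \code{iterations}, \code{converged},
#'   \code{grad_norm}, \code{n_regularized}.
#' @export
minimize_action <- function(model, from, to, M = 100,
                            T_grid = c(5, 10, 20, 40, 80), via = NULL,
                            init = NULL, n_starts = 5, seed = 1L,
                            maxit = 400) {
  from <- as.numeric(from); to <- as.numeric(to)
  if (isTRUE(all.equal(from, to))) stop("'from' and 'to' must differ")
  d <- length(from)
  best <- NULL
  set.seed(seed)
  scale0 <- sqrt(sum((to - from)^2))
  for (T_total in T_grid) {
    inits <- list(discretized_path(from, to, M, T_total)$states)
    if (!is.null(init)) {
      ini <- arclength_resample(as.matrix(init), M + 1)
      ini[1, ] <- from; ini[M + 1, ] <- to
      inits[[length(inits) + 1L]] <- ini
    }
    if (!is.null(via)) {
      half <- floor((M + 1) / 2)
      w1 <- seq(0, 1, length.out = half)
      w2 <- seq(0, 1, length.out = M + 2 - half)
      inits[[2]] <- rbind(
        outer(1 - w1, from) + outer(w1, as.numeric(via)),
        (outer(1 - w2, as.numeric(via)) + outer(w2, to))[-1, , drop = FALSE]
      )
    }
    while (length(inits) < n_starts) {
      base <- inits[[1]]
      jit <- base + matrix(stats::rnorm(length(base), 0, 0.05 * scale0),
        nrow = nrow(base))
      jit[1, ] <- from; jit[nrow(jit), ] <- to
      inits[[length(inits) + 1L]] <- jit
    }
    for (ini in inits) {
      free0 <- as.numeric(t(ini[2:M, , drop = FALSE]))
      # memoize: optim calls fn and gr back-to-back at the same point
      cache <- new.env(parent = emptyenv())
      evalag <- function(z) {
        if (!is.null(cache$z) && identical(z, cache$z)) return(cache$ag)
        cache$z <- z
        cache$ag <- action_with_grad(z, from, to, M, T_total, model)
        cache$ag
      }
      fit <- stats::optim(
        free0,
        fn = function(z) evalag(z)$value,
        gr = function(z) evalag(z)$gradient,
        method = "L-BFGS-B",
        control = list(maxit = maxit, factr = 10, pgtol = 1e-9)
      )
      ag <- action_with_grad(fit$par, from, to, M, T_total, model)
      gn <- sqrt(sum(ag$gradient^2))
      if (is.null(best) || fit$value < best$action) {
        X <- rbind(from, matrix(fit$par, nrow = M - 1, byrow = TRUE), to)
        best <- structure(
          list(
            path = discretized_path(from, to, M, T_total, states = unname(X)),
            action = fit$value,
            T_total = T_total,
            iterations = fit$counts[["function"]],
            converged = gn < 1e-6 * (1 + abs(fit$value)),
            grad_norm = gn,
            n_regularized = ag$n_reg
          ),
          class = "action_result"
        )
      }
    }
  }
  best
}

#' @export
print.action_result <- function(x, ...) {
  cat(sprintf(
    "<action result> S = %.6g (T = %g, M = %d), converged: %s, |grad| = %.2e\n",
    x$action, x$T_total, x$path$M, x$converged, x$grad_norm
  ))
  invisible(x)
}

#' Reference uphill + free-fall transition path for the toy system
#'
#' For drift with an orthogonal curl component, the uphill leg of the minimum
#' action path follows the flow \eqn{\dot X = \nabla U + f_U} from the well to
#' the saddle. The heteroclinic connection is computed robustly by integrating
#' the reversed flow from a small offset off the saddle down into the chosen
#' well and reversing the result; the downhill ("free fall") continuation
#' integrates the true drift from the saddle into the other well.
#'
#' @param params [toy_params()].
#' @param well \code{"+"} (positive-x1 minimum) or \code{"-"}.
#' @param dt internal integrator step.
#' @param offset initial offset off the saddle.
#' @param well_tol integration cutoff radius around the wells. The transverse
#'   (\code{x2}) relaxation is cubic, so the heteroclinic tails approach the
#'   wells only algebraically; inside this radius the tail is essentially a
#'   straight crawl along \code{x2} at fixed \code{x1}, and is appended as a
#'   short linear segment to the exact well location. The saddle end of the
#'   uphill leg is exact to \code{offset} by construction.
#' @param max_time abort threshold for either leg.
#' @return List with \code{uphill} and \code{downhill}
#'   \code{discretized_path}s, plus the located \code{well}, \code{saddle} and
#'   \code{other_well} states.
#' @export
toy_uphill_reference_path <- function(params = toy_params(), well = c("+", "-"),
                                      dt = 1e-3, offset = 1e-4,
                                      well_tol = 0.05, max_time = 400) {
  well <- match.arg(well)
  model <- toy_model(params)
  fp <- find_fixed_points(model, n_starts = 60, seed = 7L)
  fp <- fp[order(fp[["x1"]]), ]
  if (nrow(fp) != 3) stop("expected three toy fixed points, found ", nrow(fp))
  # all toy fixed points lie exactly on the x2 = 0 symmetry axis; snap the
  # numerically flat transverse coordinate so axis symmetry is exact
  fp$x2[abs(fp$x2) < 1e-4] <- 0
  saddle <- as.numeric(fp[2, c("x1", "x2")])
  lo <- as.numeric(fp[1, c("x1", "x2")])
  hi <- as.numeric(fp[3, c("x1", "x2")])
  target <- if (well == "+") hi else lo
  other <- if (well == "+") lo else hi

  uphill_flow <- function(x) {
    dcmp <- toy_decomposition(x, params)
    -dcmp$gradient_part + dcmp$curl_part # grad U + f_U
  }
  dirn <- sign(target[1] - saddle[1])
  x <- saddle + c(dirn * offset, 0)
  pts <- list(x)
  t_acc <- 0
  repeat {
    x <- rk4_step(function(z) -uphill_flow(z), x, dt)
    t_acc <- t_acc + dt
    pts[[length(pts) + 1L]] <- x
    if (sqrt(sum((x - target)^2)) < well_tol) break
    if (t_acc > max_time) {
      stop(sprintf(
        "uphill leg failed to reach the well within %g time units (last state %.4g, %.4g)",
        max_time, x[1], x[2]))
    }
  }
  up <- rbind(tail_segment(target, pts[[length(pts)]]),
    do.call(rbind, rev(pts))) # well -> saddle orientation

  x <- saddle + c(-dirn * offset, 0)
  pts <- list(x)
  t_acc <- 0
  repeat {
    x <- rk4_step(function(z) toy_drift(z, params), x, dt)
    t_acc <- t_acc + dt
    pts[[length(pts) + 1L]] <- x
    if (sqrt(sum((x - other)^2)) < well_tol) break
    if (t_acc > max_time) {
      stop(sprintf(
        "free-fall leg failed to reach the opposite well within %g time units (last state %.4g, %.4g)",
        max_time, x[1], x[2]))
    }
  }
  down <- do.call(rbind, pts)
  t_down <- t_acc

  # The uphill leg is a geometric reference (tube comparisons): thinning plus
  # the appended well tail keep its point set dense along arc length. The
  # downhill leg keeps its raw uniform time grid so that its
  # Freidlin-Wentzell action is (numerically) zero.
  up_thin <- thin_rows(up, 1200)
  uphill <- discretized_path(up_thin[1, ], up_thin[nrow(up_thin), ],
    M = nrow(up_thin) - 1, T_total = dt * (nrow(up) - 1), states = up_thin)
  downhill <- discretized_path(down[1, ], down[nrow(down), ],
    M = nrow(down) - 1, T_total = t_down, states = down)
  list(
    uphill = uphill, downhill = downhill,
    well = target, saddle = saddle, other_well = other
  )
}

tail_segment <- function(from, to, n = 20) {
  w <- seq(0, 1, length.out = n)
  outer(1 - w, as.numeric(from)) + outer(w, as.numeric(to))
}

rk4_step <- function(f, x, h) {
  k1 <- f(x)
  k2 <- f(x + h / 2 * k1)
  k3 <- f(x + h / 2 * k2)
  k4 <- f(x + h * k3)
  x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

thin_rows <- function(m, max_rows) {
  if (nrow(m) <= max_rows) return(m)
  idx <- unique(round(seq(1, nrow(m), length.out = max_rows)))
  m[idx, , drop = FALSE]
}

# Resample a polyline to n points uniformly in arc length.
arclength_resample <- function(states, n = 200) {
  seg <- sqrt(rowSums((states[-1, , drop = FALSE] -
    states[-nrow(states), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] == 0) {
    return(matrix(states[1, ], n, ncol(states), byrow = TRUE))
  }
  grid <- seq(0, s[length(s)], length.out = n)
  out <- matrix(NA_real_, n, ncol(states))
  for (j in seq_len(ncol(states))) {
    out[, j] <- stats::approx(s, states[, j], xout = grid, ties = "ordered")$y
  }
  out
}

#' Symmetric separation between two paths
#'
#' Discrete Frechet distance after arc-length resampling of both paths to a
#' common number of points; symmetric, zero for identical paths, and
#' insensitive to the original parametrizations.
#'
#' @param a,b \code{discretized_path}s or state matrices of equal
#'   dimensionality.
#' @param n resampling resolution.
#' @return Non-negative scalar.
#' @export
path_separation <- function(a, b, n = 200) {
  A <- if (inherits(a, "discretized_path")) a$states else as.matrix(a)
  B <- if (inherits(b, "discretized_path")) b$states else as.matrix(b)
  if (ncol(A) != ncol(B)) stop("paths must share state dimensionality")
  A <- arclength_resample(A, n)
  B <- arclength_resample(B, n)
  # pairwise distances
  D <- outer(seq_len(n), seq_len(n), function(i, j) {
    sqrt(rowSums((A[i, , drop = FALSE] - B[j, , drop = FALSE])^2))
  })
  ca <- matrix(NA_real_, n, n)
  ca[1, 1] <- D[1, 1]
  for (i in 2:n) ca[i, 1] <- max(ca[i - 1, 1], D[i, 1])
  for (j in 2:n) ca[1, j] <- max(ca[1, j - 1], D[1, j])
  for (i in 2:n) {
    for (j in 2:n) {
      ca[i, j] <- max(min(ca[i - 1, j], ca[i - 1, j - 1], ca[i, j - 1]), D[i, j])
    }
  }
  ca[n, n]
}

# Maximum over points of A of the distance to the polyline point set B
# (one-sided tube radius; used for the MAP-vs-reference tube check).
max_min_distance <- function(A, B) {
  A <- if (inherits(A, "discretized_path")) A$states else as.matrix(A)
  B <- if (inherits(B, "discretized_path")) B$states else as.matrix(B)
  mx <- 0
  for (i in seq_len(nrow(A))) {
    dmin <- min(sqrt(colSums((t(B) - A[i, ])^2)))
    if (dmin > mx) mx <- dmin
  }
  mx
}
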