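#' Classify a fixed point from its Jacobian spectrum
#'
#' \code{stable} if every real part is below \code{-tol}; \code{saddle} if any
#' real part exceeds \code{+tol}; \code{marginal} otherwise. Eigenvalues with
#' \code{|Re| < tol} are additionally counted as marginal directions — the toy
#' system has an exactly-zero transverse eigenvalue everywhere on the
#' \code{x2 = 0} axis (a structural consequence of the purely quartic
#' transverse potential), so a saddle there is reported as a saddle with one
#' marginal direction flagged.
#'
#' @param eigenvalues complex (or numeric) spectrum.
#' @param tol marginality tolerance on real parts.
#' @return List with \code{classification} and \code{n_marginal}.
#' @export
classify_fixed_point <- function(eigenvalues, tol = 1e-8) {
  if (length(eigenvalues) == 0) stop("empty spectrum")
  re <- Re(eigenvalues)
  cls <- if (any(re > tol)) "saddle" else if (all(re < -tol)) "stable" else "marginal"
  list(classification = cls, n_marginal = sum(abs(re) < tol))
}

#' Jacobian of the model drift at a point
#'
#' @param model an \code{eland_model}.
#' @param x state.
#' @param method \code{"analytic"} (closed-form, the default cross-checked
#'   oracle pair) or \code{"central"} (central differences with step
#'   \code{step * (1 + |x|)} per coordinate).
#' @param step finite-difference step scale.
#' @return d x d numeric matrix.
#' @export
jacobian_at <- function(model, x, method = c("analytic", "central"),
                        step = 1e-6) {
  method <- match.arg(method)
  if (method == "analytic") {
    return(model_jacobian(model, x))
  }
  d <- length(x)
  J <- matrix(0, d, d)
  for (j in seq_len(d)) {
    h <- step * (1 + abs(x[j]))
    e <- rep(0, d); e[j] <- h
    J[, j] <- (model_drift(model, x + e) - model_drift(model, x - e)) / (2 * h)
  }
  J
}

# Stratified Latin-hypercube starting points in a box.
lhs_starts <- function(box, n, seed) {
  set.seed(seed)
  d <- nrow(box)
  pts <- matrix(NA_real_, n, d)
  for (j in seq_len(d)) {
    strata <- (sample.int(n) - stats::runif(n)) / n
    pts[, j] <- box[j, 1] + strata * (box[j, 2] - box[j, 1])
  }
  pts
}

# Damped Newton iteration for drift roots. Copy-number models are handled
# through an even reflection (the drift is evaluated at |x|), which keeps the
# propensities defined while letting Newton cross zero; other models iterate
# in the raw coordinates. Singular Jacobians (the toy system's cubically flat
# transverse direction) fall back to a pseudo-inverse step, and converged
# roots are polished well below the user tolerance so that structurally-zero
# eigenvalues are resolved.
newton_root <- function(model, x0, tol, max_iter = 120) {
  reflect <- inherits(model, "dev_model")
  tx <- function(x) if (reflect) abs(x) else x
  x <- x0
  best <- NULL
  best_nf <- Inf
  for (it in seq_len(max_iter)) {
    xa <- tx(x)
    f <- tryCatch(model_drift(model, xa), error = function(e) NULL)
    if (is.null(f) || any(!is.finite(f))) return(NULL)
    nf <- sqrt(sum(f^2))
    if (nf < best_nf) {
      best <- xa
      best_nf <- nf
    }
    if (nf < 1e-14) break
    J <- model_jacobian(model, xa)
    if (reflect) J <- J %*% diag(sign(x) + (x == 0), length(x))
    stp <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(stp) || any(!is.finite(stp))) {
      # pseudo-inverse step for (near-)singular Jacobians
      sv <- svd(J)
      keep <- sv$d > 1e-10 * max(sv$d, 1e-30)
      if (!any(keep)) return(NULL)
      stp <- -sv$v[, keep, drop = FALSE] %*%
        ((t(sv$u[, keep, drop = FALSE]) %*% f) / sv$d[keep])
      # descend the flat directions by a scaled gradient step
      stp <- as.numeric(stp) - 1e-2 * as.numeric(crossprod(J, f))
    }
    lam <- 1
    improved <- FALSE
    for (bt in 1:15) {
      xn <- x + lam * as.numeric(stp)
      fn <- tryCatch(model_drift(model, tx(xn)), error = function(e) NULL)
      if (!is.null(fn) && all(is.finite(fn)) && sqrt(sum(fn^2)) < nf) {
        improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved && nf < tol) break
    x <- x + lam * as.numeric(stp)
  }
  if (!is.null(best) && best_nf < tol) best else NULL
}

default_search_box <- function(model) {
  if (inherits(model, "toy_model")) {
    matrix(c(-2, 2, -2, 2), nrow = 2, byrow = TRUE)
  } else {
    matrix(rep(c(0, 150), model$dim), nrow = model$dim, byrow = TRUE)
  }
}

#' Locate fixed points of the deterministic drift
#'
#' Damped-Newton multistart from Latin-hypercube starting points, with
#' deduplication in box-scaled coordinates, independent residual
#' re-evaluation, Jacobian eigenvalues and stability classification.
#'
#' @param model an \code{eland_model}.
#' @param box d x 2 matrix of search bounds (rows = coordinates); defaults to
#'   \code{[-2, 2]^2} for the toy model and \code{[0, 150]^4} for the
#'   developmental model.
#' @param n_starts number of multistart points (default 200).
#' @param tol residual norm tolerance.
#' @param seed RNG seed for the starting points.
#' @param dedup_radius dedup radius in box-scaled coordinates.
#' @return data.frame (class \code{fixed_points}) with one row per root:
#'   coordinates, residual norm, eigenvalues (complex columns \code{ev1..evd}),
#'   \code{classification}, \code{n_marginal}, \code{branch} (labelled for the
#'   developmental model). Empty (zero-row) frame if no root is found.
#' @export
find_fixed_points <- function(model, box = default_search_box(model),
                              n_starts = 200, tol = 1e-9, seed = 1L,
                              dedup_radius = 1e-4) {
  stopifnot(n_starts >= 1)
  width <- box[, 2] - box[, 1]
  starts <- lhs_starts(box, n_starts, seed)
  roots <- list()
  margin <- 0.05 * width
  for (i in seq_len(nrow(starts))) {
    r <- newton_root(model, starts[i, ], tol)
    if (is.null(r)) next
    # report only roots inside (a small margin around) the search box
    if (any(r < box[, 1] - margin | r > box[, 2] + margin)) next
    dup <- FALSE
    for (r0 in roots) {
      if (sqrt(sum(((r - r0) / width)^2)) < dedup_radius) { dup <- TRUE; break }
    }
    if (!dup) roots[[length(roots) + 1L]] <- r
  }
  fixed_points_table(model, roots, tol)
}

fixed_points_table <- function(model, roots, tol) {
  d <- model$dim
  ev_cols <- paste0("ev", seq_len(d))
  if (length(roots) == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, d, dimnames = list(NULL, model$labels)))
    out$residual <- numeric(0)
    for (cn in ev_cols) out[[cn]] <- complex(0)
    out$classification <- character(0)
    out$n_marginal <- integer(0)
    out$branch <- character(0)
    attr(out, "diagnostic") <- "no roots found in the search box"
    class(out) <- c("fixed_points", class(out))
    return(out)
  }
  rows <- lapply(roots, function(r) {
    f <- model_drift(model, r)
    ev <- eigen(model_jacobian(model, r), only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    cl <- classify_fixed_point(ev)
    row <- as.data.frame(as.list(stats::setNames(r, model$labels)))
    row$residual <- sqrt(sum(f^2))
    for (j in seq_len(d)) row[[ev_cols[j]]] <- as.complex(ev[j])
    row$classification <- cl$classification
    row$n_marginal <- cl$n_marginal
    row
  })
  out <- do.call(rbind, rows)
  out$branch <- branch_labels(model, out)
  class(out) <- c("fixed_points", class(out))
  out
}

# Branch naming for the developmental model: stable high-Nanog = stem cell,
# stable high-Gata6 = differentiated, unstable = transition.
branch_labels <- function(model, fp) {
  if (!inherits(model, "dev_model")) return(rep("unlabeled", nrow(fp)))
  vapply(seq_len(nrow(fp)), function(i) {
    if (fp$classification[i] == "saddle") return("transition")
    if (fp$classification[i] == "stable" && fp$N[i] > fp$G[i]) return("stem-cell")
    if (fp$classification[i] == "stable" && fp$G[i] > fp$N[i]) return("differentiated")
    "unlabeled"
  }, character(1))
}

#' Sweep a control parameter and track fixed-point branches
#'
#' Locates fixed points at each parameter value and matches them into branches
#' by greedy nearest-neighbour assignment between consecutive values;
#' unmatched points open new branches, and a disappearing branch is recorded
#' (not an error).
#'
#' @param model an \code{eland_model} (parameter values are substituted into
#'   its parameter set).
#' @param parameter parameter name, e.g. \code{"L"} or \code{"beta"}.
#' @param values numeric vector (length >= 2) of parameter values.
#' @param seed seed for the per-value multistart.
#' @param jump maximum state-space distance for branch continuation.
#' @param ... passed to [find_fixed_points()].
#' @return data.frame with columns \code{value}, \code{branch}, coordinates,
#'   eigenvalues, \code{classification}.
#' @export
sweep_parameter <- function(model, parameter, values, seed = 1L, jump = 60,
                           ...) {
  stopifnot(length(values) >= 2)
  tables <- list()
  prev <- NULL
  next_id <- 1L
  d <- model$dim
  for (v in values) {
    m_v <- model
    m_v$params <- params_with(model$params, parameter, v)
    fp <- find_fixed_points(m_v, seed = seed, ...)
    fp$value <- rep(v, nrow(fp))
    fp$branch_id <- rep(NA_integer_, nrow(fp))
    if (!is.null(prev) && nrow(fp) > 0 && nrow(prev) > 0) {
      dmat <- as.matrix(stats::dist(rbind(
        as.matrix(prev[, model$labels, drop = FALSE]),
        as.matrix(fp[, model$labels, drop = FALSE])
      )))[seq_len(nrow(prev)), nrow(prev) + seq_len(nrow(fp)), drop = FALSE]
      # greedy global assignment by increasing distance
      repeat {
        if (all(!is.finite(dmat)) || min(dmat, na.rm = TRUE) > jump) break
        ij <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
        fp$branch_id[ij[2]] <- prev$branch_id[ij[1]]
        dmat[ij[1], ] <- Inf
        dmat[, ij[2]] <- Inf
        if (all(is.infinite(dmat))) break
      }
    }
    for (i in which(is.na(fp$branch_id))) {
      fp$branch_id[i] <- next_id
      next_id <- next_id + 1L
    }
    tables[[length(tables) + 1L]] <- fp
    prev <- fp
  }
  out <- do.call(rbind, tables)
  # name each branch by its most frequent label
  for (bid in unique(out$branch_id)) {
    rows <- out$branch_id == bid
    lab <- names(sort(table(out$branch[rows]), decreasing = TRUE))[1]
    out$branch[rows] <- lab
  }
  rownames(out) <- NULL
  out
}

#' Structural calibration gate for the developmental parameter set
#'
#' Checks the figure-level structure that a valid developmental parameter set
#' must reproduce: at every swept LIF level there are (at least) three fixed
#' points forming a stem-cell branch (stable, Nanog above Gata6), a
#' differentiated branch (stable, Gata6 above Nanog) and a transition branch
#' with at least one positive-real-part eigenvalue. This gate determines which
#' packaged parameter set may serve as the repository default.
#'
#' @param params a [dev_params()] object.
#' @param L_values LIF levels to check (default \code{seq(0, 200, by = 25)}).
#' @param seed multistart seed.
#' @return List with \code{pass} (logical), \code{sweep} (the branch table)
#'   and \code{reasons} (character vector of failed requirements).
#' @export
dev_structure_gate <- function(params, L_values = seq(0, 200, by = 25),
                               seed = 1L) {
  sweep <- sweep_parameter(dev_model(params), "L", L_values, seed = seed)
  reasons <- character(0)
  for (v in L_values) {
    sl <- sweep[sweep$value == v, ]
    has <- function(b) any(sl$branch == b)
    if (!(has("stem-cell") && has("differentiated") && has("transition"))) {
      reasons <- c(reasons, sprintf(
        "L = %g: branches found {%s}, need stem-cell/transition/differentiated",
        v, paste(sl$branch, collapse = ", ")
      ))
    }
    tr <- sl[sl$branch == "transition", ]
    if (nrow(tr) > 0 && !any(Re(tr$ev1) > 1e-8)) {
      reasons <- c(reasons, sprintf("L = %g: transition branch not unstable", v))
    }
  }
  list(pass = length(reasons) == 0, sweep = sweep, reasons = reasons)
}
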