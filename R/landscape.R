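#' Empirical probability landscape on a binned grid
#'
#' Bins samples over one or two chosen axes, normalizes to a probability mass
#' function, and (via [potential_from_density()]) attaches the quasi-potential
#' \eqn{U = -\ln(P + \epsilon)} with a pseudocount \eqn{\epsilon} so that
#' unexplored bins map to a finite plateau.
#'
#' @param samples numeric matrix with named columns (or an
#'   \code{eland_trajectory} / \code{eland_ensemble}, whose states are pooled).
#' @param axes character vector (length 1 or 2) of column names to bin over.
#' @param bins number of bins per axis (scalar or per-axis vector).
#' @param limits optional list of length-2 ranges per axis; default spans the
#'   1st-99th percentile of the data per axis.
#' @param pseudocount pseudo-mass added inside the log; default
#'   \code{0.5 / nrow(samples)} (Jeffreys-style).
#' @return Object of class \code{landscape_grid} with fields \code{axes},
#'   \code{edges}, \code{counts}, \code{mass}, \code{potential},
#'   \code{pseudocount}, \code{n_overflow}.
#' @export
histogram_density <- function(samples, axes, bins = 60, limits = NULL,
                              pseudocount = NULL) {
  samples <- as_state_matrix(samples)
  if (nrow(samples) < 1) stop("need at least one sample")
  if (!all(axes %in% colnames(samples))) {
    stop("unknown axis: ", paste(setdiff(axes, colnames(samples)), collapse = ", "))
  }
  d <- length(axes)
  if (!d %in% 1:2) stop("1 or 2 axes supported")
  bins <- rep(as.integer(bins), length.out = d)
  edges <- vector("list", d)
  names(edges) <- axes
  for (j in seq_len(d)) {
    if (!is.null(limits) && !is.null(limits[[axes[j]]])) {
      r <- limits[[axes[j]]]
    } else {
      r <- stats::quantile(samples[, axes[j]], c(0.01, 0.99), names = FALSE)
    }
    if (r[2] <= r[1]) r <- r + c(-0.5, 0.5) # degenerate data: widen
    edges[[j]] <- seq(r[1], r[2], length.out = bins[j] + 1L)
    if (any(diff(edges[[j]]) <= 0)) stop("degenerate (zero-width) bins")
  }
  idx <- lapply(seq_len(d), function(j) {
    findInterval(samples[, axes[j]], edges[[j]], rightmost.closed = TRUE)
  })
  inside <- Reduce(`&`, lapply(seq_len(d), function(j) {
    idx[[j]] >= 1L & idx[[j]] <= bins[j]
  }))
  n_over <- sum(!inside)
  counts <- array(0L, dim = bins)
  if (any(inside)) {
    flat <- idx[[1]][inside]
    if (d == 2L) flat <- flat + bins[1] * (idx[[2]][inside] - 1L)
    tab <- tabulate(flat, nbins = prod(bins))
    counts <- array(tab, dim = bins)
  }
  total <- sum(counts)
  if (total == 0) stop("no samples fall inside the grid limits")
  if (is.null(pseudocount)) pseudocount <- 0.5 / nrow(samples)
  grid <- structure(
    list(axes = axes, edges = edges, counts = counts, mass = counts / total,
         potential = NULL, pseudocount = pseudocount, n_overflow = n_over,
         n_samples = nrow(samples)),
    class = "landscape_grid"
  )
  potential_from_density(grid, pseudocount)
}

as_state_matrix <- function(samples) {
  if (inherits(samples, "eland_trajectory")) return(samples$states)
  if (inherits(samples, "eland_ensemble")) return(ensemble_states(samples, "all"))
  if (is.data.frame(samples)) samples <- as.matrix(samples)
  if (!is.matrix(samples)) stop("'samples' must be a matrix with named columns")
  samples
}

#' Attach the negative-log potential to a landscape grid
#'
#' \eqn{U = -\ln(P + \epsilon)}: the global potential minimum coincides with
#' the global mass maximum, and empty bins map to the finite cap
#' \eqn{-\ln \epsilon}.
#'
#' @param grid a \code{landscape_grid}.
#' @param pseudocount non-negative pseudo-mass; 0 is allowed but gives infinite
#'   potential on empty bins.
#' @return The grid with its \code{potential} field (re)computed.
#' @export
potential_from_density <- function(grid, pseudocount = grid$pseudocount) {
  stopifnot(inherits(grid, "landscape_grid"))
  if (!is.numeric(pseudocount) || pseudocount < 0) {
    stop("'pseudocount' must be non-negative")
  }
  grid$pseudocount <- pseudocount
  grid$potential <- -log(grid$mass + pseudocount)
  grid
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf(
    "<landscape grid> axes: %s; bins: %s; %d samples (%d outside grid)\n",
    paste(x$axes, collapse = " x "),
    paste(dim(x$counts), collapse = " x "), x$n_samples, x$n_overflow
  ))
  invisible(x)
}

bin_centers <- function(edges) (utils::head(edges, -1) + utils::tail(edges, -1)) / 2

#' Marginal distribution along one axis
#'
#' Either sums a 2D grid over the other axis, or bins raw samples directly.
#'
#' @param x a \code{landscape_grid} or a sample matrix.
#' @param axis axis name.
#' @param ... passed to [histogram_density()] when \code{x} is raw samples.
#' @return A \code{landscape_grid} over the single axis.
#' @export
marginalize <- function(x, axis, ...) {
  if (!inherits(x, "landscape_grid")) {
    return(histogram_density(x, axes = axis, ...))
  }
  j <- match(axis, x$axes)
  if (is.na(j)) stop(sprintf("unknown axis '%s'", axis))
  counts <- if (length(x$axes) == 1L) x$counts else {
    as.array(apply(x$counts, j, sum))
  }
  grid <- structure(
    list(axes = axis, edges = x$edges[j], counts = counts,
         mass = counts / sum(counts), potential = NULL,
         pseudocount = x$pseudocount, n_overflow = x$n_overflow,
         n_samples = x$n_samples),
    class = "landscape_grid"
  )
  potential_from_density(grid)
}

#' Local modes of a landscape grid
#'
#' A bin is a mode if its mass exceeds all of its (8-connected in 2D)
#' neighbours and carries at least \code{min_mass} of the total mass. The
#' mass threshold makes detection robust to Monte Carlo noise at reduced
#' sample sizes.
#'
#' @param grid a \code{landscape_grid}.
#' @param min_mass minimum bin mass for a mode (default 1%).
#' @return data.frame of mode bin indices, centers and masses.
#' @export
landscape_modes <- function(grid, min_mass = 0.01) {
  m <- grid$mass
  if (length(grid$axes) == 1L) {
    n <- length(m)
    res <- data.frame()
    for (i in seq_len(n)) {
      nb <- m[intersect(c(i - 1, i + 1), seq_len(n))]
      if (m[i] >= min_mass && all(m[i] > nb)) {
        res <- rbind(res, data.frame(
          i = i, center = bin_centers(grid$edges[[1]])[i], mass = m[i]
        ))
      }
    }
    return(res)
  }
  nr <- nrow(m); nc <- ncol(m)
  res <- data.frame()
  cx <- bin_centers(grid$edges[[1]])
  cy <- bin_centers(grid$edges[[2]])
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (m[i, j] < min_mass) next
      ii <- intersect((i - 1):(i + 1), seq_len(nr))
      jj <- intersect((j - 1):(j + 1), seq_len(nc))
      nb <- m[ii, jj, drop = FALSE]
      self <- outer(ii == i, jj == j, "&")
      if (all(m[i, j] > nb[!self])) {
        res <- rbind(res, data.frame(
          i = i, j = j, center1 = cx[i], center2 = cy[j], mass = m[i, j]
        ))
      }
    }
  }
  res
}

#' Total-variation distance between two landscape grids
#'
#' Grids must share bin edges. Used for the curl-indistinguishability check:
#' stationary histograms with and without the curl component are practically
#' identical.
#'
#' @param a,b \code{landscape_grid}s on identical edges.
#' @return Scalar in [0, 1].
#' @export
tv_distance <- function(a, b) {
  stopifnot(inherits(a, "landscape_grid"), inherits(b, "landscape_grid"))
  if (!isTRUE(all.equal(a$edges, b$edges))) stop("grids must share bin edges")
  sum(abs(a$mass - b$mass)) / 2
}

#' Per-variable ensemble variance over time
#'
#' Unbiased (n - 1) variance across ensemble members at each record time; the
#' transitory-landscape signature is an interior maximum of this series for
#' the switching variable.
#'
#' @param ensemble an \code{eland_ensemble} with at least 2 members.
#' @return data.frame: \code{time} plus one variance column per variable.
#' @export
variance_timeseries <- function(ensemble) {
  stopifnot(inherits(ensemble, "eland_ensemble"))
  n <- dim(ensemble$states)[3]
  if (n < 2) stop("ensemble variance needs at least 2 members")
  v <- apply(ensemble$states, c(1, 2), stats::var)
  out <- data.frame(time = ensemble$times)
  for (j in seq_len(ncol(v))) out[[colnames(ensemble$states)[j]]] <- v[, j]
  out
}
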