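# Plain-text serialization (schema version 1). Trajectories and ensembles are
# written as CSV; scalars and diagnostics as JSON sidecars.

ELAND_SCHEMA_VERSION <- "1"

#' Write a trajectory to CSV
#'
#' Long format: \code{time} plus one column per variable; a \code{#}-prefixed
#' header line records the schema version, model id and seed.
#'
#' @param trajectory an \code{eland_trajectory}.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# epiland trajectory v%s model=%s seed=%d",
    ELAND_SCHEMA_VERSION, trajectory$model_id, trajectory$seed
  ), con)
  df <- data.frame(time = trajectory$times, trajectory$states,
    check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory_csv()]
#' @param path CSV file.
#' @return An \code{eland_trajectory}.
#' @export
read_trajectory_csv <- function(path) {
  header <- readLines(path, n = 1)
  df <- utils::read.csv(path, comment.char = "#")
  model_id <- sub(".*model=(\\S+).*", "\\1", header)
  seed <- as.integer(sub(".*seed=(-?\\d+).*", "\\1", header))
  new_trajectory(df$time, as.matrix(df[, -1, drop = FALSE]), model_id,
    colnames(df)[-1], seed)
}

#' Write an ensemble to CSV (long format: member, time, variables)
#' @param ensemble an \code{eland_ensemble}.
#' @param path output file.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  n <- dim(ensemble$states)[3]
  blocks <- lapply(seq_len(n), function(i) {
    data.frame(member = i, seed = ensemble$seeds[i], time = ensemble$times,
      ensemble$states[, , i], check.names = FALSE)
  })
  df <- do.call(rbind, blocks)
  colnames(df)[-(1:3)] <- dimnames(ensemble$states)[[2]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# epiland ensemble v%s model=%s base_seed=%d",
    ELAND_SCHEMA_VERSION, ensemble$model_id, ensemble$base_seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a landscape grid to CSV (long format: bin centers, mass, potential)
#' @param grid a \code{landscape_grid}.
#' @param path output file.
#' @export
write_landscape_csv <- function(grid, path) {
  centers <- lapply(grid$edges, bin_centers)
  if (length(grid$axes) == 1L) {
    df <- data.frame(centers[[1]], mass = as.vector(grid$mass),
      potential = as.vector(grid$potential))
    names(df)[1] <- grid$axes[1]
  } else {
    df <- expand.grid(centers[[1]], centers[[2]])
    names(df) <- grid$axes
    df$mass <- as.vector(grid$mass)
    df$potential <- as.vector(grid$potential)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# epiland landscape v%s pseudocount=%g overflow=%d",
    ELAND_SCHEMA_VERSION, grid$pseudocount, grid$n_overflow), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a fixed-point sweep table to CSV
#' @param sweep output of [sweep_parameter()].
#' @param path output file.
#' @export
write_sweep_csv <- function(sweep, path) {
  df <- sweep
  for (cn in names(df)) {
    if (is.complex(df[[cn]])) {
      df[[paste0(cn, "_re")]] <- Re(df[[cn]])
      df[[paste0(cn, "_im")]] <- Im(df[[cn]])
      df[[cn]] <- NULL
    }
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a transition path as CSV plus a JSON action sidecar
#'
#' CSV layout: arc-length coordinate followed by per-species values; the
#' sidecar (same path with extension \code{.json}) records the action and
#' optimizer diagnostics.
#'
#' @param result an \code{action_result} (or bare \code{discretized_path}).
#' @param path CSV output file.
#' @param labels variable names.
#' @export
write_path_csv <- function(result, path, labels = NULL) {
  p <- if (inherits(result, "action_result")) result$path else result
  st <- p$states
  seg <- sqrt(rowSums((st[-1, , drop = FALSE] - st[-nrow(st), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  s <- if (max(s) > 0) s / max(s) else s
  df <- data.frame(arclength = s, st)
  if (!is.null(labels)) colnames(df)[-1] <- labels
  utils::write.csv(df, path, row.names = FALSE)
  if (inherits(result, "action_result")) {
    side <- list(
      action = result$action, T_total = result$T_total,
      iterations = result$iterations, converged = result$converged,
      grad_norm = result$grad_norm, n_regularized = result$n_regularized,
      schema = ELAND_SCHEMA_VERSION
    )
    jsonlite::write_json(side, sub("\\.csv$", ".json", path),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
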