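# Named, config-driven experiment recipes. Each recipe reproduces the numeric
# content of one results figure of the analysis end-to-end and runs at a
# reduced "desk" scale (default) or at "full" scale.

recipe_ids <- c(
  "fig1_landscape", "fig2_saddle_escape", "fig3_toy_transitory",
  "fig4_dev_landscape", "fig5_differentiation_paths", "fig6_maps",
  "fig7_L_sweep", "fig8_dev_transitory"
)

# Stem-cell initial-condition region: N and G ranges as printed; O and F
# ranges bracket the stem fixed point (documented package choice).
stem_box <- function() {
  list(N = c(60, 100), O = c(5, 15), F = c(80, 120), G = c(0, 16))
}

fnv_hash <- function(x) {
  bytes <- as.integer(charToRaw(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

bundle_init <- function(recipe, scale, seed, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  list(
    recipe = recipe, scale = scale, seed = seed, config = config,
    config_hash = fnv_hash(config),
    package_version = as.character(utils::packageVersion("epiland")),
    out_dir = out_dir, files = character(0), summary = list()
  )
}

bundle_finish <- function(bundle) {
  bundle$files <- c(bundle$files, "summary.json", "provenance.json")
  prov <- bundle[c("recipe", "scale", "seed", "config", "config_hash",
    "package_version", "files")]
  jsonlite::write_json(prov, file.path(bundle$out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$summary, file.path(bundle$out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA)
  class(bundle) <- "output_bundle"
  invisible(bundle)
}

#' @export
print.output_bundle <- function(x, ...) {
  cat(sprintf("<bundle %s/%s> seed %d -> %s\n  files: %s\n",
    x$recipe, x$scale, x$seed, x$out_dir, paste(x$files, collapse = ", ")))
  invisible(x)
}

bundle_add <- function(bundle, file) {
  bundle$files <- c(bundle$files, basename(file))
  bundle
}

#' Run a named experiment recipe
#'
#' Executes a full pipeline (simulation, then landscape / fixed-point / action
#' analysis as appropriate) and writes a self-describing output bundle
#' (CSV data files, \code{summary.json}, \code{provenance.json}).
#'
#' @param recipe one of \code{"fig1_landscape"}, \code{"fig2_saddle_escape"},
#'   \code{"fig3_toy_transitory"}, \code{"fig4_dev_landscape"},
#'   \code{"fig5_differentiation_paths"}, \code{"fig6_maps"},
#'   \code{"fig7_L_sweep"}, \code{"fig8_dev_transitory"}.
#' @param scale \code{"desk"} (reduced, minutes) or \code{"full"}.
#' @param seed base seed for all randomness in the recipe.
#' @param out_dir output directory (created if needed).
#' @param param_set developmental parameter set selector.
#' @param overrides named list of recipe-config overrides (e.g. \code{n},
#'   \code{t_end}).
#' @return An \code{output_bundle}, invisibly.
#' @export
run_recipe <- function(recipe, scale = c("desk", "full"), seed = 1L,
                       out_dir = file.path(tempdir(), recipe),
                       param_set = c("calibrated", "paper-printed"),
                       overrides = list()) {
  scale <- match.arg(scale)
  param_set <- match.arg(param_set)
  if (!recipe %in% recipe_ids) {
    stop(sprintf("unknown recipe '%s'; choices: %s", recipe,
      paste(recipe_ids, collapse = ", ")))
  }
  fun <- get(paste0("recipe_", recipe), mode = "function")
  fun(scale, as.integer(seed), out_dir, param_set, overrides)
}

recipe_config <- function(defaults, scale_overrides, user_overrides) {
  cfg <- utils::modifyList(defaults, scale_overrides)
  utils::modifyList(cfg, user_overrides)
}

# -- fig 1: stationary toy landscape and minimum action paths ----------------
recipe_fig1_landscape <- function(scale, seed, out_dir, param_set, overrides) {
  cfg <- recipe_config(
    list(t_end = 40000, dt = 1e-3, record = 0.2, bins = 60, M = 100,
      n_starts = 3),
    if (scale == "desk") list(t_end = 5000, M = 60, n_starts = 2) else list(),
    overrides
  )
  b <- bundle_init("fig1_landscape", scale, seed, cfg, out_dir)
  model <- toy_model()
  tr <- euler_maruyama(model, c(1, 0),
    sim_config(cfg$t_end, cfg$dt, cfg$record, seed))
  grid <- histogram_density(tr$states, c("x1", "x2"), bins = cfg$bins,
    limits = list(x1 = c(-2, 2), x2 = c(-2, 2)))
  f1 <- file.path(out_dir, "landscape.csv")
  write_landscape_csv(grid, f1); b <- bundle_add(b, f1)
  modes <- landscape_modes(grid)
  fp <- find_fixed_points(model, seed = seed)
  fp <- fp[order(fp$x1), ]
  fwd <- minimize_action(model, unlist(fp[3, c("x1", "x2")]),
    unlist(fp[1, c("x1", "x2")]), M = cfg$M,
    via = unlist(fp[2, c("x1", "x2")]), n_starts = cfg$n_starts, seed = seed)
  rev <- minimize_action(model, unlist(fp[1, c("x1", "x2")]),
    unlist(fp[3, c("x1", "x2")]), M = cfg$M,
    via = unlist(fp[2, c("x1", "x2")]), n_starts = cfg$n_starts, seed = seed + 1L)
  f2 <- file.path(out_dir, "map_forward.csv")
  f3 <- file.path(out_dir, "map_reverse.csv")
  write_path_csv(fwd, f2, model$labels); b <- bundle_add(b, f2)
  write_path_csv(rev, f3, model$labels); b <- bundle_add(b, f3)
  b$summary <- list(
    n_modes = nrow(modes),
    mode_centers = if (nrow(modes)) modes[, c("center1", "center2")] else NULL,
    action_forward = fwd$action, action_reverse = rev$action,
    overflow_fraction = grid$n_overflow / grid$n_samples
  )
  bundle_finish(b)
}

# -- fig 2: escape from the saddle for small/large positive eigenvalue -------
recipe_fig2_saddle_escape <- function(scale, seed, out_dir, param_set, overrides) {
  cfg <- recipe_config(
    list(n = 50, t_end = 8, dt = 1e-3, record = 0.02, alphas = c(0.4, 1.6)),
    if (scale == "desk") list(n = 20) else list(),
    overrides
  )
  b <- bundle_init("fig2_saddle_escape", scale, seed, cfg, out_dir)
  esc <- list()
  for (alpha in cfg$alphas) {
    # alpha / lambda held at the default ratio 2
    p <- toy_params(alpha = alpha, lambda = alpha / 2, beta = 0)
    model <- toy_model(p)
    ens <- run_ensemble(
      function(x0, c2, sch) euler_maruyama(model, x0, c2, sch),
      c(0, 0), sim_config(cfg$t_end, cfg$dt, cfg$record, seed), cfg$n
    )
    f <- file.path(out_dir, sprintf("trajectories_alpha_%g.csv", alpha))
    write_ensemble_csv(ens, f); b <- bundle_add(b, f)
    # first time |x1| exceeds half the well position (escape proxy)
    t_esc <- apply(abs(ens$states[, "x1", ]) > 0.5, 2, function(z) {
      i <- which(z)[1]
      if (is.na(i)) NA_real_ else ens$times[i]
    })
    esc[[sprintf("alpha_%g", alpha)]] <- list(
      saddle_eigenvalue = 2 * alpha,
      median_escape_time = stats::median(t_esc, na.rm = TRUE),
      frac_escaped = mean(!is.na(t_esc))
    )
  }
  b$summary <- esc
  bundle_finish(b)
}

# Two-stage toy simulator: equilibrate at the ramp's start tilt, then ramp.
toy_transitory_simulator <- function(model, burn_t, ramp) {
  function(x0, cfg, sch) {
    burn_cfg <- sim_config(burn_t, cfg$dt, burn_t,
      bitwXor(cfg$seed, 987654321L))
    burn <- euler_maruyama(model, x0, burn_cfg,
      constant_schedule("beta", ramp$from))
    x1 <- burn$states[nrow(burn$states), ]
    euler_maruyama(model, x1, cfg, ramp)
  }
}

# -- fig 3: toy transitory landscape (beta ramp ensemble) --------------------
recipe_fig3_toy_transitory <- function(scale, seed, out_dir, param_set, overrides) {
  # The tilt follows beta = t - 0.5 exactly over the one-unit ramp and is then
  # held at +0.5; the observation window extends to t_end because the
  # ensemble's stochastic switching (and hence the variance peak) lags the
  # ramp at these parameters (see the methods vignette).
  cfg <- recipe_config(
    list(n = 5000, burn = 2, ramp_duration = 1, t_end = 12, dt = 1e-3,
      record = 0.05, beta_from = -0.5, beta_to = 0.5, stat_t = 2000),
    if (scale == "desk") list(n = 500, stat_t = 500) else list(),
    overrides
  )
  b <- bundle_init("fig3_toy_transitory", scale, seed, cfg, out_dir)
  model <- toy_model()
  ramp <- param_schedule("beta", "linear", cfg$beta_from, cfg$beta_to,
    duration = cfg$ramp_duration)
  # start well: minimum of the tilted potential at beta_from
  x_start <- toy_ramp_start(model$params, cfg$beta_from)
  ens <- run_ensemble(
    toy_transitory_simulator(model, cfg$burn, ramp),
    x_start, sim_config(cfg$t_end, cfg$dt, cfg$record, seed), cfg$n,
    schedule = ramp
  )
  vts <- variance_timeseries(ens)
  f1 <- file.path(out_dir, "variance_timeseries.csv")
  utils::write.csv(vts, f1, row.names = FALSE); b <- bundle_add(b, f1)
  # stationary marginals at three tilt values
  margs <- list()
  for (beta in c(cfg$beta_from, 0, cfg$beta_to)) {
    m2 <- toy_model(toy_params(beta = beta))
    tr <- euler_maruyama(m2, x_start,
      sim_config(cfg$stat_t, cfg$dt, 0.1, bitwXor(seed, 1000L + round(100 * beta))))
    mg <- marginalize(tr$states, "x1", bins = 60, limits = list(x1 = c(-2, 2)))
    f <- file.path(out_dir, sprintf("marginal_x1_beta_%+.2f.csv", beta))
    write_landscape_csv(mg, f); b <- bundle_add(b, f)
    margs[[sprintf("beta_%+.2f", beta)]] <- nrow(landscape_modes(mg))
  }
  i_max <- which.max(vts$x1)
  b$summary <- list(
    var_x1_peak = max(vts$x1), var_x1_peak_time = vts$time[i_max],
    var_x1_start = vts$x1[1], var_x1_end = vts$x1[nrow(vts)],
    var_x2_ratio = max(vts$x2) / min(vts$x2),
    marginal_mode_counts = margs
  )
  bundle_finish(b)
}

toy_ramp_start <- function(params, beta) {
  p <- params
  p$beta <- beta
  fp <- find_fixed_points(toy_model(p), n_starts = 60, seed = 11L)
  fp <- fp[fp$classification != "saddle", , drop = FALSE]
  i <- which.max(fp$x1) # the positive-x1 well is the favored start
  c(fp$x1[i], fp$x2[i])
}

# -- fig 4: developmental probabilistic landscape at L = 50 ------------------
recipe_fig4_dev_landscape <- function(scale, seed, out_dir, param_set, overrides) {
  cfg <- recipe_config(
    list(n = 2000, t_end = 2000, record = 2000, L = 50, bins = 60),
    if (scale == "desk") list(n = 600, bins = 40) else list(),
    overrides
  )
  b <- bundle_init("fig4_dev_landscape", scale, seed, cfg, out_dir)
  net <- dev_network(dev_params(param_set, L = cfg$L))
  ens <- run_ensemble(
    function(x0, c2, sch) ssa_gillespie(net, x0, c2, sch),
    function(n, s) sample_box(stem_box(), n, s, integer_valued = TRUE),
    sim_config(cfg$t_end, record_interval = cfg$record, seed = seed), cfg$n
  )
  finals <- ensemble_states(ens, "final")
  grid <- histogram_density(finals, c("G", "N"), bins = cfg$bins,
    limits = list(G = c(0, 120), N = c(0, 120)))
  f1 <- file.path(out_dir, "landscape_GN.csv")
  write_landscape_csv(grid, f1); b <- bundle_add(b, f1)
  modes <- landscape_modes(grid)
  b$summary <- list(
    n_modes = nrow(modes),
    frac_stem = mean(finals[, "N"] > finals[, "G"]),
    frac_differentiated = mean(finals[, "G"] > finals[, "N"])
  )
  bundle_finish(b)
}

# -- fig 5: differentiation / reprogramming / plateau trajectories -----------
recipe_fig5_differentiation_paths <- function(scale, seed, out_dir, param_set,
                                              overrides) {
  cfg <- recipe_config(
    list(n_show = 5, n_A = 100, n_B = 200, n_C = 50, n_D = 50, n_E = 50,
      t_end = 2000, record = 10, noise_E = 5),
    if (scale == "desk") list(n_A = 50, n_C = 30, n_D = 30, n_E = 30) else list(),
    overrides
  )
  b <- bundle_init("fig5_differentiation_paths", scale, seed, cfg, out_dir)
  params <- dev_params(param_set)
  fp <- find_fixed_points(dev_model(dev_params(param_set, L = 50)), seed = seed)
  diffd <- round(unlist(fp[fp$branch == "differentiated", dev_species][1, ]))
  trans <- unlist(fp[fp$branch == "transition", dev_species][1, ])

  run_panel <- function(panel, L, sampler, n) {
    net <- dev_network(dev_params(param_set, L = L))
    ens <- run_ensemble(
      function(x0, c2, sch) ssa_gillespie(net, x0, c2, sch),
      sampler, sim_config(cfg$t_end, record_interval = cfg$record,
        seed = bitwXor(seed, utf8ToInt(panel) * 1000L)), n
    )
    # "randomly selected" display trajectories = first n_show member seeds
    k <- min(cfg$n_show, n)
    show <- ens
    show$states <- ens$states[, , seq_len(k), drop = FALSE]
    show$seeds <- ens$seeds[seq_len(k)]
    f <- file.path(out_dir, sprintf("panel_%s_trajectories.csv", panel))
    write_ensemble_csv(show, f)
    list(ens = ens, file = f)
  }

  boxes <- list(
    A = stem_box(),
    C = list(N = c(60, 100), O = c(60, 100), F = c(10, 50), G = c(60, 100)),
    D = list(N = c(20, 50), O = c(60, 100), F = c(60, 100), G = c(60, 100))
  )
  summary <- list()

  pa <- run_panel("A", 0,
    function(n, s) sample_box(boxes$A, n, s, integer_valued = TRUE), cfg$n_A)
  b <- bundle_add(b, pa$file)
  finals <- ensemble_states(pa$ens, "final")
  summary$A <- list(frac_differentiated = mean(finals[, "G"] > finals[, "N"]))

  pb <- run_panel("B", 200, diffd, cfg$n_B)
  b <- bundle_add(b, pb$file)
  finals <- ensemble_states(pb$ens, "final")
  summary$B <- list(frac_reprogrammed = mean(finals[, "N"] > finals[, "G"]))

  for (panel in c("C", "D")) {
    pp <- run_panel(panel, 0,
      function(n, s) sample_box(boxes[[panel]], n, s, integer_valued = TRUE),
      cfg[[paste0("n_", panel)]])
    b <- bundle_add(b, pp$file)
    finals <- ensemble_states(pp$ens, "final")
    # fraction whose path visited the low-Nanog/low-Gata6 transition region
    visited <- apply(
      pp$ens$states[, "N", , drop = FALSE] < 40 &
        pp$ens$states[, "G", , drop = FALSE] < 40, 3, any)
    summary[[panel]] <- list(
      frac_differentiated = mean(finals[, "G"] > finals[, "N"]),
      frac_via_transition_region = mean(visited)
    )
  }

  pe <- run_panel("E", 50, function(n, s) {
    set.seed(s)
    st <- matrix(rep(trans, each = n), nrow = n,
      dimnames = list(NULL, dev_species))
    pmax(round(st + matrix(stats::rnorm(n * 4, 0, cfg$noise_E), n)), 0)
  }, cfg$n_E)
  b <- bundle_add(b, pe$file)
  finals <- ensemble_states(pe$ens, "final")
  summary$E <- list(
    frac_to_stem = mean(finals[, "N"] > finals[, "G"]),
    frac_to_differentiated = mean(finals[, "G"] > finals[, "N"])
  )
  b$summary <- summary
  bundle_finish(b)
}

# -- fig 6: developmental minimum action paths (forward and reverse) ---------
recipe_fig6_maps <- function(scale, seed, out_dir, param_set, overrides) {
  cfg <- recipe_config(
    list(L = 50, M = 120, T_grid = c(1200, 2400, 4800), n_starts = 3,
      maxit = 800),
    if (scale == "desk") list(M = 80, T_grid = c(1200, 2400), n_starts = 2) else list(),
    overrides
  )
  b <- bundle_init("fig6_maps", scale, seed, cfg, out_dir)
  model <- dev_model(dev_params(param_set, L = cfg$L))
  fp <- find_fixed_points(model, seed = seed)
  stem <- unlist(fp[fp$branch == "stem-cell", dev_species][1, ])
  diffd <- unlist(fp[fp$branch == "differentiated", dev_species][1, ])
  trans <- unlist(fp[fp$branch == "transition", dev_species][1, ])
  fwd <- minimize_action(model, stem, diffd, M = cfg$M, T_grid = cfg$T_grid,
    via = trans, n_starts = cfg$n_starts, seed = seed, maxit = cfg$maxit %||% 800)
  rev <- minimize_action(model, diffd, stem, M = cfg$M, T_grid = cfg$T_grid,
    via = trans, n_starts = cfg$n_starts, seed = seed + 1L, maxit = cfg$maxit %||% 800)
  f1 <- file.path(out_dir, "map_forward.csv")
  f2 <- file.path(out_dir, "map_reverse.csv")
  write_path_csv(fwd, f1, dev_species); b <- bundle_add(b, f1)
  write_path_csv(rev, f2, dev_species); b <- bundle_add(b, f2)
  rev_aligned <- rev$path$states[rev(seq_len(nrow(rev$path$states))), ]
  b$summary <- list(
    action_forward = fwd$action, action_reverse = rev$action,
    separation = path_separation(fwd$path, rev_aligned),
    dist_fwd_to_transition = min_point_distance(fwd$path$states, trans),
    dist_rev_to_transition = min_point_distance(rev$path$states, trans)
  )
  bundle_finish(b)
}

min_point_distance <- function(states, point) {
  min(sqrt(colSums((t(states) - as.numeric(point))^2)))
}

# -- fig 7: fixed points and eigenvalues versus LIF concentration ------------
recipe_fig7_L_sweep <- function(scale, seed, out_dir, param_set, overrides) {
  cfg <- recipe_config(
    list(L_values = seq(0, 200, by = 25), n_starts = 200),
    if (scale == "desk") list(n_starts = 120) else list(),
    overrides
  )
  b <- bundle_init("fig7_L_sweep", scale, seed, cfg, out_dir)
  sweep <- sweep_parameter(dev_model(dev_params(param_set)), "L",
    cfg$L_values, seed = seed, n_starts = cfg$n_starts)
  f1 <- file.path(out_dir, "sweep.csv")
  write_sweep_csv(sweep, f1); b <- bundle_add(b, f1)
  stem <- sweep[sweep$branch == "stem-cell", ]
  trans <- sweep[sweep$branch == "transition", ]
  b$summary <- list(
    n_branches = length(unique(sweep$branch_id)),
    stem_N_range = range(stem$N),
    stem_N_nondecreasing = !is.unsorted(stem$N[order(stem$value)]),
    transition_max_re_range = range(Re(trans$ev1))
  )
  bundle_finish(b)
}

# -- fig 8: developmental transitory landscape (LIF ramp ensemble) -----------
recipe_fig8_dev_transitory <- function(scale, seed, out_dir, param_set,
                                       overrides) {
  cfg <- recipe_config(
    list(n = 10000, L_from = 150, T_ramp = 2000, t_end = 5000, record = 25),
    if (scale == "desk") list(n = 1000) else list(),
    overrides
  )
  b <- bundle_init("fig8_dev_transitory", scale, seed, cfg, out_dir)
  net <- dev_network(dev_params(param_set))
  ramp <- param_schedule("L", "linear", cfg$L_from, 0, duration = cfg$T_ramp)
  ens <- run_ensemble(
    function(x0, c2, sch) ssa_gillespie(net, x0, c2, sch),
    function(n, s) sample_box(stem_box(), n, s, integer_valued = TRUE),
    sim_config(cfg$t_end, record_interval = cfg$record, seed = seed), cfg$n,
    schedule = ramp
  )
  vts <- variance_timeseries(ens)
  f1 <- file.path(out_dir, "variance_timeseries.csv")
  utils::write.csv(vts, f1, row.names = FALSE); b <- bundle_add(b, f1)
  snap <- list()
  for (tq in c(0, cfg$T_ramp / 2, cfg$T_ramp)) {
    idx <- which.min(abs(ens$times - tq))
    st <- t(ens$states[idx, , ])
    colnames(st) <- dimnames(ens$states)[[2]]
    mg <- marginalize(st, "G", bins = 40, limits = list(G = c(0, 130)))
    f <- file.path(out_dir, sprintf("marginal_G_t_%d.csv", round(tq)))
    write_landscape_csv(mg, f); b <- bundle_add(b, f)
    snap[[sprintf("t_%d", round(tq))]] <- schedule_value(ramp, tq)
  }
  peaks <- lapply(c(N = "N", G = "G"), function(v) {
    list(start = vts[[v]][1], peak = max(vts[[v]]),
      peak_time = vts$time[which.max(vts[[v]])], end = vts[[v]][nrow(vts)])
  })
  b$summary <- list(variance = peaks, snapshot_L = snap)
  bundle_finish(b)
}

#' Generate the small deterministic fixture set used by the test-suite
#'
#' Writes a short toy trajectory, a 20-member toy ensemble, a small exact-SSA
#' run and an 8-point path, all seeded and bit-reproducible.
#'
#' @param seed integer seed.
#' @param dir output directory.
#' @return Character vector of file paths, invisibly.
#' @export
make_fixtures <- function(seed = 1L, dir = file.path(tempdir(), "epiland-fixtures")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model <- toy_model()
  files <- character(0)

  tr <- euler_maruyama(model, c(1, 0), sim_config(10, 0.01, 0.1, seed))
  f <- file.path(dir, "toy_trajectory.csv")
  write_trajectory_csv(tr, f); files <- c(files, f)

  ens <- run_ensemble(
    function(x0, c2, sch) euler_maruyama(model, x0, c2, sch),
    c(1, 0), sim_config(1, 0.001, 0.05, seed), 20
  )
  f <- file.path(dir, "toy_ensemble.csv")
  write_ensemble_csv(ens, f); files <- c(files, f)

  net <- dev_network(dev_params(L = 50))
  ssa <- ssa_gillespie(net, c(70, 10, 100, 1),
    sim_config(50, record_interval = 1, seed = seed))
  f <- file.path(dir, "dev_ssa.csv")
  write_trajectory_csv(ssa, f); files <- c(files, f)

  pth <- discretized_path(c(-1, 0), c(1, 0), M = 8, T_total = 10)
  f <- file.path(dir, "toy_path.csv")
  write_path_csv(pth, f, model$labels); files <- c(files, f)

  invisible(files)
}
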