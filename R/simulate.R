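# Running simulations: config -> engine parameters -> tracks + snapshots.

.engine_params <- function(config, owner_init = NULL) {
  c_ <- function(k) config[[k]]
  n <- c_("cell-count")
  model <- c_("model")
  J <- matrix(c(0, c_("j-cell-medium"),
                c_("j-cell-medium"), c_("j-cell-cell")), 2, 2)
  list(
    width = as.integer(c_("lattice-width")),
    height = as.integer(c_("lattice-height")),
    n_cells = as.integer(n),
    temperature = c_("temperature"),
    connectivity = isTRUE(c_("connectivity-constraint")),
    J = J,
    cell_type = rep(1L, n),
    lambda_v = rep(c_("lambda-v"), n),
    target_area = rep(c_("target-area"), n),
    total_mcs = as.integer(c_("total-mcs")),
    equilibration_mcs = as.integer(c_("equilibration-mcs")),
    sample_interval = as.integer(c_("sample-interval")),
    snapshot_interval = as.integer(c_("snapshot-interval")),
    use_persistence = model == "persistence",
    use_act = model == "act",
    use_pseudopods = model %in% c("ariotti", "pseudopod-ext"),
    use_tip_adhesion = model == "pseudopod-ext" && c_("tip-bonus") != 0,
    use_pulling = model == "pseudopod-ext" && c_("pull-strength") != 0,
    lambda_p = c_("lambda-persistence"),
    persistence_decay_time = c_("decay-time"),
    lambda_act = c_("lambda-act"),
    max_act = c_("max-act"),
    n_pseudopods = as.integer(c_("n-pseudopods")),
    p_ext = c_("p-ext"),
    p_retr = c_("p-retr"),
    kappa_init = c_("init-dir-strength"),
    kappa_cont = c_("cont-dir-strength"),
    max_growth_time = as.integer(c_("max-growth-time")),
    stall_limit = 20L,
    time_between_extensions = as.integer(c_("time-between-extensions")),
    retraction_mode = match(c_("retraction-mode"), .retraction_modes) - 1L,
    neighboring_actin_bonus = c_("neighboring-actin-bonus"),
    movement_decay_time = c_("movement-decay-time"),
    tip_bonus = c_("tip-bonus"),
    r_max = c_("max-distance-for-tip-bonus"),
    pull_strength = c_("pull-strength"),
    touch_behavior = match(c_("touch-behavior"), .touch_behaviors) - 1L,
    p_touch_retr = c_("p-touch-retr"),
    lateral_threshold = c_("lateral-threshold"),
    owner_init = owner_init,
    record_actin = FALSE,
    record_states = FALSE
  )
}

#' Run a Cellular Potts simulation
#'
#' One Monte Carlo Step (MCS) performs `width * height` elementary copy
#' attempts (uniform random target site, uniform random Moore-neighbor
#' source). Cells start as randomly placed single pixels and grow toward
#' their target area during early MCS; centroids are recorded at the
#' configured sampling interval after the equilibration period. The run is
#' fully determined by the seed.
#'
#' @param config a [cpm_config()] (or arguments forwarded to it via `...`).
#' @param seed RNG seed (integer); the same seed reproduces the run exactly.
#' @param owner_init optional initial owner matrix (e.g. from
#'   [initialize_random_cells()]); by default the engine places cells itself.
#' @param record_actin record pseudopod actin chains at every sampled MCS
#'   (pseudopod models only).
#' @param record_states record the per-MCS FSM state of every pseudopod.
#' @param ... overrides forwarded to [cpm_config()] when `config` is missing.
#' @return an object of class `cpm_sim`: list with `tracks` (a [tracks]
#'   table, `t` in MCS), `final_owner`, `areas`, `snapshots`, `actin`,
#'   `states`, `diagnostics`, and the resolved `config` and `seed`.
#' @export
simulate_cpm <- function(config = NULL, seed = 1, owner_init = NULL,
                         record_actin = FALSE, record_states = FALSE, ...) {
  if (is.null(config)) config <- cpm_config(...)
  validate_config(config)
  p <- .engine_params(config, owner_init)
  p$record_actin <- isTRUE(record_actin)
  p$record_states <- isTRUE(record_states)
  set.seed(seed)
  res <- cpm_run_cpp(p)
  tr <- as.data.frame(res$tracks)
  names(tr) <- c("track_id", "t", "x", "y")
  actin <- NULL
  if (isTRUE(record_actin) && length(res$actin) > 0) {
    actin <- do.call(rbind, lapply(seq_along(res$actin), function(i) {
      m <- as.data.frame(res$actin[[i]])
      names(m) <- c("cell", "pod", "order", "x", "y", "owner")
      m$t <- res$actin_mcs[i]
      m
    }))
  }
  out <- list(
    tracks = as_tracks(tr, dt = config[["sample-interval"]]),
    final_owner = res$final_owner,
    areas = res$areas,
    snapshots = res$snapshots,
    actin = actin,
    states = if (isTRUE(record_states)) res$states else NULL,
    diagnostics = res$diagnostics,
    config = config,
    seed = seed
  )
  class(out) <- "cpm_sim"
  out
}

#' @export
print.cpm_sim <- function(x, ...) {
  cat(sprintf(
    "CPM simulation: model %s, %d cells on %dx%d, %d MCS (seed %d)\n",
    x$config[["model"]], x$config[["cell-count"]],
    x$config[["lattice-width"]], x$config[["lattice-height"]],
    x$config[["total-mcs"]], x$seed))
  cat(sprintf("  %d track samples, %d cells alive at end\n",
              nrow(x$tracks), sum(x$areas > 0)))
  invisible(x)
}

#' Write label-image snapshots of a simulation
#'
#' Writes each recorded snapshot as a 16-bit TIFF label image (cell id per
#' pixel) and, when actin chains were recorded, a second channel with the
#' actin occupancy. Requires the `tiff` package.
#'
#' @param sim a `cpm_sim` with recorded snapshots.
#' @param dir output directory (created if needed).
#' @return the written file paths, invisibly.
#' @export
write_snapshots <- function(sim, dir) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write snapshots")
  }
  if (length(sim$snapshots) == 0) {
    stop("no snapshots recorded; set snapshot-interval > 0")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(sim$snapshots)) {
    m <- sim$snapshots[[i]]
    path <- file.path(dir, sprintf("snapshot_%04d.tif", i))
    tiff::writeTIFF(t(m) / 65535, path, bits.per.sample = 16L)
    paths <- c(paths, path)
  }
  invisible(paths)
}
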