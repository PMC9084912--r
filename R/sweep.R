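# Density sweeps: simulate a model at several cell counts, quantify speed
# and persistence per run, and correlate with density.

#' Run a density sweep of a CPM model
#'
#' For each (cell count, seed) pair: simulate, compute mean instantaneous
#' speed from non-overlapping subtracks, fit the directional
#' autocorrelation for the persistence time, and record the observed density
#' (cells per lattice site). Per-run failures are logged and skipped so the
#' sweep continues.
#'
#' @param cell_counts vector of cell counts (>= 2 distinct values for any
#'   correlation output).
#' @param seeds seeds used at every cell count (each seed is a replicate).
#' @param config shared model configuration; its `cell-count` is overridden.
#' @param subtrack_length subtrack duration (time units) for speed.
#' @param max_lag largest DAC lag in frames for the persistence fit.
#' @param thin analyze every `thin`-th sample (tracks stay at the simulated
#'   resolution; thinning only stabilizes step directions for the DAC).
#' @return list of class `density_sweep` with `summaries` (one row per run:
#'   `cell_count`, `seed`, `density`, `speed`, `phi`, `tau_p`, `flagged`)
#'   and the shared `config`.
#' @export
run_density_sweep <- function(cell_counts, seeds, config = cpm_config(),
                              subtrack_length = 50, max_lag = 100,
                              thin = 5) {
  rows <- list()
  for (cc in cell_counts) {
    for (s in seeds) {
      cfg <- config
      cfg[["cell-count"]] <- cc
      row <- tryCatch({
        sim <- simulate_cpm(cfg, seed = s)
        sm <- summarize_run(sim, subtrack_length = subtrack_length,
                            max_lag = max_lag, thin = thin)
        cbind(data.frame(cell_count = cc, seed = s), sm)
      }, error = function(e) {
        message(sprintf("sweep run (count %d, seed %d) failed: %s",
                        cc, s, conditionMessage(e)))
        NULL
      })
      if (!is.null(row)) rows[[length(rows) + 1]] <- row
    }
  }
  out <- list(summaries = do.call(rbind, rows), config = config)
  class(out) <- "density_sweep"
  out
}

#' Summarize one simulation run for a density sweep
#'
#' @param sim a `cpm_sim`.
#' @param subtrack_length subtrack duration for mean speed.
#' @param max_lag DAC fit lag range (frames of the thinned track).
#' @param thin thinning factor for the DAC step directions.
#' @return one-row data frame with `density`, `speed`, `phi`, `tau_p`,
#'   `flagged`.
#' @export
summarize_run <- function(sim, subtrack_length = 50, max_lag = 100,
                          thin = 5) {
  tr <- sim$tracks
  dt <- attr(tr, "dt")
  sp <- instantaneous_speed(tr, subtrack_length = subtrack_length)
  if (thin > 1) {
    keep <- tr$t %% (dt * thin) == 0
    tr <- as_tracks(as.data.frame(tr)[keep, ], dt = dt * thin)
  }
  dac <- directional_autocorrelation(tr, max_lag = max_lag)
  fit <- fit_dac(dac)
  area <- sim$config[["lattice-width"]] * sim$config[["lattice-height"]]
  data.frame(density = sim$config[["cell-count"]] / area,
             speed = mean(sp$speed), phi = fit$phi, tau_p = fit$tau_p,
             flagged = fit$flagged)
}

#' Density correlations of a sweep
#'
#' Spearman rank correlations of density with mean speed and with
#' persistence time over all runs of a sweep (the qualitative signature a
#' model is judged by), plus the Fisher-averaged Pearson correlogram across
#' seed replicates via [build_correlogram()].
#'
#' @param sweep a `density_sweep` (or its `summaries` data frame).
#' @return list with `spearman_density_speed`, `spearman_density_tau_p` and
#'   `correlogram` (NA entries when only one replicate or cell count).
#' @export
sweep_correlations <- function(sweep) {
  sm <- if (inherits(sweep, "density_sweep")) sweep$summaries else sweep
  if (length(unique(sm$cell_count)) < 2) {
    stop("correlations undefined: need at least 2 distinct cell counts")
  }
  ws <- data.frame(replicate = sm$seed, density = sm$density,
                   speed = sm$speed, tau_p = sm$tau_p)
  cg <- tryCatch(build_correlogram(ws), error = function(e) NULL)
  list(
    spearman_density_speed = cor(sm$density, sm$speed, method = "spearman"),
    spearman_density_tau_p = cor(sm$density, sm$tau_p, method = "spearman"),
    correlogram = cg
  )
}
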