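# Track quantification: speed, directional autocorrelation + persistence fit,
# streaming angles, drift correction, polar histograms, Ripley L, confinement
# ratio, Fisher-averaged correlograms, mean squared displacement.

#' Instantaneous speed of tracks
#'
#' Per-frame displacement divided by the sampling interval; when
#' `subtrack_length` is given (e.g. 50 MCS for simulated tracks), speed is
#' instead the net displacement over non-overlapping subtracks of that
#' duration divided by the elapsed time, which suppresses the centroid
#' jitter of lattice simulations.
#'
#' @param tracks a track table (see [as_tracks()]).
#' @param subtrack_length subtrack duration in time units (multiple of `dt`),
#'   or `NULL` for per-frame speeds.
#' @return data frame with `track_id`, `t` (interval start) and `speed`.
#' @export
instantaneous_speed <- function(tracks, subtrack_length = NULL) {
  dt <- attr(tracks, "dt")
  parts <- split(tracks[, c("t", "x", "y")], tracks$track_id)
  out <- lapply(names(parts), function(id) {
    d <- parts[[id]]
    n <- nrow(d)
    if (is.null(subtrack_length)) {
      if (n < 2) return(NULL)
      data.frame(track_id = id, t = d$t[-n],
                 speed = sqrt(diff(d$x)^2 + diff(d$y)^2) / diff(d$t))
    } else {
      k <- round(subtrack_length / dt)
      if (k < 1 || n < k + 1) return(NULL)
      starts <- seq(1, n - k, by = k)
      data.frame(
        track_id = id, t = d$t[starts],
        speed = sqrt((d$x[starts + k] - d$x[starts])^2 +
                     (d$y[starts + k] - d$y[starts])^2) /
                (d$t[starts + k] - d$t[starts]))
    }
  })
  out <- do.call(rbind, out)
  if (is.null(out)) stop("no track long enough for the requested speeds")
  rownames(out) <- NULL
  out
}

# per-track unit step directions; zero-length steps become NA
.unit_steps <- function(tracks) {
  lapply(split(tracks[, c("x", "y")], tracks$track_id), function(d) {
    if (nrow(d) < 2) return(NULL)
    dx <- diff(d$x); dy <- diff(d$y)
    nrm <- sqrt(dx^2 + dy^2)
    bad <- nrm == 0
    dx[bad] <- NA; dy[bad] <- NA; nrm[bad] <- 1
    cbind(dx / nrm, dy / nrm)
  })
}

#' Directional autocorrelation of a track set
#'
#' For each lag `n`, the mean over all cells and all time offsets of the dot
#' product between normalized step directions separated by `n` frames
#' (lag time `n * dt`). Every valid (cell, offset) pair is weighted equally.
#' Zero-length steps have no direction and are skipped; lags with no valid
#' pair are omitted. DAC(0) is 1 by construction.
#'
#' @param tracks a track table with uniform sampling interval.
#' @param max_lag largest lag in frames.
#' @return data frame of class `dac_curve` with `lag` (frames), `tau`
#'   (time units), `dac` and `n_pairs`.
#' @export
directional_autocorrelation <- function(tracks, max_lag = 20) {
  dt <- attr(tracks, "dt")
  steps <- Filter(Negate(is.null), .unit_steps(tracks))
  if (length(steps) == 0) stop("no track with at least 2 samples")
  sums <- numeric(max_lag + 1)
  counts <- numeric(max_lag + 1)
  for (e in steps) {
    m <- nrow(e)
    for (n in 0:min(max_lag, m - 1)) {
      i <- seq_len(m - n)
      d <- e[i, 1] * e[i + n, 1] + e[i, 2] * e[i + n, 2]
      ok <- !is.na(d)
      sums[n + 1] <- sums[n + 1] + sum(d[ok])
      counts[n + 1] <- counts[n + 1] + sum(ok)
    }
  }
  keep <- counts > 0
  out <- data.frame(lag = (0:max_lag)[keep], tau = (0:max_lag)[keep] * dt,
                    dac = sums[keep] / counts[keep], n_pairs = counts[keep])
  class(out) <- c("dac_curve", "data.frame")
  attr(out, "dt") <- dt
  out
}

#' Fit an exponential decay to a DAC curve
#'
#' After removing lag 0 (unity by definition), fits
#' \eqn{\phi \exp(-\tau / \tau_p)} by nonlinear least squares with
#' \eqn{\phi \in [0, 1]} and \eqn{\tau_p \in (0, 10 \cdot \tau_{max}]}.
#' Non-convergence or a parameter pinned at a bound yields a flagged result
#' rather than an error; flagged estimates should be interpreted cautiously.
#'
#' @param dac a `dac_curve` from [directional_autocorrelation()].
#' @return list of class `dac_fit` with `phi`, `tau_p`, `converged`,
#'   `flagged`, `flag_reason` and `rss`.
#' @export
fit_dac <- function(dac) {
  d <- dac[dac$lag > 0, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 positive-lag DAC values")
  tau_max <- 10 * max(d$tau)
  phi0 <- min(max(d$dac[1], 0.05), 1)
  below <- d$tau[d$dac < phi0 / exp(1)]
  tau0 <- if (length(below) > 0) max(below[1], attr(dac, "dt") %||% 1) else
    max(d$tau) / 3
  fit <- tryCatch(
    minpack.lm::nlsLM(dac ~ phi * exp(-tau / tau_p), data = d,
                      start = list(phi = phi0, tau_p = tau0),
                      lower = c(0, 1e-6), upper = c(1, tau_max),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    obj <- function(p) sum((d$dac - p[1] * exp(-d$tau / p[2]))^2)
    op <- nlminb(c(phi0, tau0), obj, lower = c(0, 1e-6),
                 upper = c(1, tau_max))
    pars <- op$par
    rss <- op$objective
    converged <- op$convergence == 0
  } else {
    pars <- coef(fit)
    rss <- sum(residuals(fit)^2)
    converged <- TRUE
  }
  phi <- unname(pars[1])
  tau_p <- unname(pars[2])
  pinned <- tau_p >= 0.999 * tau_max || tau_p <= 2e-6
  flagged <- !converged || pinned
  out <- list(phi = phi, tau_p = tau_p, converged = converged,
              flagged = flagged,
              flag_reason = if (pinned) "tau_p at bound" else
                if (!converged) "no convergence" else "",
              rss = rss, tau_max = tau_max)
  class(out) <- "dac_fit"
  out
}

#' @export
print.dac_fit <- function(x, ...) {
  cat(sprintf("DAC fit: phi = %.4f, tau_p = %.4g%s\n", x$phi, x$tau_p,
              if (x$flagged) paste0("  [flagged: ", x$flag_reason, "]") else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pairwise migration angles as a function of cell separation
#'
#' For every frame and every unordered pair of cells moving in that frame,
#' the angle (degrees, in \[0, 180\]) between their displacement directions,
#' binned by the distance between their centers of mass at the frame start.
#' Randomly migrating cells average 90 degrees; local streams push nearby
#' pairs below 90.
#'
#' @param tracks a track table.
#' @param bin_width distance bin width (same units as positions).
#' @param min_pairs bins with fewer pairs are suppressed.
#' @param frames optional subset of frame start times to analyze.
#' @return data frame with `bin_mid`, `mean_angle` (degrees) and `n_pairs`.
#' @export
pairwise_angle_by_distance <- function(tracks, bin_width = 5, min_pairs = 20,
                                       frames = NULL) {
  dt <- attr(tracks, "dt")
  df <- as.data.frame(tracks)
  times <- sort(unique(df$t))
  if (!is.null(frames)) times <- intersect(times, frames)
  acc <- list()
  for (t0 in times) {
    a <- df[df$t == t0, ]
    b <- df[df$t == t0 + dt, ]
    m <- merge(a, b, by = "track_id", suffixes = c("", ".next"))
    if (nrow(m) < 2) next
    dx <- m$x.next - m$x
    dy <- m$y.next - m$y
    nrm <- sqrt(dx^2 + dy^2)
    ok <- nrm > 0
    m <- m[ok, ]; dx <- dx[ok] / nrm[ok]; dy <- dy[ok] / nrm[ok]
    n <- nrow(m)
    if (n < 2) next
    pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    dotp <- pmin(pmax(dx[pr[, 1]] * dx[pr[, 2]] + dy[pr[, 1]] * dy[pr[, 2]],
                      -1), 1)
    ang <- acos(dotp) * 180 / pi
    dist <- sqrt((m$x[pr[, 1]] - m$x[pr[, 2]])^2 +
                 (m$y[pr[, 1]] - m$y[pr[, 2]])^2)
    acc[[length(acc) + 1]] <- data.frame(dist = dist, angle = ang)
  }
  if (length(acc) == 0) stop("no frame with at least 2 moving cells")
  all <- do.call(rbind, acc)
  bin <- floor(all$dist / bin_width)
  agg <- aggregate(all$angle, by = list(bin = bin),
                   FUN = function(v) c(mean(v), length(v)))
  out <- data.frame(bin_mid = (agg$bin + 0.5) * bin_width,
                    mean_angle = agg$x[, 1], n_pairs = agg$x[, 2])
  out[out$n_pairs >= min_pairs, , drop = FALSE]
}

#' Remove the net per-frame drift from a track set
#'
#' Subtracts, for every frame, the mean displacement over all cells from each
#' cell's displacement, then rebuilds positions by cumulative summation from
#' each track's first position. This removes rigid large-scale streams (e.g.
#' stage drift) while leaving relative motion intact; applying it twice is
#' the same as applying it once.
#'
#' @param tracks a track table.
#' @return a drift-corrected track table.
#' @export
drift_correct <- function(tracks) {
  dt <- attr(tracks, "dt")
  df <- as.data.frame(tracks)
  parts <- split(df, df$track_id)
  steps <- lapply(parts, function(d) {
    n <- nrow(d)
    if (n < 2) return(NULL)
    data.frame(t = d$t[-n], dx = diff(d$x), dy = diff(d$y))
  })
  allsteps <- do.call(rbind, Filter(Negate(is.null), steps))
  if (is.null(allsteps)) stop("need at least one displacement per frame")
  mdx <- tapply(allsteps$dx, allsteps$t, mean)
  mdy <- tapply(allsteps$dy, allsteps$t, mean)
  corrected <- lapply(parts, function(d) {
    n <- nrow(d)
    if (n < 2) return(d)
    key <- as.character(d$t[-n])
    dx <- diff(d$x) - unname(mdx[key])
    dy <- diff(d$y) - unname(mdy[key])
    d$x <- d$x[1] + c(0, cumsum(dx))
    d$y <- d$y[1] + c(0, cumsum(dy))
    d
  })
  out <- do.call(rbind, corrected)
  extra <- setdiff(names(out), c("track_id", "t", "x", "y"))
  as_tracks(out[, c("track_id", "t", "x", "y", extra)], dt = dt)
}

#' Migration step directions of a track set
#'
#' @param tracks a track table.
#' @return angles in degrees in \[0, 360) of all nonzero steps.
#' @export
step_directions <- function(tracks) {
  steps <- Filter(Negate(is.null), .track_steps(tracks))
  dx <- unlist(lapply(steps, `[[`, "dx"))
  dy <- unlist(lapply(steps, `[[`, "dy"))
  ok <- dx != 0 | dy != 0
  (atan2(dy[ok], dx[ok]) * 180 / pi) %% 360
}

#' Polar histogram of migration directions
#'
#' @param directions angles in degrees.
#' @param n_bins number of angular bins (>= 2) covering \[0, 360).
#' @return data frame with `bin_start`, `bin_mid` (degrees) and `count`;
#'   counts sum to `length(directions)`.
#' @export
polar_histogram <- function(directions, n_bins = 16) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  width <- 360 / n_bins
  bin <- floor((directions %% 360) / width)
  counts <- tabulate(bin + 1, nbins = n_bins)
  data.frame(bin_start = (0:(n_bins - 1)) * width,
             bin_mid = (0:(n_bins - 1) + 0.5) * width,
             count = counts)
}

#' Ripley L clustering statistic
#'
#' Computes Ripley's K with isotropic edge correction on a rectangular
#' window (via `spatial::Kfn`), transforms to \eqn{L(r) = \sqrt{K(r)/\pi}}
#' and reports \eqn{r - L(r)}: negative values signal clustering, positive
#' values dispersion, and 0 complete spatial randomness.
#'
#' @param points data frame with columns `x`, `y` (>= 10 points).
#' @param window rectangular observation window `c(xmin, xmax, ymin, ymax)`.
#' @param r_max largest distance evaluated.
#' @param n_r number of distance grid points.
#' @return data frame of class `ripley_curve` with `r`, `L` and `r_minus_L`
#'   (exactly 0 at r = 0).
#' @export
ripley_L <- function(points, window, r_max, n_r = 100) {
  if (nrow(points) < 10) stop("need at least 10 points")
  if (length(window) != 4 || window[2] <= window[1] || window[4] <= window[3]) {
    stop("window must be c(xmin, xmax, ymin, ymax)")
  }
  spatial::ppregion(window[1], window[2], window[3], window[4])
  k <- spatial::Kfn(list(x = points$x, y = points$y), fs = r_max, k = n_r)
  out <- data.frame(r = c(0, k$x), L = c(0, k$y))
  out$r_minus_L <- out$r - out$L
  class(out) <- c("ripley_curve", "data.frame")
  out
}

#' Confinement ratio (straightness / meandering index) per track
#'
#' Net displacement divided by total path length, in \[0, 1\]. Because the
#' expected ratio of a random walk decreases with track duration, this
#' statistic is biased when track durations vary; the directional
#' autocorrelation should be preferred in that situation.
#'
#' @param tracks a track table.
#' @return data frame with `track_id`, `ratio` (NA with `flagged = TRUE`
#'   when the path length is zero) and `n_steps`.
#' @export
confinement_ratio <- function(tracks) {
  parts <- split(tracks[, c("x", "y")], tracks$track_id)
  out <- lapply(names(parts), function(id) {
    d <- parts[[id]]
    if (nrow(d) < 2) stop("track ", id, " has fewer than 2 samples")
    path <- sum(sqrt(diff(d$x)^2 + diff(d$y)^2))
    net <- sqrt((d$x[nrow(d)] - d$x[1])^2 + (d$y[nrow(d)] - d$y[1])^2)
    data.frame(track_id = id,
               ratio = if (path == 0) NA_real_ else net / path,
               flagged = path == 0, n_steps = nrow(d) - 1)
  })
  do.call(rbind, out)
}

#' Fisher-transformed average of Pearson correlations
#'
#' `tanh(mean(artanh(r)))`: correlations from separate replicates are mapped
#' to Fisher z, averaged, and back-transformed. Values with |r| = 1 are
#' excluded with a warning (their z is infinite).
#'
#' @param r vector of correlations with |r| <= 1.
#' @return the averaged correlation.
#' @export
fisher_average <- function(r) {
  r <- r[!is.na(r)]
  if (any(abs(r) >= 1)) {
    warning("excluding correlation(s) with |r| = 1 from Fisher averaging")
    r <- r[abs(r) < 1]
  }
  if (length(r) == 0) return(NA_real_)
  tanh(mean(atanh(r)))
}

#' Correlogram of density, speed and persistence time
#'
#' Pearson correlations between observed cell density, mean instantaneous
#' speed and persistence time across the wells of each replicate, Fisher-
#' averaged across replicates.
#'
#' @param well_summaries data frame with columns `replicate`, `density`,
#'   `speed`, `tau_p` (one row per well; >= 3 wells per replicate).
#' @return a symmetric 3x3 correlation matrix of class `correlogram` with
#'   unit diagonal; entries involving a constant column are NA (flagged with
#'   a warning).
#' @export
build_correlogram <- function(well_summaries) {
  need <- c("replicate", "density", "speed", "tau_p")
  if (!all(need %in% names(well_summaries))) {
    stop("well summaries need columns: ", paste(need, collapse = ", "))
  }
  vars <- c("density", "speed", "tau_p")
  reps <- split(well_summaries, well_summaries$replicate)
  mats <- lapply(reps, function(d) {
    if (nrow(d) < 3) stop("each replicate needs at least 3 wells")
    if (any(vapply(d[vars], sd, numeric(1)) == 0)) {
      warning("constant column within a replicate; correlation undefined")
    }
    suppressWarnings(cor(d[vars]))
  })
  out <- diag(3)
  dimnames(out) <- list(vars, vars)
  for (i in 1:2) for (j in (i + 1):3) {
    rs <- vapply(mats, function(m) m[i, j], numeric(1))
    rs <- rs[!is.na(rs)]
    # |r| = 1 has infinite Fisher z; it is the limit of the average only
    # when every replicate is at the same bound
    out[i, j] <- out[j, i] <- if (length(rs) == 0) {
      NA_real_
    } else if (all(abs(rs) >= 1)) {
      mean(rs)
    } else {
      fisher_average(rs[abs(rs) < 1])
    }
  }
  class(out) <- c("correlogram", class(out))
  out
}

#' Mean squared displacement of a track set
#'
#' Mean over all cells and time offsets of the squared displacement after a
#' lag of `n` frames. A freely diffusing (Brownian) cell gives MSD linear in
#' lag (log-log slope 1); ballistic motion gives slope 2.
#'
#' @param tracks a track table.
#' @param max_lag largest lag in frames.
#' @return data frame with `lag`, `tau`, `msd` and `n_pairs`.
#' @export
mean_squared_displacement <- function(tracks, max_lag = 100) {
  dt <- attr(tracks, "dt")
  parts <- split(tracks[, c("x", "y")], tracks$track_id)
  sums <- numeric(max_lag)
  counts <- numeric(max_lag)
  for (d in parts) {
    m <- nrow(d)
    if (m < 2) next
    for (n in seq_len(min(max_lag, m - 1))) {
      i <- seq_len(m - n)
      sums[n] <- sums[n] +
        sum((d$x[i + n] - d$x[i])^2 + (d$y[i + n] - d$y[i])^2)
      counts[n] <- counts[n] + (m - n)
    }
  }
  keep <- counts > 0
  data.frame(lag = seq_len(max_lag)[keep], tau = seq_len(max_lag)[keep] * dt,
             msd = sums[keep] / counts[keep], n_pairs = counts[keep])
}
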