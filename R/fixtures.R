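# Seeded fixture generators with known ground truth: Brownian, persistent
# random walk, streaming track sets, and CSR / clustered / hard-core point
# patterns. All generators are pure functions of their arguments and seed.

#' Brownian (uncorrelated random walk) tracks
#'
#' Fixed-length steps in i.i.d. uniformly random directions; the reference
#' for zero directional persistence (DAC approximately 0 beyond lag 0).
#'
#' @param n number of tracks.
#' @param steps steps per track.
#' @param step_size displacement per step.
#' @param dt sampling interval.
#' @param window start positions drawn uniformly in
#'   `c(xmin, xmax, ymin, ymax)`.
#' @param seed RNG seed (mandatory; same seed, identical output).
#' @return a track table.
#' @export
generate_brownian_tracks <- function(n = 100, steps = 200, step_size = 1,
                                     dt = 1, window = c(0, 500, 0, 500),
                                     seed) {
  if (missing(seed)) stop("seed is mandatory for fixture generators")
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    th <- runif(steps, 0, 2 * pi)
    x0 <- runif(1, window[1], window[2])
    y0 <- runif(1, window[3], window[4])
    data.frame(track_id = i, t = (0:steps) * dt,
               x = x0 + c(0, cumsum(step_size * cos(th))),
               y = y0 + c(0, cumsum(step_size * sin(th))))
  })) |> as_tracks(dt = dt)
}

#' von Mises concentration giving a target persistence time
#'
#' For a fixed-speed walk whose heading turns by i.i.d. von Mises(0, kappa)
#' angles each frame, the direction autocorrelation after n frames is
#' \eqn{c^n} with \eqn{c = I_1(\kappa) / I_0(\kappa)} (mean cosine of the
#' turning angle), i.e. an exponential decay \eqn{\exp(-n\,\Delta t/\tau_p)}
#' with \eqn{\tau_p = -\Delta t / \log c}. This solves the inverse mapping
#' \eqn{\kappa(\tau_p)}.
#'
#' @param tau_p target persistence time (same units as `dt`), > 0.
#' @param dt sampling interval.
#' @return concentration kappa.
#' @export
kappa_for_tau_p <- function(tau_p, dt = 1) {
  if (tau_p <= 0) stop("tau_p must be > 0")
  c_target <- exp(-dt / tau_p)
  bessel_ratio <- function(k) {
    besselI(k, 1, expon.scaled = TRUE) / besselI(k, 0, expon.scaled = TRUE)
  }
  # besselI overflows long before k where the asymptotic expansion
  # I1/I0 = 1 - 1/(2k) + O(k^-2) is already exact to ~1e-7
  if (c_target >= bessel_ratio(1e4)) return(1 / (2 * (1 - c_target)))
  uniroot(function(k) bessel_ratio(k) - c_target,
          lower = 1e-8, upper = 1e4, tol = 1e-10)$root
}

#' Persistent random walk tracks with known persistence time
#'
#' Fixed-speed walk whose heading evolves by von Mises turning with the
#' concentration from [kappa_for_tau_p()], so the fitted DAC persistence
#' time has analytic ground truth `tau_p`.
#'
#' @inheritParams generate_brownian_tracks
#' @param speed displacement per step.
#' @param tau_p ground-truth persistence time (> 0).
#' @export
generate_prw_tracks <- function(n = 100, steps = 200, speed = 1, tau_p = 10,
                                dt = 1, window = c(0, 500, 0, 500), seed) {
  if (missing(seed)) stop("seed is mandatory for fixture generators")
  kappa <- kappa_for_tau_p(tau_p, dt)
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    turns <- rvonmises_cpp(steps - 1, 0, kappa)
    th <- cumsum(c(runif(1, 0, 2 * pi), turns))
    x0 <- runif(1, window[1], window[2])
    y0 <- runif(1, window[3], window[4])
    data.frame(track_id = i, t = (0:steps) * dt,
               x = x0 + c(0, cumsum(speed * cos(th))),
               y = y0 + c(0, cumsum(speed * sin(th))))
  })) |> as_tracks(dt = dt)
}

#' Streaming tracks: shared drift plus private random motion
#'
#' Each step is `drift_fraction` of a shared drift vector plus
#' `1 - drift_fraction` of a private uniformly-directed step, emulating
#' large-scale streams; drift correction and pairwise-angle analysis have
#' known behavior on this fixture.
#'
#' @inheritParams generate_brownian_tracks
#' @param drift_fraction fraction of each step shared by all cells, in
#'   \[0, 1\].
#' @param drift_direction drift direction in degrees.
#' @export
generate_streaming_tracks <- function(n = 50, steps = 100, step_size = 1,
                                      drift_fraction = 0.5,
                                      drift_direction = 0, dt = 1,
                                      window = c(0, 500, 0, 500), seed) {
  if (missing(seed)) stop("seed is mandatory for fixture generators")
  if (drift_fraction < 0 || drift_fraction > 1) {
    stop("drift_fraction must be in [0, 1]")
  }
  set.seed(seed)
  phi <- drift_direction * pi / 180
  ddx <- step_size * cos(phi)
  ddy <- step_size * sin(phi)
  do.call(rbind, lapply(seq_len(n), function(i) {
    th <- runif(steps, 0, 2 * pi)
    sx <- drift_fraction * ddx + (1 - drift_fraction) * step_size * cos(th)
    sy <- drift_fraction * ddy + (1 - drift_fraction) * step_size * sin(th)
    x0 <- runif(1, window[1], window[2])
    y0 <- runif(1, window[3], window[4])
    data.frame(track_id = i, t = (0:steps) * dt,
               x = x0 + c(0, cumsum(sx)), y = y0 + c(0, cumsum(sy)))
  })) |> as_tracks(dt = dt)
}

#' Point patterns with known spatial structure
#'
#' `csr`: homogeneous Poisson (uniform) points. `clustered`: parent points
#' with Gaussian-offset offspring (Thomas-type process) producing
#' \eqn{r - L(r) < 0} at the cluster scale. `hardcore`: sequential rejection
#' sampling with a minimum inter-point distance producing \eqn{r - L(r) > 0}
#' below the core distance; an error is raised when `n` points cannot be
#' placed.
#'
#' @param kind one of `"csr"`, `"clustered"`, `"hardcore"`.
#' @param n number of points.
#' @param window `c(xmin, xmax, ymin, ymax)` with positive area.
#' @param n_clusters number of cluster parents (`clustered`).
#' @param cluster_sd Gaussian offspring spread (`clustered`).
#' @param core_distance minimum pair distance (`hardcore`).
#' @param seed RNG seed (mandatory).
#' @return data frame with columns `x`, `y`.
#' @export
generate_point_pattern <- function(kind = c("csr", "clustered", "hardcore"),
                                   n = 500, window = c(0, 1000, 0, 1000),
                                   n_clusters = 20, cluster_sd = 10,
                                   core_distance = 20, seed) {
  if (missing(seed)) stop("seed is mandatory for fixture generators")
  kind <- match.arg(kind)
  if ((window[2] - window[1]) <= 0 || (window[4] - window[3]) <= 0) {
    stop("window area must be positive")
  }
  set.seed(seed)
  if (kind == "csr") {
    return(data.frame(x = runif(n, window[1], window[2]),
                      y = runif(n, window[3], window[4])))
  }
  if (kind == "clustered") {
    px <- runif(n_clusters, window[1], window[2])
    py <- runif(n_clusters, window[3], window[4])
    parent <- sample.int(n_clusters, n, replace = TRUE)
    x <- px[parent] + rnorm(n, 0, cluster_sd)
    y <- py[parent] + rnorm(n, 0, cluster_sd)
    # wrap into the window to keep intensity homogeneous at the edges
    w <- window[2] - window[1]; h <- window[4] - window[3]
    return(data.frame(x = window[1] + (x - window[1]) %% w,
                      y = window[3] + (y - window[3]) %% h))
  }
  # hardcore
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0
  max_tries <- 2000 * n
  while (length(xs) < n) {
    if (tries > max_tries) {
      stop("hardcore saturation: cannot place ", n, " points at core distance ",
           core_distance)
    }
    tries <- tries + 1
    cx <- runif(1, window[1], window[2])
    cy <- runif(1, window[3], window[4])
    if (length(xs) == 0 ||
        min((xs - cx)^2 + (ys - cy)^2) >= core_distance^2) {
      xs <- c(xs, cx); ys <- c(ys, cy)
    }
  }
  data.frame(x = xs, y = ys)
}
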