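# Track statistics: speed, DAC + fit, streaming angles, drift correction,
# polar histograms, Ripley L, confinement ratio, Fisher averaging,
# correlograms.

test_that("instantaneous speed handles straight, stationary and subtracks", {
  tr <- as_tracks(data.frame(track_id = 1, t = (0:10) * 11,
                             x = (0:10) * 5, y = 0), dt = 11)
  sp <- instantaneous_speed(tr)
  expect_equal(sp$speed, rep(5 / 11, 10))
  still <- as_tracks(data.frame(track_id = 1, t = 0:5, x = 2, y = 3), dt = 1)
  expect_equal(instantaneous_speed(still)$speed, rep(0, 5))
  # subtrack speed of a random walk is below per-frame speed
  set.seed(1)
  rw <- generate_brownian_tracks(n = 20, steps = 100, seed = 10)
  per_frame <- mean(instantaneous_speed(rw)$speed)
  sub <- mean(instantaneous_speed(rw, subtrack_length = 10)$speed)
  expect_lt(sub, per_frame)
  expect_error(instantaneous_speed(still, subtrack_length = 50), "long enough")
})

test_that("DAC is 1 at lag 0, 1 for straight lines, ~0 for random walks", {
  st <- straight_tracks()
  dac <- directional_autocorrelation(st, max_lag = 5)
  expect_equal(dac$dac, rep(1, 6))
  rw <- generate_brownian_tracks(n = 100, steps = 200, seed = 2)
  dac_rw <- directional_autocorrelation(rw, max_lag = 10)
  expect_equal(dac_rw$dac[1], 1)
  expect_true(all(abs(dac_rw$dac[-1]) < 0.05))
  expect_true(all(dac_rw$dac >= -1 & dac_rw$dac <= 1))
})

test_that("zero-length steps are skipped in the DAC", {
  # track that pauses: the pause step has no direction
  tr <- as_tracks(data.frame(track_id = 1, t = 0:4,
                             x = c(0, 1, 1, 2, 3), y = 0), dt = 1)
  dac <- directional_autocorrelation(tr, max_lag = 1)
  expect_equal(dac$dac[dac$lag == 0], 1)       # over the 3 moving steps
  expect_equal(dac$n_pairs[dac$lag == 0], 3)
  # lag-1 pairs (1,2) and (2,3) involve the pause step: only (3,4) remains
  expect_equal(dac$n_pairs[dac$lag == 1], 1)
})

test_that("exponential DAC fit recovers noiseless parameters exactly", {
  tau <- 0:20
  curve <- data.frame(lag = tau, tau = tau, dac = 0.8 * exp(-tau / 10),
                      n_pairs = 1000)
  class(curve) <- c("dac_curve", "data.frame")
  attr(curve, "dt") <- 1
  fit <- fit_dac(curve)
  expect_false(fit$flagged)
  expect_equal(fit$phi, 0.8, tolerance = 1e-6)
  expect_equal(fit$tau_p, 10, tolerance = 1e-6)
})

test_that("an all-ones DAC pins tau_p at its bound and is flagged", {
  curve <- data.frame(lag = 0:10, tau = 0:10, dac = 1, n_pairs = 100)
  class(curve) <- c("dac_curve", "data.frame")
  attr(curve, "dt") <- 1
  fit <- fit_dac(curve)
  expect_true(fit$flagged)
  expect_gte(fit$tau_p, 0.99 * fit$tau_max)
})

test_that("DAC fit recovers the persistence time of PRW fixtures", {
  prw <- generate_prw_tracks(n = 100, steps = 200, tau_p = 10, seed = 3)
  dac <- directional_autocorrelation(prw, max_lag = 30)
  fit <- fit_dac(dac)
  expect_lt(abs(fit$tau_p - 10) / 10, 0.15)
  expect_gt(fit$phi, 0.9)  # every track is persistent
})

test_that("pairwise angles match a brute-force oracle on a toy frame", {
  # 5 cells, one step each
  pos <- data.frame(track_id = 1:5, x = c(0, 10, 20, 5, 15),
                    y = c(0, 0, 10, 20, 5))
  step <- data.frame(dx = c(1, 1, 0, -1, 0.5), dy = c(0, 1, 1, 0.5, -0.5))
  tr <- as_tracks(rbind(
    data.frame(track_id = pos$track_id, t = 0, x = pos$x, y = pos$y),
    data.frame(track_id = pos$track_id, t = 1, x = pos$x + step$dx,
               y = pos$y + step$dy)), dt = 1)
  got <- pairwise_angle_by_distance(tr, bin_width = 1000, min_pairs = 1)
  # oracle: explicit double loop
  angs <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    u <- c(step$dx[i], step$dy[i]); v <- c(step$dx[j], step$dy[j])
    angs <- c(angs, acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi)
  }
  expect_equal(got$n_pairs, 10)
  expect_equal(got$mean_angle, mean(angs))
})

test_that("parallel cells give 0 degrees; random cells approach 90", {
  par <- generate_streaming_tracks(n = 30, steps = 20, drift_fraction = 1,
                                   seed = 4)
  a_par <- pairwise_angle_by_distance(par, bin_width = 1000, min_pairs = 1)
  expect_lt(max(a_par$mean_angle), 1e-6)
  rnd <- generate_brownian_tracks(n = 40, steps = 40, seed = 5)
  a_rnd <- pairwise_angle_by_distance(rnd, bin_width = 1000, min_pairs = 1)
  expect_lt(abs(a_rnd$mean_angle - 90), 2)
})

test_that("drift correction removes rigid translation and is idempotent", {
  # static cells translated rigidly: corrected displacements all zero
  base <- expand.grid(track_id = 1:6, t = 0:10)
  base$x <- base$track_id * 7 + base$t * 2
  base$y <- base$track_id * 3 - base$t * 1.5
  tr <- as_tracks(base[, c("track_id", "t", "x", "y")], dt = 1)
  cor1 <- drift_correct(tr)
  sp <- instantaneous_speed(cor1)
  expect_true(all(abs(sp$speed) < 1e-12))
  # idempotence on a stochastic track set
  rw <- generate_streaming_tracks(n = 20, steps = 30, drift_fraction = 0.5,
                                  seed = 6)
  c1 <- drift_correct(rw)
  c2 <- drift_correct(c1)
  expect_equal(as.data.frame(c1), as.data.frame(c2), tolerance = 1e-12)
})

test_that("drift correction restores large-distance angles toward 90", {
  str <- generate_streaming_tracks(n = 40, steps = 50, drift_fraction = 0.5,
                                   seed = 7)
  before <- pairwise_angle_by_distance(str, bin_width = 1000, min_pairs = 1)
  after <- pairwise_angle_by_distance(drift_correct(str), bin_width = 1000,
                                      min_pairs = 1)
  expect_lt(before$mean_angle, 60)            # strong apparent streaming
  expect_lt(abs(after$mean_angle - 90), 8)    # corrected toward random
})

test_that("polar histograms count step directions per bin", {
  expect_equal(polar_histogram(rep(45, 10), n_bins = 8)$count,
               c(0, 10, 0, 0, 0, 0, 0, 0))
  expect_equal(sum(polar_histogram(numeric(0), n_bins = 12)$count), 0)
  expect_error(polar_histogram(1:5, n_bins = 1), ">= 2")
  set.seed(8)
  h <- polar_histogram(runif(20000, 0, 360), n_bins = 8)
  expect_lt(max(h$count) / min(h$count), 1.15)
  expect_equal(sum(h$count), 20000)
})

test_that("Ripley r - L(r) separates CSR, hardcore and clustered patterns", {
  win <- c(0, 1000, 0, 1000)
  csr <- generate_point_pattern("csr", n = 500, window = win, seed = 9)
  rl <- ripley_L(csr, win, r_max = 100)
  expect_equal(rl$r_minus_L[rl$r == 0], 0)
  expect_lt(abs(mean(rl$r_minus_L[rl$r >= 20 & rl$r <= 100])), 3)
  hc <- generate_point_pattern("hardcore", n = 300, window = win,
                               core_distance = 20, seed = 10)
  rl_hc <- ripley_L(hc, win, r_max = 60)
  expect_true(all(rl_hc$r_minus_L[rl_hc$r > 2 & rl_hc$r < 20] > 0))
  # oracle: naive K is exactly 0 below the core distance
  expect_equal(k_naive(hc, 1e6, c(5, 10, 19)), c(0, 0, 0))
  cl <- generate_point_pattern("clustered", n = 500, window = win,
                               n_clusters = 25, cluster_sd = 10, seed = 11)
  rl_cl <- ripley_L(cl, win, r_max = 100)
  expect_lt(mean(rl_cl$r_minus_L[rl_cl$r >= 10 & rl_cl$r <= 40]), -3)
})

test_that("Ripley L is invariant to point order and window translation", {
  win <- c(0, 500, 0, 500)
  pts <- generate_point_pattern("csr", n = 200, window = win, seed = 12)
  a <- ripley_L(pts, win, r_max = 80)
  b <- ripley_L(pts[sample(nrow(pts)), ], win, r_max = 80)
  expect_equal(a, b)
  shifted <- data.frame(x = pts$x + 1000, y = pts$y - 250)
  cshift <- ripley_L(shifted, win + c(1000, 1000, -250, -250), r_max = 80)
  expect_equal(a$L, cshift$L)
  expect_error(ripley_L(pts[1:5, ], win, r_max = 50), "at least 10")
})

test_that("confinement ratio: straight 1, loop 0, biased by duration", {
  st <- as_tracks(data.frame(track_id = 1, t = 0:5, x = 0:5, y = 0), dt = 1)
  expect_equal(confinement_ratio(st)$ratio, 1)
  loop <- as_tracks(data.frame(track_id = 1, t = 0:4,
                               x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0)),
                    dt = 1)
  expect_equal(confinement_ratio(loop)$ratio, 0)
  still <- as_tracks(data.frame(track_id = 1, t = 0:3, x = 1, y = 1), dt = 1)
  cr <- confinement_ratio(still)
  expect_true(is.na(cr$ratio) && cr$flagged)
  # mean ratio of Brownian walks decreases with duration
  means <- sapply(c(20, 50, 100, 200), function(len) {
    rw <- generate_brownian_tracks(n = 60, steps = len, seed = 13 + len)
    mean(confinement_ratio(rw)$ratio)
  })
  expect_true(all(diff(means) < 0))
})

test_that("Fisher averaging is exact on symmetric and constant inputs", {
  expect_equal(fisher_average(c(0.4, 0.4, 0.4)), 0.4)
  expect_equal(fisher_average(c(0.5, -0.5)), 0)
  expect_equal(fisher_average(0), 0)
  expect_warning(out <- fisher_average(c(1, 0.3)), "excluding")
  expect_equal(out, 0.3)
})

test_that("correlograms recover exact linear relations and average", {
  ws <- data.frame(replicate = rep(1, 4), density = 1:4,
                   speed = 2 * (1:4), tau_p = c(4, 1, 3, 2))
  cg <- build_correlogram(ws)
  expect_equal(cg["density", "speed"], 1)
  expect_equal(diag(unclass(cg)), c(density = 1, speed = 1, tau_p = 1))
  expect_equal(cg, t(cg))
  # single replicate: Fisher average equals the raw correlation
  expect_equal(cg["density", "tau_p"], cor(1:4, c(4, 1, 3, 2)))
  # independent shuffled columns: small correlation
  set.seed(14)
  ws2 <- data.frame(replicate = rep(1:3, each = 40),
                    density = runif(120), speed = runif(120),
                    tau_p = runif(120))
  cg2 <- build_correlogram(ws2)
  expect_lt(abs(cg2["density", "speed"]), 0.25)
  expect_error(build_correlogram(ws[1:2, ]), "at least 3 wells")
  ws3 <- ws; ws3$speed <- 5
  expect_warning(build_correlogram(ws3), "constant column")
})

test_that("Brownian MSD grows linearly in lag", {
  rw <- generate_brownian_tracks(n = 50, steps = 300, seed = 15)
  m <- mean_squared_displacement(rw, max_lag = 50)
  slope <- coef(lm(log(msd) ~ log(lag), m))[2]
  expect_lt(abs(slope - 1), 0.1)
})
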