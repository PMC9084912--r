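# Pseudopod finite-state machine, actin coupling, and the tip-adhesion /
# pulling / touch extensions.

test_that("von Mises sampling covers the concentration limits", {
  set.seed(1)
  # near-degenerate concentration: draws collapse onto the mean
  th <- sample_von_mises(50, mu = 1.2, kappa = 1e6)
  expect_true(all(abs(th - 1.2) < 0.01))
  # kappa 0: uniform on the circle, tiny mean resultant length
  th0 <- sample_von_mises(1e4, mu = 0, kappa = 0)
  R <- sqrt(mean(cos(th0))^2 + mean(sin(th0))^2)
  expect_lt(R, 0.05)
  # kappa 4: circular mean close to mu
  th4 <- sample_von_mises(1e4, mu = pi / 3, kappa = 4)
  mu_hat <- atan2(mean(sin(th4)), mean(cos(th4)))
  expect_lt(abs(mu_hat - pi / 3) * 180 / pi, 3)
  expect_error(sample_von_mises(5, 0, -1), "non-negative")
})

test_that("pseudopod vector sum adds origin-to-tip vectors", {
  expect_equal(pseudopod_vector_sum(matrix(0, 0, 2), matrix(0, 0, 2)),
               c(0, 0))
  expect_equal(
    pseudopod_vector_sum(rbind(c(0, 0), c(2, 2)), rbind(c(2, 2), c(0, 0))),
    c(0, 0))
  expect_equal(pseudopod_vector_sum(c(0, 0), c(3, 4)), c(3, 4))
})

test_that("pulling delta-H is the area-scaled alignment with the pod sum", {
  expect_equal(delta_h_pulling(c(1, 0), c(5, 0), 250, 10), -0.2)
  expect_equal(delta_h_pulling(c(0, 1), c(5, 0), 250, 10), 0)
  # a cell without pseudopods exerts no pull
  expect_equal(delta_h_pulling(c(1, 0), c(0, 0), 250, 10), 0)
  # two involved cells: sum of both terms
  expect_equal(
    delta_h_pulling(c(1, 0), rbind(c(5, 0), c(-10, 0)), c(250, 100), 10),
    -0.2 + 1)
})

test_that("tip-adhesion case table doubles and cancels as specified", {
  E <- 30; rmax <- 3
  expect_equal(delta_h_tip_adhesion(Inf, Inf, E, rmax), 0)
  expect_equal(delta_h_tip_adhesion(2, Inf, E, rmax), -E)
  expect_equal(delta_h_tip_adhesion(Inf, 1, E, rmax), -E)
  expect_equal(delta_h_tip_adhesion(2, 1, E, rmax), -2 * E)
  # growth displacing another cell: grower bonus + shrinker penalty nets zero
  expect_equal(delta_h_tip_adhesion(2, 1, E, rmax, growing = TRUE) +
                 delta_h_tip_adhesion(1, 2, E, rmax, growing = FALSE),
               0)
})

test_that("touch behaviors transition the FSM as specified", {
  expect_equal(handle_touch("GROWING", "nothing"), "GROWING")
  expect_equal(handle_touch("GROWING", "retract"), "RETRACTING")
  expect_equal(handle_touch("GROWING", "attach"), "TOUCHING")
  # poof-dir: lateral pseudopod (cos alpha < 0.85) is instantly reset
  expect_equal(
    handle_touch("GROWING", "poof-dir", pod_vector = c(0, 1),
                 move_dir = c(1, 0)),
    "INIT")
  # aligned pseudopod (cos alpha = 0.95) is left alone
  ang <- acos(0.95)
  expect_equal(
    handle_touch("GROWING", "poof-dir", pod_vector = c(cos(ang), sin(ang)),
                 move_dir = c(1, 0)),
    "GROWING")
  expect_error(handle_touch("GROWING", "explode"), "unknown touch behavior")
})

test_that("FSM dwell times and extension attempts follow their laws", {
  # single cell, pseudopods that cannot extend (p_ext = 0) cycle
  # INIT -> GROWING -> RETRACTING -> INACTIVE -> INIT; INACTIVE dwell is
  # geometric with mean time-between-extensions
  tbe <- 8
  sim <- simulate_cpm(
    cpm_config(model = "ariotti", "lattice-width" = 40,
               "lattice-height" = 40, "cell-count" = 1, "total-mcs" = 4000,
               "equilibration-mcs" = 0, "target-area" = 100,
               "n-pseudopods" = 1, "p-ext" = 0, "max-growth-time" = 5,
               "time-between-extensions" = tbe),
    seed = 2, record_states = TRUE)
  st <- sim$states[, 1]
  # mean INACTIVE dwell (completed runs of state 3)
  r <- rle(st)
  dwell <- r$lengths[r$values == 3]
  dwell <- dwell[-length(dwell)]
  expect_gt(length(dwell), 40)
  expect_lt(abs(mean(dwell) - tbe) / tbe, 0.25)

  # growing pseudopods attempt extension with probability p_ext per MCS
  sim2 <- simulate_cpm(
    cpm_config(model = "ariotti", "lattice-width" = 40,
               "lattice-height" = 40, "cell-count" = 1, "total-mcs" = 3000,
               "equilibration-mcs" = 0, "target-area" = 100,
               "n-pseudopods" = 2, "max-growth-time" = 40),
    seed = 3, record_states = TRUE)
  d <- sim2$diagnostics
  expect_gt(d$growing_mcs, 500)
  expect_lt(abs(d$ext_attempts / d$growing_mcs - 0.3), 0.05)
  # chain emptied during retraction always lands in INACTIVE: the state
  # after every RETRACTING run is INACTIVE (or the log ends)
  r2 <- rle(sim2$states[, 1])
  after_retracting <- r2$values[which(r2$values == 2) + 1]
  after_retracting <- after_retracting[!is.na(after_retracting)]
  expect_true(all(after_retracting == 3))
})

test_that("attach touch behavior gives geometric TOUCHING dwell", {
  # dense pair of cells so pseudopods touch often
  p <- 0.2
  sim <- simulate_cpm(
    cpm_config(model = "pseudopod-ext", "lattice-width" = 30,
               "lattice-height" = 30, "cell-count" = 4, "total-mcs" = 4000,
               "equilibration-mcs" = 0, "target-area" = 120,
               "n-pseudopods" = 2, "touch-behavior" = "attach",
               "p-touch-retr" = p, "pull-strength" = 10, "tip-bonus" = 20),
    seed = 4, record_states = TRUE)
  dwell <- c()
  for (j in seq_len(ncol(sim$states))) {
    r <- rle(sim$states[, j])
    d <- r$lengths[r$values == 4]
    if (length(d) > 1) dwell <- c(dwell, d[-length(d)])
  }
  expect_gt(length(dwell), 30)
  expect_lt(abs(mean(dwell) - 1 / p) / (1 / p), 0.3)
})

test_that("actin stays inside its cell and chains stay contiguous", {
  sim <- simulate_cpm(
    cpm_config(model = "ariotti", "lattice-width" = 60,
               "lattice-height" = 60, "cell-count" = 4, "total-mcs" = 1000,
               "equilibration-mcs" = 200, "sample-interval" = 25,
               "snapshot-interval" = 0, "target-area" = 150,
               "n-pseudopods" = 2),
    seed = 5, record_actin = TRUE, record_states = FALSE)
  expect_gt(nrow(sim$actin), 0)
  # containment: every sampled actin site owned by its cell at that MCS
  expect_true(all(sim$actin$owner == sim$actin$cell))
  # contiguity at every sampled MCS: consecutive chain sites Moore-adjacent
  # on the periodic lattice
  for (tt in unique(sim$actin$t)) {
    sl <- sim$actin[sim$actin$t == tt, ]
    for (key in split(sl, paste(sl$cell, sl$pod))) {
      if (nrow(key) < 2) next
      key <- key[order(key$order), ]
      dx <- abs(diff(key$x)); dy <- abs(diff(key$y))
      dx <- pmin(dx, 60 - dx); dy <- pmin(dy, 60 - dy)
      expect_true(all(dx <= 1 & dy <= 1))
    }
  }
})

test_that("forward (treadmilling) retraction keeps chains contiguous", {
  sim <- simulate_cpm(
    cpm_config(model = "ariotti", "lattice-width" = 50,
               "lattice-height" = 50, "cell-count" = 2, "total-mcs" = 800,
               "equilibration-mcs" = 100, "sample-interval" = 20,
               "target-area" = 150, "n-pseudopods" = 2,
               "retraction-mode" = "forward"),
    seed = 6, record_actin = TRUE)
  for (tt in unique(sim$actin$t)) {
    sl <- sim$actin[sim$actin$t == tt, ]
    for (key in split(sl, paste(sl$cell, sl$pod))) {
      if (nrow(key) < 2) next
      key <- key[order(key$order), ]
      dx <- abs(diff(key$x)); dy <- abs(diff(key$y))
      dx <- pmin(dx, 50 - dx); dy <- pmin(dy, 50 - dy)
      expect_true(all(dx <= 1 & dy <= 1))
    }
  }
})
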