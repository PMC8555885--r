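# Kinematic quantities against closed-form and brute-force oracles.

test_that("arc-length resampling is linear-exact, idempotent and speed invariant", {
  # straight line: stations uniform in x
  seg <- cbind(seq(0, 9.9, length.out = 12), 0, 0)
  it <- interpolate_trajectory(seg)
  expect_equal(it[, 1], seq(0, 9.9, length.out = 100), tolerance = 1e-9)
  expect_true(all(abs(it[, 2:3]) < 1e-12))
  # resampling an already-uniform 100-point trajectory is the identity
  expect_equal(interpolate_trajectory(it), it, tolerance = 1e-9)
  # the same path with pauses (duplicated vertices) interpolates identically
  set.seed(2)
  path <- cbind(cumsum(runif(40)), sin(1:40 / 5), cos(1:40 / 7))
  slow <- path[rep(seq_len(40), times = sample(1:3, 40, replace = TRUE)), ]
  expect_lt(max(abs(interpolate_trajectory(path) -
                    interpolate_trajectory(slow))), 1e-6)
  expect_error(interpolate_trajectory(path[1, , drop = FALSE]), "at least 2")
  expect_error(interpolate_trajectory(rbind(c(1, 2, 3), c(1, 2, 3))), "at least 2")
})

test_that("trajectory variability matches its definition and a brute-force oracle", {
  base <- interpolate_trajectory(cbind(seq(0, 10, length.out = 30),
                                       seq(0, 5, length.out = 30), 0))
  # identical trials -> 0
  expect_equal(trajectory_variability(list(base, base, base))$D, 0)
  # two trials offset +/- 1 mm along x from their mean -> 1 mm
  off <- base; off[, 1] <- off[, 1] + 2
  expect_equal(trajectory_variability(list(base, off))$D, 1)
  # 20 random trials vs naive double loop
  set.seed(8)
  trials <- lapply(1:20, function(i) base + matrix(rnorm(300, sd = 0.7), 100, 3))
  tv <- trajectory_variability(trials)
  expect_equal(tv$D, brute_force_dbar(trials), tolerance = 1e-12)
  expect_error(trajectory_variability(list(base)), "fewer than 2")
})

test_that("D-bar is invariant under rigid motions of all trials", {
  set.seed(3)
  base <- interpolate_trajectory(cbind(seq(0, 10, length.out = 25),
                                       (1:25)^0.5, 0))
  trials <- lapply(1:6, function(i) base + matrix(rnorm(300, sd = 0.4), 100, 3))
  D0 <- trajectory_variability(trials)$D
  R <- random_rotation(); tvec <- rnorm(3, sd = 20)
  moved <- lapply(trials, function(tr) sweep(tr %*% t(R), 2, -tvec))
  expect_equal(trajectory_variability(moved)$D, D0, tolerance = 1e-9)
})

test_that("within-session variability windows match the per-window oracle", {
  base <- interpolate_trajectory(cbind(0:20, 0, 0))
  expect_identical(within_session_variability(rep(list(base), 9)), numeric(0))
  expect_equal(within_session_variability(rep(list(base), 10)), 0)
  set.seed(5)
  trials <- lapply(1:12, function(i) base + matrix(rnorm(300, sd = 1), 100, 3))
  ws <- within_session_variability(trials)
  expect_length(ws, 3)
  for (i in 1:3)
    expect_equal(ws[i], trajectory_variability(trials[i:(i + 9)])$D)
})

test_that("aperture, orientation and flexion match their geometric definitions", {
  expect_equal(aperture(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(aperture(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(6)
  d1 <- matrix(rnorm(30), 10, 3); d4 <- matrix(rnorm(30), 10, 3)
  expect_equal(aperture(d1, d4),
               sqrt((d1[, 1] - d4[, 1])^2 + (d1[, 2] - d4[, 2])^2 +
                      (d1[, 3] - d4[, 3])^2))

  expect_equal(hand_orientation(c(0, 0), c(1, 0)), 0)
  expect_equal(hand_orientation(c(0, 0), c(0, 1)), 90)
  expect_equal(hand_orientation(c(0, 0), c(-1, 1)), 135)
  expect_true(is.na(hand_orientation(c(1, 1), c(1, 1))))
  # left-hand mirror symmetry: reflecting about x gives the right-hand value
  set.seed(9)
  for (i in 1:25) {
    a <- rnorm(2); b <- rnorm(2)
    am <- c(-a[1], a[2]); bm <- c(-b[1], b[2])
    expect_equal(hand_orientation(am, bm, hand = "left"),
                 hand_orientation(a, b, hand = "right"))
  }

  expect_equal(digit_flexion(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 0)
  expect_equal(digit_flexion(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 90)
  expect_true(is.na(digit_flexion(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0))))
  for (i in 1:25) {
    h <- rnorm(3); m <- rnorm(3); t <- rnorm(3)
    u <- m - h; v <- t - m
    want <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    expect_equal(digit_flexion(h, m, t), want, tolerance = 1e-9)
  }
})

test_that("reach velocity and duration follow the frame-rate arithmetic", {
  still <- matrix(1, 10, 3)
  rv <- reach_velocity(still)
  expect_true(all(rv$speed == 0))
  # 1 mm per frame at 300 fps -> 300 mm/s
  mv <- cbind(seq_len(10), 0, 0)
  expect_equal(reach_velocity(mv)$max_speed, 300)
  # gaps yield no sample
  v <- rep(TRUE, 10); v[5] <- FALSE
  rv2 <- reach_velocity(mv, v)
  expect_length(rv2$speed, 7)
  expect_false(4 %in% rv2$frame)
  # random walk vs brute force
  set.seed(10)
  w <- apply(matrix(rnorm(60), 20, 3), 2, cumsum)
  rv3 <- reach_velocity(w, frame_rate = 300)
  want <- sqrt(rowSums(diff(w)^2)) * 300
  expect_equal(rv3$speed, want)

  expect_equal(reach_duration(100, 160), 0.2)
  expect_equal(reach_duration(7, 7), 0)
  expect_error(reach_duration(10, 5), "precedes")
})

test_that("generalized variance recovers a known covariance determinant", {
  pts <- matrix(5, 10, 3)
  expect_equal(endpoint_generalized_variance(pts), 0)
  expect_warning(gv <- endpoint_generalized_variance(matrix(rnorm(9), 3, 3)),
                 "fewer than 4")
  expect_true(is.na(gv))
  set.seed(13)
  S <- matrix(c(1.0, 0.3, 0.1,
                0.3, 0.8, 0.2,
                0.1, 0.2, 1.2), 3, 3)
  X <- matrix(rnorm(600), 200, 3) %*% chol(S)
  expect_lt(abs(endpoint_generalized_variance(X) / det(S) - 1), 0.25)
  # identity covariance: GV -> 1 at large n
  X2 <- matrix(rnorm(3 * 4000), ncol = 3)
  expect_lt(abs(endpoint_generalized_variance(X2) - 1), 0.15)
})

test_that("hand subtraction removes rigid transport variability", {
  set.seed(14)
  hand <- matrix(rnorm(600, sd = 2), 200, 3)
  # digit rigidly attached -> subtracted GV is 0
  digit <- hand + matrix(rep(c(1, 2, 3), each = 200), 200, 3)
  sub <- hand_subtracted_endpoints(digit, hand)
  expect_equal(endpoint_generalized_variance(sub), 0)
  expect_true(all(hand_subtracted_endpoints(hand, hand) == 0))
  # independent digit jitter of known covariance is recovered
  S <- diag(c(0.5, 0.7, 0.9))
  digit2 <- hand + matrix(rnorm(600), 200, 3) %*% chol(S)
  gv <- endpoint_generalized_variance(hand_subtracted_endpoints(digit2, hand))
  expect_lt(abs(gv / det(S) - 1), 0.25)
  expect_error(hand_subtracted_endpoints(digit[1:5, ], hand), "matching")
})

test_that("MRL obeys its closed forms and the Bessel-ratio limit", {
  expect_equal(mean_resultant_length(rep(37, 5))$MRL, 1)
  expect_equal(mean_resultant_length(c(37, 37 + 360))$MRL, 1)
  expect_equal(mean_resultant_length(c(0, 90, 180, 270))$MRL, 0, tolerance = 1e-12)
  expect_error(mean_resultant_length(NA_real_), "no angles")
  set.seed(15)
  ang <- rvonmises(1e4, mu = 1, kappa = 2) * 180 / pi
  want <- besselI(2, 1) / besselI(2, 0)
  expect_lt(abs(mean_resultant_length(ang)$MRL - want), 0.02)
})

test_that("more angular noise means lower MRL (von Mises, seeded)", {
  set.seed(16)
  mrls <- vapply(c(8, 4, 2, 1, 0.5), function(k) {
    mean_resultant_length(rvonmises(3000, 0, k) * 180 / pi)$MRL
  }, numeric(1))
  expect_true(all(diff(mrls) < 0))
})

test_that("coordination profiles reproduce linear relations and respect coverage", {
  grid <- coordination_grid()
  expect_length(grid, 351)
  expect_equal(grid[1], -20); expect_equal(grid[351], 15)
  # aperture linear in z: profile reproduces the line on covered stations
  z <- seq(-18, 10, length.out = 60)
  tr <- data.frame(z_digit2 = z, aperture = 10 + 0.5 * z,
                   orientation = 40 + z, flexion = 30 - 0.25 * z)
  prof <- coordination_profile(list(tr))
  cov_ <- !is.na(prof$aperture)
  expect_equal(prof$aperture[cov_], 10 + 0.5 * prof$z[cov_], tolerance = 1e-6)
  s <- sample_profile(prof, 3.0)
  expect_equal(s$aperture, 11.5, tolerance = 1e-9)
  # a trial reaching only z = +1 contributes nothing at +3
  short <- data.frame(z_digit2 = seq(-18, 1, length.out = 30),
                      aperture = 5, orientation = 50, flexion = 20)
  prof2 <- coordination_profile(list(short))
  expect_false(sample_profile(prof2, 3.0)$covered)
  # two trials with known profiles average per station
  tr2 <- tr; tr2$aperture <- 6 + 0.5 * z
  prof3 <- coordination_profile(list(tr, tr2))
  cov3 <- prof3$n_aperture == 2
  expect_equal(prof3$aperture[cov3], 8 + 0.5 * prof3$z[cov3], tolerance = 1e-6)
  # mixed coverage: station covered by one trial only uses that trial
  prof4 <- coordination_profile(list(tr, short))
  i <- which(abs(prof4$z - 3) < 1e-9)
  expect_equal(prof4$aperture[i], 11.5, tolerance = 1e-6)
})

test_that("profiles from a synthetic trial match direct recomputation", {
  g <- generate_reach_trajectory()
  ev <- g$true_events
  idx <- ev$reach_start:ev$reach_end
  p <- g$traj$positions
  tr <- data.frame(
    z_digit2 = p$digit2[idx, 3],
    aperture = aperture(p$digit1[idx, ], p$digit4[idx, ]),
    orientation = hand_orientation(p$digit1[idx, 1:2], p$digit4[idx, 1:2]),
    flexion = digit_flexion(p$hand_dorsum[idx, ], p$mcp2[idx, ], p$digit2[idx, ]))
  prof <- coordination_profile(list(tr))
  s <- sample_profile(prof, 3.0)
  expect_true(s$covered)
  # designed shape: values at z = +3 on the rising limb, via the generator's
  # own profile table as the independent reference
  pr <- g$profiles[idx, ]
  ok <- !is.na(pr$z_digit2)
  expect_equal(s$aperture, signal::pchip(pr$z_digit2, pr$aperture, 3),
               tolerance = 1e-6)
})
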