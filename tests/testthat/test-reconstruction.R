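# Mirror-pair calibration and triangulation geometry.

scene <- synthetic_calibration()

test_that("noiseless checkerboard pairs satisfy the epipolar identity and recover the cameras", {
  pairs <- generate_checkerboard_correspondences(scene, n_points = 48, pixel_noise = 0)
  xd <- cbind(pairs$x_direct, pairs$y_direct)
  xm <- cbind(scene$camera$image_width - pairs$x_mirror, pairs$y_mirror)
  E <- estimate_essential_matrix(xd, xm, scene$camera)
  # essential-matrix constraints: rank 2, equal nonzero singular values
  sv <- svd(E)$d
  expect_lt(sv[3], 1e-10)
  expect_lt(abs(sv[1] - sv[2]) / sv[1], 1e-6)
  expect_lt(max(skilledreach:::epipolar_residuals(E, xd, xm, scene$camera)), 1e-9)

  cal <- calibrate_mirror_views(pairs, scene$camera)
  expect_lt(rotation_angle_deg(cal$R, scene$R), 1e-5)
  # metric scale: recovered translation matches the true baseline
  expect_lt(abs(cal$scale - sqrt(sum(scene$t_mm^2))) / sqrt(sum(scene$t_mm^2)), 1e-6)
})

test_that("estimation requires at least 8 correspondences", {
  expect_error(generate_checkerboard_correspondences(scene, n_points = 7),
               "at least 8")
  pairs <- generate_checkerboard_correspondences(scene, n_points = 10)
  xd <- cbind(pairs$x_direct, pairs$y_direct)[1:7, ]
  xm <- cbind(pairs$x_mirror, pairs$y_mirror)[1:7, ]
  expect_error(estimate_essential_matrix(xd, xm, scene$camera), "at least 8")
})

test_that("0.5 px noise still recovers the mirror rotation within 1 degree", {
  set.seed(71)
  t_true <- scene$t_mm / sqrt(sum(scene$t_mm^2))
  for (rep in 1:3) {
    pairs <- generate_checkerboard_correspondences(scene, n_points = 40,
                                                   pixel_noise = 0.5)
    cal <- calibrate_mirror_views(pairs, scene$camera)
    expect_lt(rotation_angle_deg(cal$R, scene$R), 1)
    # translation direction within 1% (radians ~ unit-vector distance)
    expect_lt(acos(pmin(1, sum(cal$t * t_true))), 0.01)
    # metric scale from the 4 mm checker square within 2%
    expect_lt(abs(cal$scale / sqrt(sum(scene$t_mm^2)) - 1), 0.02)
  }
})

test_that("cheirality selects the same candidate as brute-force depth checking", {
  set.seed(5)
  pairs <- generate_checkerboard_correspondences(scene, n_points = 40,
                                                 pixel_noise = 0.5)
  xd <- cbind(pairs$x_direct, pairs$y_direct)
  xm <- cbind(scene$camera$image_width - pairs$x_mirror, pairs$y_mirror)
  E <- estimate_essential_matrix(xd, xm, scene$camera)
  dec <- decompose_to_cameras(E, scene$camera, xd, xm)
  # enumerate all four candidates against ground-truth depths
  X_true <- attr(pairs, "X_true")
  cands <- skilledreach:::decompose_essential(E)
  scores <- vapply(cands, function(cd) {
    P2 <- scene$camera$K %*% cbind(cd$R, cd$t)
    X <- skilledreach:::dlt_triangulate(xd, xm, dec$P_real, P2)
    # candidate agrees with truth when depths have the true signs
    sum(sign(X[, 3]) == sign(X_true[, 3]) &
          sign(X %*% cd$R[3, ] + cd$t[3]) > 0)
  }, numeric(1))
  best <- cands[[which.max(scores)]]
  expect_lt(rotation_angle_deg(dec$R, best$R), 1e-3)
})

test_that("noiseless triangulation round-trips and one-view points are absent", {
  pairs <- generate_checkerboard_correspondences(scene, n_points = 48)
  cal <- calibrate_mirror_views(pairs, scene$camera)
  X_true <- attr(pairs, "X_true")
  xd <- cbind(pairs$x_direct, pairs$y_direct)
  xm <- cbind(pairs$x_mirror, pairs$y_mirror)
  tri <- triangulate_points(xd, xm, cal)
  expect_true(all(tri$valid))
  expect_lt(max(abs(tri$points - X_true)), 1e-6)
  expect_lt(max(tri$reproj_err_px), 1e-9)
  # missing observation in one view -> no 3D point, no error
  xm[3, ] <- NA
  tri2 <- triangulate_points(xd, xm, cal)
  expect_false(tri2$valid[3])
  expect_true(all(is.na(tri2$points[3, ])))
})

test_that("noisy triangulation matches a nonlinear least-squares oracle", {
  set.seed(23)
  pairs <- generate_checkerboard_correspondences(scene, n_points = 48)
  cal <- calibrate_mirror_views(pairs, scene$camera)
  X_true <- attr(pairs, "X_true")
  xd <- cbind(pairs$x_direct, pairs$y_direct) + matrix(rnorm(96), 48, 2)
  xm <- cbind(pairs$x_mirror, pairs$y_mirror) + matrix(rnorm(96), 48, 2)
  tri <- triangulate_points(xd, xm, cal)
  expect_lt(median(tri$reproj_err_px), 3)  # ~ noise scale (1 px per coord)
  xm_f <- cbind(scene$camera$image_width - xm[, 1], xm[, 2])
  err_dlt <- err_nl <- numeric(10)
  for (i in 1:10) {
    Xn <- nonlinear_triangulate(xd[i, ], xm_f[i, ], cal$P_real, cal$P_virtual,
                                init = tri$points[i, ] + rnorm(3, sd = 0.5))
    err_dlt[i] <- sqrt(sum((tri$points[i, ] - X_true[i, ])^2))
    err_nl[i] <- sqrt(sum((Xn - X_true[i, ])^2))
  }
  expect_lt(abs(mean(err_dlt) - mean(err_nl)) / mean(err_nl), 0.10)
})

test_that("reprojection filter applies the threshold rule and catches mislabels", {
  expect_equal(filter_by_reprojection(c(0, 0, 0)), c(TRUE, TRUE, TRUE),
               ignore_attr = TRUE)
  m <- filter_by_reprojection(c(1, 5, 20), threshold_px = 10)
  expect_equal(as.logical(m), c(TRUE, TRUE, FALSE))
  expect_equal(attr(m, "n_excluded"), 1L)
  # mislabels displaced > 20 px are excluded by the analysis pipeline
  # (confidence/jump validity rule first, reprojection filter on survivors;
  # a displacement along the epipolar line is invisible to the reprojection
  # residual, which is why the validity rule gates reconstruction)
  set.seed(31)
  g <- generate_reach_trajectory()
  obs <- project_to_views(g$traj, scene, mislabel_rate = 0.15)
  pairs <- generate_checkerboard_correspondences(scene, n_points = 48)
  cal <- calibrate_mirror_views(pairs, scene$camera)
  excluded <- displaced <- 0
  for (b in c("hand_dorsum", "digit2")) {
    o1 <- obs[obs$bodypart == b & obs$view == "direct", ]
    o2 <- obs[obs$bodypart == b & obs$view == "mirror", ]
    v1 <- classify_point_validity(o1)$valid
    v2 <- classify_point_validity(o2)$valid
    x1 <- cbind(o1$x, o1$y); x1[!v1, ] <- NA
    x2 <- cbind(o2$x, o2$y); x2[!v2, ] <- NA
    tri <- triangulate_points(x1, x2, cal)
    mask <- tri$valid & filter_by_reprojection(tri$reproj_err_px)
    bad <- o1$true_mislabel | o2$true_mislabel  # displacement > 50 px
    displaced <- displaced + sum(bad)
    excluded <- excluded + sum(bad & !mask)
  }
  expect_gt(excluded / displaced, 0.95)
})

test_that("pellet-frame transform applies origin, axes and the left-hand sign rule", {
  porig <- c(5, -2, 310)
  expect_equal(as.numeric(to_pellet_frame(rbind(porig), porig, "right")),
               c(0, 0, 0))
  # camera offset chosen to give pellet-frame (+2, 1, 3) before negation
  pt <- porig + c(2, -1, -3)
  expect_equal(as.numeric(to_pellet_frame(rbind(pt), porig, "right")),
               c(2, 1, 3))
  expect_equal(as.numeric(to_pellet_frame(rbind(pt), porig, "left")),
               c(-2, 1, 3))
})

test_that("full synthetic trial reconstructs ground truth below 1e-6 mm (noiseless)", {
  for (hand in c("right", "left")) {
    g <- generate_reach_trajectory()
    obs <- project_to_views(g$traj, scene, hand = hand)
    pairs <- generate_checkerboard_correspondences(scene, n_points = 48)
    cal <- calibrate_mirror_views(pairs, scene$camera)
    get2 <- function(b, v) obs[obs$bodypart == b & obs$view == v, ]
    pel <- triangulate_points(
      cbind(get2("pellet", "direct")$x, get2("pellet", "direct")$y),
      cbind(get2("pellet", "mirror")$x, get2("pellet", "mirror")$y), cal)
    porig <- estimate_pellet_origin(pel$points, pel$valid,
                                    g$true_events$reach_start)
    for (b in c("hand_dorsum", "digit2", "digit4")) {
      tri <- triangulate_points(cbind(get2(b, "direct")$x, get2(b, "direct")$y),
                                cbind(get2(b, "mirror")$x, get2(b, "mirror")$y),
                                cal)
      rec <- to_pellet_frame(tri$points, porig, hand)
      expect_lt(max(abs(rec - g$traj$positions[[b]])), 1e-6)
    }
  }
})

test_that("pellet origin estimation needs valid pre-reach pellet frames", {
  xyz <- matrix(rnorm(30), 10, 3)
  expect_error(estimate_pellet_origin(xyz, rep(FALSE, 10), 5), "unusable")
  v <- rep(TRUE, 10)
  expect_equal(estimate_pellet_origin(xyz, v, 11), apply(xyz, 2, median))
})
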