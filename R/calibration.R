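# Mirror-pair calibration: essential matrix estimation (normalized 8-point),
# decomposition into real/virtual camera pair, metric scale from the known
# checker square.

# Hartley conditioning: translate centroid to origin, scale mean radius to
# sqrt(2). Returns list(pts = conditioned n x 2, T = 3 x 3 similarity).
hartley_condition <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  T <- matrix(c(s, 0, -s * ctr[1],
                0, s, -s * ctr[2],
                0, 0, 1), 3, 3, byrow = TRUE)
  list(pts = cbind(s * (pts[, 1] - ctr[1]), s * (pts[, 2] - ctr[2])), T = T)
}

#' Estimate the essential matrix relating the direct and mirror views
#'
#' Normalized 8-point algorithm on matched keypoints seen in the direct view
#' and in the mirror view (mirror pixel x-coordinates must already be
#' reflected so that the virtual camera behind the mirror is a proper
#' rotation of the real camera). Pixel coordinates are first mapped to
#' normalized camera coordinates through the shared intrinsics, Hartley
#' conditioning is applied, the linear solution is taken from the smallest
#' singular vector, and the result is projected onto the essential manifold
#' (two equal singular values, one zero).
#'
#' @param x_direct,x_mirror n x 2 matrices of matched pixel coordinates
#'   (mirror x already reflected).
#' @param camera A [camera_model()].
#' @return A 3x3 essential matrix `E` such that for normalized homogeneous
#'   correspondences `x'` (mirror) and `x` (direct), `t(x') %*% E %*% x ~ 0`.
#' @export
estimate_essential_matrix <- function(x_direct, x_mirror, camera) {
  x_direct <- as.matrix(x_direct); x_mirror <- as.matrix(x_mirror)
  n <- nrow(x_direct)
  if (n < 8 || nrow(x_mirror) != n)
    stop("need at least 8 matched, equal-length point sets")
  n1 <- px_to_norm(x_direct, camera)
  n2 <- px_to_norm(x_mirror, camera)
  h1 <- hartley_condition(n1); h2 <- hartley_condition(n2)
  p <- h1$pts; q <- h2$pts  # q' E p = 0
  A <- cbind(q[, 1] * p[, 1], q[, 1] * p[, 2], q[, 1],
             q[, 2] * p[, 1], q[, 2] * p[, 2], q[, 2],
             p[, 1],          p[, 2],          1)
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] / sv$d[1] < 1e-12)
    stop("degenerate point configuration for essential-matrix estimation")
  Ehat <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  E <- t(h2$T) %*% Ehat %*% h1$T
  # project onto the essential manifold: singular values (s, s, 0)
  es <- svd(E)
  s <- mean(es$d[1:2])
  E <- es$u %*% diag(c(s, s, 0)) %*% t(es$v)
  E / sqrt(sum(E^2)) * sqrt(2)  # fix Frobenius norm for reproducibility
}

# epipolar residuals |x2' E x1| in normalized coordinates
epipolar_residuals <- function(E, x_direct, x_mirror, camera) {
  p <- cbind(px_to_norm(as.matrix(x_direct), camera), 1)
  q <- cbind(px_to_norm(as.matrix(x_mirror), camera), 1)
  abs(rowSums((q %*% E) * p))
}

skew3 <- function(v) matrix(c(0, v[3], -v[2],
                              -v[3], 0, v[1],
                              v[2], -v[1], 0), 3, 3)

rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  K <- skew3(w / th)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# mean Sampson distance of E on normalized correspondences
sampson_cost <- function(E, p, q) {
  Ep <- p %*% t(E)       # rows: E x
  Etq <- q %*% E         # rows: E' x'
  num <- rowSums(q * Ep)^2
  den <- Ep[, 1]^2 + Ep[, 2]^2 + Etq[, 1]^2 + Etq[, 2]^2
  mean(num / den)
}

# Gauss-Newton style refinement of (R, t) by minimizing the Sampson error,
# initialised from the 8-point decomposition. t is kept on the unit sphere.
refine_essential <- function(R0, t0, x_direct, x_mirror, camera) {
  p <- cbind(px_to_norm(x_direct, camera), 1)
  q <- cbind(px_to_norm(x_mirror, camera), 1)
  th0 <- acos(t0[3]); ph0 <- atan2(t0[2], t0[1])
  par0 <- c(0, 0, 0, th0, ph0)
  obj <- function(par) {
    R <- rodrigues(par[1:3]) %*% R0
    t <- c(sin(par[4]) * cos(par[5]), sin(par[4]) * sin(par[5]), cos(par[4]))
    sampson_cost(skew3(t) %*% R, p, q)
  }
  par <- optim(par0, obj, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-14))$par
  R <- rodrigues(par[1:3]) %*% R0
  t <- c(sin(par[4]) * cos(par[5]), sin(par[4]) * sin(par[5]), cos(par[4]))
  list(R = R, t = t, E = skew3(t) %*% R)
}

# the four (R, t) candidates from an essential matrix
decompose_essential <- function(E) {
  es <- svd(E)
  U <- es$u; V <- es$v
  if (det(U) < 0) U <- -U
  if (det(V) < 0) V <- -V
  W <- matrix(c(0, -1, 0,
                1,  0, 0,
                0,  0, 1), 3, 3, byrow = TRUE)
  R1 <- U %*% W %*% t(V)
  R2 <- U %*% t(W) %*% t(V)
  tt <- U[, 3]
  list(list(R = R1, t = tt), list(R = R1, t = -tt),
       list(R = R2, t = tt), list(R = R2, t = -tt))
}

#' Resolve the real/virtual camera pair from an essential matrix
#'
#' Of the four rotation/translation candidates obtained from the SVD of `E`,
#' selects the one that places the triangulated calibration points in front
#' of both cameras (cheirality test). The real camera is fixed at
#' `P_real = K [I | 0]`.
#'
#' @inheritParams estimate_essential_matrix
#' @param E Essential matrix from [estimate_essential_matrix()].
#' @return List with `R`, `t` (unit norm), `P_real`, `P_virtual`.
#' @export
decompose_to_cameras <- function(E, camera, x_direct, x_mirror) {
  cands <- decompose_essential(E)
  P1 <- camera$K %*% cbind(diag(3), 0)
  best <- NULL; best_n <- -1L
  for (cand in cands) {
    P2 <- camera$K %*% cbind(cand$R, cand$t)
    X <- dlt_triangulate(as.matrix(x_direct), as.matrix(x_mirror), P1, P2)
    z1 <- X[, 3]
    z2 <- X %*% cand$R[3, ] + cand$t[3]
    n_front <- sum(z1 > 0 & z2 > 0)
    if (n_front > best_n) { best_n <- n_front; best <- cand }
  }
  if (best_n < 1) stop("cheirality test failed: no candidate places points in front of both cameras")
  list(R = best$R, t = best$t / sqrt(sum(best$t^2)),
       P_real = P1, P_virtual = camera$K %*% cbind(best$R, best$t))
}

#' Calibrate the direct/mirror camera pair from checkerboard correspondences
#'
#' Full calibration path: optional mirror x-reflection, essential-matrix
#' estimation, cheirality-resolved decomposition, and metric scale fixing.
#' The translation recovered from `E` is only defined up to scale; the
#' physical scale is set by least squares so that reconstructed distances
#' between grid-adjacent checker corners match the known square size.
#'
#' @param pairs Data frame of correspondences with columns `x_direct`,
#'   `y_direct`, `x_mirror`, `y_mirror` (raw mirror pixels) and grid ids
#'   `face`, `row`, `col` used to identify 4 mm neighbours.
#' @param camera A [camera_model()].
#' @param checker_square_mm Physical side of one checker square (default 4).
#' @param mirror_flip If `TRUE` (default) mirror x pixels are reflected as
#'   `image_width - x` before estimation; the flag is recorded.
#' @param refine If `TRUE` (default) the 8-point solution is refined by
#'   minimizing the Sampson error over rotation and translation direction.
#' @return An object of class `mirror_calibration`: `E`, `R`, unit `t`,
#'   `scale` (mm per reconstruction unit), metric `P_real`/`P_virtual`,
#'   `camera`, `mirror_flip`, and the median epipolar residual.
#' @export
calibrate_mirror_views <- function(pairs, camera, checker_square_mm = 4,
                                   mirror_flip = TRUE, refine = TRUE) {
  xd <- cbind(pairs$x_direct, pairs$y_direct)
  xm <- cbind(pairs$x_mirror, pairs$y_mirror)
  if (mirror_flip) xm[, 1] <- camera$image_width - xm[, 1]
  E <- estimate_essential_matrix(xd, xm, camera)
  dec <- decompose_to_cameras(E, camera, xd, xm)
  if (refine) {
    rf <- refine_essential(dec$R, dec$t, xd, xm, camera)
    E <- rf$E / sqrt(sum(rf$E^2)) * sqrt(2)
    dec <- decompose_to_cameras(E, camera, xd, xm)
  }
  # reconstruct at |t| = 1 and fit the metric scale from checker spacing
  P2u <- camera$K %*% cbind(dec$R, dec$t)
  X <- dlt_triangulate(xd, xm, dec$P_real, P2u)
  s <- checker_scale_fit(X, pairs, checker_square_mm)
  t_mm <- dec$t * s
  structure(list(E = E, R = dec$R, t = dec$t, scale = s,
                 P_real = dec$P_real,
                 P_virtual = camera$K %*% cbind(dec$R, t_mm),
                 camera = camera, mirror_flip = mirror_flip,
                 checker_square_mm = checker_square_mm,
                 median_residual = median(epipolar_residuals(E, xd, xm, camera))),
            class = "mirror_calibration")
}

#' @export
print.mirror_calibration <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$R)) - 1) / 2))) * 180 / pi
  cat(sprintf("mirror_calibration: rotation %.1f deg, scale %.3f mm/unit, median epipolar residual %.2e\n",
              ang, x$scale, x$median_residual))
  invisible(x)
}

# least-squares scale so grid-neighbour reconstructed distances match the
# physical square: minimise sum (square_mm - s * d_rec)^2 over s
checker_scale_fit <- function(X, pairs, square_mm) {
  if (is.null(pairs$face)) stop("correspondence table lacks face/row/col grid ids for scale fixing")
  frame <- if (is.null(pairs$frame)) rep(1L, nrow(pairs)) else pairs$frame
  d_rec <- numeric(0)
  key <- paste(frame, pairs$face, pairs$row, pairs$col, sep = "/")
  idx <- setNames(seq_len(nrow(pairs)), key)
  for (i in seq_len(nrow(pairs))) {
    for (nb in list(c(1, 0), c(0, 1))) {
      k <- paste(frame[i], pairs$face[i], pairs$row[i] + nb[1],
                 pairs$col[i] + nb[2], sep = "/")
      j <- idx[k]
      if (!is.na(j)) d_rec <- c(d_rec, sqrt(sum((X[i, ] - X[j, ])^2)))
    }
  }
  if (!length(d_rec)) stop("no grid-adjacent correspondence pairs found for scale fixing")
  sum(d_rec * square_mm) / sum(d_rec^2)
}
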