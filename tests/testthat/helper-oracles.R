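# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force loops, closed forms, and direct
# textbook formulas.

# von Mises sampler (Best & Fisher rejection method), radians
rvonmises <- function(n, mu, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n); i <- 1
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1
    }
  }
  out
}

# naive double-loop D-bar: mean over trials of mean station distance
brute_force_dbar <- function(trials) {
  n <- length(trials)
  m <- nrow(trials[[1]])
  xbar <- matrix(0, m, 3)
  for (tr in trials) xbar <- xbar + tr / n
  total <- 0
  for (tr in trials) {
    s <- 0
    for (i in seq_len(m)) s <- s + sqrt(sum((tr[i, ] - xbar[i, ])^2))
    total <- total + s / m
  }
  total / n
}

# nonlinear two-view triangulation by direct optimisation of the summed
# squared reprojection error, initialised away from the solution
nonlinear_triangulate <- function(x1, x2, P1, P2, init) {
  obj <- function(X) {
    h1 <- P1 %*% c(X, 1); h2 <- P2 %*% c(X, 1)
    sum((h1[1:2] / h1[3] - x1)^2) + sum((h2[1:2] / h2[3] - x2)^2)
  }
  optim(init, obj, method = "BFGS",
        control = list(maxit = 500, reltol = 1e-14))$par
}

# brute-force rotation angle between two rotation matrices, degrees
rotation_angle_deg <- function(R1, R2) {
  acos(pmin(1, pmax(-1, (sum(diag(t(R1) %*% R2)) - 1) / 2))) * 180 / pi
}

# Pearson chi-squared on a 2x2 table, written out longhand
chi2_2x2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# random rigid motion
random_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(M))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# ground-truth event vector for comparisons
events_vec <- function(ev) {
  unlist(ev[c("reach_start", "slot_crossing", "reach_end",
              "grasp_start", "grasp_end")])
}
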