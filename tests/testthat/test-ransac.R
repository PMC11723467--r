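test_that("point-line residual is the perpendicular distance", {
  expect_equal(point_line_residual(c(5, 3, 4), c(0, 0, 0), c(1, 0, 0)), 5)
  expect_equal(point_line_residual(c(7, 0, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  # invariant to sliding the anchor along the direction
  set.seed(6)
  p <- matrix(rnorm(30), 10)
  v <- c(1, 2, -0.5) / sqrt(sum(c(1, 2, -0.5)^2))
  r1 <- point_line_residual(p, c(0, 1, 2), v)
  r2 <- point_line_residual(p, c(0, 1, 2) + 3.7 * v, v)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("noiseless collinear points are fitted exactly", {
  v <- c(2, 1, 0.5) / sqrt(sum(c(2, 1, 0.5)^2))
  pts <- t(sapply(seq(0, 9), function(s) c(1, 2, 3) + s * v))
  fit <- fit_path_line(pts, seed = 1)
  expect_equal(abs(sum(fit$v0 * v)), 1, tolerance = 1e-9)
  expect_equal(fit$n_inliers, 10L)
  expect_lt(max(fit$residuals), 1e-9)
  expect_error(fit_path_line(pts[c(1, 1), ]), "degenerate")
})

test_that("line fitting rejects gross outliers over repeated draws", {
  v <- c(1, 0.1, -0.05); v <- v / sqrt(sum(v^2))
  ang_err <- inl <- numeric(100)
  for (s in 1:100) {
    set.seed(s)
    on_line <- t(sapply(runif(70, 0, 10), function(u) c(0, 2, 4) + u * v)) +
      matrix(rnorm(210, sd = 0.05), 70)
    outliers <- cbind(runif(30, 0, 10), runif(30, 0, 10), runif(30, 0, 10))
    fit <- fit_path_line(rbind(on_line, outliers), t1 = 1.0, seed = s)
    ang_err[s] <- acos(min(1, abs(sum(fit$v0 * v)))) * 180 / pi
    inl[s] <- fit$n_inliers
  }
  expect_true(all(inl >= 70))
  # box outliers that happen to fall inside the inlier band tug the refit a
  # little; the direction stays within a degree on average and never drifts
  expect_lt(mean(ang_err), 0.5)
  expect_lt(max(ang_err), 2)
})

shifted_paths <- function(n, dy, dz, sd = 0, n_out = 0, seed = 1) {
  set.seed(seed)
  ry <- seq(0, by = 2.8, length.out = n)
  lz <- rep(seq(0, by = -0.8, length.out = ceiling(n / 4)), each = 4)[1:n]
  Ry <- ry + dy + rnorm(n, sd = sd)
  Lz <- lz + dz + rnorm(n, sd = sd)
  if (n_out > 0) {
    idx <- sample(n, n_out)
    Ry[idx] <- Ry[idx] + runif(n_out, 2, 6) * sample(c(-1, 1), n_out, TRUE)
    Lz[idx] <- Lz[idx] + runif(n_out, 2, 6) * sample(c(-1, 1), n_out, TRUE)
  }
  data.frame(Ry = Ry, Lz = Lz, ry = ry, lz = lz)
}

test_that("deviation estimation recovers exact shifts to machine precision", {
  pp <- shifted_paths(40, 0, 0)
  d0 <- estimate_deviation(pp, n2 = 30, seed = 2)
  expect_equal(c(d0$dnr, d0$dnl), c(0, 0), tolerance = 1e-12)
  pp2 <- shifted_paths(40, 0.4, -0.2)
  d2 <- estimate_deviation(pp2, n2 = 30, seed = 2)
  expect_equal(c(d2$dnr, d2$dnl), c(0.4, -0.2), tolerance = 1e-9)
  expect_error(estimate_deviation(shifted_paths(10, 0, 0), n2 = 30),
               "insufficient")
})

test_that("deviation estimation is translation-equivariant", {
  pp <- shifted_paths(40, 0.3, 0.5, sd = 0.05, n_out = 4, seed = 11)
  d1 <- estimate_deviation(pp, n2 = 30, seed = 3)
  # shift lines and plan together: estimate unchanged
  both <- pp
  both[c("Ry", "ry")] <- both[c("Ry", "ry")] + 1.7
  both[c("Lz", "lz")] <- both[c("Lz", "lz")] - 0.9
  d2 <- estimate_deviation(both, n2 = 30, seed = 3)
  expect_equal(c(d1$dnr, d1$dnl), c(d2$dnr, d2$dnl), tolerance = 1e-12)
  # shift only the lines: estimate shifts identically
  lines_only <- pp
  lines_only$Ry <- lines_only$Ry + 1.7
  d3 <- estimate_deviation(lines_only, n2 = 30, seed = 3)
  expect_equal(d3$dnr - d1$dnr, 1.7, tolerance = 1e-12)
})

test_that("noisy contaminated shifts are recovered within 0.05 mm", {
  errs <- t(sapply(1:100, function(s) {
    pp <- shifted_paths(40, 0.3, 0.5, sd = 0.05, n_out = 4, seed = s)
    d <- estimate_deviation(pp, n2 = 30, seed = 1000 + s)
    c(abs(d$dnr - 0.3), abs(d$dnl - 0.5))
  }))
  expect_lt(mean(errs[, 1]), 0.05)
  expect_lt(mean(errs[, 2]), 0.05)
})

test_that("the BestNum sweep runs across sample sizes", {
  res <- sapply(c(20, 25, 30, 32), function(n2) {
    pp <- shifted_paths(40, -0.25, 0.15, sd = 0.05, n_out = 4, seed = 21)
    d <- estimate_deviation(pp, n2 = n2, seed = n2)
    abs(c(d$dnr + 0.25, d$dnl - 0.15))
  })
  expect_true(all(is.finite(res)))
  expect_lt(max(res), 0.1)
})
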