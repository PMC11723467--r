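test_that("chip geometry matches the closed forms", {
  spec <- cutter_spec(radius = 2, dtheta_deg = 4, helix_deg = 30)
  g <- chip_geometry(spec, theta_m = 0.5)
  expect_equal(g$db, 2 * 4 * pi / 180, tolerance = 1e-12)   # R dtheta
  expect_equal(g$db, 0.1396, tolerance = 1e-3)
  # at theta = pi/2 the helical term vanishes: ds reduces to R dtheta
  g2 <- chip_geometry(spec, theta_m = pi / 2)
  expect_equal(g2$ds, g2$db, tolerance = 1e-12)
  # chip thickness: projection of the feed per tooth on the radial direction
  g3 <- chip_geometry(spec, theta_m = 0.3, vt_vector = c(0.01, 0, 0),
                      radial = rbind(c(0, 2, 0), c(2, 0, 0), c(-2, 0, 0)))
  expect_equal(g3$tn, c(0, 0.01, 0), tolerance = 1e-12)
})

test_that("gray weighting scales the mechanistic force by lambda^mu", {
  co <- force_coefficients()
  f0 <- micro_force(0.005, 0.14, 0.145, lambda = 0, coeffs = co)
  expect_equal(as.numeric(f0), c(0, 0, 0))
  f1 <- micro_force(0.005, 0.14, 0.145, lambda = 1, coeffs = co)
  expect_equal(f1[1, "dFr"][[1]], co$Krc * 0.005 * 0.14 + co$Kre * 0.145,
               tolerance = 1e-12)
  fh <- micro_force(0.005, 0.14, 0.145, lambda = 0.5, coeffs = co,
                    mu = 1.815)
  expect_equal(as.numeric(fh / f1), rep(0.5^1.815, 3), tolerance = 1e-12)
  expect_equal(0.5^1.815, 0.2842, tolerance = 1e-4)
})

test_that("the micro-force rotation is orthonormal and norm-preserving", {
  set.seed(2)
  for (i in 1:20) {
    th <- runif(1, 0, pi); ph <- runif(1, -pi, pi)
    M <- micro_force_rotation(th, ph)
    expect_lt(max(abs(M %*% t(M) - diag(3))), 1e-12)
    v <- rnorm(3)
    expect_equal(sqrt(sum((M %*% v)^2)), sqrt(sum(v^2)), tolerance = 1e-12)
  }
  expect_equal(as.numeric(micro_force_rotation(0, 0) %*% c(1, 0, 0)),
               c(-1, 0, 0))
  # vectorized path agrees with the matrix
  dF <- matrix(rnorm(9), 3)
  th <- c(0.2, 0.9, 1.3); ph <- c(-1, 0.4, 2.2)
  expected <- t(vapply(1:3, function(i)
    as.numeric(micro_force_rotation(th[i], ph[i]) %*% dF[i, ]), numeric(3)))
  expect_equal(unname(rotate_micro_force(dF, th, ph)), expected,
               tolerance = 1e-12)
})

test_that("compiled force trace matches the plain-R wrench summation", {
  s <- tiny_setup(gray = 650)
  edges <- edge_points(s$spec)
  dev <- pose_deviation(c(0.004, -0.006, 0.002), c(0.2, -0.15, 0.1))
  tr <- milling_force_trace(s$vol, s$plan, s$spec, s$coeffs, s$norm,
                            2, 2, deviation = dev, phase = 0.8, n_sub = 1)
  st <- machined_state(s$plan, s$spec, s$vol, 4)
  for (idx in c(3L, 40L, 100L)) {
    pose <- pose_at(tr$t[idx], s$plan, 2, 2, s$spec, deviation = dev,
                    phase = 0.8)
    w <- instantaneous_wrench(pose, edges, st, s$vol, s$norm, s$coeffs,
                              s$spec)
    expect_equal(as.numeric(tr[idx, c("Fx", "Fy", "Fz", "Mz")]),
                 as.numeric(w[c("Fx", "Fy", "Fz", "Mz")]), tolerance = 1e-9)
    expect_equal(tr$n_engaged[idx], w[["n_engaged"]])
  }
})

test_that("wrench scales by the gray weight on homogeneous stock", {
  s1 <- tiny_setup(gray = 400)
  s2 <- tiny_setup(gray = 740)
  tr1 <- milling_force_trace(s1$vol, s1$plan, s1$spec, s1$coeffs, s1$norm,
                             1, 1, n_sub = 2)
  tr2 <- milling_force_trace(s2$vol, s2$plan, s2$spec, s2$coeffs, s2$norm,
                             1, 1, n_sub = 2)
  lam <- normalize_gray(c(400, 740), s1$norm)
  ratio <- (lam[2] / lam[1])^s1$norm$mu
  for (ch in c("Fx", "Fy", "Fz", "Mz"))
    expect_equal(tr2[[ch]], tr1[[ch]] * ratio, tolerance = 1e-9)
})

test_that("the wrench is periodic in the flute-passing phase", {
  s <- tiny_setup()
  tr1 <- milling_force_trace(s$vol, s$plan, s$spec, s$coeffs, s$norm, 1, 1,
                             phase = 0, n_sub = 1)
  tr2 <- milling_force_trace(s$vol, s$plan, s$spec, s$coeffs, s$norm, 1, 1,
                             phase = 2 * pi / s$spec$flutes, n_sub = 1)
  expect_equal(tr1$Fz, tr2$Fz, tolerance = 1e-9)
  expect_equal(tr1$Mz, tr2$Mz, tolerance = 1e-9)
})

test_that("prediction bank bookkeeping and gradient response", {
  vol <- make_step_phantom(c(12, 12, 6), 0.25)
  plan <- milling_plan(n_layers = 2, n_paths = 2, path_length = 8,
                       origin = c(2, 4, 6))
  spec <- cutter_spec()
  bank <- predict_bank(vol, plan, spec)
  expect_equal(dim(bank$seq), c(15L, 4L, 2L * 2L * plan$grids_per_path))
  expect_equal(nrow(bank$index), dim(bank$seq)[3])
  # identical inputs give identical banks
  bank2 <- predict_bank(vol, plan, spec)
  expect_identical(bank$seq, bank2$seq)
  # paths run up the gray gradient: per-grid |Fz| never decreases
  e11 <- bank$index$entry[bank$index$i == 1 & bank$index$j == 1]
  mfz <- vapply(e11, function(e) mean(abs(bank$seq[, 3, e])), numeric(1))
  expect_true(all(diff(mfz) > -1e-6))
})

test_that("paths across the gradient see constant per-grid force", {
  vol <- make_step_phantom(c(12, 12, 6), 0.25, gradient_axis = "y")
  plan <- milling_plan(n_layers = 1, n_paths = 2, path_length = 8,
                       origin = c(2, 4, 6))
  bank <- predict_bank(vol, plan, cutter_spec())
  for (j in 1:2) {
    e <- bank$index$entry[bank$index$j == j]
    mfz <- vapply(e, function(k) mean(abs(bank$seq[, 3, k])), numeric(1))
    expect_lt((max(mfz) - min(mfz)) / mean(mfz), 0.05)
  }
})
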