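test_that("the undisturbed closed loop reproduces the bank sample-for-sample", {
  s <- tiny_setup(gray = 800)
  # give the block some structure so the check is non-trivial
  s$vol$data[, , 1:10] <- 400
  bank <- predict_bank(s$vol, s$plan, s$spec, s$coeffs, s$norm)
  run <- simulate_run(s$vol, s$plan, s$spec, s$coeffs, s$norm,
                      noise_sigma = c(0, 0), phase = 0, seed = 1)
  sig <- as.matrix(run$signal[, c("Fx", "Fy", "Fz", "Mz")])
  stacked <- matrix(aperm(bank$seq, c(1, 3, 2)), ncol = 4)
  expect_equal(unname(sig), unname(stacked), tolerance = 1e-12)
})

test_that("simulation is deterministic for a fixed seed", {
  s <- tiny_setup()
  r1 <- simulate_run(s$vol, s$plan, s$spec, s$coeffs, s$norm,
                     feed = feed_disturbance(0.2, 1, NULL), seed = 5)
  r2 <- simulate_run(s$vol, s$plan, s$spec, s$coeffs, s$norm,
                     feed = feed_disturbance(0.2, 1, NULL), seed = 5)
  expect_identical(r1$signal, r2$signal)
  expect_identical(r1$truth, r2$truth)
})

test_that("the feed disturbance integrates to the sine-modulated feed", {
  fd <- feed_disturbance(0.2, 1.3, 0.7)
  t <- seq(0, 8, by = 0.005)
  prof <- feed_profile(fd, 0.5, t)
  num_rate <- diff(prof$offset) / diff(t)
  expect_equal(num_rate, (prof$rate[-1] + prof$rate[-length(t)]) / 2,
               tolerance = 1e-4)
  expect_true(all(prof$rate > 0))
  expect_error(feed_profile(feed_disturbance(0.6), 0.5, t), "below")
})

test_that("a run under a printed large deviation completes on the narrow
           protocol phantom", {
  st <- study_setup("narrow", phantom_seed = 3)
  cd <- narrow_plan_deviations()[8, ]
  dev <- pose_deviation(c(cd$rx, cd$ry, cd$rz), c(cd$tx, cd$ty, cd$tz))
  expect_equal(round(dev$incline_deg, 1), 0.6)
  run <- simulate_run(st$vol, st$plan, st$spec, st$coeffs, st$norm,
                      deviation = dev, seed = 2)
  expect_equal(nrow(run$signal),
               st$plan$samples_per_path * st$plan$n_layers * st$plan$n_paths)
  expect_true(all(is.finite(as.matrix(run$signal[, -1]))))
})

test_that("runs that leave the stock abort with a diagnostic", {
  s <- tiny_setup()
  expect_error(
    simulate_run(s$vol, s$plan, s$spec, s$coeffs, s$norm,
                 deviation = pose_deviation(translation = c(0, 30, 0)),
                 seed = 1),
    "exits the volume")
})

test_that("error reports score perfect and grid-shifted estimates", {
  s <- tiny_setup(gray = 700)
  s$vol$data[] <- s$vol$data + rep(seq(0, 400, length.out = 32), times = 32 * 20)
  bank <- predict_bank(s$vol, s$plan, s$spec, s$coeffs, s$norm)
  run <- simulate_run(s$vol, s$plan, s$spec, s$coeffs, s$norm,
                      noise_sigma = c(0, 0), phase = 0, seed = 1)
  track <- estimate_track(run$signal, bank, s$plan, "dtw")
  rep0 <- evaluate_run(track, run$truth)
  expect_equal(rep0$mean_raw, 0, tolerance = 1e-9)
  expect_equal(rep0$max_raw, 0, tolerance = 1e-9)
  # displace every estimate by one grid along the path
  off <- track
  off$x <- off$x + s$plan$grid_length
  rep1 <- evaluate_run(off, run$truth)
  expect_equal(rep1$mean_raw, s$plan$grid_length, tolerance = 1e-9)
})

test_that("correlation matrices follow the similarity conventions", {
  set.seed(8)
  a <- rnorm(50)
  R <- correlation_matrix(cbind(a, 2 * a + 3, -a, rnorm(50)))
  expect_equal(diag(R), rep(1, 4), ignore_attr = TRUE)
  expect_equal(R[1, 2], 1, tolerance = 1e-12)
  expect_equal(R[1, 3], -1, tolerance = 1e-12)
  ind <- attr(R, "independent")
  expect_false(ind[1, 2])
  expect_false(any(diag(ind)))
  expect_message(Rz <- correlation_matrix(cbind(a, rep(1, 50))),
                 "zero-variance")
  expect_equal(Rz[1, 2], 0)
  expect_equal(diag(Rz), rep(1, 2), ignore_attr = TRUE)
  expect_error(correlation_matrix(matrix(a, ncol = 1)), "two sequences")
})

test_that("experiment-suite bookkeeping covers the protocol grids", {
  cond <- feed_sweep_conditions(seeds = 1)
  expect_equal(nrow(cond), 5L)
  expect_equal(cond$amplitude, c(0.05, 0.10, 0.15, 0.20, 0.30))
  expect_equal(nrow(feed_sweep_conditions(seeds = integer(0))), 0L)
  s <- tiny_setup()
  empty <- run_experiment_suite(s$vol, s$plan, s$spec, s$coeffs, s$norm,
                                conditions = data.frame())
  expect_equal(nrow(empty$summary), 0L)
  nd <- narrow_plan_deviations()
  expect_equal(nrow(nd), 11L)
  expect_equal(round(nd$incline_deg[1], 1), 4.3)
})

test_that("a pipeline pass reports both similarity branches", {
  s <- tiny_setup(gray = 700)
  set.seed(30)
  s$vol$data[] <- pmax(0, s$vol$data +
    array(200 * rnorm(length(s$vol$data)), dim = dim(s$vol$data)))
  bank <- predict_bank(s$vol, s$plan, s$spec, s$coeffs, s$norm)
  run <- simulate_run(s$vol, s$plan, s$spec, s$coeffs, s$norm, seed = 3)
  pr <- run_pipeline(run, bank, s$plan, s$spec, n2 = 4)
  expect_named(pr, c("dtw", "pearson"))
  for (m in names(pr)) {
    expect_s3_class(pr[[m]]$report, "error_report")
    expect_true(is.finite(pr[[m]]$report$mean_ref))
  }
})
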