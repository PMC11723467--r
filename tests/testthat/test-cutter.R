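test_that("micro-edge geometry matches the closed-form positions", {
  spec <- cutter_spec(radius = 2, flutes = 4, helix_deg = 30,
                      tip_offset = 0.25, dtheta_deg = 4)
  # apex edge of the first flute sits on the +x axis
  expect_equal(as.numeric(edge_position(spec, 0, 0)), c(2, 0, 0))
  # theta = pi/3: on the sphere, z = -R sin(theta)
  p <- edge_position(spec, pi / 3, 0)
  expect_equal(sqrt(sum(p^2)), 2, tolerance = 1e-12)
  expect_equal(p[1, "z"][[1]], -sqrt(3), tolerance = 1e-12)
  # axial range stops where the edge leaves the apex clearance
  expect_equal(spec$theta_max, acos(0.25 / 2), tolerance = 1e-12)
  expect_equal(spec$theta_max, 1.4455, tolerance = 1e-4)
})

test_that("all sampled micro-edges lie on the cutter sphere", {
  spec <- cutter_spec()
  ed <- edge_points(spec, phase = 0.37)
  r <- sqrt(ed$x^2 + ed$y^2 + ed$z^2)
  expect_lt(max(abs(r - spec$radius)), 1e-9)
  expect_true(all(ed$theta_m >= 0 & ed$theta_m <= spec$theta_max))
  expect_equal(length(unique(ed$flute)), spec$flutes)
})

test_that("feed per tooth and the phase condition behave as scaled ratios", {
  expect_equal(feed_per_tooth(0.5, 4, 800), 0.009375)
  expect_equal(feed_per_tooth(0, 4, 800), 0)
  expect_equal(feed_per_tooth(0.5, 4, 1600), feed_per_tooth(0.5, 4, 800) / 2)
  expect_error(feed_per_tooth(0.5, 4, 0), "spindle")
  pc <- check_phase_condition(0.5, 4, 800, 0.25)
  expect_equal(pc$ratio, 0.0375)
  expect_true(pc$pass)
  fast <- check_phase_condition(25, 4, 800, 0.25)
  expect_equal(fast$ratio, 1.875)
  expect_false(fast$pass)
  expect_true(check_phase_condition(0.5, 4, 800, 1e9)$pass)
})

test_that("tool pose chains spin, feed, incline and path origin", {
  plan <- milling_plan(n_layers = 2, n_paths = 2, path_length = 4,
                       origin = c(2, 2.5, 5))
  spec <- cutter_spec()
  pose0 <- pose_at(0, plan, 1, 1, spec)
  # MCCS origin lands at the ball centre above the path start
  expect_equal(pose0$centre_nom, c(2, 2.5, 5 - 0.8 + 2), tolerance = 1e-12)
  # one spindle revolution: positions repeat apart from the feed advance
  t_rev <- 60 / 800
  pose1 <- pose_at(t_rev, plan, 1, 1, spec)
  expect_equal(pose1$spin_phase, 2 * pi, tolerance = 1e-12)
  ed <- as.matrix(edge_points(spec)[, c("x", "y", "z")])
  hom <- cbind(ed, 1)
  p0 <- hom %*% t(pose0$T_nom)
  p1 <- hom %*% t(pose1$T_nom)
  shift <- p1[, 1:3] - p0[, 1:3]
  expect_equal(shift[, 1], rep(plan$feed * t_rev, nrow(ed)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_lt(max(abs(shift[, 2:3])), 1e-9)
  expect_error(pose_at(1e3, plan, 1, 1, spec), "interval")
})

test_that("the incline tilts the cutter axis in the y-z plane", {
  plan <- milling_plan(n_layers = 1, n_paths = 1, path_length = 4,
                       incline_deg = 30, origin = c(2, 2, 5))
  spec <- cutter_spec()
  pose <- pose_at(0, plan, 1, 1, spec)
  axis <- (pose$T_nom %*% c(0, 0, 1, 0))[1:3]
  expect_equal(axis[1], 0, tolerance = 1e-12)
  expect_equal(acos(axis[3]), 30 * pi / 180, tolerance = 1e-12)
})

test_that("pose rotations stay orthonormal and the centre tracks the feed", {
  plan <- milling_plan(n_layers = 2, n_paths = 3, path_length = 5,
                       origin = c(2, 2, 6))
  spec <- cutter_spec()
  dev <- pose_deviation(c(0.01, -0.02, 0.005), c(0.3, -0.2, 0.1))
  set.seed(4)
  for (t in runif(8, 0, plan$path_length / plan$feed)) {
    pose <- pose_at(t, plan, 2, 2, spec, deviation = dev)
    R <- pose$T_act[1:3, 1:3]
    expect_lt(max(abs(R %*% t(R) - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
  # identity deviation: straight centre line along x at speed vd
  ts <- seq(0, 4, by = 0.5)
  centres <- t(vapply(ts, function(t)
    pose_at(t, plan, 1, 1, spec)$centre_nom, numeric(3)))
  expect_equal(centres[, 1], 2 + plan$feed * ts, tolerance = 1e-12)
  expect_equal(unique(round(centres[, 2], 12)), 2)
  expect_equal(diff(range(centres[, 3])), 0, tolerance = 1e-12)
})
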