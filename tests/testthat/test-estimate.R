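make_sig <- function(n, fs = 20) {
  set.seed(1)
  force_signal(data.frame(Fx = rnorm(n), Fy = rnorm(n), Fz = rnorm(n),
                          Mz = rnorm(n)), fs = fs)
}

test_that("tumbling window cuts whole segments and drops the remainder", {
  segs <- tumble_segment(make_sig(300), ns = 15, feed = 0.5)
  expect_length(segs, 20L)
  expect_equal(segs[[1]]$l, 0.375)                 # vd * ns / fs
  expect_equal(dim(segs[[7]]$channels), c(15L, 4L))
  expect_warning(out <- tumble_segment(make_sig(14), ns = 15), "shorter")
  expect_length(out, 0L)
  # 317 samples: the 2-sample remainder is dropped
  expect_length(tumble_segment(make_sig(317), ns = 15), 21L)
})

test_that("dtw distance reproduces hand-computed DP tables", {
  expect_equal(dtw_distance(c(0, 0), c(1, 1)), 2)
  expect_equal(dtw_distance(c(0, 1, 2), c(1, 2, 3)), 2)
  expect_lt(dtw_distance(c(0, 1, 2), c(1, 2, 3)), 3)  # beats lockstep
  s <- c(0.3, -1, 2, 0.5)
  expect_equal(dtw_distance(s, s), 0)
  expect_error(dtw_distance(numeric(0), 1), "empty")
})

test_that("dtw distance is symmetric, lockstep-bounded and matches the
           independent DP oracle", {
  set.seed(10)
  for (i in 1:100) {
    n <- sample(5:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    d <- dtw_distance(a, b)
    expect_equal(d, dtw_distance(b, a), tolerance = 1e-12)
    expect_lte(d, sum(abs(a - b)) + 1e-12)
    expect_equal(d, dtw_ref(a, b), tolerance = 1e-9)
  }
})

tiny_bank <- function() {
  vol <- make_step_phantom(c(12, 12, 6), 0.25)
  plan <- milling_plan(n_layers = 2, n_paths = 2, path_length = 6,
                       origin = c(2, 4, 6))
  list(bank = predict_bank(vol, plan, cutter_spec()), plan = plan)
}

test_that("similarity fields have the bank's index shape and sign rules", {
  tb <- tiny_bank()
  seg <- tb$bank$seq[, , 5]
  fd <- similarity_field(seg, tb$bank, "dtw")
  expect_equal(dim(fd), c(2L, 2L, tb$plan$grids_per_path))
  expect_true(all(fd >= 0))
  expect_equal(attr(fd, "method"), "dtw")
  hit <- tb$bank$index[5, ]
  expect_equal(fd[hit$i, hit$j, hit$k], 0)
  fp <- similarity_field(seg, tb$bank, "pearson")
  expect_true(all(fp >= -4 - 1e-9 & fp <= 4 + 1e-9))  # 4 channels summed
})

test_that("tip estimation returns the exact self-match and breaks ties
           lexicographically", {
  tb <- tiny_bank()
  e <- 9L
  est <- estimate_tip(tb$bank$seq[, , e], tb$bank, "dtw")
  expect_equal(c(est$i, est$j, est$k),
               unlist(tb$bank$index[e, c("i", "j", "k")], use.names = FALSE))
  expect_equal(est$score, 0)
  expect_equal(c(est$x, est$y, est$z),
               unlist(tb$bank$index[e, c("x", "y", "z")], use.names = FALSE))
  # duplicate the sequence at a later index: the earlier (i,j,k) must win
  dup <- tb$bank
  dup$seq[, , 20] <- dup$seq[, , 3]
  est2 <- estimate_tip(dup$seq[, , 20], dup, "dtw")
  expect_equal(est2$score, 0)
  expect_equal(c(est2$i, est2$j, est2$k),
               unlist(dup$index[3, c("i", "j", "k")], use.names = FALSE))
  # single-entry bank returns its only entry whatever the input
  one <- dup
  one$seq <- dup$seq[, , 1, drop = FALSE]
  one$index <- dup$index[1, ]
  est3 <- estimate_tip(matrix(rnorm(60), 15), one, "dtw")
  expect_equal(est3$i, one$index$i[1])
})

test_that("pearson similarity honours affine invariance and flags
           zero-variance channels", {
  tb <- tiny_bank()
  seg <- tb$bank$seq[, , 5]
  aff <- 2 * seg + 3
  fp <- similarity_field(aff, tb$bank, "pearson")
  hit <- tb$bank$index[5, ]
  expect_equal(fp[hit$i, hit$j, hit$k], max(fp), tolerance = 1e-9)
  flat <- seg; flat[, 2] <- 7  # constant channel: contributes 0 similarity
  ff <- similarity_field(flat, tb$bank, "pearson")
  expect_true(all(is.finite(ff)))
})

test_that("white noise of vanishing amplitude leaves the estimate unchanged", {
  tb <- tiny_bank()
  e <- 12L
  seg <- tb$bank$seq[, , e]
  set.seed(3)
  noisy <- seg + matrix(rnorm(length(seg), sd = 1e-9), nrow(seg))
  est <- estimate_tip(noisy, tb$bank, "dtw")
  expect_equal(c(est$i, est$j, est$k),
               unlist(tb$bank$index[e, c("i", "j", "k")], use.names = FALSE))
})
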