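#' Sinusoidal feed-rate disturbance
#'
#' Models an unstable feed rate as `vd + A sin(2 pi f t + phase)`. The
#' instantaneous feed must stay positive (`A < vd`).
#'
#' @param amplitude A (mm/s, >= 0).
#' @param frequency f (Hz).
#' @param phase Phase (rad), or `NULL` to draw it uniformly from the
#'   current RNG stream when the disturbance is used in a simulation.
#' @return Object of class `feed_disturbance`.
#' @export
feed_disturbance <- function(amplitude = 0, frequency = 1, phase = 0) {
  stopifnot(amplitude >= 0, frequency > 0)
  structure(list(amplitude = amplitude, frequency = frequency,
                 phase = phase), class = "feed_disturbance")
}

#' Feed profile under a sinusoidal disturbance
#'
#' Centre offset along the path (the time integral of the instantaneous
#' feed) and the instantaneous feed rate at the sample times.
#'
#' @param feed A [feed_disturbance()].
#' @param vd Nominal feed rate (mm/s).
#' @param t Times since the start of the path (s).
#' @return List with `offset` (mm) and `rate` (mm/s), one value per time.
#' @export
feed_profile <- function(feed, vd, t) {
  if (feed$amplitude == 0)
    return(list(offset = vd * t, rate = rep(vd, length(t))))
  if (feed$amplitude >= vd)
    stop("feed disturbance amplitude must stay below the nominal feed")
  w <- 2 * pi * feed$frequency
  ph <- if (is.null(feed$phase)) 0 else feed$phase
  list(offset = vd * t + feed$amplitude / w * (cos(ph) - cos(w * t + ph)),
       rate = vd + feed$amplitude * sin(w * t + ph))
}

#' Draw a random small pose deviation
#'
#' Uniform small rotations and translations, drawn from the current RNG
#' stream (seed upstream for reproducibility).
#'
#' @param rot_max Per-axis rotation bound (rad).
#' @param trans_max Per-axis translation bound (mm).
#' @return A [pose_deviation()].
#' @export
random_pose_deviation <- function(rot_max = 0.01, trans_max = 0.5) {
  pose_deviation(angles = stats::runif(3, -rot_max, rot_max),
                 translation = stats::runif(3, -trans_max, trans_max))
}

#' Closed-loop milling simulation
#'
#' Executes the plan path-by-path through the cutter / engagement / force
#' modules with a rigid workspace deviation, an optional sinusoidal
#' feed-rate disturbance, a random initial cutter phase and i.i.d. Gaussian
#' sensor noise, and records the true (deviated) tip position at every
#' sample. Deterministic given `seed`.
#'
#' @inheritParams milling_force_trace
#' @param deviation A [pose_deviation()] applied to the whole executed
#'   workspace.
#' @param feed A [feed_disturbance()]; a `NULL` phase is drawn per run.
#' @param noise_sigma Length-2 vector: standard deviation of the additive
#'   noise on the force channels (N) and on Mz (N mm).
#' @param seed Integer seed; `NULL` continues the caller's RNG stream.
#' @param phase Initial cutter phase (rad); `NULL` draws it uniformly.
#' @param n_sub Spindle-phase substeps per sample.
#' @return List of class `milling_run`: `signal` (a [force_signal()]),
#'   `truth` (per-sample data.frame `t`, `x`, `y`, `z` true tip position,
#'   `ord`, `layer`, `path`), `deviation`, `feed`, `phase`,
#'   `noise_sigma`, `seed`.
#' @export
simulate_run <- function(vol, plan, spec, coeffs = force_coefficients(),
                         norm = norm_params(), deviation = pose_deviation(),
                         feed = feed_disturbance(0),
                         noise_sigma = c(0.05, 0.5), seed = NULL,
                         phase = NULL, n_sub = 8) {
  if (!is.null(seed)) {
    old <- save_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  if (is.null(phase)) phase <- stats::runif(1, 0, 2 * pi)
  if (is.null(feed$phase)) feed$phase <- stats::runif(1, 0, 2 * pi)
  paths <- plan_paths(plan)
  b <- volume_bounds(vol)
  spp <- plan$samples_per_path
  sig <- vector("list", nrow(paths))
  truth <- vector("list", nrow(paths))
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    tr <- milling_force_trace(vol, plan, spec, coeffs, norm, p$layer,
                              p$path, deviation = deviation, feed = feed,
                              phase = phase, n_sub = n_sub)
    t_loc <- tr$t
    fp <- feed_profile(feed, plan$feed, t_loc)
    x_nom <- (if (p$dir > 0) p$x0 else p$x1) + p$dir * fp$offset
    centre_nom <- cbind(x_nom, p$y, p$z_tip + spec$radius)
    centre_act <- apply_deviation(centre_nom, deviation, plan$origin)
    tip_act <- centre_act - rep(c(0, 0, spec$radius), each = spp)
    if (any(tip_act[, 1] < b$lo[1] | tip_act[, 1] > b$hi[1] |
            tip_act[, 2] < b$lo[2] | tip_act[, 2] > b$hi[2] |
            tip_act[, 3] < b$lo[3]))
      stop("deviated path (layer ", p$layer, ", path ", p$path,
           ") exits the volume; enlarge the phantom or reduce the deviation")
    t_glob <- (r - 1) * spp / plan$fs + t_loc
    sig[[r]] <- data.frame(t = t_glob, Fx = tr$Fx, Fy = tr$Fy, Fz = tr$Fz,
                           Mz = tr$Mz)
    truth[[r]] <- data.frame(t = t_glob, x = tip_act[, 1], y = tip_act[, 2],
                             z = tip_act[, 3], ord = p$ord, layer = p$layer,
                             path = p$path)
  }
  sig <- do.call(rbind, sig)
  n <- nrow(sig)
  sig$Fx <- sig$Fx + stats::rnorm(n, 0, noise_sigma[1])
  sig$Fy <- sig$Fy + stats::rnorm(n, 0, noise_sigma[1])
  sig$Fz <- sig$Fz + stats::rnorm(n, 0, noise_sigma[1])
  sig$Mz <- sig$Mz + stats::rnorm(n, 0, noise_sigma[2])
  structure(list(signal = force_signal(sig, plan$fs),
                 truth = do.call(rbind, truth), deviation = deviation,
                 feed = feed, phase = phase, noise_sigma = noise_sigma,
                 seed = seed),
            class = "milling_run")
}

#' True constant-offset summary of a workspace deviation
#'
#' The deviation-estimation stage models the executed workspace as the plan
#' shifted by a constant `(dnr, dnl)`; for a general rigid deviation the
#' best-achievable constants are the mean y/z displacement of the planned
#' path midpoints. These are the ground-truth values the estimated
#' `(dnr, dnl)` are scored against.
#'
#' @param plan A [milling_plan()].
#' @param spec A [cutter_spec()].
#' @param deviation A [pose_deviation()].
#' @return Named vector `dnr`, `dnl` (mm).
#' @export
true_deviation_offsets <- function(plan, spec, deviation) {
  paths <- plan_paths(plan)
  mid <- cbind((paths$x0 + paths$x1) / 2, paths$y,
               paths$z_tip + spec$radius)
  moved <- apply_deviation(mid, deviation, plan$origin)
  c(dnr = mean(moved[, 2] - mid[, 2]), dnl = mean(moved[, 3] - mid[, 3]))
}

#' Score a matched (and optionally refined) track against the ground truth
#'
#' Per-segment position error is the Euclidean distance between the
#' estimated tip position and the true tip position at the segment's
#' temporal midpoint. When a refined track and a deviation estimate are
#' supplied, the refined errors and the two deviation-channel errors
#' (distance deviation `|dnr_hat - dnr|`, milling depth `|dnl_hat - dnl|`)
#' are reported as well.
#'
#' @param track An [estimate_track()] result, or the `track` element of a
#'   [refine_track()] result (with `x_ref`, `y_ref`, `z_ref` columns).
#' @param truth The `truth` element of a [simulate_run()].
#' @param deviation_est An [estimate_deviation()] result (optional).
#' @param true_offsets A [true_deviation_offsets()] vector (optional).
#' @return List of class `error_report`: `per_segment` (data.frame with
#'   `seg`, `ord`, `t_mid`, `err_raw`, `err_ref`), `mean_raw`, `max_raw`,
#'   `mean_ref`, `max_ref`, `dev_err` (named `dnr`, `dnl`), `method`.
#' @export
evaluate_run <- function(track, truth, deviation_est = NULL,
                         true_offsets = NULL) {
  if (nrow(track) == 0L) stop("empty track")
  tx <- stats::approx(truth$t, truth$x, track$t_mid, rule = 2)$y
  ty <- stats::approx(truth$t, truth$y, track$t_mid, rule = 2)$y
  tz <- stats::approx(truth$t, truth$z, track$t_mid, rule = 2)$y
  err_raw <- sqrt((track$x - tx)^2 + (track$y - ty)^2 + (track$z - tz)^2)
  err_ref <- if (all(c("x_ref", "y_ref", "z_ref") %in% names(track)))
    sqrt((track$x_ref - tx)^2 + (track$y_ref - ty)^2 + (track$z_ref - tz)^2)
  else rep(NA_real_, nrow(track))
  dev_err <- c(dnr = NA_real_, dnl = NA_real_)
  if (!is.null(deviation_est) && !is.null(true_offsets))
    dev_err <- c(dnr = abs(deviation_est$dnr - true_offsets["dnr"][[1]]),
                 dnl = abs(deviation_est$dnl - true_offsets["dnl"][[1]]))
  structure(list(
    per_segment = data.frame(seg = track$seg, ord = track$ord,
                             t_mid = track$t_mid, err_raw = err_raw,
                             err_ref = err_ref),
    mean_raw = mean(err_raw), max_raw = max(err_raw),
    mean_ref = mean(err_ref), max_ref = max(err_ref),
    dev_err = dev_err,
    method = if ("method" %in% names(track)) track$method[1] else NA),
    class = "error_report")
}

#' Pearson correlation matrix of per-path force sequences
#'
#' Quantifies how similar the force sequences of different paths are; a
#' pair with `|R| < threshold` is flagged as independent (the property that
#' makes the density profile a usable localization landmark).
#'
#' @param seqs Matrix with one sequence per column (equal lengths), or a
#'   list of equal-length numeric vectors.
#' @param threshold Independence threshold on `|R|`.
#' @return Correlation matrix with unit diagonal; zero-variance sequences
#'   get zero off-diagonal entries (with a message). Attribute
#'   `independent` is the logical matrix `|R| < threshold` (diagonal
#'   `FALSE`).
#' @export
correlation_matrix <- function(seqs, threshold = 0.4) {
  if (is.list(seqs) && !is.data.frame(seqs)) seqs <- do.call(cbind, seqs)
  seqs <- as.matrix(seqs)
  if (ncol(seqs) < 2L) stop("need at least two sequences")
  sds <- apply(seqs, 2L, stats::sd)
  R <- suppressWarnings(stats::cor(seqs))
  if (any(sds == 0)) {
    message("zero-variance sequence(s): ",
            paste(which(sds == 0), collapse = ", "),
            "; correlations set to 0")
    R[sds == 0, ] <- 0
    R[, sds == 0] <- 0
  }
  diag(R) <- 1
  ind <- abs(R) < threshold
  diag(ind) <- FALSE
  attr(R, "independent") <- ind
  R
}
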