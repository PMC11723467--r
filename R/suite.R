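#' One full estimation pipeline pass over a simulated run
#'
#' Simulation -> tumbling-window matching -> RANSAC refinement ->
#' error report, for one or more similarity methods on the same run.
#'
#' @param run A [simulate_run()] result.
#' @param bank A [predict_bank()] result (nominal plan).
#' @param plan The executed [milling_plan()].
#' @param spec The [cutter_spec()] (for the ground-truth offsets).
#' @param methods Similarity methods to score (`"dtw"`, `"pearson"`).
#' @param weights Per-channel similarity weights.
#' @param n2,k2,t2,n1,k1,t1 RANSAC parameters ([refine_track()]).
#' @param refine_seed Seed for the (deterministic) refinement stage.
#' @return List of class `pipeline_result` with one entry per method, each
#'   holding `track` (refined), `refined` (the [refine_track()] result) and
#'   `report` (an [evaluate_run()] report).
#' @export
run_pipeline <- function(run, bank, plan, spec, methods = c("dtw", "pearson"),
                         weights = c(1, 1, 1, 1), n1 = 2, k1 = 2000, t1 = 1.0,
                         n2 = 30, k2 = 2000, t2 = 1.0, refine_seed = 1L) {
  stopifnot(inherits(run, "milling_run"))
  offs <- true_deviation_offsets(plan, spec, run$deviation)
  out <- lapply(methods, function(m) {
    track <- estimate_track(run$signal, bank, plan, method = m,
                            weights = weights)
    ref <- refine_track(track, plan, n1 = n1, k1 = k1, t1 = t1, n2 = n2,
                        k2 = k2, t2 = t2, seed = refine_seed)
    report <- evaluate_run(ref$track, run$truth, ref$deviation, offs)
    list(track = ref$track, refined = ref, report = report)
  })
  names(out) <- methods
  structure(out, class = "pipeline_result")
}

#' Condition grid for the feed-rate disturbance protocol
#'
#' @param amplitudes Sine amplitudes (mm/s) about the nominal feed.
#' @param seeds Integer seeds; each (amplitude, seed) pair is one run.
#' @return Data.frame with columns `amplitude`, `seed`.
#' @export
feed_sweep_conditions <- function(amplitudes = c(0.05, 0.10, 0.15, 0.20,
                                                 0.30),
                                  seeds = 1:5) {
  if (length(seeds) == 0L)
    return(data.frame(amplitude = numeric(0), seed = integer(0)))
  expand.grid(seed = as.integer(seeds), amplitude = amplitudes)[
    , c("amplitude", "seed")]
}

#' Deviation conditions of the narrow-plan validation protocol
#'
#' Eleven representative random rigid-pose deviations (three small rotation
#' angles in rad, three translations in mm) used by the two-path
#' narrow-workspace protocol; the implied total rotation magnitude is
#' reported in degrees for reference.
#'
#' @return Data.frame with columns `cond`, `rx`, `ry`, `rz`, `tx`, `ty`,
#'   `tz`, `incline_deg`.
#' @export
narrow_plan_deviations <- function() {
  m <- matrix(c(
    0.065, 0.024, 0.030, 0.43, 2.48, -0.24,
    0.054, 0.033, 0.024, -0.32, -0.01, 0.20,
    0.069, -0.000, 0.019, -0.35, 0.04, -0.21,
    0.053, 0.021, 0.022, 0.07, -0.18, -2.39,
    0.064, 0.010, 0.009, -1.43, 0.48, 0.97,
    0.055, 0.019, 0.022, 0.53, -0.02, 1.02,
    0.053, 0.029, 0.034, -1.24, -1.07, -1.43,
    0.009, 0.004, 0.004, 1.37, -0.89, -1.02,
    0.056, 0.031, 0.017, -0.77, 0.22, 1.19,
    0.064, 0.028, 0.029, 1.61, 1.74, 0.47,
    0.030, 0.003, 0.013, 1.36, -0.37, 1.43), ncol = 6, byrow = TRUE)
  out <- data.frame(cond = seq_len(nrow(m)), rx = m[, 1], ry = m[, 2],
                    rz = m[, 3], tx = m[, 4], ty = m[, 5], tz = m[, 6])
  out$incline_deg <- sqrt(out$rx^2 + out$ry^2 + out$rz^2) * 180 / pi
  out
}

#' Run a suite of closed-loop estimation experiments
#'
#' Executes one simulated run per condition row and scores every requested
#' similarity method. A condition row carries `seed` and either an explicit
#' deviation (`rx`, `ry`, `rz`, `tx`, `ty`, `tz` columns) or bounds for a
#' random one; `amplitude` (mm/s), if present, drives the sinusoidal
#' feed-rate disturbance. Failed conditions are recorded and the suite
#' continues.
#'
#' @param vol,plan,spec,coeffs,norm The study setup.
#' @param conditions Data.frame of condition rows (may be empty).
#' @param bank A [predict_bank()]; computed once here if `NULL`.
#' @param methods Similarity methods to score.
#' @param rot_max,trans_max Bounds for random deviations when the condition
#'   does not fix one (rad / mm).
#' @param noise_sigma Sensor noise (N, N mm).
#' @param feed_frequency Feed-disturbance frequency (Hz).
#' @param n2,t2 Deviation-stage RANSAC parameters.
#' @param n_sub Spindle-phase substeps per sample.
#' @return List: `summary` (data.frame, one row per condition x method:
#'   condition columns plus `method`, `mean_err`, `max_err`,
#'   `mean_err_raw`, `dev_err_dnr`, `dev_err_dnl`, `failed`, `message`)
#'   and `reports` (per-condition [run_pipeline()] results).
#' @export
run_experiment_suite <- function(vol, plan, spec,
                                 coeffs = force_coefficients(),
                                 norm = norm_params(), conditions,
                                 bank = NULL, methods = c("dtw", "pearson"),
                                 rot_max = 0.01, trans_max = 0.5,
                                 noise_sigma = c(0.05, 0.5),
                                 feed_frequency = 1, n2 = 30, t2 = 1.0,
                                 n_sub = 8) {
  conditions <- as.data.frame(conditions)
  if (nrow(conditions) == 0L)
    return(list(summary = data.frame(), reports = list()))
  if (is.null(bank))
    bank <- predict_bank(vol, plan, spec, coeffs, norm, n_sub = n_sub)
  has_dev <- all(c("rx", "ry", "rz", "tx", "ty", "tz") %in% names(conditions))
  rows <- list()
  reports <- vector("list", nrow(conditions))
  for (r in seq_len(nrow(conditions))) {
    cond <- conditions[r, , drop = FALSE]
    seed <- if ("seed" %in% names(cond)) as.integer(cond$seed) else r
    amp <- if ("amplitude" %in% names(cond)) cond$amplitude else 0
    res <- tryCatch({
      old <- save_rng_state()
      set.seed(seed)
      dev <- if (has_dev)
        pose_deviation(angles = c(cond$rx, cond$ry, cond$rz),
                       translation = c(cond$tx, cond$ty, cond$tz))
      else random_pose_deviation(rot_max, trans_max)
      fd <- feed_disturbance(amp, feed_frequency, phase = NULL)
      run <- simulate_run(vol, plan, spec, coeffs, norm, deviation = dev,
                          feed = fd, noise_sigma = noise_sigma, seed = NULL,
                          n_sub = n_sub)
      restore_rng_state(old)
      run_pipeline(run, bank, plan, spec, methods = methods, n2 = n2,
                   t2 = t2, refine_seed = seed)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[length(rows) + 1L]] <- cbind(
        cond, data.frame(method = NA_character_, mean_err = NA_real_,
                         max_err = NA_real_, mean_err_raw = NA_real_,
                         dev_err_dnr = NA_real_, dev_err_dnl = NA_real_,
                         failed = TRUE, message = conditionMessage(res)))
      next
    }
    reports[[r]] <- res
    for (m in methods) {
      rep_m <- res[[m]]$report
      rows[[length(rows) + 1L]] <- cbind(
        cond, data.frame(method = m, mean_err = rep_m$mean_ref,
                         max_err = rep_m$max_ref,
                         mean_err_raw = rep_m$mean_raw,
                         dev_err_dnr = rep_m$dev_err[["dnr"]],
                         dev_err_dnl = rep_m$dev_err[["dnl"]],
                         failed = FALSE, message = ""))
    }
  }
  list(summary = do.call(rbind, rows), reports = reports)
}
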