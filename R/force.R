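#' Mechanistic milling-force coefficients
#'
#' Shear (cutting) and edge (ploughing) coefficients of the Lee-Altintas
#' micro-edge force model, split by dimensional role: shear coefficients
#' multiply the chip cross-section `tn * db` (N/mm^2), edge coefficients the
#' edge-arc length `ds` (N/mm).
#'
#' The defaults are the published bone-grinding calibration this package
#' ships with. That source table names two values "Kte" and none "Krc"; the
#' convention adopted here (configurable) assigns the large-magnitude
#' -1203.1 to the radial shear coefficient `Krc` and keeps -75 and -199.1 as
#' the radial/tangential edge coefficients, matching the usual
#' shear >> edge magnitude ordering.
#'
#' @param Krc,Kac,Ktc Radial/axial/tangential shear coefficients (N/mm^2).
#' @param Kre,Kae,Kte Radial/axial/tangential edge coefficients (N/mm).
#' @return An object of class `force_coefficients`.
#' @export
force_coefficients <- function(Krc = -1203.1, Kac = -105.2, Ktc = 2142.1,
                               Kre = -75, Kae = 22.4, Kte = -199.1) {
  v <- c(Krc = Krc, Kac = Kac, Ktc = Ktc, Kre = Kre, Kae = Kae, Kte = Kte)
  if (any(!is.finite(v))) stop("force coefficients must be finite")
  structure(as.list(v), class = "force_coefficients")
}

coeff_vector <- function(coeffs) {
  unlist(coeffs[c("Krc", "Kac", "Ktc", "Kre", "Kae", "Kte")])
}

#' Micro-edge chip geometry
#'
#' For a micro-edge at axial angle `theta_m` spanning `dtheta`:
#' chip width `db = R dtheta`, edge-arc length
#' `ds = R sqrt(1 + cos^4(theta_m) tan^2(helix)) dtheta` (reducing to
#' `R dtheta` for a straight flute), and undeformed chip thickness
#' `tn = max(0, vt . n / |n|)`, the projection of the feed-per-tooth vector
#' on the outward radial direction of the edge.
#'
#' @param spec A [cutter_spec()].
#' @param theta_m Axial position angle(s), rad.
#' @param dtheta Axial step (rad), default `spec$dtheta`.
#' @param vt_vector Optional feed-per-tooth vector (mm) for `tn`.
#' @param radial Optional centre-to-edge vector(s) (n x 3) matching
#'   `theta_m`.
#' @return Data.frame with columns `db`, `ds` and (when `vt_vector` and
#'   `radial` are given) `tn`, all in mm.
#' @export
chip_geometry <- function(spec, theta_m, dtheta = spec$dtheta,
                          vt_vector = NULL, radial = NULL) {
  stopifnot(inherits(spec, "cutter_spec"))
  db <- spec$radius * dtheta
  ds <- spec$radius * sqrt(1 + cos(theta_m)^4 * tan(spec$helix)^2) * dtheta
  out <- data.frame(db = rep(db, length(theta_m)), ds = ds)
  if (!is.null(vt_vector) && !is.null(radial)) {
    if (is.null(dim(radial))) radial <- matrix(radial, ncol = 3L)
    if (nrow(out) == 1L && nrow(radial) > 1L)
      out <- out[rep(1L, nrow(radial)), , drop = FALSE]
    nrm <- sqrt(rowSums(radial^2))
    out$tn <- pmax(0, as.numeric(radial %*% vt_vector) / nrm)
    rownames(out) <- NULL
  }
  out
}

#' Grayscale-weighted micro-edge force
#'
#' `dF. = lambda^mu (K.c tn db + K.e ds)` for the radial, axial and
#' tangential components; at `lambda^mu = 1` this is the unweighted
#' mechanistic model.
#'
#' @param tn,db,ds Chip thickness, chip width, edge length (mm), vectors.
#' @param lambda Normalized gray in `[0, 1]` at the edge position.
#' @param coeffs A [force_coefficients()].
#' @param mu Power coefficient of the gray weight.
#' @return Matrix (n x 3) with columns `dFr`, `dFa`, `dFt` (N).
#' @export
micro_force <- function(tn, db, ds, lambda, coeffs = force_coefficients(),
                        mu = 1.815) {
  stopifnot(all(lambda >= 0 & lambda <= 1), all(tn >= 0))
  w <- lambda^mu
  cbind(dFr = w * (coeffs$Krc * tn * db + coeffs$Kre * ds),
        dFa = w * (coeffs$Kac * tn * db + coeffs$Kae * ds),
        dFt = w * (coeffs$Ktc * tn * db + coeffs$Kte * ds))
}

#' Rotation of micro-edge force components into the cutter frame
#'
#' The radial/axial/tangential components at a micro-edge are not parallel
#' to the cutter-frame axes; this orthonormal matrix maps
#' `(dFr, dFa, dFt)` to `(dFx, dFy, dFz)` for an edge at axial angle
#' `theta_m` and circumferential angle `phi_m`.
#'
#' @param theta_m,phi_m Edge angles (rad).
#' @return 3 x 3 orthonormal matrix.
#' @export
micro_force_rotation <- function(theta_m, phi_m) {
  ct <- cos(theta_m); st <- sin(theta_m)
  cp <- cos(phi_m); sp <- sin(phi_m)
  matrix(c(-ct * cp, -ct * sp, -st,
           -st * cp, -st * sp, ct,
           sp, -cp, 0), nrow = 3)
}

#' @rdname micro_force_rotation
#' @param dF Matrix (n x 3) of `(dFr, dFa, dFt)` components.
#' @return `rotate_micro_force`: matrix (n x 3) of `(dFx, dFy, dFz)`.
#' @export
rotate_micro_force <- function(dF, theta_m, phi_m) {
  if (is.null(dim(dF))) dF <- matrix(dF, ncol = 3L)
  ct <- cos(theta_m); st <- sin(theta_m)
  cp <- cos(phi_m); sp <- sin(phi_m)
  cbind(dFx = -ct * cp * dF[, 1] - st * cp * dF[, 2] + sp * dF[, 3],
        dFy = -ct * sp * dF[, 1] - st * sp * dF[, 2] - cp * dF[, 3],
        dFz = -st * dF[, 1] + ct * dF[, 2])
}

#' Instantaneous wrench at one pose (reference implementation)
#'
#' Sums the rotated, grayscale-weighted micro-edge forces over the engaged
#' edges at a pose, in the instantaneous (non-spinning) cutter frame, and
#' the torque of the tangential components about the spindle axis. This is
#' the plain-R reference path; production traces use the compiled
#' [milling_force_trace()], and the two are cross-checked in the tests.
#'
#' @param pose A [pose_at()] result.
#' @param edges An [edge_points()] table.
#' @param state A [machined_state()].
#' @param vol A [ct_volume()].
#' @param norm A [norm_params()].
#' @param coeffs A [force_coefficients()].
#' @param spec A [cutter_spec()].
#' @return Named vector `Fx`, `Fy`, `Fz` (N), `Mz` (N mm), `gray_mean`,
#'   `n_engaged`.
#' @export
instantaneous_wrench <- function(pose, edges, state, vol, norm, coeffs,
                                 spec) {
  eng <- engaged_edges(pose, edges, state, spec)
  if (nrow(eng) == 0L)
    return(c(Fx = 0, Fy = 0, Fz = 0, Mz = 0, gray_mean = 0, n_engaged = 0))
  gray <- gray_at(vol, cbind(eng$wx, eng$wy, eng$wz))
  lam <- normalize_gray(gray, norm)
  geom <- chip_geometry(spec, eng$theta_m)
  dF <- micro_force(eng$tn, geom$db, geom$ds, lam, coeffs, norm$mu)
  dFxyz <- rotate_micro_force(dF, eng$theta_m, eng$phi_inst)
  c(Fx = sum(dFxyz[, 1]), Fy = sum(dFxyz[, 2]), Fz = sum(dFxyz[, 3]),
    Mz = sum(spec$radius * cos(eng$theta_m) * dF[, 3]),
    gray_mean = mean(gray), n_engaged = nrow(eng))
}

#' Four-channel force trace along one path
#'
#' Simulates the instantaneous milling wrench at every force-sensor sampling
#' instant while the cutter traverses one planned path, with the machined
#' state implied by the execution order, an optional rigid workspace
#' deviation and an optional sinusoidal feed-rate disturbance. Each sample
#' is the average over `n_sub` spindle-phase substeps spanning one flute
#' period (the force sensor's effective bandwidth is far below the
#' tooth-passing frequency). Timestamps are sample-centred:
#' `t_s = (s - 1/2) / fs`.
#'
#' @param vol A [ct_volume()].
#' @param plan A [milling_plan()].
#' @param spec A [cutter_spec()].
#' @param coeffs A [force_coefficients()].
#' @param norm A [norm_params()].
#' @param layer,path Path to execute.
#' @param deviation A [pose_deviation()].
#' @param feed A [feed_disturbance()] (default: none).
#' @param phase Initial cutter phase (rad).
#' @param n_sub Spindle-phase substeps per sample.
#' @return Data.frame with `t`, `Fx`, `Fy`, `Fz`, `Mz`, `gray_mean`,
#'   `n_engaged`, one row per sample (`plan$samples_per_path` rows).
#' @export
milling_force_trace <- function(vol, plan, spec, coeffs, norm, layer, path,
                                deviation = pose_deviation(),
                                feed = feed_disturbance(0), phase = 0,
                                n_sub = 8) {
  stopifnot(inherits(vol, "ct_volume"), inherits(plan, "milling_plan"),
            inherits(spec, "cutter_spec"))
  paths <- plan_paths(plan)
  p <- paths[paths$layer == layer & paths$path == path, ]
  if (nrow(p) != 1L) stop("no such (layer, path) in the plan")
  st <- machined_state(plan, spec, vol, p$ord)
  n <- plan$samples_per_path
  t <- (seq_len(n) - 0.5) / plan$fs
  fp <- feed_profile(feed, plan$feed, t)
  edges <- edge_points(spec)
  # feed sign encodes the traversal direction; the engagement test keeps
  # only edges advancing into material either way
  origin_path <- c(if (p$dir > 0) p$x0 else p$x1, p$y, p$z_tip + spec$radius)
  tr <- .force_trace_cpp(
    t, p$dir * fp$offset, p$dir * fp$rate,
    2 * pi * plan$spin / 60, phase, as.integer(n_sub), spec$flutes,
    as.matrix(cbind(edges$theta_m, edges$phi_m,
                    chip_geometry(spec, edges$theta_m)[, c("db", "ds")])),
    spec$radius, plan$incline, origin_path,
    st$priors, st$stock_lo, st$stock_hi,
    deviation$R, deviation$translation, plan$origin,
    as.numeric(vol$data), dim(vol$data), vol$spacing, vol$origin,
    norm$mmin, norm$mmax, norm$mu, coeff_vector(coeffs),
    60 / (spec$flutes * plan$spin))
  out <- data.frame(t = t, Fx = tr[, 1], Fy = tr[, 2], Fz = tr[, 3],
                    Mz = tr[, 4], gray_mean = tr[, 5], n_engaged = tr[, 6])
  out
}

#' Prediction bank: per-grid force template sequences
#'
#' Runs the nominal (deviation-free, constant-feed, zero-phase) plan through
#' the CT image-force model, slices every path's four-channel trace into
#' consecutive length-`ns` grid sequences and attaches each grid's landmark
#' position. The bank is the pre-operative template library the estimator
#' matches intra-operative segments against.
#'
#' @inheritParams milling_force_trace
#' @param n_sub Spindle-phase substeps per sample.
#' @return Object of class `prediction_bank`: `seq` (array
#'   `ns x 4 x n_entries`, channels Fx, Fy, Fz, Mz, entries sorted
#'   lexicographically by (i, j, k)), `index` (the [grid_landmarks()]
#'   table), `gray` (per-grid mean gray), `ns`, `fs`, `channels`, `plan`,
#'   `spec`, `norm`, `coeffs`.
#' @export
predict_bank <- function(vol, plan, spec, coeffs = force_coefficients(),
                         norm = norm_params(), n_sub = 8) {
  landmarks <- grid_landmarks(plan)
  paths <- plan_paths(plan)
  ns <- plan$ns
  n_entries <- nrow(landmarks)
  bank <- array(0, dim = c(ns, 4L, n_entries))
  gray <- numeric(n_entries)
  channels <- c("Fx", "Fy", "Fz", "Mz")
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    tr <- milling_force_trace(vol, plan, spec, coeffs, norm, p$layer,
                              p$path, n_sub = n_sub)
    for (k in seq_len(plan$grids_per_path)) {
      rows <- ((k - 1) * ns + 1):(k * ns)
      e <- landmarks$entry[landmarks$i == p$layer & landmarks$j == p$path &
                             landmarks$k == k]
      bank[, , e] <- as.matrix(tr[rows, channels])
      gray[e] <- mean(tr$gray_mean[rows])
    }
  }
  structure(list(seq = bank, index = landmarks, gray = gray, ns = ns,
                 fs = plan$fs, channels = channels, plan = plan, spec = spec,
                 norm = norm, coeffs = coeffs),
            class = "prediction_bank")
}

#' @export
print.prediction_bank <- function(x, ...) {
  cat("<prediction_bank> ", dim(x$seq)[3], " grid sequences (ns = ", x$ns,
      ", ", length(x$channels), " channels) over ", x$plan$n_layers,
      " layers x ", x$plan$n_paths, " paths\n", sep = "")
  invisible(x)
}
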