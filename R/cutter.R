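#' Ball-end cutter specification
#'
#' Geometry of a helical-flute ball-end cutter. Cutting edges wind over the
#' hemispherical tip; the edge of flute `f` at axial position angle
#' `theta_m` sits at circumferential angle
#' `phi_m = phi0_f - sin(theta_m) * tan(helix)` (the lag law used throughout),
#' and edges exist for `theta_m` in `[0, acos(tip_offset / radius)]` because
#' the edges stop `tip_offset` mm short of the tool centre at the apex.
#'
#' @param radius Ball radius R (mm).
#' @param flutes Number of flutes n (>= 1); flute start angles are spaced
#'   evenly over the circumference.
#' @param helix_deg Helix angle beta_G (degrees).
#' @param tip_offset Edge-to-centre distance h at the apex (mm),
#'   `0 < tip_offset < radius`.
#' @param dtheta_deg Axial discretization step d(theta_m) (degrees),
#'   in (0, 90).
#' @return An object of class `cutter_spec`.
#' @export
cutter_spec <- function(radius = 2, flutes = 4, helix_deg = 30,
                        tip_offset = 0.25, dtheta_deg = 4) {
  stopifnot(radius > 0, flutes >= 1, dtheta_deg > 0, dtheta_deg < 90)
  if (tip_offset <= 0 || tip_offset >= radius)
    stop("`tip_offset` must lie strictly between 0 and `radius`")
  structure(list(radius = radius, flutes = as.integer(flutes),
                 helix = helix_deg * pi / 180,
                 tip_offset = tip_offset, dtheta = dtheta_deg * pi / 180,
                 theta_max = acos(tip_offset / radius)),
            class = "cutter_spec")
}

#' @export
print.cutter_spec <- function(x, ...) {
  cat("<cutter_spec> R = ", x$radius, " mm, ", x$flutes, " flutes, helix ",
      round(x$helix * 180 / pi, 2), " deg, h = ", x$tip_offset,
      " mm, dtheta = ", round(x$dtheta * 180 / pi, 2), " deg\n", sep = "")
  invisible(x)
}

#' Position of a micro-edge on the ball end (MCCS)
#'
#' Evaluates the edge position at axial angle `theta_m` for a flute starting
#' at `phi0`: `(R cos(th) cos(phi_m), R cos(th) sin(phi_m), -R sin(th))`
#' with `phi_m = phi0 - sin(th) tan(helix)`. All returned points lie on the
#' sphere of radius R.
#'
#' @param spec A [cutter_spec()].
#' @param theta_m Axial position angle(s), rad.
#' @param phi0 Circumferential start angle of the flute, rad.
#' @return Matrix (n x 3) of MCCS positions in mm.
#' @export
edge_position <- function(spec, theta_m, phi0 = 0) {
  stopifnot(inherits(spec, "cutter_spec"))
  phi_m <- phi0 - sin(theta_m) * tan(spec$helix)
  cbind(x = spec$radius * cos(theta_m) * cos(phi_m),
        y = spec$radius * cos(theta_m) * sin(phi_m),
        z = -spec$radius * sin(theta_m))
}

#' Discretized micro-edge table
#'
#' Samples every flute's cutting edge at the midpoints of consecutive
#' `dtheta` bins over `[0, acos(h/R)]` (midpoint quadrature for the force
#' summation). `phase` adds a common offset to all flute start angles (the
#' random initial phase of the cutter).
#'
#' @param spec A [cutter_spec()].
#' @param phase Common circumferential offset added to every flute (rad).
#' @return Data.frame with one row per micro-edge: `flute`, `theta_m`,
#'   `phi0`, `phi_m` (lag included, zero spin), MCCS position `x`, `y`, `z`.
#' @export
edge_points <- function(spec, phase = 0) {
  stopifnot(inherits(spec, "cutter_spec"))
  n_bins <- floor(spec$theta_max / spec$dtheta + 1e-12)
  theta <- (seq_len(n_bins) - 0.5) * spec$dtheta
  out <- do.call(rbind, lapply(seq_len(spec$flutes), function(f) {
    phi0 <- (f - 1) * 2 * pi / spec$flutes + phase
    pos <- edge_position(spec, theta, phi0)
    data.frame(flute = f, theta_m = theta, phi0 = phi0,
               phi_m = phi0 - sin(theta) * tan(spec$helix),
               x = pos[, 1], y = pos[, 2], z = pos[, 3])
  }))
  rownames(out) <- NULL
  out
}

#' Feed per tooth
#'
#' `vt = 60 * vd / (n * N)`: the advance of the cutter per cutting edge at
#' feed `vd` (mm/s), `n` flutes and spindle speed `N` (RPM).
#'
#' @param vd Feed rate (mm/s).
#' @param n Number of flutes.
#' @param N Spindle speed (RPM).
#' @return Feed per tooth (mm).
#' @export
feed_per_tooth <- function(vd, n, N) {
  if (n * N <= 0) stop("`n * N` must be positive (spindle not turning)")
  60 * vd / (n * N)
}

#' Phase-insensitivity condition
#'
#' The initial cutter phase can be ignored when the feed per tooth is much
#' smaller than the voxel size, i.e. the cutter spins many times while
#' traversing one voxel. Returns the ratio `feed_per_tooth / voxel_mm` and
#' whether it passes the (configurable) smallness threshold.
#'
#' @param vd,n,N As in [feed_per_tooth()].
#' @param voxel_mm In-plane voxel size (mm).
#' @param threshold Pass threshold on the ratio (default 0.1; the condition
#'   is qualitative, "much smaller").
#' @return List with `ratio` and logical `pass`.
#' @export
check_phase_condition <- function(vd, n, N, voxel_mm, threshold = 0.1) {
  ratio <- feed_per_tooth(vd, n, N) / voxel_mm
  list(ratio = ratio, pass = ratio < threshold)
}

#' Rigid pose deviation of the executed workspace
#'
#' A small rigid transform of the executed workspace relative to the plan:
#' rotation (three small angles about x, y, z, applied about the workspace
#' origin) followed by a translation.
#'
#' @param angles Rotation angles (rad), length 3.
#' @param translation Translation (mm), length 3.
#' @return An object of class `pose_deviation` with the rotation matrix `R`,
#'   `angles`, `translation` and the total rotation magnitude
#'   `incline_deg` (degrees).
#' @export
pose_deviation <- function(angles = c(0, 0, 0), translation = c(0, 0, 0)) {
  angles <- as.numeric(angles); translation <- as.numeric(translation)
  stopifnot(length(angles) == 3L, length(translation) == 3L,
            all(is.finite(angles)), all(is.finite(translation)))
  R <- rot_x(angles[1]) %*% rot_y(angles[2]) %*% rot_z(angles[3])
  structure(list(R = R, angles = angles, translation = translation,
                 incline_deg = sqrt(sum(angles^2)) * 180 / pi),
            class = "pose_deviation")
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)

# apply a pose deviation about the workspace origin: p = R (q - o) + o + t
apply_deviation <- function(points, deviation, ws_origin) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  shifted <- sweep(points, 2L, ws_origin, "-")
  out <- shifted %*% t(deviation$R)
  sweep(out, 2L, ws_origin + deviation$translation, "+")
}

#' Tool pose during a path traversal
#'
#' Chains the four coordinate frames: spin and feed in the instantaneous
#' cutter frame, the incline rotation about x into the path-local frame, the
#' path origin into the WCS, and (optionally) a rigid workspace deviation.
#' Returns homogeneous transforms mapping cutter-frame (MCCS) coordinates to
#' the nominal and to the deviated WCS.
#'
#' @param t Time since the start of the path traversal (s); must lie within
#'   `[0, path_length / feed]`.
#' @param plan A [milling_plan()].
#' @param layer,path Which planned path is being executed.
#' @param spec A [cutter_spec()] (for the ball-centre height above the tip
#'   line).
#' @param deviation A [pose_deviation()] (identity by default).
#' @param phase Initial cutter phase (rad).
#' @param feed_offset,feed_rate Optional overrides for the centre offset
#'   along the path (mm) and instantaneous feed rate (mm/s) at time `t`
#'   (used under a feed-rate disturbance); defaults are the constant-feed
#'   values `feed * t` and `feed`.
#' @return List of class `tool_pose`: `t`, `spin_phase`, `omega`,
#'   `feed_offset`, `vt` (feed per tooth, mm), `incline`, `T_nom`, `T_act`
#'   (4 x 4), `centre_nom`, `centre_act`, `feed_dir_act`.
#' @export
pose_at <- function(t, plan, layer, path, spec, deviation = pose_deviation(),
                    phase = 0, feed_offset = NULL, feed_rate = NULL) {
  stopifnot(inherits(plan, "milling_plan"), inherits(spec, "cutter_spec"))
  t_end <- plan$path_length / plan$feed
  if (t < 0 || t > t_end + 1e-9)
    stop("`t` outside the path traversal interval [0, ", t_end, "] s")
  if (is.null(feed_offset)) feed_offset <- plan$feed * t
  if (is.null(feed_rate)) feed_rate <- plan$feed
  paths <- plan_paths(plan)
  p <- paths[paths$layer == layer & paths$path == path, ]
  if (nrow(p) != 1L) stop("no such (layer, path) in the plan")
  omega <- 2 * pi * plan$spin / 60
  spin_phase <- omega * t + phase
  # centre of the ball at the start of the path
  origin_path <- c(if (p$dir > 0) p$x0 else p$x1, p$y, p$z_tip + spec$radius)
  Om <- rbind(cbind(rot_z(spin_phase), c(p$dir * feed_offset, 0, 0)),
              c(0, 0, 0, 1))
  Tl <- rbind(cbind(rot_x(plan$incline), origin_path), c(0, 0, 0, 1))
  T_nom <- Tl %*% Om
  D <- rbind(cbind(deviation$R,
                   plan$origin + deviation$translation -
                     deviation$R %*% plan$origin), c(0, 0, 0, 1))
  T_act <- D %*% T_nom
  centre_nom <- T_nom[1:3, 4]
  centre_act <- T_act[1:3, 4]
  feed_dir <- deviation$R %*% rot_x(plan$incline) %*% c(p$dir, 0, 0)
  structure(list(t = t, spin_phase = spin_phase, omega = omega,
                 feed_offset = feed_offset, feed_rate = feed_rate,
                 vt = feed_per_tooth(feed_rate, spec$flutes, plan$spin),
                 incline = plan$incline, layer = layer, path = path,
                 dir = p$dir, T_nom = T_nom, T_act = T_act,
                 centre_nom = centre_nom, centre_act = centre_act,
                 feed_dir_act = as.numeric(feed_dir)),
            class = "tool_pose")
}
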