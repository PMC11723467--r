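#' Perpendicular distance from points to a 3-D line
#'
#' `|(P - P0) x v0|` for a unit direction `v0`; invariant to sliding `P0`
#' along the line.
#'
#' @param points Matrix (n x 3) or a single 3-vector.
#' @param p0 A point on the line (mm).
#' @param v0 Line direction (normalized internally).
#' @return Non-negative distances (mm).
#' @export
point_line_residual <- function(points, p0, v0) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  v0 <- v0 / sqrt(sum(v0^2))
  d <- sweep(points, 2L, p0, "-")
  cx <- d[, 2] * v0[3] - d[, 3] * v0[2]
  cy <- d[, 3] * v0[1] - d[, 1] * v0[3]
  cz <- d[, 1] * v0[2] - d[, 2] * v0[1]
  sqrt(cx^2 + cy^2 + cz^2)
}

#' RANSAC 3-D line fit to matched tip positions
#'
#' Hypothesize-and-verify line fitting: `k1` random two-point hypotheses,
#' inliers within perpendicular distance `t1`, best hypothesis by inlier
#' count (ties by smaller mean inlier residual), optionally refit by total
#' least squares (principal axis) over the best inlier set. Coincident
#' sample pairs are skipped. Deterministic for a fixed seed.
#'
#' @param points Matrix (n x 3) of matched tip positions (mm), n >= 2 with
#'   at least two distinct rows.
#' @param n1 Minimum sample size (2 for a line).
#' @param k1 Number of hypotheses.
#' @param t1 Inlier threshold (mm).
#' @param seed Optional integer seed.
#' @param refit Refit the line to all inliers by least squares.
#' @return List of class `fitted_line`: `p0`, `v0` (unit), `inliers`
#'   (logical), `n_inliers`, `residuals`, `mean_residual`.
#' @export
fit_path_line <- function(points, n1 = 2, k1 = 2000, t1 = 1.0, seed = NULL,
                          refit = TRUE) {
  points <- as.matrix(points)
  if (nrow(points) < n1 || nrow(unique(points)) < 2L)
    stop("degenerate input: need at least two distinct points")
  if (!is.null(seed)) {
    old <- save_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  n <- nrow(points)
  i1 <- sample.int(n, k1, replace = TRUE)
  i2 <- sample.int(n, k1, replace = TRUE)
  dirs <- points[i2, , drop = FALSE] - points[i1, , drop = FALSE]
  len <- sqrt(rowSums(dirs^2))
  ok <- len > 1e-12
  if (!any(ok)) stop("degenerate input: all sampled pairs coincide")
  dirs <- dirs[ok, , drop = FALSE] / len[ok]
  p0s <- points[i1[ok], , drop = FALSE]
  # residual matrix: hypotheses x points, via the cross-product norm
  dx <- outer(p0s[, 1], points[, 1], function(a, b) b - a)
  dy <- outer(p0s[, 2], points[, 2], function(a, b) b - a)
  dz <- outer(p0s[, 3], points[, 3], function(a, b) b - a)
  cx <- dy * dirs[, 3] - dz * dirs[, 2]
  cy <- dz * dirs[, 1] - dx * dirs[, 3]
  cz <- dx * dirs[, 2] - dy * dirs[, 1]
  res <- sqrt(cx^2 + cy^2 + cz^2)
  inl <- res < t1
  counts <- rowSums(inl)
  mres <- rowSums(res * inl) / pmax(counts, 1L)
  best <- order(-counts, mres)[1]
  inliers <- inl[best, ]
  p0 <- p0s[best, ]
  v0 <- dirs[best, ]
  if (refit && sum(inliers) >= 2L) {
    sub <- points[inliers, , drop = FALSE]
    p0 <- colMeans(sub)
    sv <- svd(sweep(sub, 2L, p0, "-"))
    v0 <- sv$v[, 1]
  }
  if (v0[which.max(abs(v0))] < 0) v0 <- -v0
  r <- point_line_residual(points, p0, v0)
  structure(list(p0 = as.numeric(p0), v0 = as.numeric(v0),
                 inliers = inliers, n_inliers = sum(inliers),
                 residuals = r, mean_residual = mean(r[inliers])),
            class = "fitted_line")
}

# y/z coordinates of a line at the plane x = x_at; if the line is nearly
# perpendicular to x the anchor point's y/z is used instead
line_yz_at <- function(line, x_at) {
  if (abs(line$v0[1]) < 0.1) return(line$p0[2:3])
  s <- (x_at - line$p0[1]) / line$v0[1]
  (line$p0 + s * line$v0)[2:3]
}

#' RANSAC estimate of the workspace deviation
#'
#' Given per-path fitted line positions and their planned counterparts,
#' estimates the rigid workspace offsets `dnr` (y, step direction) and
#' `dnl` (z, depth direction) under the constant-deviation model: per
#' iteration a sample of `n2` paths fixes `(dnr, dnl)` as the mean y/z
#' differences, inliers are the paths whose residual
#' `sqrt((Ry - ry - dnr)^2 + (Lz - lz - dnl)^2)` stays below `t2`, and the
#' best model (most inliers, ties by smaller mean residual) is recomputed
#' over its inlier set.
#'
#' @param path_pos Data.frame with one row per fitted path: `Ry`, `Lz`
#'   (fitted line y/z at the path midpoint) and `ry`, `lz` (planned y/z).
#' @param n2 Sample size per iteration (BestNum); at most the number of
#'   paths, otherwise an insufficient-data error is raised.
#' @param k2 Number of iterations.
#' @param t2 Inlier threshold (mm).
#' @param seed Optional integer seed.
#' @return List of class `deviation_estimate`: `dnr`, `dnl` (mm),
#'   `inliers`, `n_inliers`, `residuals`, `depth_offset` (= `dnl`, the
#'   milling-depth correction to the planned layer depth).
#' @export
estimate_deviation <- function(path_pos, n2 = 30, k2 = 2000, t2 = 1.0,
                               seed = NULL) {
  need <- c("Ry", "Lz", "ry", "lz")
  stopifnot(all(need %in% names(path_pos)))
  m <- nrow(path_pos)
  if (m < n2)
    stop("insufficient data: ", m, " fitted paths but BestNum n2 = ", n2)
  if (!is.null(seed)) {
    old <- save_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  dy <- path_pos$Ry - path_pos$ry
  dz <- path_pos$Lz - path_pos$lz
  samp <- matrix(0L, k2, n2)
  for (it in seq_len(k2)) samp[it, ] <- sample.int(m, n2)
  dnr <- rowMeans(matrix(dy[samp], k2, n2))
  dnl <- rowMeans(matrix(dz[samp], k2, n2))
  res <- sqrt(outer(dnr, dy, function(a, b) (b - a)^2) +
                outer(dnl, dz, function(a, b) (b - a)^2))
  inl <- res < t2
  counts <- rowSums(inl)
  mres <- rowSums(res * inl) / pmax(counts, 1L)
  best <- order(-counts, mres)[1]
  inliers <- inl[best, ]
  if (sum(inliers) >= 1L) {
    dnr_hat <- mean(dy[inliers]); dnl_hat <- mean(dz[inliers])
  } else {
    dnr_hat <- dnr[best]; dnl_hat <- dnl[best]
  }
  structure(list(dnr = dnr_hat, dnl = dnl_hat, inliers = inliers,
                 n_inliers = sum(inliers),
                 residuals = sqrt((dy - dnr_hat)^2 + (dz - dnl_hat)^2),
                 depth_offset = dnl_hat),
            class = "deviation_estimate")
}

#' Refine a matched track with the RANSAC stages
#'
#' Fits a 3-D line to every executed path's matched tip positions,
#' reads each line's y/z at the path midpoint, estimates the workspace
#' deviation `(dnr, dnl)` from the fitted-vs-planned differences, and
#' produces refined per-segment estimates: the point on the
#' deviation-corrected current path (planned y/z shifted by the estimated
#' `(dnr, dnl)`) at the window's scheduled along-path position. The
#' along-path deviation itself is not estimated: a line's y/z offsets are
#' observable from its geometry, its x registration is not.
#'
#' @param track An [estimate_track()] result.
#' @param plan The executed [milling_plan()].
#' @param n1,k1,t1 Line-fit RANSAC parameters ([fit_path_line()]).
#' @param n2,k2,t2 Deviation RANSAC parameters ([estimate_deviation()]).
#' @param seed Optional integer seed (drives both stages).
#' @param min_signal Air-cutting gate (N): segments whose mean force
#'   magnitude is below this carry no localization information (the cutter
#'   is not engaged) and are excluded from the fitting stages; paths left
#'   with fewer than two gated segments contribute no line.
#' @return List of class `refined_track`: `track` (with `x_ref`, `y_ref`,
#'   `z_ref` columns), `lines` (per-path [fit_path_line()] results),
#'   `path_pos` (the Ry/Lz/ry/lz table), `deviation`
#'   (an [estimate_deviation()] result).
#' @export
refine_track <- function(track, plan, n1 = 2, k1 = 2000, t1 = 1.0,
                         n2 = 30, k2 = 2000, t2 = 1.0, seed = NULL,
                         min_signal = 0.5) {
  paths <- plan_paths(plan)
  if (!is.null(seed)) {
    old <- save_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  cutting <- if ("seg_rms" %in% names(track)) track$seg_rms >= min_signal
             else rep(TRUE, nrow(track))
  lines <- vector("list", nrow(paths))
  pos <- vector("list", nrow(paths))
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    pts <- as.matrix(track[track$ord == p$ord & cutting,
                           c("x", "y", "z"), drop = FALSE])
    fit <- tryCatch(fit_path_line(pts, n1 = n1, k1 = k1, t1 = t1),
                    error = function(e) NULL)
    lines[[r]] <- fit
    if (is.null(fit)) next
    yz <- line_yz_at(fit, (p$x0 + p$x1) / 2)
    pos[[r]] <- data.frame(ord = p$ord, Ry = yz[1], Lz = yz[2],
                           ry = p$y, lz = p$z_tip)
  }
  path_pos <- do.call(rbind, pos)
  if (is.null(path_pos) || nrow(path_pos) == 0L)
    stop("no executed path yielded a line fit")
  dev <- estimate_deviation(path_pos, n2 = n2, k2 = k2, t2 = t2)
  idx <- match(track$ord, paths$ord)
  # refined estimate: the point on the deviation-corrected current path at
  # the window's scheduled along-path position (the along-path deviation is
  # not estimated; the step/depth offsets come from the deviation stage)
  track$x_ref <- if ("x_sched" %in% names(track)) track$x_sched else track$x
  track$y_ref <- paths$y[idx] + dev$dnr
  track$z_ref <- paths$z_tip[idx] + dev$dnl
  structure(list(track = track, lines = lines, path_pos = path_pos,
                 deviation = dev), class = "refined_track")
}
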