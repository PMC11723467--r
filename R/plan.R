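#' Layer-by-layer milling plan
#'
#' Describes the rectangular milling workspace: `n_layers` horizontal layers,
#' each removed by `n_paths` parallel straight paths along +x, separated by
#' `step` mm along y, with the layer-i tip line sitting `i * depth` mm below
#' the initial top surface. The workpiece coordinate system is right-handed:
#' x is the feed direction, y the step direction, z points out of the bone.
#' Paths are executed layer-major in increasing path order; grid `k` of a
#' path is the k-th tumbling-window cell of physical length
#' `l = feed * ns / fs` mm, so a force sequence of length `ns` corresponds to
#' exactly one grid.
#'
#' @param n_layers,n_paths Number of milling layers and paths per layer.
#' @param path_length Length of each path (mm).
#' @param depth Per-layer milling depth d (mm).
#' @param step Path step distance w along y (mm).
#' @param feed Nominal feed rate vd (mm/s).
#' @param spin Spindle speed N (RPM).
#' @param incline_deg Cutter incline angle delta_m (degrees).
#' @param origin Workspace origin in WCS (mm): the start of the first path,
#'   with the z component at the initial (uncut) top surface.
#' @param ns Force-sequence (grid) length in samples.
#' @param fs Force sampling frequency (Hz).
#' @param direction `"unidirectional"` (all paths along +x, the default) or
#'   `"bidirectional"` (alternate +x / -x within a layer).
#' @return An object of class `milling_plan`.
#' @export
milling_plan <- function(n_layers = 3, n_paths = 4, path_length = 12,
                         depth = 0.8, step = 2.8, feed = 0.5, spin = 800,
                         incline_deg = 30, origin = c(0, 0, 0), ns = 15,
                         fs = 20, direction = c("unidirectional",
                                                "bidirectional")) {
  direction <- match.arg(direction)
  stopifnot(n_layers >= 1, n_paths >= 1, path_length > 0, depth > 0,
            step > 0, feed > 0, spin > 0, ns >= 2, fs > 0)
  l <- feed * ns / fs
  grids_per_path <- floor(path_length / l + 1e-9)
  if (grids_per_path < 1)
    stop("path shorter than one grid (l = ", l, " mm)")
  samples_per_path <- grids_per_path * ns
  plan <- structure(list(
    n_layers = as.integer(n_layers), n_paths = as.integer(n_paths),
    path_length = path_length, depth = depth, step = step, feed = feed,
    spin = spin, incline = incline_deg * pi / 180, origin = as.numeric(origin),
    ns = as.integer(ns), fs = fs, grid_length = l,
    grids_per_path = as.integer(grids_per_path),
    samples_per_path = as.integer(samples_per_path),
    direction = direction), class = "milling_plan")
  plan
}

#' @export
print.milling_plan <- function(x, ...) {
  cat("<milling_plan> ", x$n_layers, " layers x ", x$n_paths, " paths, ",
      "path ", x$path_length, " mm, d = ", x$depth, " mm, w = ", x$step,
      " mm\n  feed ", x$feed, " mm/s, spin ", x$spin, " RPM, grid l = ",
      x$grid_length, " mm (", x$grids_per_path, " grids/path)\n", sep = "")
  invisible(x)
}

#' Build a milling plan from a configuration list or YAML file
#'
#' Accepts either a named list or the path to a YAML file with the
#' [milling_plan()] argument names. If `vol` is supplied, the planned
#' workspace (inflated by `margin` mm, typically the cutter radius) is
#' checked to lie inside the volume.
#'
#' @param config Named list or YAML file path.
#' @param vol Optional [ct_volume()] for bounds validation.
#' @param margin Safety margin in mm added around the workspace for the check.
#' @return A [milling_plan()].
#' @export
build_plan <- function(config, vol = NULL, margin = 0) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  keep <- intersect(names(config), names(formals(milling_plan)))
  plan <- do.call(milling_plan, config[keep])
  if (!is.null(vol)) {
    b <- volume_bounds(vol)
    lo <- c(plan$origin[1], plan$origin[2], plan$origin[3] -
              plan$n_layers * plan$depth)
    hi <- c(plan$origin[1] + plan$path_length,
            plan$origin[2] + (plan$n_paths - 1) * plan$step, plan$origin[3])
    if (any(lo - margin < b$lo) || any(hi + margin > b$hi))
      stop("invalid plan: workspace (with ", margin,
           " mm margin) exceeds the volume bounds")
  }
  plan
}

#' Planned path table
#'
#' One row per path in execution order (layer-major): start/end x of the tip
#' line, path y, tip-line z, and traversal direction (+1 along +x).
#'
#' @param plan A [milling_plan()].
#' @return A data.frame with columns `ord`, `layer`, `path`, `x0`, `x1`,
#'   `y`, `z_tip`, `dir`.
#' @export
plan_paths <- function(plan) {
  stopifnot(inherits(plan, "milling_plan"))
  g <- expand.grid(path = seq_len(plan$n_paths), layer = seq_len(plan$n_layers))
  dir <- rep(1, nrow(g))
  if (plan$direction == "bidirectional") dir <- ifelse(g$path %% 2 == 1, 1, -1)
  data.frame(ord = seq_len(nrow(g)), layer = g$layer, path = g$path,
             x0 = plan$origin[1], x1 = plan$origin[1] + plan$path_length,
             y = plan$origin[2] + (g$path - 1) * plan$step,
             z_tip = plan$origin[3] - g$layer * plan$depth, dir = dir)
}

#' Grid landmark positions
#'
#' The landmark of grid (i, j, k) is the midpoint of the grid's centreline
#' on the planned tip line: the position the estimator reports when that
#' grid's prediction sequence is matched.
#'
#' @param plan A [milling_plan()].
#' @return Data.frame with `entry`, `i`, `j`, `k`, `ord`, `x`, `y`, `z`,
#'   sorted lexicographically by (i, j, k).
#' @export
grid_landmarks <- function(plan) {
  paths <- plan_paths(plan)
  k <- seq_len(plan$grids_per_path)
  out <- do.call(rbind, lapply(seq_len(nrow(paths)), function(r) {
    p <- paths[r, ]
    xs <- if (p$dir > 0) p$x0 + (k - 0.5) * plan$grid_length
          else p$x1 - (k - 0.5) * plan$grid_length
    data.frame(i = p$layer, j = p$path, k = k, ord = p$ord, x = xs,
               y = p$y, z = p$z_tip)
  }))
  out <- out[order(out$i, out$j, out$k), ]
  out$entry <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("entry", "i", "j", "k", "ord", "x", "y", "z")]
}

#' Gray values along one grid's centreline
#'
#' Returns the ordered gray values of the voxels traversed by the grid's
#' centreline segment (nearest-voxel lookup at the tip line, one value per
#' voxel crossed).
#'
#' @param vol A [ct_volume()].
#' @param plan A [milling_plan()].
#' @param i,j,k Layer, path and grid ordinals (1-based).
#' @return Numeric vector of gray values (length >= 1).
#' @export
extract_grid_grays <- function(vol, plan, i, j, k) {
  stopifnot(inherits(vol, "ct_volume"), inherits(plan, "milling_plan"))
  if (i < 1 || i > plan$n_layers || j < 1 || j > plan$n_paths ||
      k < 1 || k > plan$grids_per_path)
    stop("grid index out of plan bounds")
  paths <- plan_paths(plan)
  p <- paths[paths$layer == i & paths$path == j, ]
  l <- plan$grid_length
  xa <- if (p$dir > 0) p$x0 + (k - 1) * l else p$x1 - (k - 1) * l
  xb <- xa + p$dir * l
  # sample the segment finely, then keep one value per voxel crossed
  nstep <- max(2L, ceiling(abs(xb - xa) / (min(vol$spacing) / 4)))
  xs <- seq(xa + p$dir * 1e-9, xb - p$dir * 1e-9, length.out = nstep)
  pts <- cbind(xs, p$y, p$z_tip)
  b <- volume_bounds(vol)
  if (any(pts[, 1] < b$lo[1] | pts[, 1] > b$hi[1]) ||
      p$y < b$lo[2] || p$y > b$hi[2] ||
      p$z_tip < b$lo[3] || p$z_tip > b$hi[3])
    stop("grid centreline lies outside the volume")
  vox <- floor(sweep(sweep(pts, 2L, vol$origin, "-"), 2L, vol$spacing, "/"))
  changed <- c(TRUE, rowSums(abs(diff(vox))) > 0)
  gray_at(vol, pts[changed, , drop = FALSE])
}
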