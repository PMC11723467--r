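#' Classify the cutter-workpiece engagement case of a path
#'
#' The layer-by-layer policy produces five qualitatively different
#' engagement regions, depending on whether the path is the first of its
#' layer and whether the layer is the top one:
#' \describe{
#'   \item{a}{first path, top layer (virgin stock)}
#'   \item{b}{later path, top layer (one side opened by the previous path)}
#'   \item{c}{first path, lower layer (floor left by the layer above)}
#'   \item{d}{middle path, lower layer}
#'   \item{e}{last path, lower layer}
#' }
#'
#' @param i Layer ordinal (1 = top).
#' @param j Path ordinal within the layer.
#' @param n_paths Paths per layer.
#' @return One of `"a"`..`"e"`.
#' @export
classify_cwe_case <- function(i, j, n_paths) {
  stopifnot(i >= 1, j >= 1, j <= n_paths)
  if (i == 1) {
    if (j == 1) "a" else "b"
  } else if (j == 1) "c"
  else if (j == n_paths) "e"
  else "d"
}

#' Machined state before executing a path
#'
#' Captures everything the engagement test needs: the stock box (the CT
#' volume's bounding box, capped above by the plan's initial top surface)
#' and the swept volumes of all previously completed paths in execution
#' order. Each completed path sweeps a ball of radius R along its centre
#' line: a cylinder with spherical end caps.
#'
#' @param plan A [milling_plan()].
#' @param spec A [cutter_spec()].
#' @param vol A [ct_volume()] defining the stock extent.
#' @param ord Execution ordinal of the path about to be milled (its
#'   predecessors `1..ord-1` are complete); `plan$n_layers * plan$n_paths +
#'   1` describes the fully machined part.
#' @return List of class `machined_state`: `stock_lo`, `stock_hi`,
#'   `priors` (matrix with columns `y`, `zc`, `x0`, `x1`, one row per
#'   completed path), `layer`, `path`, `case`.
#' @export
machined_state <- function(plan, spec, vol, ord) {
  stopifnot(inherits(plan, "milling_plan"), inherits(spec, "cutter_spec"),
            inherits(vol, "ct_volume"))
  paths <- plan_paths(plan)
  n_total <- nrow(paths)
  if (ord < 1 || ord > n_total + 1) stop("`ord` out of range")
  b <- volume_bounds(vol)
  stock_hi <- c(b$hi[1], b$hi[2], min(b$hi[3], plan$origin[3]))
  done <- paths[paths$ord < ord, , drop = FALSE]
  priors <- cbind(y = done$y, zc = done$z_tip + spec$radius,
                  x0 = done$x0, x1 = done$x1)
  cur <- if (ord <= n_total) paths[paths$ord == ord, ] else NULL
  structure(list(stock_lo = b$lo, stock_hi = stock_hi, priors = priors,
                 layer = cur$layer, path = cur$path,
                 case = if (!is.null(cur))
                   classify_cwe_case(cur$layer, cur$path, plan$n_paths)),
            class = "machined_state")
}

# TRUE for points inside the union of the completed paths' swept volumes
removed_by_priors <- function(points, priors, radius) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  out <- rep(FALSE, nrow(points))
  if (is.null(priors) || nrow(priors) == 0L) return(out)
  R2 <- radius^2
  for (r in seq_len(nrow(priors))) {
    dy <- points[, 2] - priors[r, "y"]
    dz <- points[, 3] - priors[r, "zc"]
    d2 <- dy * dy + dz * dz
    x <- points[, 1]
    dx <- pmax(priors[r, "x0"] - x, 0, x - priors[r, "x1"])
    out <- out | (d2 + dx * dx < R2)
  }
  out
}

#' Point-wise engagement test
#'
#' A point is engaged with uncut material when it lies inside the original
#' stock (the volume box, below the initial top surface) and outside every
#' previously machined swept volume. Pure geometry; the chip-thickness
#' condition that selects the advancing side of the cutter is applied
#' separately in [engaged_edges()].
#'
#' @param points WCS positions, n x 3 matrix (or one 3-vector), mm.
#' @param state A [machined_state()].
#' @param radius Cutter ball radius R (mm).
#' @return Logical vector, one entry per point.
#' @export
is_engaged <- function(points, state, radius) {
  stopifnot(inherits(state, "machined_state"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  inside <- points[, 1] >= state$stock_lo[1] & points[, 1] <= state$stock_hi[1] &
            points[, 2] >= state$stock_lo[2] & points[, 2] <= state$stock_hi[2] &
            points[, 3] >= state$stock_lo[3] & points[, 3] < state$stock_hi[3]
  inside & !removed_by_priors(points, state$priors, radius)
}

#' Engaged micro-edges at a pose
#'
#' Transforms the micro-edge table to the WCS at the given pose, keeps the
#' edges that are engaged with uncut material ([is_engaged()], evaluated in
#' the nominal frame for the machined history and in the deviated frame for
#' the stock), and additionally requires a positive undeformed chip
#' thickness (the rake face must advance into material).
#'
#' @param pose A [pose_at()] result.
#' @param edges An [edge_points()] table.
#' @param state A [machined_state()].
#' @param spec A [cutter_spec()].
#' @return The engaged subset of `edges` with extra columns `wx`, `wy`,
#'   `wz` (deviated WCS position), `qx`, `qy`, `qz` (nominal), `tn` (mm)
#'   and `phi_inst` (instantaneous circumferential angle, rad).
#' @export
engaged_edges <- function(pose, edges, state, spec) {
  stopifnot(inherits(pose, "tool_pose"))
  pm <- t(rbind(t(as.matrix(edges[, c("x", "y", "z")])), 1))
  q <- pm %*% t(pose$T_nom)
  w <- pm %*% t(pose$T_act)
  q <- q[, 1:3, drop = FALSE]; w <- w[, 1:3, drop = FALSE]
  # radial direction and chip thickness
  radial <- sweep(w, 2L, pose$centre_act, "-") / spec$radius
  tn <- pose$vt * as.numeric(radial %*% pose$feed_dir_act)
  geom <- rep(TRUE, nrow(q))
  geom <- geom & !removed_by_priors(q, state$priors, spec$radius)
  geom <- geom & w[, 1] >= state$stock_lo[1] & w[, 1] <= state$stock_hi[1] &
    w[, 2] >= state$stock_lo[2] & w[, 2] <= state$stock_hi[2] &
    w[, 3] >= state$stock_lo[3] & w[, 3] < state$stock_hi[3]
  keep <- geom & tn > 0
  out <- edges[keep, , drop = FALSE]
  out$qx <- q[keep, 1]; out$qy <- q[keep, 2]; out$qz <- q[keep, 3]
  out$wx <- w[keep, 1]; out$wy <- w[keep, 2]; out$wz <- w[keep, 3]
  out$tn <- tn[keep]
  out$phi_inst <- out$phi_m + pose$spin_phase
  rownames(out) <- NULL
  out
}

#' Voxel-carving removal oracle
#'
#' Brute-force material-removal simulator used as an independent check of
#' the analytic engagement test: rasterizes the stock onto a voxel grid and
#' marks every voxel whose centre lies inside a completed path's swept
#' volume as removed. Material occupancy at a query point is then the state
#' of the voxel containing it.
#'
#' @param plan A [milling_plan()].
#' @param spec A [cutter_spec()].
#' @param vol A [ct_volume()] defining the stock extent.
#' @param ord Execution ordinal (paths `1..ord-1` are carved out).
#' @param voxel_mm Oracle grid resolution (mm), independent of the CT grid.
#' @return List of class `carve_oracle` with the logical `removed` array,
#'   grid `origin`, `spacing` and `stock_hi`, plus `occupied_at(points)`
#'   semantics via [oracle_engaged()].
#' @export
carve_voxels <- function(plan, spec, vol, ord, voxel_mm = 0.1) {
  b <- volume_bounds(vol)
  stock_hi <- c(b$hi[1], b$hi[2], min(b$hi[3], plan$origin[3]))
  nvox <- pmax(1L, ceiling((b$hi - b$lo) / voxel_mm - 1e-9))
  cx <- b$lo[1] + (seq_len(nvox[1]) - 0.5) * voxel_mm
  cy <- b$lo[2] + (seq_len(nvox[2]) - 0.5) * voxel_mm
  cz <- b$lo[3] + (seq_len(nvox[3]) - 0.5) * voxel_mm
  removed <- array(FALSE, dim = nvox)
  st <- machined_state(plan, spec, vol, ord)
  pr <- st$priors
  R <- spec$radius
  for (r in seq_len(nrow(pr))) {
    iy <- which(abs(cy - pr[r, "y"]) < R)
    iz <- which(abs(cz - pr[r, "zc"]) < R)
    if (!length(iy) || !length(iz)) next
    d2 <- outer((cy[iy] - pr[r, "y"])^2, (cz[iz] - pr[r, "zc"])^2, "+")
    for (a in seq_along(cx)) {
      dx <- max(pr[r, "x0"] - cx[a], 0, cx[a] - pr[r, "x1"])
      if (dx >= R) next
      hit <- d2 < R^2 - dx^2
      if (any(hit)) {
        sl <- removed[a, iy, iz]
        removed[a, iy, iz] <- sl | hit
      }
    }
  }
  structure(list(removed = removed, origin = b$lo, spacing = rep(voxel_mm, 3),
                 stock_lo = b$lo, stock_hi = stock_hi, nvox = nvox),
            class = "carve_oracle")
}

#' Engagement according to the voxel oracle
#'
#' @param oracle A [carve_voxels()] result.
#' @param points WCS positions (n x 3), mm.
#' @return Logical vector: point lies in a stock voxel that has not been
#'   carved away.
#' @export
oracle_engaged <- function(oracle, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  idx <- floor(sweep(sweep(points, 2L, oracle$origin, "-"), 2L,
                     oracle$spacing, "/")) + 1
  n <- oracle$nvox
  inside <- idx[, 1] >= 1 & idx[, 1] <= n[1] &
            idx[, 2] >= 1 & idx[, 2] <= n[2] &
            idx[, 3] >= 1 & idx[, 3] <= n[3] &
            points[, 3] < oracle$stock_hi[3]
  out <- rep(FALSE, nrow(points))
  ok <- which(inside)
  if (length(ok))
    out[ok] <- !oracle$removed[idx[ok, , drop = FALSE]]
  out
}
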