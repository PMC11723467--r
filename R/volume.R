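#' CT volume container
#'
#' A minimal container for a 3-D CT grayscale grid with physical geometry:
#' the voxel `data[i, j, k]` occupies the axis-aligned box from
#' `origin + (c(i, j, k) - 1) * spacing` to `origin + c(i, j, k) * spacing`
#' (mm), i.e. `origin` is the physical position of the corner of the first
#' voxel and voxel centres sit at `origin + (index - 0.5) * spacing`.
#'
#' @param data 3-D numeric array of grayscale values (CT units, >= 0).
#' @param spacing Per-axis voxel size in mm (length 3, all > 0).
#' @param origin Physical position of the corner of voxel (1,1,1) in the
#'   workpiece coordinate system (mm). Defaults to the origin.
#' @return An object of class `ct_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("`data` must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive voxel sizes in mm")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite 3-vector in mm")
  if (any(!is.finite(data))) stop("volume gray values must be finite")
  if (any(data < 0)) stop("volume gray values must be non-negative")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<ct_volume> ", paste(d, collapse = " x "), " voxels, spacing ",
      paste(signif(x$spacing, 4), collapse = " x "), " mm\n", sep = "")
  cat("  physical size ", paste(signif(d * x$spacing, 5), collapse = " x "),
      " mm, gray range [", signif(min(x$data), 5), ", ",
      signif(max(x$data), 5), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' Physical bounds of a CT volume
#'
#' @param vol A [ct_volume()].
#' @return List with `lo` and `hi`, the opposite corners of the volume's
#'   axis-aligned bounding box in mm.
#' @export
volume_bounds <- function(vol) {
  stopifnot(inherits(vol, "ct_volume"))
  list(lo = vol$origin, hi = vol$origin + dim(vol$data) * vol$spacing)
}

#' Nearest-voxel gray lookup at physical positions
#'
#' Positions outside the grid return `outside` (default 0, i.e. air).
#'
#' @param vol A [ct_volume()].
#' @param points Numeric matrix (n x 3) of WCS positions in mm (a single
#'   3-vector is also accepted).
#' @param outside Gray value reported outside the volume.
#' @return Numeric vector of gray values, one per point.
#' @export
gray_at <- function(vol, points, outside = 0) {
  stopifnot(inherits(vol, "ct_volume"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  idx <- sweep(points, 2L, vol$origin, "-")
  idx <- floor(sweep(idx, 2L, vol$spacing, "/")) + 1
  d <- dim(vol$data)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
        idx[, 2] >= 1 & idx[, 2] <= d[2] &
        idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- rep(outside, nrow(points))
  if (any(ok)) out[ok] <- vol$data[idx[ok, , drop = FALSE]]
  out
}

#' Grayscale normalization parameters
#'
#' Bounds for the piecewise-linear gray-to-lambda ramp and the power
#' coefficient used to weight the mechanistic force model. In practice
#' `mmin` is taken near the low tail of cancellous-bone gray values and
#' `mmax` near the high tail of cortical values of the specific scan.
#'
#' @param mmin Lower gray bound (CT units).
#' @param mmax Upper gray bound (CT units), must exceed `mmin`.
#' @param mu Power coefficient applied to the normalized gray (> 0).
#' @return An object of class `norm_params`.
#' @export
norm_params <- function(mmin = 80, mmax = 1400, mu = 1.815) {
  stopifnot(is.finite(mmin), is.finite(mmax), is.finite(mu))
  if (mmax <= mmin) stop("`mmax` must be greater than `mmin`")
  if (mu <= 0) stop("`mu` must be positive")
  structure(list(mmin = mmin, mmax = mmax, mu = mu), class = "norm_params")
}

#' Normalize CT gray values to [0, 1]
#'
#' Piecewise-linear ramp: 0 at or below `mmin`, 1 at or above `mmax`,
#' linear in between. Total and continuous in `x`.
#'
#' @param x Gray values (CT units), any numeric vector.
#' @param params A [norm_params()] object.
#' @return Normalized gray `lambda` in `[0, 1]`, same shape as `x`.
#' @export
normalize_gray <- function(x, params = norm_params()) {
  stopifnot(inherits(params, "norm_params"))
  pmin(pmax((x - params$mmin) / (params$mmax - params$mmin), 0), 1)
}

#' Read / write a CT volume as NIfTI
#'
#' Voxel spacing is taken from (written to) the NIfTI header; the stored
#' image array is used as-is (no slope/intercept rescaling beyond what the
#' reader applies).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param vol A [ct_volume()] (for writing).
#' @return `read_ct_volume`: a [ct_volume()]. `write_ct_volume`: `path`,
#'   invisibly.
#' @export
read_ct_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  ct_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing = sp)
}

#' @rdname read_ct_volume
#' @export
write_ct_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
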