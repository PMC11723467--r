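#' Stepped-gradient CT phantom
#'
#' Builds a rectangular volume whose gray level is constant within each of
#' `n_levels` equal-width slabs along one axis and steps monotonically across
#' `gray_range`, emulating a calibration block of graded apparent density.
#' The other two axes are homogeneous.
#'
#' @param size_mm Physical size of the block, 3-vector in mm; must be
#'   (within tolerance) an integer multiple of `voxel_mm` per axis.
#' @param voxel_mm Voxel size, scalar or 3-vector in mm.
#' @param n_levels Number of gray steps (>= 1).
#' @param gray_range Interval `c(lo, hi)` spanned by the steps (CT units).
#' @param gradient_axis Axis along which the gray steps run: 1/2/3 or
#'   `"x"`/`"y"`/`"z"`.
#' @return A [ct_volume()].
#' @export
make_step_phantom <- function(size_mm, voxel_mm, n_levels = 10,
                              gray_range = c(0, 1400), gradient_axis = "x") {
  size_mm <- as.numeric(size_mm)
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  if (length(size_mm) != 3L || any(size_mm <= 0) || any(voxel_mm <= 0))
    stop("`size_mm` and `voxel_mm` must be positive")
  if (n_levels < 1) stop("`n_levels` must be at least 1")
  nvox <- round(size_mm / voxel_mm)
  if (any(abs(nvox * voxel_mm - size_mm) > 1e-6))
    stop("`size_mm` must be divisible by `voxel_mm` on every axis")
  ax <- axis_index(gradient_axis)
  levels <- seq(gray_range[1], gray_range[2], length.out = n_levels)
  # slab of voxel i (1-based) along the gradient axis
  slab <- floor((seq_len(nvox[ax]) - 1) * n_levels / nvox[ax]) + 1
  profile <- levels[slab]
  perm_shape <- c(nvox[ax], nvox[-ax])
  block <- array(profile, dim = perm_shape) # recycles along the first axis
  data <- aperm(block, order(c(ax, setdiff(1:3, ax))))
  ct_volume(data, spacing = voxel_mm)
}

axis_index <- function(axis) {
  if (is.character(axis)) axis <- match(tolower(axis), c("x", "y", "z"))
  axis <- as.integer(axis)
  if (is.na(axis) || axis < 1L || axis > 3L)
    stop("`gradient_axis` must be 1, 2, 3 or one of 'x', 'y', 'z'")
  axis
}

#' Lamina-like CT phantom: cortical shell around a cancellous core
#'
#' A synthetic stand-in for a segmented vertebral lamina: a dense cortical
#' shell within `shell_mm` of every face of the block, a lighter cancellous
#' core, and a smooth random gray texture superimposed everywhere so that
#' each milling path sees a distinct density profile. The texture is white
#' Gaussian noise smoothed by a separable Gaussian kernel of standard
#' deviation `smoothness` mm; the default of 0.6 mm reflects the
#' trabecular-separation scale of vertebral cancellous bone (0.5--1 mm),
#' which is what gives real laminae voxel-scale density contrast.
#' `texture_sd` is the approximate post-smoothing standard deviation at
#' that default smoothness (the same input noise is attenuated further as
#' `smoothness` grows, so the field tends to the noiseless shell/core
#' structure in the smooth limit).
#'
#' @param size_mm,voxel_mm Block and voxel size in mm (as in
#'   [make_step_phantom()]).
#' @param cortical_gray,cancellous_gray Shell and core gray levels (CT units).
#' @param shell_mm Shell thickness, must be below `min(size_mm) / 2`.
#' @param smoothness Texture correlation scale (Gaussian sigma, mm).
#' @param seed Mandatory integer seed; the generator is a pure function of
#'   its arguments and the seed.
#' @param texture_sd Texture amplitude (CT units) at the reference
#'   smoothness of 0.6 mm.
#' @param gray_clip Final clipping interval (CT units).
#' @return A [ct_volume()].
#' @export
make_lamina_phantom <- function(size_mm, voxel_mm, cortical_gray = 1200,
                                cancellous_gray = 400, shell_mm = 1.5,
                                smoothness = 0.6, seed, texture_sd = 200,
                                gray_clip = c(0, 1400)) {
  if (missing(seed) || is.null(seed))
    stop("`seed` is required: phantom generation must be reproducible")
  size_mm <- as.numeric(size_mm)
  voxel_mm <- as.numeric(voxel_mm)
  if (length(voxel_mm) == 1L) voxel_mm <- rep(voxel_mm, 3L)
  if (shell_mm >= min(size_mm) / 2)
    stop("`shell_mm` must be smaller than half the smallest block dimension")
  nvox <- round(size_mm / voxel_mm)
  if (any(abs(nvox * voxel_mm - size_mm) > 1e-6))
    stop("`size_mm` must be divisible by `voxel_mm` on every axis")

  # distance from each voxel centre to the nearest face of the block
  centre <- lapply(1:3, function(a) (seq_len(nvox[a]) - 0.5) * voxel_mm[a])
  dist_face <- lapply(1:3, function(a) pmin(centre[[a]], size_mm[a] - centre[[a]]))
  dmin <- outer(outer(dist_face[[1]], dist_face[[2]], pmin), dist_face[[3]], pmin)
  # logistic shell/core blend, ~0.25 mm transition
  shell_frac <- stats::plogis((shell_mm - dmin) / 0.25)
  base <- cancellous_gray + (cortical_gray - cancellous_gray) * shell_frac

  old <- save_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  noise <- array(stats::rnorm(prod(nvox)), dim = nvox)
  # input amplitude referenced to the attenuation of a sigma = 0.6 mm kernel
  ref_att <- prod(vapply(1:3, function(a)
    sqrt(sum(gauss_kernel(0.6 / voxel_mm[a])^2)), numeric(1)))
  noise <- noise * texture_sd / ref_att
  for (a in 1:3) noise <- smooth_axis(noise, a, smoothness / voxel_mm[a])

  data <- pmin(pmax(base + noise, gray_clip[1]), gray_clip[2])
  ct_volume(data, spacing = voxel_mm)
}

gauss_kernel <- function(sigma_vox) {
  half <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-0.5 * ((-half:half) / sigma_vox)^2)
  k / sum(k)
}

# separable Gaussian smoothing along one array axis (edge-renormalized)
smooth_axis <- function(arr, axis, sigma_vox) {
  d <- dim(arr)
  n <- d[axis]
  k <- gauss_kernel(sigma_vox)
  half <- (length(k) - 1L) / 2L
  # banded n x n smoothing matrix with rows renormalized at the edges
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmax(1L, i - half):pmin(n, i + half)
    w <- k[j - i + half + 1L]
    K[i, j] <- w / sum(w)
  }
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(arr, perm), nrow = n)
  sm <- K %*% m
  aperm(array(sm, dim = d[perm]), order(perm))
}

# save/restore the global RNG state so seeded generators do not perturb
# the caller's random stream
save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng_state <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
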