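#' Frozen study setups for the validation protocols
#'
#' Builds the phantom, plan and model parameters of the three packaged
#' validation protocols, so that tests, scripts and documentation exercise
#' identical conditions:
#' \describe{
#'   \item{step}{The stepped-gradient block (12 x 12 x 6 mm, 0.25 mm
#'     voxels, 10 gray steps over 0--1400 along x) milled with the
#'     reference parameters: 3 layers x 4 paths, 8 mm paths. Used for the
#'     closed-loop exactness check.}
#'   \item{feed_sweep}{A lamina phantom (12 x 16 x 12 mm) milled with
#'     10 layers x 4 paths of 6 mm; sinusoidal feed-rate disturbance and
#'     small random pose deviations (rotations within 0.01 rad,
#'     translations within 0.5 mm per axis). Deviation stage BestNum 30.}
#'   \item{narrow}{A narrow lamina phantom (12 x 12 x 13 mm) milled with
#'     11 layers x 2 paths of 4.5 mm; the eleven
#'     [narrow_plan_deviations()] conditions; deviation stage BestNum 8.
#'     The tight lateral margins mean large step-direction deviations
#'     reach the phantom's side cortical wall, as they would in a narrow
#'     lamina.}
#' }
#' All protocols share the reference milling parameters (feed 0.5 mm/s,
#' spin 800 RPM, depth 0.8 mm, step 2.8 mm, incline 30 deg, fs 20 Hz,
#' ns 15) and the default cutter and force coefficients.
#'
#' @param protocol One of `"step"`, `"feed_sweep"`, `"narrow"`.
#' @param phantom_seed Seed for the lamina texture (ignored for `step`).
#' @return List with `vol`, `plan`, `spec`, `coeffs`, `norm`, `n2`,
#'   `rot_max`, `trans_max`, `noise_sigma`, `amplitudes`.
#' @export
study_setup <- function(protocol = c("step", "feed_sweep", "narrow"),
                        phantom_seed = 7) {
  protocol <- match.arg(protocol)
  spec <- cutter_spec()
  coeffs <- force_coefficients()
  norm <- norm_params()
  common <- list(spec = spec, coeffs = coeffs, norm = norm,
                 noise_sigma = c(0.05, 0.5),
                 amplitudes = c(0.05, 0.10, 0.15, 0.20, 0.30),
                 rot_max = 0.01, trans_max = 0.5)
  if (protocol == "step") {
    vol <- make_step_phantom(c(12, 12, 6), 0.25, n_levels = 10,
                             gray_range = c(0, 1400), gradient_axis = "x")
    plan <- milling_plan(n_layers = 3, n_paths = 4, path_length = 8,
                         origin = c(2, 1.8, 6))
    n2 <- 10
  } else if (protocol == "feed_sweep") {
    vol <- make_lamina_phantom(c(12, 16, 12), 0.25, seed = phantom_seed)
    plan <- milling_plan(n_layers = 10, n_paths = 4, path_length = 6,
                         origin = c(3, 3, 12))
    n2 <- 30
  } else {
    vol <- make_lamina_phantom(c(12, 12, 13), 0.25, seed = phantom_seed)
    plan <- milling_plan(n_layers = 11, n_paths = 2, path_length = 4.5,
                         origin = c(3.75, 4.5, 13))
    n2 <- 8
  }
  c(list(protocol = protocol, vol = vol, plan = plan, n2 = n2), common)
}
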