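# Synthetic CT of the phantom and the bilinear HU -> mu(511 keV) scaling.

#' Bilinear CT-to-mu scaling parameters
#'
#' Standard 120 kVp bilinear calibration: below `break_hu` the slope maps
#' water (0 HU) to 0.096 cm^-1; above it a shallower slope accounts for the
#' energy dependence of bone-like materials. The high-segment offset is
#' fixed by continuity at the break.
#'
#' @param slope_low Slope below the break, cm^-1 per (HU + 1000).
#' @param break_hu Break point, HU.
#' @param slope_high Slope above the break, cm^-1 per (HU + 1000).
#' @param offset_high Intercept of the high segment, cm^-1; `NULL` (default)
#'   derives it from continuity at `break_hu`.
#' @return An object of class `bilinear_params`.
#' @export
bilinear_params <- function(slope_low = 9.6e-5, break_hu = 47,
                            slope_high = 5.1e-5, offset_high = NULL) {
  if (is.null(offset_high))
    offset_high <- (slope_low - slope_high) * (break_hu + 1000)
  structure(list(slope_low = slope_low, break_hu = break_hu,
                 slope_high = slope_high, offset_high = offset_high),
            class = "bilinear_params")
}

#' Convert CT numbers to 511 keV attenuation coefficients
#'
#' Bilinear scaling: `mu = slope_low (HU + 1000)` up to `break_hu`, then
#' `mu = slope_high (HU + 1000) + offset_high`; negative results are clamped
#' to zero. With the default 120 kVp parameters, 0 HU maps to 0.096 cm^-1
#' (the water value used in the segmented maps) and -1000 HU (air) to 0.
#'
#' @param ct An `image_volume` of Hounsfield units (e.g. from
#'   [simulate_ct()]), or a plain numeric array/vector.
#' @param params A [bilinear_params()] object.
#' @return An `attenuation_map` tagged `CT_AC` if `ct` is an `image_volume`,
#'   otherwise a numeric object shaped like `ct`.
#' @export
ct_to_mu <- function(ct, params = bilinear_params()) {
  hu <- if (inherits(ct, "image_volume")) ct$data else ct
  if (any(!is.finite(hu))) stop("CT volume contains non-finite values")
  mu <- ifelse(hu <= params$break_hu,
               params$slope_low * (hu + 1000),
               params$slope_high * (hu + 1000) + params$offset_high)
  mu <- pmax(mu, 0)
  if (inherits(ct, "image_volume"))
    attenuation_map(array(mu, dim = ct$grid$shape), ct$grid, "CT_AC")
  else mu
}

#' Hounsfield value that maps to a given attenuation coefficient
#'
#' Inverse of [ct_to_mu()]; used to choose the synthetic CT value of the
#' polymer so that the CT-derived map reproduces the published material
#' coefficient (0.1037 cm^-1).
#'
#' @param mu Attenuation coefficient, cm^-1.
#' @param params A [bilinear_params()] object.
#' @return Hounsfield units.
#' @export
hu_for_mu <- function(mu, params = bilinear_params()) {
  mu_break <- params$slope_low * (params$break_hu + 1000)
  ifelse(mu <= mu_break,
         mu / params$slope_low - 1000,
         (mu - params$offset_high) / params$slope_high - 1000)
}

#' Simulate a co-registered CT volume
#'
#' Mixes per-voxel Hounsfield units from the anti-aliased label fractions
#' (background is air at -1000 HU), adds Gaussian noise, and clamps at
#' -1000 HU. The default material value is the HU whose bilinear mapping
#' gives 0.1037 cm^-1, so a noise-free synthetic CT-AC reproduces the
#' published coefficients exactly away from borders.
#'
#' @param label A `label_volume` from [rasterize()].
#' @param hu_water Water value, HU (default 0).
#' @param hu_material Material value, HU; `NULL` uses
#'   `hu_for_mu(0.1037, params)`.
#' @param noise_sigma Gaussian noise SD, HU (0 disables).
#' @param seed Integer seed.
#' @param params [bilinear_params()] used to derive the default material HU.
#' @return An `image_volume` with `units = "HU"`.
#' @export
simulate_ct <- function(label, hu_water = 0, hu_material = NULL,
                        noise_sigma = 0, seed = 1L,
                        params = bilinear_params()) {
  stopifnot(inherits(label, "label_volume"))
  if (is.null(hu_material)) hu_material <- hu_for_mu(0.1037, params)
  w <- label$frac_water
  p <- label$frac_material
  hu <- w * hu_water + p * hu_material + (1 - w - p) * (-1000)
  if (noise_sigma > 0)
    hu <- with_seed(seed, hu + stats::rnorm(length(hu), sd = noise_sigma))
  hu <- pmax(hu, -1000)
  image_volume(array(hu, dim = label$grid$shape), label$grid, units = "HU")
}
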