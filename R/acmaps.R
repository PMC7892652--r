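# Construction of the four competing attenuation maps from Dixon and CT
# volumes: threshold/morphology segmentation of the opposed-phase and fat
# images into total-phantom and water masks, fixed-mu assignment, the
# vendor-style whole-object soft-tissue map, the wall-less variant, and the
# bilinear CT reference.

#' Segmentation parameters
#'
#' Thresholds are in the scanner-arbitrary intensity units of the Dixon
#' images (the simulator calibrates water to 1000 a.u. so the published
#' values separate water from the polymer, which sits at ~1/3 of water).
#'
#' @param phantom_threshold Opposed-phase threshold for the total-phantom
#'   mask, a.u.
#' @param water_threshold Threshold on the fat-enhanced opposed-phase image
#'   for the water mask, a.u.
#' @param fat_floor Filtered fat values below this are zeroed, a.u.
#' @param fat_sigma In-plane Gaussian sigma for the fat image, pixels.
#' @param fat_weight How many times the fat image is subtracted from the
#'   opposed-phase image.
#' @param erosion_radius Isotropic erosion of the total mask, voxels.
#' @param closing_radius Radius of the morphological closings, voxels
#'   (6-connected cross applied that many times). The default of 1 fills
#'   isolated sub-threshold voxels while leaving holes of two or more pixels
#'   — i.e. all but the smallest rods — open, matching the reported
#'   behaviour of the segmentation around the rod array.
#' @param mu_water,mu_material,mu_soft_tissue Linear attenuation
#'   coefficients at 511 keV, cm^-1 (published values 0.096, 0.1037, 0.1).
#' @param standard_dilation Dilation of the total mask emulating the
#'   vendor MR-AC's ~one-pixel overestimation of the object extent, voxels.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(phantom_threshold = 100, water_threshold = 400,
                                fat_floor = 10, fat_sigma = 0.5,
                                fat_weight = 4, erosion_radius = 1L,
                                closing_radius = 1L,
                                mu_water = 0.096, mu_material = 0.1037,
                                mu_soft_tissue = 0.1,
                                standard_dilation = 1L) {
  stopifnot(phantom_threshold >= 0, water_threshold >= 0, fat_floor >= 0,
            fat_sigma >= 0, mu_water >= 0, mu_material >= 0,
            mu_soft_tissue >= 0)
  structure(as.list(environment()), class = "segmentation_params")
}

#' Total-phantom mask from the opposed-phase image
#'
#' Thresholds the opposed-phase image, closes small gaps, keeps the largest
#' 26-connected component (discarding stray above-threshold voxels), and
#' applies an isotropic 1-voxel erosion to counter the extent overestimation
#' caused by the low threshold.
#'
#' @param opposed_phase An `image_volume` (opposed-phase magnitudes).
#' @param params A [segmentation_params()] object.
#' @return A `binary_mask` of the total phantom support.
#' @export
total_phantom_mask <- function(opposed_phase, params = segmentation_params()) {
  stopifnot(inherits(opposed_phase, "image_volume"))
  thr <- opposed_phase$data > params$phantom_threshold
  if (!any(thr)) stop("empty phantom mask: no voxel above the phantom threshold")
  m <- mask_close(thr, params$closing_radius)
  m <- largest_component(m)
  m <- mask_erode(m, params$erosion_radius)
  binary_mask(m, opposed_phase$grid)
}

#' Water-compartment mask
#'
#' The fat image is smoothed in-plane (Gaussian, `fat_sigma` pixels), values
#' below `fat_floor` are zeroed, and the result is subtracted `fat_weight`
#' times from the opposed-phase image to sharpen the water/material border
#' (partial-volume dephasing makes the border bright in the fat channel).
#' The water mask is the closed thresholding (> `water_threshold`) of that
#' enhanced image.
#'
#' @param opposed_phase,fat `image_volume`s on the same grid.
#' @param params A [segmentation_params()] object.
#' @param slice_axis Slice-select axis of the Dixon acquisition (the fat
#'   smoothing is applied in-plane only).
#' @return A `binary_mask` of the water compartment.
#' @export
water_mask <- function(opposed_phase, fat, params = segmentation_params(),
                       slice_axis = 1L) {
  stopifnot(inherits(opposed_phase, "image_volume"), inherits(fat, "image_volume"))
  check_same_grid(opposed_phase$grid, fat$grid, "opposed-phase and fat volumes")
  sigma <- rep(params$fat_sigma, 3)
  sigma[slice_axis] <- 0
  f <- gaussian_smooth(fat$data, sigma)
  f[f < params$fat_floor] <- 0
  enhanced <- opposed_phase$data - params$fat_weight * f
  binary_mask(mask_close(enhanced > params$water_threshold,
                         params$closing_radius),
              opposed_phase$grid)
}

#' Material mask by subtraction
#'
#' Set difference: voxels in the total-phantom mask but not in the water
#' mask.
#'
#' @param total,water `binary_mask`s on the same grid.
#' @return A `binary_mask`.
#' @export
material_mask <- function(total, water) {
  stopifnot(inherits(total, "binary_mask"), inherits(water, "binary_mask"))
  check_same_grid(total$grid, water$grid, "masks")
  binary_mask(total$values & !water$values, total$grid)
}

#' Phantom-specific MR attenuation map
#'
#' Assigns `mu_water` to the water mask and `mu_material` to the material
#' (total minus water) mask; background stays at zero.
#'
#' @param total,water `binary_mask`s on the same grid.
#' @param params A [segmentation_params()] object.
#' @return An `attenuation_map` tagged `PHANTOM_MRAC`.
#' @export
build_phantom_mrac <- function(total, water, params = segmentation_params()) {
  check_same_grid(total$grid, water$grid, "masks")
  mu <- array(0, dim = total$grid$shape)
  mu[total$values & !water$values] <- params$mu_material
  mu[water$values] <- params$mu_water
  attenuation_map(mu, total$grid, "PHANTOM_MRAC")
}

#' Wall-less attenuation map
#'
#' As [build_phantom_mrac()] but with the phantom material set to zero
#' attenuation — emulating a conventional phantom whose housing is invisible
#' to MR-based AC.
#'
#' @inheritParams build_phantom_mrac
#' @return An `attenuation_map` tagged `NOWALL_MRAC`.
#' @export
build_nowall_mrac <- function(total, water, params = segmentation_params()) {
  check_same_grid(total$grid, water$grid, "masks")
  mu <- array(0, dim = total$grid$shape)
  mu[water$values] <- params$mu_water
  attenuation_map(mu, total$grid, "NOWALL_MRAC")
}

#' Vendor-style standard MR attenuation map
#'
#' Emulates the whole-body Dixon MR-AC output for this phantom: the entire
#' object is treated as soft tissue (0.1 cm^-1), with a one-voxel dilation
#' reproducing the observed ~one-pixel overestimation of the object extent.
#'
#' @param total A `binary_mask` of the total phantom.
#' @param params A [segmentation_params()] object.
#' @return An `attenuation_map` tagged `STANDARD_MRAC`.
#' @export
build_standard_mrac <- function(total, params = segmentation_params()) {
  stopifnot(inherits(total, "binary_mask"))
  mu <- array(0, dim = total$grid$shape)
  mu[mask_dilate(total$values, params$standard_dilation)] <- params$mu_soft_tissue
  attenuation_map(mu, total$grid, "STANDARD_MRAC")
}
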