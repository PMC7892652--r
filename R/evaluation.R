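# Quantification-bias evaluation: voxel %-difference images against the
# CT-AC reconstruction, ROI definitions (whole water compartment, single
# slices, 5-pixel wall and rod bands) and mean +/- SD statistics, plus line
# profiles for visual inspection.

#' ROI specification
#'
#' @param kind One of `"WHOLE_WATER"`, `"SLICE_HOMOGENEOUS"`,
#'   `"SLICE_HETEROGENEOUS"`, `"WALL_BAND"`, `"ROD_BAND"`.
#' @param band_width Band width in pixels for the band kinds (>= 1).
#' @param slice_index Axial slice index for the slice/band kinds.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(kind = c("WHOLE_WATER", "SLICE_HOMOGENEOUS",
                              "SLICE_HETEROGENEOUS", "WALL_BAND", "ROD_BAND"),
                     band_width = 5L, slice_index = NULL) {
  kind <- match.arg(kind)
  if (band_width < 1) stop("band_width must be >= 1")
  if (kind != "WHOLE_WATER" && is.null(slice_index))
    stop("slice_index is required for slice and band ROIs")
  structure(list(kind = kind, band_width = as.integer(band_width),
                 slice_index = slice_index), class = "roi_spec")
}

#' Voxel-wise percent difference
#'
#' `100 (test - ref) / ref` inside the support mask, `NA` elsewhere. Support
#' voxels where the reference is not positive are excluded (set `NA`) and
#' counted in the `"excluded"` attribute.
#'
#' @param test,ref `activity_volume`s on one grid.
#' @param support A `binary_mask` on the same grid.
#' @return An `image_volume` (units `%`) with attribute `excluded`.
#' @export
percent_difference <- function(test, ref, support) {
  stopifnot(inherits(test, "activity_volume"), inherits(ref, "activity_volume"),
            inherits(support, "binary_mask"))
  check_same_grid(test$grid, ref$grid, "test and reference volumes")
  check_same_grid(test$grid, support$grid, "volumes and support mask")
  out <- array(NA_real_, dim = test$grid$shape)
  ok <- support$values & ref$activity > 0
  excluded <- sum(support$values & !(ref$activity > 0))
  out[ok] <- 100 * (test$activity[ok] - ref$activity[ok]) / ref$activity[ok]
  res <- image_volume(out, test$grid, units = "%")
  attr(res, "excluded") <- excluded
  res
}

#' Water-compartment support from the CT-based attenuation map
#'
#' Thresholds the CT-AC map with a water window (default
#' `[0.090, 0.100)` cm^-1), keeps the part inside the largest connected
#' phantom component, and erodes by one voxel to drop border partial-volume
#' voxels.
#'
#' @param ct_ac An `attenuation_map` (typically tagged `CT_AC`).
#' @param window Water mu window, cm^-1 (half-open).
#' @param phantom_floor mu above which a voxel counts as phantom when
#'   finding the largest connected component, cm^-1.
#' @param erosion Erosion radius in voxels.
#' @return A `binary_mask`.
#' @export
water_support_from_ct <- function(ct_ac, window = c(0.090, 0.100),
                                  phantom_floor = 0.05, erosion = 1L) {
  stopifnot(inherits(ct_ac, "attenuation_map"))
  phantom <- ct_ac$mu > phantom_floor
  if (!any(phantom)) stop("no water found: attenuation map contains no phantom")
  phantom <- largest_component(phantom)
  m <- phantom & ct_ac$mu >= window[1] & ct_ac$mu < window[2]
  if (!any(m)) stop("no water found in the mu window")
  binary_mask(mask_erode(m, erosion), ct_ac$grid)
}

#' Material support from the CT-based attenuation map
#'
#' Voxels of the largest connected phantom component whose mu lies at or
#' above the upper edge of the water window — the housing and rods as seen
#' by CT. Used to anchor the wall/rod band ROIs on the reconstruction grid.
#'
#' @inheritParams water_support_from_ct
#' @param mu_min Lower mu bound for material, cm^-1.
#' @return A `binary_mask`.
#' @export
material_support_from_ct <- function(ct_ac, mu_min = 0.100,
                                     phantom_floor = 0.05) {
  stopifnot(inherits(ct_ac, "attenuation_map"))
  phantom <- ct_ac$mu > phantom_floor
  if (!any(phantom)) stop("attenuation map contains no phantom")
  phantom <- largest_component(phantom)
  binary_mask(phantom & ct_ac$mu >= mu_min, ct_ac$grid)
}

#' Build an ROI mask
#'
#' `WHOLE_WATER` is the water support itself; the slice kinds restrict it to
#' one axial slice; `WALL_BAND` keeps the water voxels of the slice within
#' `band_width` pixels (in-plane Euclidean distance) of the material;
#' `ROD_BAND` is the same construction in a rod slice, so the band
#' surrounds both the rods and the housing.
#'
#' @param roi A [roi_spec()].
#' @param water_support A `binary_mask` of the water compartment.
#' @param material A `binary_mask` of the housing material (required for the
#'   band kinds).
#' @return A `binary_mask`.
#' @export
make_roi <- function(roi, water_support, material = NULL) {
  stopifnot(inherits(roi, "roi_spec"), inherits(water_support, "binary_mask"))
  grid <- water_support$grid
  w <- water_support$values
  out <- array(FALSE, dim = grid$shape)
  if (roi$kind == "WHOLE_WATER") {
    out <- w
  } else {
    s <- roi$slice_index
    if (s < 1 || s > grid$shape[3]) stop("slice_index out of range")
    if (roi$kind %in% c("SLICE_HOMOGENEOUS", "SLICE_HETEROGENEOUS")) {
      out[, , s] <- w[, , s]
    } else {
      if (is.null(material)) stop("band ROIs need a material mask")
      check_same_grid(grid, material$grid, "masks")
      mslice <- material$values[, , s]
      # dilate by a Euclidean disc of radius band_width pixels
      bw <- roi$band_width
      band <- matrix(FALSE, nrow(mslice), ncol(mslice))
      n1 <- nrow(mslice); n2 <- ncol(mslice)
      for (di in -bw:bw) for (dj in -bw:bw) {
        if (di * di + dj * dj > bw * bw) next
        si <- max(1, 1 - di):min(n1, n1 - di)
        sj <- max(1, 1 - dj):min(n2, n2 - dj)
        band[si + di, sj + dj] <- band[si + di, sj + dj] | mslice[si, sj]
      }
      out[, , s] <- w[, , s] & band
    }
  }
  binary_mask(out, grid)
}

#' ROI statistics of a %-difference image
#'
#' Mean and SD of the %-difference voxels inside the ROI. The SD is the
#' population SD (divide by n) by default; `sample_sd = TRUE` switches to
#' the n-1 denominator.
#'
#' @param diff_volume An `image_volume` from [percent_difference()].
#' @param roi_mask A `binary_mask`.
#' @param method_tag Label copied into the report row.
#' @param roi_label Label for the ROI column.
#' @param sample_sd Use the sample (n-1) SD instead of the population SD.
#' @return One-row `data.frame`: `method`, `roi`, `mean_pct_diff`,
#'   `sd_pct_diff`, `n_voxels`.
#' @export
roi_stats <- function(diff_volume, roi_mask, method_tag = NA_character_,
                      roi_label = NA_character_, sample_sd = FALSE) {
  stopifnot(inherits(diff_volume, "image_volume"), inherits(roi_mask, "binary_mask"))
  check_same_grid(diff_volume$grid, roi_mask$grid, "difference image and ROI")
  v <- diff_volume$data[roi_mask$values]
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0L) stop("empty ROI: no valid voxels")
  m <- mean(v)
  sd <- sqrt(sum((v - m)^2) / (if (sample_sd) max(n - 1L, 1L) else n))
  data.frame(method = method_tag, roi = roi_label,
             mean_pct_diff = m, sd_pct_diff = sd, n_voxels = n,
             stringsAsFactors = FALSE)
}

#' Line profile through a volume
#'
#' Trilinear interpolation along the segment from `start_point` to
#' `end_point` (mm) with the given step; positions outside the grid return
#' `NA`.
#'
#' @param volume An `image_volume`, `activity_volume` or `attenuation_map`.
#' @param start_point,end_point Physical endpoints, mm (length-3).
#' @param step Sampling step along the segment, mm.
#' @return `data.frame` with `position` (mm from `start_point`) and `value`.
#' @export
line_profile <- function(volume, start_point, end_point, step = 1) {
  data <- switch(class(volume)[1],
                 image_volume = volume$data,
                 activity_volume = volume$activity,
                 attenuation_map = volume$mu,
                 stop("unsupported volume type"))
  grid <- volume$grid
  len <- sqrt(sum((end_point - start_point)^2))
  pos <- seq(0, len, by = step)
  dir <- if (len > 0) (end_point - start_point) / len else c(0, 0, 0)
  pts <- outer(pos, dir) + rep(start_point, each = length(pos))
  f <- sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, `/`)
  n <- grid$shape
  val <- rep(NA_real_, length(pos))
  ok <- f[, 1] >= 0 & f[, 1] <= n[1] - 1 &
        f[, 2] >= 0 & f[, 2] <= n[2] - 1 &
        f[, 3] >= 0 & f[, 3] <= n[3] - 1
  if (any(ok)) {
    fo <- f[ok, , drop = FALSE]
    i0 <- pmin(floor(fo), rep(n - 2, each = nrow(fo)))
    i0 <- pmax(i0, 0)
    wf <- fo - i0
    gx <- i0[, 1] + 1L; gy <- i0[, 2] + 1L; gz <- i0[, 3] + 1L
    at <- function(ox, oy, oz)
      data[cbind(gx + ox, gy + oy, gz + oz)]
    wx <- wf[, 1]; wy <- wf[, 2]; wz <- wf[, 3]
    val[ok] <-
      at(0L, 0L, 0L) * (1 - wx) * (1 - wy) * (1 - wz) +
      at(1L, 0L, 0L) * wx * (1 - wy) * (1 - wz) +
      at(0L, 1L, 0L) * (1 - wx) * wy * (1 - wz) +
      at(1L, 1L, 0L) * wx * wy * (1 - wz) +
      at(0L, 0L, 1L) * (1 - wx) * (1 - wy) * wz +
      at(1L, 0L, 1L) * wx * (1 - wy) * wz +
      at(0L, 1L, 1L) * (1 - wx) * wy * wz +
      at(1L, 1L, 1L) * wx * wy * wz
  }
  data.frame(position = pos, value = val)
}

#' Choose evaluation slices from a label volume
#'
#' The heterogeneous slice is the axial middle of the rod region; the
#' homogeneous slice is the axial middle of the rod-free part of the water
#' compartment.
#'
#' @param label A `label_volume` on the evaluation grid.
#' @return List with `homogeneous` and `heterogeneous` slice indices.
#' @export
select_evaluation_slices <- function(label) {
  stopifnot(inherits(label, "label_volume"))
  spec <- label$spec
  if (is.null(spec)) stop("label volume carries no phantom spec")
  zs <- grid_axis(label$grid, 3)
  z_rod_mid <- spec$bottom_lid_thickness + spec$rod_length / 2
  z_top <- spec$outer_length - spec$top_lid_thickness
  z_hom_mid <- (spec$bottom_lid_thickness + spec$rod_length + z_top) / 2
  list(homogeneous = which.min(abs(zs - z_hom_mid)),
       heterogeneous = which.min(abs(zs - z_rod_mid)))
}
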