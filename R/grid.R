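# Voxel grids and volume containers.
#
# All physical positions are in millimetres. A grid is axis-aligned; the
# `origin` is the physical position of the centre of voxel (1,1,1) (0-based
# voxel (0,0,0)), and a voxel's spatial extent is the half-open box
# [centre - spacing/2, centre + spacing/2).

#' Create a voxel grid
#'
#' An axis-aligned metric voxel grid. Positions are in mm; `origin` is the
#' physical position of the centre of the first voxel, and each voxel's
#' extent is the half-open box `[centre - spacing/2, centre + spacing/2)`.
#'
#' @param shape Integer vector of length 3: voxel counts `(nx, ny, nz)`.
#' @param spacing Numeric vector of length 3: voxel spacing in mm; all > 0.
#' @param origin Numeric vector of length 3: centre of voxel (1,1,1) in mm.
#' @return An object of class `voxel_grid`.
#' @examples
#' voxel_grid(c(10, 10, 4), c(2.6, 2.6, 3.1))
#' @export
voxel_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(shape < 1L)) stop("grid shape must be positive")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) stop("grid spacing must be > 0")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' Centred voxel grid
#'
#' Convenience constructor for a grid whose x/y axes are centred on `centre`
#' and whose z axis starts at `z_start` (physical edge of the first slice).
#'
#' @param shape,spacing As in [voxel_grid()].
#' @param centre Transaxial centre (x, y) in mm.
#' @param z_start Physical position of the lower edge of the first slice, mm.
#' @return A `voxel_grid`.
#' @export
centred_grid <- function(shape, spacing, centre = c(0, 0), z_start = 0) {
  shape <- as.integer(shape)
  origin <- c(centre[1] - (shape[1] - 1) / 2 * spacing[1],
              centre[2] - (shape[2] - 1) / 2 * spacing[2],
              z_start + spacing[3] / 2)
  voxel_grid(shape, spacing, origin)
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d x %d x %d, spacing %.4g x %.4g x %.4g mm, origin (%.4g, %.4g, %.4g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Physical coordinates of voxel centres along one axis
#'
#' @param grid A `voxel_grid`.
#' @param axis Axis index (1 = x, 2 = y, 3 = z).
#' @return Numeric vector of voxel-centre coordinates in mm.
#' @export
grid_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

#' Physical bounding box of a grid
#'
#' @param grid A `voxel_grid`.
#' @return 2 x 3 matrix: rows are lower/upper box edges in mm.
#' @export
grid_bbox <- function(grid) {
  lo <- grid$origin - grid$spacing / 2
  hi <- grid$origin + (grid$shape - 0.5) * grid$spacing
  rbind(lower = lo, upper = hi)
}

#' Voxel volume in millilitres
#' @param grid A `voxel_grid`.
#' @return Volume of one voxel in ml (cm^3).
#' @export
voxel_ml <- function(grid) prod(grid$spacing) / 1000

same_grid <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) stop(sprintf("%s are not on the same grid", what))
  invisible(TRUE)
}

# ---- volume containers -----------------------------------------------------

#' Create an image volume
#'
#' A plain scalar image on a [voxel_grid()]. Used for MR channels, CT (HU),
#' activity (kBq/ml) and %-difference images.
#'
#' @param data 3-D numeric array matching `grid$shape`.
#' @param grid A `voxel_grid`.
#' @param units Optional unit string, kept as metadata.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, grid, units = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!identical(dim(data), as.integer(grid$shape)))
    stop("data dimensions do not match the grid")
  structure(list(grid = grid, data = data, units = units),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf("image_volume%s: ", if (is.null(x$units)) "" else paste0(" [", x$units, "]")))
  print(x$grid)
  cat(sprintf("  range %.4g .. %.4g\n", rng[1], rng[2]))
  invisible(x)
}

#' Create a binary mask
#'
#' @param values Logical 3-D array matching `grid$shape`.
#' @param grid A `voxel_grid`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  values <- array(as.logical(values), dim = dim(values))
  if (!identical(dim(values), as.integer(grid$shape)))
    stop("mask dimensions do not match the grid")
  structure(list(grid = grid, values = values), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("binary_mask: ")
  print(x$grid)
  cat(sprintf("  %d foreground voxels (%.3g ml)\n",
              sum(x$values), sum(x$values) * voxel_ml(x$grid)))
  invisible(x)
}

#' Create an attenuation map
#'
#' Per-voxel linear attenuation coefficients at 511 keV.
#'
#' @param mu 3-D numeric array of linear attenuation coefficients, cm^-1.
#' @param grid A `voxel_grid`.
#' @param method_tag One of `"CT_AC"`, `"PHANTOM_MRAC"`, `"STANDARD_MRAC"`,
#'   `"NOWALL_MRAC"`, `"GROUND_TRUTH"`.
#' @return An object of class `attenuation_map`.
#' @export
attenuation_map <- function(mu, grid,
                            method_tag = c("CT_AC", "PHANTOM_MRAC",
                                           "STANDARD_MRAC", "NOWALL_MRAC",
                                           "GROUND_TRUTH")) {
  method_tag <- match.arg(method_tag)
  stopifnot(inherits(grid, "voxel_grid"))
  if (!identical(dim(mu), as.integer(grid$shape)))
    stop("mu dimensions do not match the grid")
  if (any(!is.finite(mu)) || any(mu < 0))
    stop("attenuation coefficients must be finite and >= 0")
  structure(list(grid = grid, mu = mu, method_tag = method_tag),
            class = "attenuation_map")
}

#' @export
print.attenuation_map <- function(x, ...) {
  cat(sprintf("attenuation_map [%s]: ", x$method_tag))
  print(x$grid)
  cat(sprintf("  mu range %.4g .. %.4g cm^-1\n", min(x$mu), max(x$mu)))
  invisible(x)
}

#' Create an activity volume
#'
#' @param activity 3-D numeric array of activity concentration, kBq/ml; >= 0.
#' @param grid A `voxel_grid`.
#' @return An object of class `activity_volume`.
#' @export
activity_volume <- function(activity, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!identical(dim(activity), as.integer(grid$shape)))
    stop("activity dimensions do not match the grid")
  if (any(activity < 0)) stop("activity must be >= 0")
  structure(list(grid = grid, activity = activity), class = "activity_volume")
}

#' @export
print.activity_volume <- function(x, ...) {
  cat("activity_volume [kBq/ml]: ")
  print(x$grid)
  cat(sprintf("  range %.4g .. %.4g kBq/ml\n", min(x$activity), max(x$activity)))
  invisible(x)
}

#' Nearest-neighbour resampling onto another grid
#'
#' Resamples an axis-aligned volume or mask onto a target grid by
#' nearest-neighbour lookup of voxel centres (preserves binary labels, which
#' is why segmentation masks are moved between the MR and reconstruction
#' grids this way). Target voxels whose centres fall outside the source grid
#' receive `fill`.
#'
#' @param x An `image_volume`, `binary_mask`, `attenuation_map` or
#'   `activity_volume`.
#' @param target A `voxel_grid`.
#' @param fill Fill value for uncovered target voxels.
#' @return Object of the same class as `x`, on `target`.
#' @export
resample_nearest <- function(x, target, fill = 0) {
  src_grid <- x$grid
  data <- switch(class(x)[1],
                 image_volume = x$data,
                 binary_mask = x$values,
                 attenuation_map = x$mu,
                 activity_volume = x$activity,
                 stop("unsupported type"))
  out <- array(if (is.logical(data)) as.logical(fill) else fill,
               dim = target$shape)
  idx <- lapply(1:3, function(ax) {
    i <- round((grid_axis(target, ax) - src_grid$origin[ax]) / src_grid$spacing[ax]) + 1L
    i[i < 1L | i > src_grid$shape[ax]] <- NA_integer_
    i
  })
  vx <- which(!is.na(idx[[1]])); vy <- which(!is.na(idx[[2]])); vz <- which(!is.na(idx[[3]]))
  if (length(vx) && length(vy) && length(vz))
    out[vx, vy, vz] <- data[idx[[1]][vx], idx[[2]][vy], idx[[3]][vz]]
  switch(class(x)[1],
         image_volume = image_volume(out, target, units = x$units),
         binary_mask = binary_mask(out, target),
         attenuation_map = attenuation_map(out, target, method_tag = x$method_tag),
         activity_volume = activity_volume(out, target))
}
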