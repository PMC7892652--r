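# Slice-wise 2-D parallel-beam projector. A sparse system matrix (rays x
# transaxial voxels) is built once per geometry by sampling each ray at half
# a voxel pitch with bilinear interpolation (Joseph-style); all slices share
# the matrix, so projecting a volume is one sparse-dense product. Ray weights
# carry path length in mm; attenuation line integrals divide by 10 to match
# mu in cm^-1.

#' Parallel-beam projector for a voxel grid
#'
#' Builds the sparse system matrix for `n_angles` uniformly spaced view
#' angles over [0, pi) and `n_bins` radial bins of `bin_spacing` mm centred
#' on the grid's transaxial centre. The matrix maps a transaxial image
#' (column-major x-fastest) to line integrals in mm.
#'
#' @param grid A `voxel_grid`; projections are per z-slice.
#' @param n_angles Number of view angles.
#' @param n_bins Number of radial bins; default spans the grid width.
#' @param bin_spacing Radial bin spacing, mm; default = x voxel pitch.
#' @param step Ray sampling step, mm; default half the smaller in-plane
#'   voxel pitch.
#' @return An object of class `projector` holding the system matrix `A`
#'   (`n_angles * n_bins` rows), the geometry, and a subset cache.
#' @export
make_projector <- function(grid, n_angles = 48L, n_bins = NULL,
                           bin_spacing = NULL, step = NULL) {
  stopifnot(inherits(grid, "voxel_grid"), n_angles >= 1)
  nx <- grid$shape[1]; ny <- grid$shape[2]
  dx <- grid$spacing[1]; dy <- grid$spacing[2]
  if (is.null(bin_spacing)) bin_spacing <- dx
  if (is.null(n_bins)) n_bins <- nx
  if (is.null(step)) step <- min(dx, dy) / 2
  cx <- mean(grid_axis(grid, 1)); cy <- mean(grid_axis(grid, 2))
  s <- (seq_len(n_bins) - (n_bins + 1) / 2) * bin_spacing
  half_diag <- sqrt((nx * dx)^2 + (ny * dy)^2) / 2
  t <- seq(-half_diag, half_diag, by = step)
  angles <- (seq_len(n_angles) - 1) * pi / n_angles
  x0 <- grid$origin[1]; y0 <- grid$origin[2]

  ii <- vector("list", n_angles); jj <- ii; ww <- ii
  for (a in seq_len(n_angles)) {
    th <- angles[a]
    px <- cx + outer(-sin(th) * s, cos(th) * t, `+`)
    py <- cy + outer(cos(th) * s, sin(th) * t, `+`)
    fx <- (px - x0) / dx
    fy <- (py - y0) / dy
    ok <- fx >= 0 & fx <= nx - 1 & fy >= 0 & fy <= ny - 1
    if (!any(ok)) next
    ray <- ((a - 1L) * n_bins) + as.integer(row(px)[ok])
    fx <- fx[ok]; fy <- fy[ok]
    i0 <- pmin(floor(fx), nx - 2); wx <- fx - i0
    j0 <- pmin(floor(fy), ny - 2); wy <- fy - j0
    v00 <- i0 + j0 * nx + 1
    ii[[a]] <- c(ray, ray, ray, ray)
    jj[[a]] <- c(v00, v00 + 1, v00 + nx, v00 + nx + 1)
    ww[[a]] <- step * c((1 - wx) * (1 - wy), wx * (1 - wy),
                        (1 - wx) * wy, wx * wy)
  }
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                            dims = c(n_angles * n_bins, nx * ny))
  structure(list(A = A, grid = grid, n_angles = n_angles, n_bins = n_bins,
                 bin_spacing = bin_spacing, step = step, angles = angles,
                 cache = new.env(parent = emptyenv())),
            class = "projector")
}

#' @export
print.projector <- function(x, ...) {
  cat(sprintf("projector: %d angles x %d bins (%.3g mm), %d transaxial voxels, %.3g M nonzeros\n",
              x$n_angles, x$n_bins, x$bin_spacing,
              ncol(x$A), length(x$A@x) / 1e6))
  invisible(x)
}

# volume (nx,ny,nz) array -> (nx*ny, nz) matrix and back
as_slice_matrix <- function(vol3d) {
  d <- dim(vol3d)
  dim(vol3d) <- c(d[1] * d[2], d[3])
  vol3d
}

sinogram_new <- function(values, projector) {
  # values: (n_angles*n_bins, nz) matrix
  nz <- ncol(values)
  arr <- array(as.numeric(values),
               dim = c(projector$n_bins, projector$n_angles, nz))
  structure(list(values = arr, n_angles = projector$n_angles,
                 n_bins = projector$n_bins, n_slices = nz,
                 bin_spacing = projector$bin_spacing),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("sinogram: %d bins x %d angles x %d slices (bin %.3g mm), range %.4g .. %.4g\n",
              x$n_bins, x$n_angles, x$n_slices, x$bin_spacing,
              min(x$values), max(x$values)))
  invisible(x)
}

sino_as_matrix <- function(sino) {
  v <- sino$values
  dim(v) <- c(sino$n_bins * sino$n_angles, sino$n_slices)
  v
}

#' Attenuation factors of a mu-map
#'
#' `exp(-integral of mu)` along every ray; values in (0, 1].
#'
#' @param mu An `attenuation_map` on the projector's grid.
#' @param projector A [make_projector()] object.
#' @return A `sinogram` of attenuation factors.
#' @export
attenuation_factors <- function(mu, projector) {
  stopifnot(inherits(mu, "attenuation_map"), inherits(projector, "projector"))
  check_same_grid(mu$grid, projector$grid, "mu-map and projector grid")
  li <- as.matrix(projector$A %*% as_slice_matrix(mu$mu)) / 10  # mm -> cm
  sinogram_new(exp(-li), projector)
}

#' Attenuated forward projection
#'
#' Emission line integrals attenuated by the true mu-map:
#' `y = (ray transform of activity) * exp(-integral mu)`, per slice. With
#' `poisson = TRUE` the sinogram is scaled to expected counts, Poisson
#' sampled, and scaled back (deterministic under `seed`).
#'
#' @param activity An `activity_volume`.
#' @param mu_true An `attenuation_map` on the same grid (the physical truth).
#' @param projector A [make_projector()] object on the same grid.
#' @param poisson Add Poisson counting noise?
#' @param counts_per_unit Expected counts per sinogram unit when sampling.
#' @param seed Integer seed for the Poisson draw.
#' @return A `sinogram`.
#' @export
forward_project <- function(activity, mu_true, projector,
                            poisson = FALSE, counts_per_unit = 0.2,
                            seed = 1L) {
  stopifnot(inherits(activity, "activity_volume"),
            inherits(mu_true, "attenuation_map"),
            inherits(projector, "projector"))
  check_same_grid(activity$grid, projector$grid, "activity and projector grid")
  check_same_grid(mu_true$grid, projector$grid, "mu-map and projector grid")
  proj <- as.matrix(projector$A %*% as_slice_matrix(activity$activity))
  li <- as.matrix(projector$A %*% as_slice_matrix(mu_true$mu)) / 10
  y <- proj * exp(-li)
  if (poisson) {
    y <- with_seed(seed,
                   matrix(stats::rpois(length(y), y * counts_per_unit),
                          nrow(y)) / counts_per_unit)
  }
  sinogram_new(y, projector)
}
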