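# Parametric model of the 3-D-printed cylindrical PET/MRI phantom and its
# voxelization. The phantom is a water-fillable cylinder with a polymer
# shell, lids of unequal thickness, and a Jaszczak-style array of solid
# polymer rods of graded diameters attached to the bottom lid.
#
# Coordinate convention: right-handed, z along the cylinder axis, z = 0 at
# the outer bottom face, the axis through x = y = 0. All lengths in mm.

#' Create a phantom specification
#'
#' All dimensions in mm. Derived quantities (`inner_diameter`,
#' `inner_length`) are computed from the others and validated if supplied.
#' Rod positions are given explicitly so that any layout can be used;
#' [jaszczak_rod_layout()] produces the default sector arrangement.
#'
#' @param outer_length,outer_diameter Outer cylinder dimensions, mm.
#' @param shell_thickness Cylinder shell (wall) thickness, mm.
#' @param top_lid_thickness,bottom_lid_thickness Lid thicknesses, mm.
#' @param rod_length Axial rod length, mm; rods extend upward from the inner
#'   face of the bottom lid.
#' @param rod_diameters Nominal rod diameters, mm (the distinct sizes).
#' @param rod_centers `data.frame` with columns `x`, `y`, `diameter` (mm),
#'   one row per rod; every `diameter` must appear in `rod_diameters`.
#' @param inner_diameter,inner_length Optional; validated against the
#'   derived values if given.
#' @return An object of class `phantom_spec`.
#' @seealso [default_phantom_spec()], [rasterize()]
#' @export
phantom_spec <- function(outer_length, outer_diameter, shell_thickness,
                         top_lid_thickness, bottom_lid_thickness,
                         rod_length = 0, rod_diameters = numeric(0),
                         rod_centers = NULL,
                         inner_diameter = NULL, inner_length = NULL) {
  derived_d <- outer_diameter - 2 * shell_thickness
  derived_l <- outer_length - top_lid_thickness - bottom_lid_thickness
  if (!is.null(inner_diameter) && abs(inner_diameter - derived_d) > 1e-9)
    stop("inner_diameter inconsistent with outer_diameter and shell_thickness")
  if (!is.null(inner_length) && abs(inner_length - derived_l) > 1e-9)
    stop("inner_length inconsistent with outer_length and lid thicknesses")
  if (derived_d <= 0 || derived_l <= 0) stop("degenerate inner compartment")
  if (is.null(rod_centers))
    rod_centers <- data.frame(x = numeric(0), y = numeric(0), diameter = numeric(0))
  stopifnot(all(c("x", "y", "diameter") %in% names(rod_centers)))
  if (nrow(rod_centers) > 0) {
    if (!all(rod_centers$diameter %in% rod_diameters))
      stop("rod_centers uses a diameter not listed in rod_diameters")
    if (rod_length <= 0 || rod_length > derived_l)
      stop("rod_length must lie within the inner compartment")
    r <- sqrt(rod_centers$x^2 + rod_centers$y^2)
    if (any(r + rod_centers$diameter / 2 >= derived_d / 2 - 1e-9))
      stop("all rods must lie strictly inside the inner compartment")
    if (nrow(rod_centers) > 1) {
      dd <- as.matrix(stats::dist(rod_centers[, c("x", "y")]))
      rr <- outer(rod_centers$diameter, rod_centers$diameter, `+`) / 2
      diag(dd) <- Inf
      if (any(dd < rr - 1e-9)) stop("rods overlap")
    }
  }
  structure(list(
    outer_length = outer_length, outer_diameter = outer_diameter,
    shell_thickness = shell_thickness,
    top_lid_thickness = top_lid_thickness,
    bottom_lid_thickness = bottom_lid_thickness,
    inner_diameter = derived_d, inner_length = derived_l,
    rod_length = rod_length, rod_diameters = rod_diameters,
    rod_centers = rod_centers), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "phantom_spec: outer %g mm x %g mm diameter, shell %g mm,\n",
    "  lids %g mm (top) / %g mm (bottom), inner %g mm diameter x %g mm,\n",
    "  %d rods (%g mm long), diameters {%s} mm\n"),
    x$outer_length, x$outer_diameter, x$shell_thickness,
    x$top_lid_thickness, x$bottom_lid_thickness,
    x$inner_diameter, x$inner_length,
    nrow(x$rod_centers), x$rod_length,
    paste(x$rod_diameters, collapse = ", ")))
  invisible(x)
}

#' Jaszczak-style sector layout for the rod array
#'
#' One 60-degree sector per rod diameter, rods on a triangular lattice with
#' centre-to-centre pitch of two diameters (one diameter edge-to-edge, as in
#' SPECT/MRI resolution phantoms). Rods keep `sector_clearance` from the
#' sector boundaries (which also guarantees no cross-sector overlap) and
#' `wall_clearance` from the compartment wall.
#'
#' @param inner_radius Inner compartment radius, mm.
#' @param diameters Rod diameters, mm; one sector each (at most six).
#' @param wall_clearance Minimum rod-edge distance to the compartment wall, mm.
#' @param sector_clearance Minimum rod-edge distance to the sector boundary, mm.
#' @return `data.frame` with columns `x`, `y`, `diameter` (mm).
#' @export
jaszczak_rod_layout <- function(inner_radius = 120,
                                diameters = c(5, 10, 13, 17, 22, 28),
                                wall_clearance = 8, sector_clearance = 2) {
  stopifnot(length(diameters) <= 6)
  out <- list()
  for (k in seq_along(diameters)) {
    d <- diameters[k]
    pitch <- 2 * d
    rmax <- inner_radius - wall_clearance - d / 2
    half <- d / 2 + sector_clearance
    pts <- list()
    i <- 0
    repeat {
      u <- half * 2 + i * pitch * sqrt(3) / 2  # first row clear of the apex
      if (u > rmax) break
      voff <- (i %% 2) * pitch / 2
      jmax <- ceiling(rmax / pitch)
      v <- voff + (-jmax:jmax) * pitch
      keep <- (u * 0.5 - abs(v) * sqrt(3) / 2 >= half) & (u^2 + v^2 <= rmax^2)
      if (any(keep)) pts[[length(pts) + 1]] <- cbind(u = u, v = v[keep])
      i <- i + 1
    }
    if (length(pts) == 0) next
    uv <- do.call(rbind, pts)
    phi <- ((k - 1) * 60 + 30) * pi / 180  # sector bisector angle
    out[[k]] <- data.frame(
      x = uv[, "u"] * cos(phi) - uv[, "v"] * sin(phi),
      y = uv[, "u"] * sin(phi) + uv[, "v"] * cos(phi),
      diameter = d)
  }
  do.call(rbind, out)
}

#' Default phantom specification
#'
#' The dimensions of the polymer phantom: 252 mm outer diameter with a 6 mm
#' shell, a 10 mm top and 5 mm bottom lid enclosing an inner compartment of
#' 240 mm diameter and 185 mm length, and 50 mm rods with diameters 5, 10,
#' 13, 17, 22 and 28 mm arranged in sectors.
#'
#' The published dimension set is slightly over-determined (a 19 cm outer
#' length cannot hold an 18.5 cm compartment between 10 + 5 mm lids); since
#' the water compartment and lid thicknesses drive the PET quantification,
#' those are kept exact and the outer length is the derived 200 mm.
#'
#' @param rod_centers Optional replacement rod layout
#'   (`data.frame(x, y, diameter)`); defaults to [jaszczak_rod_layout()].
#' @return A `phantom_spec`.
#' @export
default_phantom_spec <- function(rod_centers = jaszczak_rod_layout()) {
  phantom_spec(outer_length = 200, outer_diameter = 252, shell_thickness = 6,
               top_lid_thickness = 10, bottom_lid_thickness = 5,
               rod_length = 50, rod_diameters = c(5, 10, 13, 17, 22, 28),
               rod_centers = rod_centers)
}

#' Analytic component volumes of a phantom
#'
#' Closed-form volumes (ml) of the water compartment and of the polymer
#' (shell + lids + rods), used as rasterization oracles.
#'
#' @param spec A `phantom_spec`.
#' @return Named list with `water_ml` and `material_ml`.
#' @export
phantom_analytic_volumes <- function(spec) {
  ri <- spec$inner_diameter / 2
  ro <- spec$outer_diameter / 2
  rod <- sum(pi * (spec$rod_centers$diameter / 2)^2 * spec$rod_length)
  water <- pi * ri^2 * spec$inner_length - rod
  shell <- pi * (ro^2 - ri^2) * spec$inner_length
  lids <- pi * ro^2 * (spec$top_lid_thickness + spec$bottom_lid_thickness)
  list(water_ml = water / 1000, material_ml = (shell + lids + rod) / 1000)
}

# label lookup: rows = 2-D class (0 outside, 1 shell annulus, 2 inner, 3 rod),
# cols = z class (0 outside, 1 lid, 2 inner rod zone, 3 inner above rods)
.label_lut <- matrix(c(0L, 0L, 0L, 0L,
                       0L, 1L, 1L, 1L,
                       0L, 1L, 2L, 2L,
                       0L, 1L, 1L, 2L),
                     nrow = 4, byrow = TRUE)

#' Voxelize a phantom onto a grid
#'
#' Anti-aliased voxelization: each voxel is probed on a `subsampling`^3
#' sub-grid; the voxel label (0 background, 1 material, 2 water) is the
#' majority vote, and the per-voxel material/water volume fractions are kept
#' alongside for partial-volume simulation.
#'
#' @param spec A `phantom_spec`.
#' @param grid A `voxel_grid` fully containing the phantom.
#' @param subsampling Sub-voxel samples per axis (>= 1).
#' @return An object of class `label_volume`: list with `grid`, `labels`
#'   (integer array in {0,1,2}), `frac_material`, `frac_water` (arrays of
#'   volume fractions), `spec` and `subsampling`.
#' @export
rasterize <- function(spec, grid, subsampling = 3L) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(grid, "voxel_grid"))
  subsampling <- as.integer(subsampling)
  if (subsampling < 1L) stop("subsampling must be >= 1")
  ro <- spec$outer_diameter / 2
  bb <- grid_bbox(grid)
  if (bb["lower", 1] > -ro || bb["upper", 1] < ro ||
      bb["lower", 2] > -ro || bb["upper", 2] < ro ||
      bb["lower", 3] > 0 || bb["upper", 3] < spec$outer_length)
    stop("grid too small: it does not contain the phantom bounding box")

  ri <- spec$inner_diameter / 2
  zb <- spec$bottom_lid_thickness
  zt <- spec$outer_length - spec$top_lid_thickness
  zr <- zb + spec$rod_length
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  xs <- grid_axis(grid, 1); ys <- grid_axis(grid, 2); zs <- grid_axis(grid, 3)
  offs <- lapply(1:3, function(ax)
    ((seq_len(subsampling) - (subsampling + 1) / 2) / subsampling) * grid$spacing[ax])

  c1 <- array(0, dim = grid$shape)  # material sample counts
  c2 <- array(0, dim = grid$shape)  # water sample counts
  rods <- spec$rod_centers
  for (ox in offs[[1]]) for (oy in offs[[2]]) {
    x <- xs + ox; y <- ys + oy
    r2 <- outer(x^2, y^2, `+`)
    cls <- matrix(0L, nx, ny)
    cls[r2 < ro^2] <- 1L
    cls[r2 < ri^2] <- 2L
    for (rod in seq_len(nrow(rods))) {
      rx <- rods$x[rod]; ry <- rods$y[rod]; rr <- rods$diameter[rod] / 2
      ix <- which(abs(x - rx) <= rr); iy <- which(abs(y - ry) <= rr)
      if (!length(ix) || !length(iy)) next
      inrod <- outer((x[ix] - rx)^2, (y[iy] - ry)^2, `+`) < rr^2
      blk <- cls[ix, iy, drop = FALSE]
      blk[inrod & blk == 2L] <- 3L
      cls[ix, iy] <- blk
    }
    for (oz in offs[[3]]) {
      z <- zs + oz
      zc <- integer(nz)                       # 0 outside
      zc[z >= 0 & z < spec$outer_length] <- 1L  # lid by default
      zc[z >= zb & z < zr] <- 2L              # inner, rod zone
      zc[z >= zr & z < zt] <- 3L              # inner, above rods
      for (zval in 1:3) {
        sl <- which(zc == zval)
        if (!length(sl)) next
        lab2d <- matrix(.label_lut[cbind(as.vector(cls) + 1L, zval + 1L)],
                        nx, ny)
        c1[, , sl] <- c1[, , sl] + as.vector(lab2d == 1L)
        c2[, , sl] <- c2[, , sl] + as.vector(lab2d == 2L)
      }
    }
  }
  s3 <- subsampling^3
  m0 <- s3 - c1 - c2
  lab <- max.col(cbind(as.vector(m0), as.vector(c1), as.vector(c2)),
                 ties.method = "first") - 1L
  structure(list(grid = grid,
                 labels = array(as.integer(lab), dim = grid$shape),
                 frac_material = c1 / s3,
                 frac_water = c2 / s3,
                 spec = spec,
                 subsampling = subsampling),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume: ")
  print(x$grid)
  v <- voxel_ml(x$grid)
  cat(sprintf("  material %.4g ml, water %.4g ml (majority labels; subsampling %d)\n",
              sum(x$labels == 1L) * v, sum(x$labels == 2L) * v, x$subsampling))
  invisible(x)
}
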