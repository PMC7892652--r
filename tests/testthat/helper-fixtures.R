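# Shared fixtures: everything is generated in code at test time.

# a small phantom (same topology as the default, desk-sized) for fast tests
small_phantom <- function(rods = TRUE) {
  centers <- if (rods)
    data.frame(x = c(-25, 25, 0), y = c(-20, -20, 28), diameter = c(10, 14, 20))
  else NULL
  phantom_spec(outer_length = 80, outer_diameter = 100, shell_thickness = 5,
               top_lid_thickness = 6, bottom_lid_thickness = 4,
               rod_length = 30, rod_diameters = c(10, 14, 20),
               rod_centers = centers)
}

small_grid <- function(spacing = c(2, 2, 2), margin = 12) {
  sp <- small_phantom()
  n <- ceiling((c(sp$outer_diameter, sp$outer_diameter, sp$outer_length) +
                  2 * margin) / spacing)
  n <- n + n %% 2  # even counts keep the grid symmetric about the axis
  centred_grid(n, spacing, z_start = -margin)
}

# uniform disk activity/mu pair on a two-slice grid (closed-form oracles)
disk_phantom <- function(n = 96, spacing = 2.6, radius = 80,
                         activity = 10, mu = 0.096) {
  grid <- centred_grid(c(n, n, 2L), c(spacing, spacing, 3.1), z_start = 0)
  r2 <- outer(grid_axis(grid, 1)^2, grid_axis(grid, 2)^2, `+`)
  disk <- array(r2 < radius^2, dim = grid$shape)
  list(grid = grid,
       activity = activity_volume(activity * disk, grid),
       mu = attenuation_map(mu * disk, grid, "GROUND_TRUTH"),
       radius = radius)
}

# label volume with hand-set fractions (bypasses rasterize)
manual_label <- function(frac_water, frac_material, grid) {
  labels <- array(0L, dim = grid$shape)
  labels[frac_material >= pmax(1 - frac_water - frac_material, frac_water) &
           frac_material > 0] <- 1L
  labels[frac_water > pmax(1 - frac_water - frac_material, frac_material)] <- 2L
  structure(list(grid = grid, labels = labels,
                 frac_material = frac_material, frac_water = frac_water,
                 spec = NULL, subsampling = 1L),
            class = "label_volume")
}

# a tiny end-to-end configuration (coarse grids, few angles) for smoke and
# determinism tests
tiny_config <- function(...) {
  experiment_config(
    phantom = small_phantom(),
    dixon = dixon_sim_params(psf_fwhm = 2, slice_psf_fwhm = 2,
                             swap_patch_count = 1L),
    dixon_grid = centred_grid(c(44L, 52L, 40L), c(3.1, 2.6, 2.6),
                              z_start = -12),
    recon_grid = centred_grid(c(64L, 64L, 24L), c(4.18, 4.18, 4),
                              z_start = -4),
    n_angles = 24L,
    recon = recon_params(iterations = 2L, subsets = 12L, postfilter_fwhm = 5),
    subsampling = 2L,
    ...)
}
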