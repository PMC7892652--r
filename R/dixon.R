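# Two-point Dixon MR simulation of the polymer phantom.
#
# The polymer gives a gradient-echo signal of about one third of the water
# signal, with its main 1H resonance at 3.5 ppm; water sits at ~4.8 ppm, so
# the chemical-shift difference the vendor's fat/water recombination sees is
# only ~1.3 ppm. At the product echo times (1.23/2.46 ms at ~123 MHz) this
# gives partial intra-voxel dephasing at material/water borders — the "fat"
# contrast the segmentation exploits — while pure-polymer voxels end up in
# the water image.

GYROMAGNETIC_MHZ_PER_T <- 42.576

#' Dixon simulation parameters
#'
#' Defaults emulate the product two-point Dixon acquisition on a 3 T system
#' (Larmor frequency ~123.2 MHz): echo times 1.23/2.46 ms, water at 4.8 ppm,
#' polymer main peak at 3.5 ppm, polymer amplitude one third of water.
#' Intensities are scanner-arbitrary units, scaled so that the published
#' segmentation thresholds (100 / 400 / 10 a.u.) are meaningful:
#' water = 1000 a.u., polymer ~ 333 a.u.
#'
#' @param te1,te2 Echo times, ms (`te2 > te1 > 0`); TE1 is the
#'   opposed-phase echo, TE2 the in-phase echo.
#' @param field_strength Static field, T (default 2.894 T, the actual field
#'   of a "3 T" PET/MR system, giving ~123.2 MHz).
#' @param water_shift,polymer_shift Chemical shifts, ppm.
#' @param water_signal Water amplitude, a.u.
#' @param polymer_relative_signal Polymer amplitude relative to water
#'   (T1/T2 weighting folded in; the polymer's T1 = 194 ms and T2 = 32 ms are
#'   kept as metadata).
#' @param polymer_t1,polymer_t2 Polymer relaxation times, ms (metadata).
#' @param bias_min Multiplicative receive/excitation bias-field value at the
#'   phantom centre (radial model `B(r) = 1 - (1 - bias_min) (1 - (r/R)^2)`,
#'   R the inner radius); 1 disables the bias field.
#' @param bias_radius Radius R of the bias model, mm; `NULL` uses the
#'   phantom's inner radius.
#' @param swap_patch_count,swap_patch_radius Number and radius (mm) of
#'   spherical tissue-swap-like patches inside the material, in which the
#'   fat and water channel values are exchanged.
#' @param psf_fwhm In-plane point-spread-function FWHM in pixels (applied to
#'   the complex signal), emulating the effective resolution of the product
#'   Dixon images (k-space apodisation, partial Fourier and interpolation).
#'   The default is calibrated so that the low-threshold object mask
#'   overestimates the true extent by about one voxel — the reported
#'   behaviour that the segmentation's 1-voxel erosion compensates. 0
#'   disables.
#' @param slice_psf_fwhm Slice-profile FWHM in slices (blur along the
#'   slice-select axis; overlapping profiles with zero gap make the apparent
#'   extent spill across slices — the direction the material overestimation
#'   is most pronounced in). 0 disables.
#' @param noise_sigma Standard deviation of the complex Gaussian noise per
#'   quadrature component, a.u. (magnitudes become Rician); default
#'   `water_signal / 40`, i.e. SNR 40 in water. 0 disables noise.
#' @param seed Integer seed; the simulation is bit-reproducible under a
#'   fixed seed.
#' @param slice_axis Axis index (1-3) of the slice-select direction. The
#'   product MR-AC Dixon is acquired with the slice normal perpendicular to
#'   the phantom axis, so the default is axis 1 (x).
#' @return An object of class `dixon_sim_params`.
#' @export
dixon_sim_params <- function(te1 = 1.23, te2 = 2.46, field_strength = 2.894,
                             water_shift = 4.8, polymer_shift = 3.5,
                             water_signal = 1000,
                             polymer_relative_signal = 1 / 3,
                             polymer_t1 = 194, polymer_t2 = 32,
                             bias_min = 0.7, bias_radius = NULL,
                             swap_patch_count = 3L, swap_patch_radius = 8,
                             psf_fwhm = 4, slice_psf_fwhm = 4,
                             noise_sigma = water_signal / 40,
                             seed = 1L, slice_axis = 1L) {
  stopifnot(te2 > te1, te1 > 0,
            polymer_relative_signal > 0, polymer_relative_signal <= 1,
            bias_min > 0, bias_min <= 1, noise_sigma >= 0, psf_fwhm >= 0,
            slice_psf_fwhm >= 0, slice_axis %in% 1:3)
  structure(as.list(environment()), class = "dixon_sim_params")
}

# run `expr` with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

radial_bias_field <- function(grid, bias_min, radius) {
  r2 <- outer(grid_axis(grid, 1)^2, grid_axis(grid, 2)^2, `+`)
  b2d <- 1 - (1 - bias_min) * pmax(1 - r2 / radius^2, 0)
  array(b2d, dim = grid$shape)  # constant along z
}

#' Simulate a two-point Dixon study
#'
#' Per voxel, the water fraction `w` and polymer fraction `p` come from the
#' anti-aliased label fractions (border voxels have 0 < w, p < 1). The
#' complex gradient-echo signal at echo time TE is
#' `S(TE) = B(x) (w W exp(i 2 pi f_w TE) + p P exp(i 2 pi f_p TE))`
#' with `W` the water amplitude, `P` the polymer amplitude and `f` the
#' chemical-shift frequency; `B(x)` is the radial bias field. Complex
#' Gaussian noise is added per echo before taking magnitudes (Rician), so
#' `opposed_phase = |S(te1)|`, `in_phase = |S(te2)|`, and the two-point
#' magnitude recombination gives `water = (IP + OP) / 2`,
#' `fat = |IP - OP| / 2`. Tissue-swap-like artifacts exchange the fat and
#' water values at material voxels inside random spherical patches.
#'
#' @param label A `label_volume` from [rasterize()].
#' @param params A `dixon_sim_params`.
#' @return An object of class `dixon_study`: list of `image_volume`s
#'   `in_phase`, `opposed_phase`, `fat`, `water`, plus `grid` and `params`.
#' @export
simulate_dixon <- function(label, params = dixon_sim_params()) {
  stopifnot(inherits(label, "label_volume"), inherits(params, "dixon_sim_params"))
  grid <- label$grid
  w <- label$frac_water
  p <- label$frac_material
  radius <- params$bias_radius
  if (is.null(radius)) {
    radius <- if (!is.null(label$spec)) label$spec$inner_diameter / 2 else
      max(sqrt(outer(grid_axis(grid, 1)^2, grid_axis(grid, 2)^2, `+`)[
        apply(label$labels > 0, c(1, 2), any)]), 1)
  }
  B <- radial_bias_field(grid, params$bias_min, radius)
  W <- params$water_signal
  P <- params$polymer_relative_signal * W
  larmor_hz <- GYROMAGNETIC_MHZ_PER_T * 1e6 * params$field_strength
  fw <- params$water_shift * 1e-6 * larmor_hz
  fp <- params$polymer_shift * 1e-6 * larmor_hz

  psf_sigma <- rep(params$psf_fwhm / (2 * sqrt(2 * log(2))), 3)
  psf_sigma[params$slice_axis] <- params$slice_psf_fwhm / (2 * sqrt(2 * log(2)))
  echo_magnitude <- function(te_ms, noise_sigma) {
    te <- te_ms / 1000
    re <- B * (w * W * cos(2 * pi * fw * te) + p * P * cos(2 * pi * fp * te))
    im <- B * (w * W * sin(2 * pi * fw * te) + p * P * sin(2 * pi * fp * te))
    if (any(psf_sigma > 0)) {
      re <- gaussian_smooth(re, psf_sigma)
      im <- gaussian_smooth(im, psf_sigma)
    }
    if (noise_sigma > 0) {
      re <- re + stats::rnorm(length(re), sd = noise_sigma)
      im <- im + stats::rnorm(length(im), sd = noise_sigma)
    }
    sqrt(re^2 + im^2)
  }

  res <- with_seed(params$seed, {
    op <- echo_magnitude(params$te1, params$noise_sigma)
    ip <- echo_magnitude(params$te2, params$noise_sigma)
    water <- (ip + op) / 2
    fat <- abs(ip - op) / 2
    if (params$swap_patch_count > 0) {
      mat_idx <- which(label$labels == 1L)
      if (length(mat_idx)) {
        centres <- sample(mat_idx, min(params$swap_patch_count, length(mat_idx)))
        xs <- grid_axis(grid, 1); ys <- grid_axis(grid, 2); zs <- grid_axis(grid, 3)
        d <- grid$shape
        for (ci in centres) {
          i <- ((ci - 1) %% d[1]) + 1
          j <- ((ci - 1) %/% d[1]) %% d[2] + 1
          k <- ((ci - 1) %/% (d[1] * d[2])) + 1
          rr <- params$swap_patch_radius
          bx <- which(abs(xs - xs[i]) <= rr)
          by <- which(abs(ys - ys[j]) <= rr)
          bz <- which(abs(zs - zs[k]) <= rr)
          d2 <- outer(outer((xs[bx] - xs[i])^2, (ys[by] - ys[j])^2, `+`),
                      (zs[bz] - zs[k])^2, `+`)
          sel <- d2 <= rr^2 & label$labels[bx, by, bz] == 1L
          fb <- fat[bx, by, bz]; wb <- water[bx, by, bz]
          tmp <- fb[sel]; fb[sel] <- wb[sel]; wb[sel] <- tmp
          fat[bx, by, bz] <- fb; water[bx, by, bz] <- wb
        }
      }
    }
    list(ip = ip, op = op, fat = fat, water = water)
  })
  structure(list(grid = grid,
                 in_phase = image_volume(res$ip, grid, "a.u."),
                 opposed_phase = image_volume(res$op, grid, "a.u."),
                 fat = image_volume(res$fat, grid, "a.u."),
                 water = image_volume(res$water, grid, "a.u."),
                 params = params),
            class = "dixon_study")
}

#' @export
print.dixon_study <- function(x, ...) {
  cat("dixon_study (in_phase / opposed_phase / fat / water): ")
  print(x$grid)
  invisible(x)
}
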