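# Segmentation masks and attenuation-map construction.

toy_volume <- function() {
  # 7x7x3 array: central 5x5x3 block bright (500), background 50
  a <- array(50, dim = c(7, 7, 3))
  a[2:6, 2:6, 1:3] <- 500
  image_volume(a, voxel_grid(c(7L, 7L, 3L), c(1, 1, 1)))
}

test_that("total-phantom mask follows the threshold/close/LCC/erode recipe", {
  # hand-executed oracle: threshold keeps the 5x5x3 block; closing leaves the
  # box unchanged; it is the only component; a 1-voxel erosion (array border
  # counts as background) leaves the central 3x3x1 block
  m <- total_phantom_mask(toy_volume(), segmentation_params(closing_radius = 1L))
  expected <- array(FALSE, dim = c(7, 7, 3))
  expected[3:5, 3:5, 2] <- TRUE
  expect_identical(m$values, expected)
})

test_that("an all-background volume yields an empty-mask error", {
  v <- image_volume(array(0, dim = c(5, 5, 2)),
                    voxel_grid(c(5L, 5L, 2L), c(1, 1, 1)))
  expect_error(total_phantom_mask(v), "empty phantom mask")
})

test_that("stray bright voxels are removed by the largest-component step", {
  v <- toy_volume()
  v$data[1, 1, 1] <- 900  # isolated artefact at the FOV corner
  m <- total_phantom_mask(v, segmentation_params(closing_radius = 1L))
  expect_false(m$values[1, 1, 1])
  expect_true(m$values[4, 4, 2])
})

test_that("fat-enhanced subtraction removes border voxels from the water mask", {
  grid <- voxel_grid(c(4L, 1L, 1L), c(1, 1, 1))
  op <- image_volume(array(c(1000, 1000, 333, 50), dim = c(4, 1, 1)), grid)
  fat <- image_volume(array(c(200, 0, 0, 0), dim = c(4, 1, 1)), grid)
  m <- water_mask(op, fat, segmentation_params(closing_radius = 0L),
                  slice_axis = 1L)
  # 1000 - 4*200 = 200 < 400 -> excluded despite bright opposed-phase
  expect_false(m$values[1, 1, 1])
  # clean water voxel: included
  expect_true(m$values[2, 1, 1])
  # interior polymer (333 < 400) and background: excluded
  expect_false(m$values[3, 1, 1])
  expect_false(m$values[4, 1, 1])
})

test_that("filtered fat below the floor is zeroed before subtraction", {
  # voxels along the slice axis so the in-plane smoothing cannot mix them
  grid <- voxel_grid(c(1L, 1L, 2L), c(1, 1, 1))
  op <- image_volume(array(c(410, 410), dim = c(1, 1, 2)), grid)
  fat <- image_volume(array(c(9, 40), dim = c(1, 1, 2)), grid)
  m <- water_mask(op, fat, segmentation_params(closing_radius = 0L),
                  slice_axis = 3L)
  expect_true(m$values[1, 1, 1])    # 9 < floor -> not subtracted
  expect_false(m$values[1, 1, 2])   # 410 - 160 = 250 < 400
})

test_that("mask algebra: material = total minus water, disjoint, union = total", {
  lab <- rasterize(small_phantom(), small_grid(), 2L)
  dx <- simulate_dixon(lab, dixon_sim_params(noise_sigma = 0))
  total <- total_phantom_mask(dx$opposed_phase)
  water <- water_mask(dx$opposed_phase, dx$fat)
  mat <- material_mask(total, water)
  expect_false(any(mat$values & water$values))
  expect_true(all((mat$values | (water$values & total$values)) == total$values))
  # water == total -> empty material
  expect_equal(sum(material_mask(total, total)$values), 0L)
  # subtraction never goes negative: water voxels outside total are just absent
  expect_true(all(!mat$values[!total$values]))
})

test_that("raising thresholds never grows the masks", {
  lab <- rasterize(small_phantom(), small_grid(), 2L)
  dx <- simulate_dixon(lab, dixon_sim_params(noise_sigma = 0))
  p_lo <- segmentation_params()
  p_hi <- segmentation_params(phantom_threshold = 200, water_threshold = 600)
  t_lo <- total_phantom_mask(dx$opposed_phase, p_lo)
  t_hi <- total_phantom_mask(dx$opposed_phase, p_hi)
  expect_true(all(t_lo$values[t_hi$values]))
  w_lo <- water_mask(dx$opposed_phase, dx$fat, p_lo)
  w_hi <- water_mask(dx$opposed_phase, dx$fat, p_hi)
  expect_true(all(w_lo$values[w_hi$values]))
})

test_that("mu assignment matches the published coefficients per compartment", {
  grid <- voxel_grid(c(3L, 1L, 1L), c(1, 1, 1))
  total <- binary_mask(array(c(TRUE, TRUE, FALSE), dim = c(3, 1, 1)), grid)
  water <- binary_mask(array(c(TRUE, FALSE, FALSE), dim = c(3, 1, 1)), grid)
  pm <- build_phantom_mrac(total, water)
  expect_equal(as.vector(pm$mu), c(0.096, 0.1037, 0))
  expect_equal(pm$method_tag, "PHANTOM_MRAC")
  nw <- build_nowall_mrac(total, water)
  expect_equal(as.vector(nw$mu), c(0.096, 0, 0))
  # phantom - nowall differs exactly on the material mask
  dmu <- pm$mu - nw$mu
  expect_identical(dmu != 0, total$values & !water$values)
})

test_that("standard map dilates the object and assigns soft tissue", {
  grid <- voxel_grid(c(5L, 1L, 1L), c(1, 1, 1))
  total <- binary_mask(array(c(FALSE, FALSE, TRUE, FALSE, FALSE),
                             dim = c(5, 1, 1)), grid)
  st <- build_standard_mrac(total)
  expect_equal(as.vector(st$mu), c(0, 0.1, 0.1, 0.1, 0))
  expect_equal(st$method_tag, "STANDARD_MRAC")
})

test_that("bilinear CT scaling hits the anchor points and is monotone", {
  expect_equal(ct_to_mu(0), 0.096)
  expect_equal(ct_to_mu(-1000), 0)
  # continuity at the break
  bp <- bilinear_params()
  lo <- ct_to_mu(bp$break_hu - 1e-9)
  hi <- ct_to_mu(bp$break_hu + 1e-9)
  expect_equal(lo, hi, tolerance = 1e-9)
  hu <- seq(-1100, 3000, by = 7)
  expect_true(all(diff(ct_to_mu(hu)) >= 0))
  expect_true(all(ct_to_mu(hu) >= 0))
  # material round trip through the inverse
  expect_equal(ct_to_mu(hu_for_mu(0.1037)), 0.1037)
  expect_equal(ct_to_mu(hu_for_mu(0.05)), 0.05)
})

test_that("phantom MR-AC equals the ground-truth map away from borders", {
  lab <- rasterize(small_phantom(), small_grid(), 2L)
  dx <- simulate_dixon(lab, dixon_sim_params(bias_min = 1, psf_fwhm = 0,
                                             slice_psf_fwhm = 0,
                                             noise_sigma = 0,
                                             swap_patch_count = 0L))
  seg <- segmentation_params()
  total <- total_phantom_mask(dx$opposed_phase, seg)
  water <- water_mask(dx$opposed_phase, dx$fat, seg)
  pm <- build_phantom_mrac(total, water, seg)
  truth <- lab$frac_water * seg$mu_water + lab$frac_material * seg$mu_material
  # exclude voxels within 2 voxels of any compartment border (fractional
  # voxels, or label transitions where a boundary aligns with voxel edges)
  frac <- (lab$frac_water > 0 & lab$frac_water < 1) |
    (lab$frac_material > 0 & lab$frac_material < 1)
  edges <- array(FALSE, dim = dim(frac))
  for (L in 0:2) {
    mL <- lab$labels == L
    edges <- edges | (mL & !mask_erode(mL, 1L))
  }
  core <- !mask_dilate(frac | edges, 2L)
  expect_equal(pm$mu[core], truth[core], tolerance = 1e-12)
})

test_that("tissue-swap patches do not change the phantom MR-AC", {
  lab <- rasterize(small_phantom(), small_grid(), 2L)
  seg <- segmentation_params()
  build <- function(params) {
    dx <- simulate_dixon(lab, params)
    total <- total_phantom_mask(dx$opposed_phase, seg)
    water <- water_mask(dx$opposed_phase, dx$fat, seg)
    build_phantom_mrac(total, water, seg)
  }
  base <- dixon_sim_params(noise_sigma = 0, swap_patch_count = 0L)
  swapped <- dixon_sim_params(noise_sigma = 0, swap_patch_count = 3L,
                              swap_patch_radius = 6)
  a <- build(base)
  b <- build(swapped)
  border <- mask_dilate(lab$frac_material > 0 & lab$frac_material < 1, 2L)
  expect_identical(a$mu[!border], b$mu[!border])
})
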