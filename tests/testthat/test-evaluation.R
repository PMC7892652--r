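# Percent-difference images, ROI construction and statistics, line profiles.

const_activity <- function(value, grid) {
  activity_volume(array(value, dim = grid$shape), grid)
}

test_that("percent difference is exact arithmetic on the support", {
  grid <- voxel_grid(c(4L, 4L, 2L), c(1, 1, 1))
  support <- binary_mask(array(TRUE, dim = grid$shape), grid)
  ref <- const_activity(100, grid)
  d0 <- percent_difference(ref, ref, support)
  expect_true(all(d0$data == 0))
  d <- percent_difference(const_activity(75, grid), ref, support)
  expect_true(all(d$data == -25))
  expect_equal(attr(d, "excluded"), 0)
})

test_that("non-positive reference voxels are excluded and tallied", {
  grid <- voxel_grid(c(3L, 1L, 1L), c(1, 1, 1))
  support <- binary_mask(array(TRUE, dim = grid$shape), grid)
  ref <- activity_volume(array(c(100, 0, 50), dim = c(3, 1, 1)), grid)
  d <- percent_difference(const_activity(75, grid), ref, support)
  expect_equal(attr(d, "excluded"), 1)
  expect_true(is.na(d$data[2, 1, 1]))
  expect_equal(d$data[1, 1, 1], -25)
  expect_equal(d$data[3, 1, 1], 50)
})

test_that("roi_stats computes mean and population/sample SD", {
  grid <- voxel_grid(c(2L, 1L, 1L), c(1, 1, 1))
  d <- image_volume(array(c(0, -50), dim = c(2, 1, 1)), grid)
  roi <- binary_mask(array(TRUE, dim = c(2, 1, 1)), grid)
  s <- roi_stats(d, roi)
  expect_equal(s$mean_pct_diff, -25)
  expect_equal(s$sd_pct_diff, 25)           # population SD (divide by n)
  expect_equal(s$n_voxels, 2L)
  s2 <- roi_stats(d, roi, sample_sd = TRUE)
  expect_equal(s2$sd_pct_diff, sqrt(2 * 625)) # n-1 denominator
  empty <- binary_mask(array(FALSE, dim = c(2, 1, 1)), grid)
  expect_error(roi_stats(d, empty), "empty ROI")
})

test_that("water support from a ground-truth CT-AC matches the water label", {
  lab <- rasterize(small_phantom(), small_grid(c(2, 2, 2)), 2L)
  ct <- simulate_ct(lab)
  ctac <- ct_to_mu(ct)
  ws <- water_support_from_ct(ctac)
  truth <- lab$labels == 2L
  # support is inside the water label and covers its eroded interior
  expect_true(all(truth[ws$values]))
  expect_gt(sum(ws$values) / sum(truth), 0.8)   # 1-voxel erosion trims the rest
  expect_true(all(ws$values[mask_erode(truth, 2L)]))
  # widening the window can only grow the mask
  ws_wide <- water_support_from_ct(ctac, window = c(1e-6, Inf))
  expect_true(all(ws_wide$values[ws$values]))
  # an air-only map has no water
  air <- attenuation_map(array(0, dim = lab$grid$shape), lab$grid, "CT_AC")
  expect_error(water_support_from_ct(air), "no water")
})

test_that("band ROIs partition the slice water and grow with band width", {
  lab <- rasterize(small_phantom(), small_grid(c(2, 2, 2)), 2L)
  ctac <- ct_to_mu(simulate_ct(lab))
  ws <- water_support_from_ct(ctac)
  mat <- material_support_from_ct(ctac)
  sl <- select_evaluation_slices(lab)
  wall <- make_roi(roi_spec("WALL_BAND", 3L, sl$homogeneous), ws, mat)
  slice <- make_roi(roi_spec("SLICE_HOMOGENEOUS", 3L, sl$homogeneous), ws, mat)
  # the band is water, lies in the slice, and is a strict subset of it
  expect_true(all(slice$values[wall$values]))
  expect_gt(sum(wall$values), 0)
  expect_lt(sum(wall$values), sum(slice$values))
  # monotone growth with band width
  rod2 <- make_roi(roi_spec("ROD_BAND", 2L, sl$heterogeneous), ws, mat)
  rod4 <- make_roi(roi_spec("ROD_BAND", 4L, sl$heterogeneous), ws, mat)
  expect_true(all(rod4$values[rod2$values]))
  expect_gte(sum(rod4$values), sum(rod2$values))
  # rod band in the heterogeneous slice surrounds more border than the wall
  expect_error(roi_spec("WALL_BAND", 0L, 1L), "band_width")
})

test_that("whole-water ROI equals the support and slice ROIs restrict it", {
  lab <- rasterize(small_phantom(), small_grid(c(2, 2, 2)), 2L)
  ctac <- ct_to_mu(simulate_ct(lab))
  ws <- water_support_from_ct(ctac)
  whole <- make_roi(roi_spec("WHOLE_WATER"), ws)
  expect_identical(whole$values, ws$values)
  sl <- select_evaluation_slices(lab)
  shet <- make_roi(roi_spec("SLICE_HETEROGENEOUS", 5L, sl$heterogeneous), ws)
  expect_identical(shet$values[, , sl$heterogeneous],
                   ws$values[, , sl$heterogeneous])
  expect_equal(sum(shet$values), sum(shet$values[, , sl$heterogeneous]))
})

test_that("line profiles interpolate, reverse, and see the shell plateau", {
  grid <- voxel_grid(c(10L, 10L, 4L), c(2, 2, 2))
  vol <- image_volume(array(7, dim = grid$shape), grid)
  pr <- line_profile(vol, c(0, 0, 2), c(16, 16, 2), step = 1)
  expect_equal(pr$value, rep(7, nrow(pr)))
  # reversed endpoints give the reversed sequence
  a <- line_profile(vol, c(0, 0, 2), c(16, 0, 2), step = 2)
  b <- line_profile(vol, c(16, 0, 2), c(0, 0, 2), step = 2)
  expect_equal(a$value, rev(b$value))
  # ground-truth mu profile across the shell plateaus at the material mu
  spec <- small_phantom(rods = FALSE)
  g <- small_grid(c(1, 1, 2))
  lab <- rasterize(spec, g, 2L)
  mu <- attenuation_map(0.096 * lab$frac_water + 0.1037 * lab$frac_material,
                        g, "GROUND_TRUTH")
  zmid <- 40
  pr <- line_profile(mu, c(0, 40, zmid), c(0, 60, zmid), step = 0.5)
  shell <- pr$value[pr$position + 40 > 45.5 & pr$position + 40 < 49.5]
  expect_true(all(abs(shell - 0.1037) < 0.002))
  outside <- pr$value[pr$position + 40 > 52]
  expect_true(all(outside < 0.002))
})

test_that("evaluation slices fall in the rod region and the homogeneous region", {
  lab <- rasterize(small_phantom(), small_grid(c(2, 2, 2)), 2L)
  sl <- select_evaluation_slices(lab)
  zs <- grid_axis(lab$grid, 3)
  spec <- lab$spec
  expect_true(zs[sl$heterogeneous] > spec$bottom_lid_thickness &&
                zs[sl$heterogeneous] < spec$bottom_lid_thickness + spec$rod_length)
  expect_true(zs[sl$homogeneous] > spec$bottom_lid_thickness + spec$rod_length &&
                zs[sl$homogeneous] < spec$outer_length - spec$top_lid_thickness)
  # rods present in the heterogeneous slice, absent in the homogeneous one
  ri <- spec$inner_diameter / 2 - 4
  r2 <- outer(grid_axis(lab$grid, 1)^2, grid_axis(lab$grid, 2)^2, `+`)
  inner <- r2 < ri^2
  expect_gt(sum(lab$labels[, , sl$heterogeneous] == 1L & inner), 0)
  expect_equal(sum(lab$labels[, , sl$homogeneous] == 1L & inner), 0L)
})
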