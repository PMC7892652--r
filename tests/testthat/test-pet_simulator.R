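# Forward model and OSEM reconstruction.

test_that("attenuation factors obey the closed-form chord oracle", {
  dp <- disk_phantom(n = 120, spacing = 2, radius = 80, mu = 0.1)
  proj <- make_projector(dp$grid, n_angles = 8L)
  af <- attenuation_factors(dp$mu, proj)
  expect_true(all(af$values > 0 & af$values <= 1))
  # central bin, any angle: chord = 2R through a centred disk
  centre_bin <- (proj$n_bins + 1) / 2
  expected <- exp(-0.1 * 2 * 80 / 10)
  for (a in c(1, 3, 6))
    expect_equal(af$values[centre_bin, a, 1], expected, tolerance = 0.01)
})

test_that("zero attenuation gives unit factors and the plain ray transform", {
  dp <- disk_phantom(n = 64, spacing = 3, radius = 60)
  proj <- make_projector(dp$grid, n_angles = 12L)
  mu0 <- attenuation_map(array(0, dim = dp$grid$shape), dp$grid, "GROUND_TRUTH")
  af <- attenuation_factors(mu0, proj)
  expect_true(all(af$values == 1))
  y0 <- forward_project(dp$activity, mu0, proj)
  # unattenuated projection of a uniform disk: central ray = activity * 2R
  centre_bin <- (proj$n_bins + 1) / 2
  expect_equal(y0$values[centre_bin, 1, 1], 10 * 2 * 60, tolerance = 0.01 * 1200)
  # zero activity -> all-zero sinogram
  act0 <- activity_volume(array(0, dim = dp$grid$shape), dp$grid)
  expect_true(all(forward_project(act0, dp$mu, proj)$values == 0))
})

test_that("attenuation factors decrease monotonically with mu scaling", {
  dp <- disk_phantom(n = 48, spacing = 4, radius = 60, mu = 0.05)
  proj <- make_projector(dp$grid, n_angles = 6L)
  f1 <- attenuation_factors(dp$mu, proj)$values
  mu2 <- attenuation_map(2 * dp$mu$mu, dp$grid, "GROUND_TRUTH")
  f2 <- attenuation_factors(mu2, proj)$values
  expect_true(all(f2 <= f1 + 1e-12))
})

test_that("a single-voxel system reaches the ML solution in one EM update", {
  # matched 1-bin system: forward = l * a * x, ML solution x* = y / (l a)
  grid <- voxel_grid(c(1L, 1L, 1L), c(7, 7, 7))
  proj <- structure(list(A = Matrix::sparseMatrix(i = 1, j = 1, x = 7,
                                                  dims = c(1, 1)),
                         grid = grid, n_angles = 1L, n_bins = 1L,
                         bin_spacing = 7, step = 1,
                         cache = new.env(parent = emptyenv())),
                    class = "projector")
  ac <- attenuation_map(array(0.2, dim = c(1, 1, 1)), grid, "GROUND_TRUTH")
  sino <- structure(list(values = array(5, dim = c(1, 1, 1)),
                         n_angles = 1L, n_bins = 1L, n_slices = 1L,
                         bin_spacing = 7), class = "sinogram")
  rec <- osem_reconstruct(sino, ac,
                          recon_params(iterations = 1L, subsets = 1L,
                                       postfilter_fwhm = 0), proj)
  a <- exp(-0.2 * 7 / 10)
  expect_equal(rec$activity[1, 1, 1], 5 / (7 * a), tolerance = 1e-12)
})

test_that("matched-AC OSEM recovers a uniform cylinder within 2 percent", {
  dp <- disk_phantom(n = 96, spacing = 2.6, radius = 80)
  proj <- make_projector(dp$grid, n_angles = 48L)
  sino <- forward_project(dp$activity, dp$mu, proj)
  rec <- osem_reconstruct(sino, dp$mu,
                          recon_params(iterations = 3L, subsets = 24L,
                                       postfilter_fwhm = 5), proj)
  r2 <- outer(grid_axis(dp$grid, 1)^2, grid_axis(dp$grid, 2)^2, `+`)
  interior <- array(r2 < (dp$radius - 15)^2, dim = dp$grid$shape)
  expect_equal(mean(rec$activity[interior]), 10, tolerance = 0.02)
})

test_that("ignoring attenuation biases the reconstruction low", {
  dp <- disk_phantom(n = 64, spacing = 4, radius = 90)
  proj <- make_projector(dp$grid, n_angles = 24L)
  sino <- forward_project(dp$activity, dp$mu, proj)
  ac0 <- attenuation_map(array(0, dim = dp$grid$shape), dp$grid, "NOWALL_MRAC")
  rec <- osem_reconstruct(sino, ac0,
                          recon_params(iterations = 3L, subsets = 12L,
                                       postfilter_fwhm = 0), proj)
  r2 <- outer(grid_axis(dp$grid, 1)^2, grid_axis(dp$grid, 2)^2, `+`)
  interior <- array(r2 < (dp$radius - 20)^2, dim = dp$grid$shape)
  expect_lt(mean(rec$activity[interior]), 10)
})

test_that("the EM log-likelihood is nondecreasing on noiseless data", {
  dp <- disk_phantom(n = 48, spacing = 4, radius = 70)
  proj <- make_projector(dp$grid, n_angles = 24L)
  sino <- forward_project(dp$activity, dp$mu, proj)
  # MLEM (one subset): monotone by construction
  rec <- osem_reconstruct(sino, dp$mu,
                          recon_params(iterations = 6L, subsets = 1L,
                                       postfilter_fwhm = 0), proj,
                          track_loglik = TRUE)
  ll <- attr(rec, "loglik")
  expect_true(all(diff(ll) >= -1e-6 * abs(ll[-length(ll)])))
  # ordered subsets on consistent data behave the same way in practice
  rec24 <- osem_reconstruct(sino, dp$mu,
                            recon_params(iterations = 4L, subsets = 12L,
                                         postfilter_fwhm = 0), proj,
                            track_loglik = TRUE)
  ll24 <- attr(rec24, "loglik")
  expect_true(all(diff(ll24) >= -1e-6 * abs(ll24[-length(ll24)])))
})

test_that("subset count must divide the number of angles", {
  dp <- disk_phantom(n = 32, spacing = 6, radius = 60)
  proj <- make_projector(dp$grid, n_angles = 10L)
  sino <- forward_project(dp$activity, dp$mu, proj)
  expect_error(osem_reconstruct(sino, dp$mu,
                                recon_params(iterations = 1L, subsets = 4L),
                                proj),
               "invalid subset partition")
})

test_that("Poisson sampling is seeded and deterministic", {
  dp <- disk_phantom(n = 32, spacing = 6, radius = 60)
  proj <- make_projector(dp$grid, n_angles = 8L)
  y1 <- forward_project(dp$activity, dp$mu, proj, poisson = TRUE, seed = 3L)
  y2 <- forward_project(dp$activity, dp$mu, proj, poisson = TRUE, seed = 3L)
  y3 <- forward_project(dp$activity, dp$mu, proj, poisson = TRUE, seed = 4L)
  expect_identical(y1$values, y2$values)
  expect_false(identical(y1$values, y3$values))
})
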