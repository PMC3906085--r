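test_that("analytic truth matches closed forms for the three profiles", {
  ph <- tube_phantom_clean()
  expect_equal(analytic_csa(ph$truth, 15), pi * 4, tolerance = 1e-12)
  expect_equal(ph$truth$inscribed(15), 4)
  expect_error(analytic_csa(ph$truth, -1), "range")
  expect_error(analytic_csa(ph$truth, ph$truth$length + 1), "range")

  phe <- generate_phantom(phantom_spec(
    profile = list(shape = "ellipse", a = 2.13, b = 1.99),
    psf_sigma = 0, noise_sd = 0))
  expect_equal(analytic_csa(phe$truth, 10), pi * 2.13 * 1.99,
               tolerance = 1e-12)
  expect_equal(phe$truth$inscribed(10), 2 * 1.99)
})

test_that("crescent truth area agrees with a Monte-Carlo oracle", {
  phc <- generate_phantom(phantom_spec(
    profile = list(shape = "crescent", R = 2.2, r = 1.6, offset = 1.2),
    psf_sigma = 0, noise_sd = 0))
  a_lens <- pi * 2.2^2 - circle_overlap_area(2.2, 1.6, 1.2)
  expect_equal(analytic_csa(phc$truth, 10), a_lens, tolerance = 1e-12)
  set.seed(1)
  n <- 1e6
  px <- stats::runif(n, -2.2, 2.2)
  py <- stats::runif(n, -2.2, 2.2)
  inside <- px^2 + py^2 <= 2.2^2 & !((px - 1.2)^2 + py^2 <= 1.6^2)
  mc <- mean(inside) * 4.4^2
  expect_equal(a_lens, mc, tolerance = 3 * stats::sd(inside) * 4.4^2 /
                 sqrt(n) / mc)
})

test_that("stenosis modulation follows the stated Gaussian dip", {
  sp <- phantom_spec(stenosis = list(depth = 0.5, center_s = 15, width = 3),
                     psf_sigma = 0, noise_sd = 0)
  ph <- generate_phantom(sp)
  expect_equal(analytic_csa(ph$truth, 15), 0.5 * pi * 4, tolerance = 1e-12)
  expect_equal(analytic_csa(ph$truth, 0), pi * 4 *
                 (1 - 0.5 * exp(-225 / 18)), tolerance = 1e-12)
  # midpoint of the dip width: direct evaluation of the modulation formula
  expect_equal(analytic_csa(ph$truth, 15 + 3),
               pi * 4 * (1 - 0.5 * exp(-0.5)), tolerance = 1e-12)
})

test_that("noise-free voxelized tube volume is within O(spacing) of truth", {
  ph <- tube_phantom_clean()
  mk <- truth_mask(ph$truth)
  v_vox <- sum(mk$data == 1L) * voxel_volume(mk)
  v_true <- pi * 4 * ph$truth$length
  # relative discretization error should scale like spacing / radius
  expect_lt(abs(v_vox - v_true) / v_true, 0.4 / 2 * 0.5)
})

test_that("phantom generation is deterministic given spec and seed", {
  sp <- phantom_spec(noise_sd = 20, seed = 99L)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$data, b$volume$data)
  sp2 <- phantom_spec(noise_sd = 20, seed = 100L)
  expect_false(identical(generate_phantom(sp2)$volume$data, a$volume$data))
})

test_that("invalid phantom geometry is rejected", {
  expect_error(phantom_spec(profile = list(shape = "crescent", R = 2,
                                           r = 1.6, offset = 2.5)),
               "offset")
  expect_error(phantom_spec(profile = list(shape = "crescent", R = 1,
                                           r = 3, offset = 0.5)),
               "swallow")
  expect_error(phantom_spec(lumen_hu = 40, background_hu = 50), "exceed")
  expect_error(generate_phantom(phantom_spec(shape = c(12, 12, 40))),
               "margin")
})

test_that("phantom volumes carry the CT intensity conventions", {
  ph <- tube_phantom_clean()
  v <- ph$volume
  expect_equal(v$data[1, 1, 1], 50, tolerance = 1e-9)   # background HU
  ctr <- world_to_index(v, ph$truth$point(15)) + 1
  expect_equal(v$data[round(ctr[1]), round(ctr[2]), round(ctr[3])], 450,
               tolerance = 1e-9)
})
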