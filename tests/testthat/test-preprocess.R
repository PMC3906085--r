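test_that("Wiener with nsr = 0 inverts a known Gaussian blur", {
  x <- array(50, c(32, 32, 32))
  x[10:22, 12:20, 8:25] <- 450
  xb <- vesselcsa:::gaussian_blur(x, 0.8, c(1, 1, 1))
  vb <- ct_volume(xb, c(1, 1, 1))
  xr <- wiener_deconvolve(vb, psf_model(0.8), 0)$data
  rel <- sqrt(sum((xr - x)^2) / sum(x^2))
  expect_lt(rel, 0.01)
  expect_error(wiener_deconvolve(vb, psf_model(0.8), -1), "nsr")
})

test_that("a near-delta PSF leaves the volume essentially unchanged", {
  set.seed(3)
  v <- ct_volume(array(stats::rnorm(20^3, 100, 50), c(20, 20, 20)),
                 c(1, 1, 1))
  out <- wiener_deconvolve(v, psf_model(0.05), 1e-4)
  expect_lt(max(abs(out$data - v$data)) / diff(range(v$data)), 0.01)
})

test_that("deconvolution sharpens a blurred step edge", {
  ph <- tube_phantom_clean()
  blurred <- ct_volume(vesselcsa:::gaussian_blur(ph$volume$data, 0.8,
                                                 ph$volume$spacing),
                       ph$volume$spacing, ph$volume$origin)
  dec <- wiener_deconvolve(blurred, psf_model(0.8), 1e-4)
  grad_mag <- function(a) max(abs(diff(a$data[, 16, 50])))
  expect_gt(grad_mag(dec), grad_mag(blurred))
})

test_that("selective deblurring is a convex blend with trivial limits", {
  ph <- tube_phantom()
  v <- ph$volume
  dec <- wiener_deconvolve(v, psf_model(0.6), 0.001)
  hi <- selective_deblur(v, dec, threshold = max(v$data, dec$data) + 100)
  expect_equal(hi$data, v$data)
  lo <- selective_deblur(v, dec, threshold = min(v$data) - 1)
  expect_equal(lo$data, dec$data)
  mid <- selective_deblur(v, dec, threshold = 300)
  lo_in <- pmin(v$data, dec$data) - 1e-9
  hi_in <- pmax(v$data, dec$data) + 1e-9
  expect_true(all(mid$data >= lo_in & mid$data <= hi_in))
  wrong <- ct_volume(v$data[1:10, , , drop = FALSE], v$spacing)
  expect_error(selective_deblur(v, wrong, 700), "grid")
})

test_that("selective deblurring keeps original noise in soft tissue and
           deconvolved gradients at calcium", {
  sp <- phantom_spec(calcific = list(center_s = 15, radius = 1.0,
                                     offset = 2.4), noise_sd = 15)
  ph <- generate_phantom(sp)
  v <- ph$volume
  dec <- wiener_deconvolve(v, psf_model(0.6), 1e-3)
  sel <- selective_deblur(v, dec, 650)
  bg <- array(FALSE, dim(v$data)); bg[1:8, 1:8, ] <- TRUE  # far from calcium
  expect_equal(sel$data[bg], v$data[bg])
  cal <- dec$data > 700
  expect_equal(sel$data[cal], dec$data[cal], tolerance = 1e-6)
})

test_that("bilateral filter fixes constants and bounds its output", {
  cv <- ct_volume(array(200, c(12, 12, 12)), c(1, 1, 1))
  expect_equal(bilateral_filter(cv, 1, 50)$data, cv$data, tolerance = 1e-10)
  ph <- tube_phantom()
  out <- bilateral_filter(ph$volume, 0.8, 100)
  expect_gte(min(out$data), min(ph$volume$data))
  expect_lte(max(out$data), max(ph$volume$data))
  expect_error(bilateral_filter(ph$volume, -1, 100), "sigma")
})

test_that("bilateral filter tends to Gaussian smoothing as range -> Inf", {
  set.seed(9)
  v <- ct_volume(array(stats::rnorm(18^3, 0, 10), c(18, 18, 18)), c(1, 1, 1))
  bl <- bilateral_filter(v, 1.5, 1e7)
  # reference: the same 2-sigma-truncated Gaussian window
  kern <- vesselcsa:::gaussian_kernel_3d(rep(1.5, 3), rep(3L, 3))
  ref <- vesselcsa:::fft_convolve(v$data, kern)
  inner <- 4:15
  rel <- sqrt(sum((bl$data[inner, inner, inner] -
                     ref[inner, inner, inner])^2) /
                sum(ref[inner, inner, inner]^2))
  expect_lt(rel, 0.01)
})

test_that("bilateral filter denoises flat regions but keeps the edge", {
  ph <- tube_phantom()
  out <- bilateral_filter(ph$volume, 1.0, 100)
  bg <- array(FALSE, dim(ph$volume$data))
  bg[1:6, 1:6, ] <- TRUE
  expect_gt(stats::var(ph$volume$data[bg]) / stats::var(out$data[bg]), 4)
  # 10-90% rise distance across the wall grows by less than one voxel
  rise <- function(v) {
    pr <- extract_profile(v, c(0, 0, 15), c(3.2, 0, 15), 65)
    r <- pr$t[range(which(pr$intensity > 0.1 & pr$intensity < 0.9))]
    diff(r)
  }
  expect_lt(rise(out) - rise(ph$volume), 0.4)
})

test_that("profiles are normalized, symmetric and bounded by the lumen", {
  cv <- ct_volume(array(7, c(10, 10, 10)), c(1, 1, 1))
  pr <- extract_profile(cv, c(1, 1, 1), c(8, 8, 8), 20)
  expect_true(all(pr$intensity == 0))       # documented degenerate case
  ph <- tube_phantom_clean()
  a <- extract_profile(ph$volume, c(-3, 0, 15), c(3, 0, 15), 61)
  b <- extract_profile(ph$volume, c(3, 0, 15), c(-3, 0, 15), 61)
  expect_equal(a$intensity, rev(b$intensity), tolerance = 1e-9)
  # width at half maximum approximates the lumen diameter
  fwhm <- diff(range(a$t[a$intensity >= 0.5]))
  expect_lt(abs(fwhm - 4), 0.4)
  expect_error(extract_profile(ph$volume, c(0, 0, 15), c(100, 0, 15), 10),
               "exits")
})
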