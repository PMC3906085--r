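pullback_fixture <- function() {
  system.file("extdata", "ivus_pullback_example.csv", package = "vesselcsa")
}

test_that("the example pullback table reads with its printed values", {
  frames <- read_pullback(pullback_fixture())
  expect_equal(nrow(frames), 8)
  expect_equal(frames$area[1], 13.2)
  expect_equal(frames$position[1], 0.0167)
  expect_equal(frames$max_d[1], 4.26)
  expect_equal(frames$min_d[1], 3.98)
})

test_that("pullback validation rejects bad rows and bad files", {
  f <- tempfile(fileext = ".csv")
  writeLines("frame,position,max_d,min_d,avg_d,area", f)
  expect_error(read_pullback(f), "empty|valid")
  writeLines(c("frame,position,max_d,min_d,avg_d,area",
               "1,0.0,3.0,3.5,3.2,10",      # min > max: rejected
               "2,0.1,4.0,3.5,3.7,11"), f)
  expect_message(frames <- read_pullback(f), "rejected")
  expect_equal(nrow(frames), 1)
  writeLines(c("frame,position,max_d,min_d,avg_d,area",
               "1,0.2,4,3,3.5,10", "2,0.1,4,3,3.5,10"), f)
  expect_error(read_pullback(f), "nondecreasing")
})

test_that("alignment interpolates CT areas at reference positions", {
  prof <- data.frame(s = seq(0, 20, by = 0.5),
                     area = 10 + 0.5 * seq(0, 20, by = 0.5))  # linear ramp
  frames <- data.frame(position = c(1.25, 5.0, 10.75), area = c(1, 2, 3))
  pairs <- align_series(prof, frames)
  expect_equal(pairs$ct_area, 10 + 0.5 * frames$position)
  # a 5 mm landmark offset shifts the interpolation accordingly
  off <- align_series(prof, frames, offset = 5)
  expect_equal(off$ct_area, 10 + 0.5 * (frames$position + 5))
  # trimming 2 mm drops the two frames within 2 mm of the overlap ends
  tr <- align_series(prof, frames, trim = 2)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$position, 5.0)
  expect_error(align_series(prof, data.frame(position = 100, area = 1)),
               "overlap")
})

test_that("percent error matches hand-computed values and scales out", {
  expect_equal(percent_error(10, 9), 10.0)
  expect_equal(percent_error(7, 7), 0.0)
  expect_equal(percent_error(12, 13.2), -10.0)
  set.seed(2)
  a <- stats::runif(20, 1, 5); b <- stats::runif(20, 1, 5)
  expect_equal(percent_error(3 * a, 3 * b), percent_error(a, b))
  expect_error(percent_error(0, 1), "> 0")
})

test_that("normalized RMSE reproduces hand values and the noise limit", {
  expect_equal(rmse_normalized(c(2, 2), c(2, 2)), 0.0)
  expect_equal(rmse_normalized(c(2, 2), c(1, 3)), 50.0)
  set.seed(4)
  ref <- stats::runif(1e4, 5, 15)
  test <- ref + stats::rnorm(1e4, 0, 0.8)
  expect_equal(rmse_normalized(ref, test), 100 * 0.8 / mean(ref),
               tolerance = 0.03)
  expect_error(rmse_normalized(1:3, 1:4), "lengths")
})

test_that("identity fits recover exact and noisy linear relations", {
  ref <- seq(1, 10, by = 0.5)
  f0 <- identity_fit(ref, ref)
  expect_equal(f0$slope, 1.0)
  expect_equal(f0$intercept, 0.0, tolerance = 1e-12)
  expect_equal(f0$rmse_pct, 0.0, tolerance = 1e-9)
  f1 <- identity_fit(ref, 0.95 * ref + 0.23)
  expect_equal(f1$slope, 0.95, tolerance = 1e-12)
  expect_equal(f1$intercept, 0.23, tolerance = 1e-12)
  set.seed(8)
  ref2 <- stats::runif(1000, 2, 12)
  f2 <- identity_fit(ref2, ref2 + stats::rnorm(1000, 0, 0.1))
  expect_gt(f2$slope, 0.98)
  expect_lt(f2$slope, 1.02)
  expect_error(identity_fit(1:2, 1:2), "3 points")
})

test_that("comparison wrapper reports aligned pairs with both error styles", {
  prof <- data.frame(s = 0:20, area = rep(10, 21))
  frames <- data.frame(position = seq(2, 18, by = 2),
                       area = 10 + c(-1, 1, -1, 1, -1, 1, -1, 1, -1))
  cmp <- compare_to_reference(prof, frames)
  expect_equal(nrow(cmp$pairs), 9)
  expect_gt(cmp$stats$mean_abs_pct_error, 0)
  expect_lt(abs(cmp$stats$mean_signed_pct_error),
            cmp$stats$mean_abs_pct_error)
})
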