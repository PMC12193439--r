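test_that("segmentation recovers the rendered mask and handles polarity", {
  fi <- sim_fiber_image(fiber_field_params(blur_sigma = 1, noise_sd = 0,
                                           seed = 3))
  mask <- segment_fibers(fi)
  truth <- attr(fi, "true_mask")
  iou <- sum(mask & truth) / sum(mask | truth)
  expect_gte(iou, 0.95)
  # inverted-contrast image with the polarity flag gives the identical mask
  inv <- fiber_image(255 - fi$pixels, fi$nm_per_pixel)
  expect_identical(segment_fibers(inv, invert = TRUE), mask)
  # degenerate image
  expect_error(segment_fibers(matrix(7, 64, 64)), class = "clotmetrics_no_fibers")
})

test_that("a single straight fiber measures its constructed width", {
  mask <- horizontal_fiber_mask(12)
  s <- measure_diameters(mask, nm_per_pixel = 8, seed = 1)
  expect_lte(abs(s$median - 96), 8)   # within one pixel equivalent
  # determinism
  expect_identical(measure_diameters(mask, 8, seed = 5)$diameters,
                   measure_diameters(mask, 8, seed = 5)$diameters)
  # recovered median scales linearly with the pixel size for a fixed mask
  expect_equal(measure_diameters(mask, 16, seed = 1)$median,
               2 * s$median, tolerance = 1e-12)
  expect_error(measure_diameters(matrix(FALSE, 64, 64), 8),
               class = "clotmetrics_no_fibers")
})

test_that("a bimodal field yields a pooled median between the modes", {
  mask <- matrix(FALSE, 128, 128)
  mask[20:25, ] <- TRUE    # 6 px  -> 48 nm
  mask[60:77, ] <- TRUE    # 18 px -> 144 nm
  s <- measure_diameters(mask, 8, seed = 2)
  # with two discrete width atoms the median lies in the closed mode interval
  expect_gte(s$median, 48)
  expect_lte(s$median, 144)
  modes <- sort(unique(round(s$diameters)))
  expect_true(any(modes <= 56) && any(modes >= 136))   # both populations hit
})

test_that("shortfall is flagged when the skeleton is smaller than the target", {
  mask <- horizontal_fiber_mask(6, size = 64L, top = 30L)
  s <- measure_diameters(mask, 8, n_target = 300, seed = 1)
  expect_true(s$shortfall)
  expect_lt(s$n, 300)
})

test_that("two sampling seeds on a large mask agree to sampling error", {
  fi <- sim_fiber_image(fiber_field_params(noise_sd = 0, seed = 9))
  mask <- segment_fibers(fi)
  m1 <- measure_diameters(mask, 8, seed = 1)$median
  m2 <- measure_diameters(mask, 8, seed = 2)$median
  expect_lt(abs(m1 - m2) / m1, 0.1)
})

test_that("diameter summaries use the exclusive quartile convention", {
  s <- structure(list(diameters = c(90, 95, 100)), class = "diameter_sample")
  sm <- summarize_diameters(s)
  expect_equal(sm$median, 95)
  expect_equal(sm$iqr, 10)
  expect_equal(sm$q1, 90)
  one <- structure(list(diameters = 95.1), class = "diameter_sample")
  expect_identical(summarize_diameters(one)$label, "95.1 [0.0]")
  expect_match(sm$label, "^[0-9]+\\.[0-9] \\[[0-9]+\\.[0-9]\\]$")
  # pooling keeps per-image rows
  sm2 <- summarize_diameters(list(s, one))
  expect_equal(nrow(sm2$per_image), 2)
  expect_equal(sm2$n, 4)
})

test_that("blur degrades diameter recovery monotonically", {
  err <- vapply(c(0, 2, 4), function(bs) {
    mean(vapply(1:4, function(s) {
      fi <- sim_fiber_image(fiber_field_params(blur_sigma = bs, noise_sd = 0,
                                               seed = s))
      sm <- measure_diameters(segment_fibers(fi), fi$nm_per_pixel, seed = 1)
      abs(sm$median - stats::median(attr(fi, "ground_truth")$widths_nm))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) > -2))   # non-decreasing within a 2 nm jitter band
})

test_that("image container enforces its invariants", {
  expect_error(fiber_image(matrix(0, 32, 32), 8), class = "clotmetrics_bad_image")
  expect_error(fiber_image(matrix(0, 64, 64), -1), class = "clotmetrics_bad_argument")
})
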