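test_that("clotting times follow closed-form interpolation on a linear rise", {
  tr <- kinetic_trace(0:10, (0:10) / 10)
  expect_equal(clotting_time(tr, 0.5), 5)
  expect_equal(clotting_time(tr, 0.9), 9)
  expect_error(clotting_time(tr, 1.2), class = "clotmetrics_bad_argument")
  expect_error(clotting_time(tr, 0), class = "clotmetrics_bad_argument")
})

test_that("a densely sampled step has CT50 = CT90 at the jump time", {
  t <- seq(0, 10, by = 0.001)
  tr <- kinetic_trace(t, as.numeric(t >= 5))
  expect_equal(clotting_time(tr, 0.5), 5, tolerance = 1e-3)
  expect_equal(clotting_time(tr, 0.9), 5, tolerance = 1e-3)
})

test_that("normalization is affine and leaves all waveform times unchanged", {
  # a trace that touches its baseline (0.05) and peaks at 0.85 maps to [0, 1]
  touch <- kinetic_trace(seq(0, 40, 5), c(0.05, 0.1, 0.4, 0.85, 0.7, 0.5,
                                          0.3, 0.2, 0.1))
  expect_equal(range(normalize_trace(touch)$absorbance), c(0, 1))
  tr <- sim_turbidity_trace(turbidity_params(baseline = 0.05, a_max = 0.85,
                                             noise_sd = 0))
  nm <- normalize_trace(tr)
  expect_equal(max(nm$absorbance), 1)
  expect_equal(nm$baseline, 0)
  for (fr in c(0.5, 0.9))
    expect_equal(clotting_time(nm, fr), clotting_time(tr, fr),
                 tolerance = 1e-9)
  expect_equal(lysis_time(nm), lysis_time(tr), tolerance = 1e-9)
  flat <- kinetic_trace(0:5, rep(0.2, 6))
  expect_error(normalize_trace(flat), class = "clotmetrics_no_clotting")
  expect_error(clotting_time(flat, 0.5), class = "clotmetrics_no_clotting")
})

test_that("maximal turbidity is exact on noiseless traces and ties break early", {
  tr <- sim_turbidity_trace(turbidity_params(noise_sd = 0))
  expect_equal(max_turbidity(tr)$a_max, 0.85, tolerance = 1e-12)
  twin <- kinetic_trace(c(0, 100, 200, 300), c(0, 1, 1, 0))
  expect_equal(max_turbidity(twin)$t_amax, 100)
})

test_that("lysis time honours the triangle closed form and the mode origin", {
  expect_equal(lysis_time(triangle_trace()), 20)
  expect_equal(lysis_time(triangle_trace("extrinsic", t_addition = 10)), 10)
  rising <- kinetic_trace(0:10, (0:10) / 10)
  lt <- lysis_time(rising)
  expect_true(is.na(lt))
  expect_identical(attr(lt, "flag"), "incomplete_lysis")
  m <- clot_lysis_metrics(rising)
  expect_identical(m$flags, "no_lysis")
})

test_that("relative units convert correctly and are scale invariant", {
  expect_equal(relative_units(43, 43), 1)
  expect_equal(relative_units(86, 43), 2)   # a 100% prolongation
  for (k in c(0.1, 3, 250))
    expect_equal(relative_units(k * 7, k * 4), relative_units(7, 4))
  expect_error(relative_units(1, 0), class = "clotmetrics_bad_argument")
  # fold-change of maximal turbidity between a 2.32x pair of generated wells
  lo <- sim_turbidity_trace(turbidity_params(baseline = 0, a_max = 0.5,
                                             noise_sd = 0))
  hi <- sim_turbidity_trace(turbidity_params(baseline = 0, a_max = 0.5 * 2.32,
                                             noise_sd = 0))
  expect_equal(relative_units(max_turbidity(hi)$a_max,
                              max_turbidity(lo)$a_max), 2.32,
               tolerance = 1e-12)
})

test_that("CT50 <= CT90 <= t_amax and metrics survive affine + resampling", {
  for (i in 1:60) {
    p <- with_seed_helper(i, turbidity_params(
      ct50_true = runif(1, 200, 600),
      formation_steepness = runif(1, 0.01, 0.03),
      lt50_true = runif(1, 1500, 3000),
      noise_sd = runif(1, 0, 0.02) * 0.8))
    tr <- sim_turbidity_trace(p, seed = i)
    m <- clot_lysis_metrics(tr, smooth_window = 5)
    expect_lte(m$ct50, m$ct90)
    expect_lte(m$ct90, m$t_amax)
    if (i <= 10) {
      # affine transform of the absorbance axis
      tr2 <- kinetic_trace(tr$times, 2.7 * tr$absorbance + 0.13,
                           baseline = 2.7 * tr$baseline + 0.13)
      m2 <- clot_lysis_metrics(tr2, smooth_window = 5)
      expect_equal(m2$ct50, m$ct50, tolerance = 1e-9)
      expect_equal(m2$ct90, m$ct90, tolerance = 1e-9)
      expect_equal(m2$lt50, m$lt50, tolerance = 1e-9)
      # uniform resampling finer than the original grid (piecewise-linear
      # interpolation preserves every crossing)
      t_fine <- seq(min(tr$times), max(tr$times), by = 2)
      tr3 <- kinetic_trace(t_fine, approx(tr$times, tr$absorbance, t_fine)$y,
                           baseline = tr$baseline)
      m3 <- clot_lysis_metrics(tr3)
      m1 <- clot_lysis_metrics(tr)
      expect_equal(m3$ct50, m1$ct50, tolerance = p$sample_interval)
      expect_equal(m3$lt50, m1$lt50, tolerance = p$sample_interval)
    }
  }
})

test_that("trace constructor validates its invariants", {
  expect_error(kinetic_trace(c(0, 1), c(0, 1)), class = "clotmetrics_bad_trace")
  expect_error(kinetic_trace(c(0, 2, 1), c(0, 1, 1)),
               class = "clotmetrics_bad_trace")
  expect_error(kinetic_trace(0:5, rep(0, 6), assay_mode = "extrinsic"),
               class = "clotmetrics_bad_trace")
  expect_error(kinetic_trace(0:5, rep(0, 6), assay_mode = "extrinsic",
                             t_addition = 99),
               class = "clotmetrics_bad_trace")
})
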