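test_that("all generators are bit-reproducible given (params, seed)", {
  p <- turbidity_params(noise_sd = 0.01)
  expect_identical(sim_turbidity_trace(p, seed = 7),
                   sim_turbidity_trace(p, seed = 7))
  expect_false(identical(sim_turbidity_trace(p, seed = 7)$absorbance,
                         sim_turbidity_trace(p, seed = 8)$absorbance))
  geo <- permeation_geometry(tubing_inner_diameter = 0.2)
  expect_identical(sim_permeation_readings(0.29e-9, geo, noise_sd = 0.5, seed = 3),
                   sim_permeation_readings(0.29e-9, geo, noise_sd = 0.5, seed = 3))
  expect_identical(sim_rheo_record(noise_sd = 0.2, seed = 5),
                   sim_rheo_record(noise_sd = 0.2, seed = 5))
  fp <- fiber_field_params(seed = 2)
  expect_identical(sim_fiber_image(fp)$pixels, sim_fiber_image(fp)$pixels)
  expect_identical(sim_clottability_course(noise_sd = 0.05, seed = 4),
                   sim_clottability_course(noise_sd = 0.05, seed = 4))
})

test_that("noiseless turbidity traces cross half-max at the programmed times", {
  tr <- sim_turbidity_trace(turbidity_params(ct50_true = 300, noise_sd = 0,
                                             lt50_true = NULL))
  expect_equal(clotting_time(tr, 0.5), 300, tolerance = 10)
  tr2 <- sim_turbidity_trace(turbidity_params(ct50_true = 300,
                                              lt50_true = 2400, noise_sd = 0))
  expect_equal(lysis_time(tr2), 2400, tolerance = 10)
  expect_error(sim_turbidity_trace(turbidity_params(lt50_true = 2400,
                                                    duration = 2000)),
               class = "clotmetrics_bad_params")
  expect_error(turbidity_params(a_max = 0.4, baseline = 0.5),
               class = "clotmetrics_bad_params")
  expect_error(turbidity_params(ct50_true = 500, lt50_true = 400),
               class = "clotmetrics_bad_params")
})

test_that("mean recovered CT50 over 50 noisy seeds is within 2% of truth", {
  p <- turbidity_params(ct50_true = 300, noise_sd = 0.01 * 0.85)
  ct <- vapply(1:50, function(s)
    clotting_time(sim_turbidity_trace(p, seed = s), 0.5), numeric(1))
  expect_lt(abs(mean(ct) - 300) / 300, 0.02)
})

test_that("permeation generator round-trips exactly and scales linearly", {
  geo <- permeation_geometry(tubing_inner_diameter = 0.2)
  pe <- sim_permeation_readings(0.29e-9, geo, noise_sd = 0)
  expect_equal(analyze_permeation(pe)$ks, 0.29e-9, tolerance = 1e-9)
  # doubling ks doubles the throughput length at fixed time
  pe2 <- sim_permeation_readings(0.58e-9, geo, noise_sd = 0)
  expect_equal(max(pe2$cumlength_mm) / max(pe$cumlength_mm), 2,
               tolerance = 1e-9)
  # 0.5 mm reading noise: mean recovery over 20 seeds within 5%
  ks_hat <- vapply(1:20, function(s)
    analyze_permeation(sim_permeation_readings(0.29e-9, geo, noise_sd = 0.5,
                                               seed = s))$ks, numeric(1))
  expect_lt(abs(mean(ks_hat) - 0.29e-9) / 0.29e-9, 0.05)
  expect_error(sim_permeation_readings(0.29e-9, geo, read_interval = 0),
               class = "clotmetrics_bad_argument")
})

test_that("rheometry generator places the programmed flow limit on the ramp", {
  r_step <- 10^(5 / 99)   # default log ramp: 100 steps over 0.01-1000 Pa
  fl <- flow_limit(sim_rheo_record())   # plain fibrin defaults
  expect_true(fl$transition_found)
  expect_equal(fl$gamma_max, 1.9, tolerance = 1e-9)
  expect_lte(abs(log(fl$tau0 / 100.4)), log(r_step) * 1.0001)
  # stiff-gel parameter set (high tau0, high gamma_max)
  fl2 <- flow_limit(sim_rheo_record(gprime_plateau = 82.1,
                                    gdoubleprime_plateau = 8.3,
                                    tau0_true = 678.5, gamma_max_true = 5.5))
  expect_equal(fl2$gamma_max, 5.5, tolerance = 1e-9)
  expect_lte(abs(log(fl2$tau0 / 678.5)), log(r_step) * 1.0001)
  # no transition programmed
  expect_false(flow_limit(sim_rheo_record(tau0_true = NULL))$transition_found)
  # physically inconsistent combination is rejected with a message
  expect_error(sim_rheo_record(gprime_plateau = 34.6, tau0_true = 20,
                               gamma_max_true = 100),
               class = "clotmetrics_inconsistent_params")
  expect_error(sim_rheo_record(tau0_true = 5000),
               class = "clotmetrics_bad_params")
})

test_that("fiber generator validates inputs and warns on sub-resolution fibers", {
  expect_error(fiber_field_params(n_fibers = 0), class = "clotmetrics_bad_params")
  expect_warning(
    sim_fiber_image(fiber_field_params(
      n_fibers = 3, diameter_law = list(family = "constant", value = 8),
      blur_sigma = 0, noise_sd = 0)),
    class = "clotmetrics_subresolution")
  fi <- sim_fiber_image(fiber_field_params(seed = 11))
  gt <- attr(fi, "ground_truth")
  expect_length(gt$widths_nm, 12)
  expect_true(all(gt$widths_nm > 0))
  expect_true(is.matrix(attr(fi, "true_mask")))
})

test_that("clottability generator censors and reports the programmed crossing", {
  flat <- sim_clottability_course(initial_ct = 10, prolongation_rate = 0)
  expect_true(all(flat$display_s == 10))
  expect_false(any(flat$censored))
  # crossing 120 s between the 15 and 20 min samplings
  cc <- sim_clottability_course(initial_ct = 10, prolongation_rate = 0.13,
                                sampling_times = c(0, 5, 10, 15, 20, 30))
  expect_equal(time_to_nonclottability(cc), 20)
  expect_true(all(cc$display_s[cc$censored] == 121))
  expect_error(sim_clottability_course(sampling_times = numeric(0)),
               class = "clotmetrics_bad_params")
})

test_that("analysis error shrinks monotonically as generator noise vanishes", {
  # turbidity: median |CT50 - truth| over 30 seeds on a 3-point noise ladder
  med_err <- vapply(c(0.016, 0.008, 0), function(ns) {
    errs <- vapply(1:30, function(s) {
      tr <- sim_turbidity_trace(turbidity_params(noise_sd = ns), seed = s)
      abs(clotting_time(tr, 0.5, smooth_window = if (ns > 0) 5 else NULL) - 300)
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) <= 0))
  # permeation: mean |ks - truth| over 15 seeds
  geo <- permeation_geometry(tubing_inner_diameter = 0.2)
  ks_err <- vapply(c(1, 0.3, 0), function(ns) {
    mean(vapply(1:15, function(s)
      abs(analyze_permeation(sim_permeation_readings(0.29e-9, geo,
                                                     noise_sd = ns,
                                                     seed = s))$ks - 0.29e-9),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ks_err) <= 0))
})
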