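test_that("maximum-likelihood fits recover parameters and rank families", {
  x <- with_seed_helper(1, stats::rlnorm(10000, 4.5, 0.4))
  f <- fit_distribution(x, "lognormal")
  expect_lt(abs(f$params[["meanlog"]] - 4.5) / 4.5, 0.02)
  expect_lt(abs(f$params[["sdlog"]] - 0.4) / 0.4, 0.02)
  # true family wins the likelihood comparison on large samples
  x2 <- with_seed_helper(2, stats::rlnorm(2000, log(95), 0.5))
  ll <- vapply(c("lognormal", "gamma", "normal"), function(fam)
    fit_distribution(x2, fam)$loglik, numeric(1))
  expect_equal(names(which.max(ll)), "lognormal")
  # degenerate and invalid inputs
  expect_error(fit_distribution(rep(5, 10), "lognormal"),
               class = "clotmetrics_degenerate_fit")
  expect_error(fit_distribution(c(-1, 2, 3, 4, 5), "gamma"),
               class = "clotmetrics_bad_sample")
  expect_error(fit_distribution(1:3, "normal"), class = "clotmetrics_bad_sample")
})

test_that("the gamma MLE agrees with the MASS::fitdistr cross-check", {
  x <- with_seed_helper(3, stats::rgamma(3000, shape = 4, rate = 0.05))
  f <- fit_distribution(x, "gamma")
  ref <- suppressWarnings(MASS::fitdistr(x, "gamma"))
  expect_equal(f$params[["shape"]], unname(ref$estimate["shape"]),
               tolerance = 1e-3)
  expect_equal(f$params[["rate"]], unname(ref$estimate["rate"]),
               tolerance = 1e-3)
})

test_that("Kuiper's statistic matches its defining constructions", {
  # a single observation at the fitted median: V = 0.5 + 0.5 = 1
  expect_equal(kuiper_statistic(0, function(q) rep(0.5, length(q))), 1)
  # quantile-spaced sample attains the minimal V = 1/n
  f <- fit_distribution(with_seed_helper(4, stats::rlnorm(500, 4.5, 0.4)),
                        "lognormal")
  n <- 20
  q <- stats::qlnorm((seq_len(n) - 0.5) / n, f$params[1L], f$params[2L])
  expect_equal(kuiper_statistic(q, dist_cdf(f)), 1 / n, tolerance = 1e-12)
  # invariance under a common strictly monotone transform (rank statistic)
  x <- with_seed_helper(5, stats::rlnorm(40, 4.5, 0.4))
  cdf <- dist_cdf(f)
  expect_equal(kuiper_statistic(x, cdf),
               kuiper_statistic(log(x), function(q) cdf(exp(q))),
               tolerance = 1e-12)
})

test_that("the Kuiper MC test is reproducible and sane on self-comparison", {
  a <- with_seed_helper(6, stats::rlnorm(120, log(95), 0.4))
  # self-comparison is clearly non-significant (the fitted-reference V of a
  # sample against itself is not materially smaller than a null replicate, so
  # p spreads broadly over the non-rejection region rather than piling at 1)
  t1 <- kuiper_mc_test(a, a, n_mc = 500, seed = 11)
  expect_gte(t1$p_value, 0.2)
  expect_identical(kuiper_mc_test(a, a, n_mc = 500, seed = 11)$p_value,
                   t1$p_value)
  expect_warning(kuiper_mc_test(a, a, n_mc = 50, seed = 1),
                 class = "clotmetrics_unstable_p")
  # pooled-fit variant runs and returns a valid p
  t2 <- kuiper_mc_test(a, a * 1.05, n_mc = 200, seed = 3,
                       fit_target = "pooled")
  expect_true(t2$p_value > 0 && t2$p_value <= 1)
})

test_that("MC p-values with different seeds agree to Monte Carlo error", {
  a <- with_seed_helper(7, stats::rlnorm(300, log(95), 0.4))
  b <- with_seed_helper(8, stats::rlnorm(300, log(95 * 1.13), 0.4))
  p1 <- kuiper_mc_test(a, b, n_mc = 10000, seed = 21)$p_value
  p2 <- kuiper_mc_test(a, b, n_mc = 10000, seed = 22)$p_value
  expect_lt(abs(p1 - p2), 0.01)
})

test_that("two-sample KS matches hand results and stats::ks.test", {
  r <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 1)
  expect_equal(r$p_value, 2 / choose(6, 3))   # 0.1 by full enumeration
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  # exact branch against R's reference implementation
  a <- with_seed_helper(9, stats::rnorm(8)); b <- with_seed_helper(10, stats::rnorm(6))
  mine <- ks_two_sample(a, b)
  ref <- stats::ks.test(a, b, exact = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  # asymptotic branch
  a2 <- with_seed_helper(11, stats::rnorm(150))
  b2 <- with_seed_helper(12, stats::rnorm(200, 0.2))
  mine2 <- ks_two_sample(a2, b2)
  ref2 <- stats::ks.test(a2, b2, exact = FALSE)
  expect_equal(mine2$p_value, ref2$p.value, tolerance = 1e-9)
  expect_error(ks_two_sample(numeric(0), 1:3), class = "clotmetrics_bad_sample")
})

test_that("KS D is invariant under common strictly monotone transforms", {
  a <- with_seed_helper(13, stats::rlnorm(30, 4, 0.3))
  b <- with_seed_helper(14, stats::rlnorm(25, 4.2, 0.3))
  expect_equal(ks_two_sample(a, b)$statistic,
               ks_two_sample(log(a), log(b))$statistic, tolerance = 1e-12)
  expect_equal(kuiper_statistic(a, stats::plnorm),
               kuiper_statistic(log(a), stats::pnorm), tolerance = 1e-12)
})
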