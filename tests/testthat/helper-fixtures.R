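# In-code fixtures shared across test files.

# piecewise-linear "triangle" trace: rise 0 -> 1 over [0, 10], fall 1 -> 0
# over [10, 30]; half-max crossings at t = 5 (up) and t = 20 (down)
triangle_trace <- function(assay_mode = "intrinsic", t_addition = NULL) {
  t <- seq(0, 30, by = 2.5)
  a <- ifelse(t <= 10, t / 10, 1 - (t - 10) / 20)
  kinetic_trace(t, a, assay_mode = assay_mode, t_addition = t_addition)
}

# a mask with a single horizontal fiber of the given width (px)
horizontal_fiber_mask <- function(width_px, size = 128L, top = 60L) {
  m <- matrix(FALSE, size, size)
  m[top:(top + width_px - 1L), ] <- TRUE
  m
}

# a group of synthetic lysis wells sharing a programmed LT50 scale, with
# small multiplicative well-to-well variation
make_lysis_group <- function(lt50, n_wells, seed0, well_cv = 0.05,
                             noise_sd = 0.008) {
  lapply(seq_len(n_wells), function(i) {
    lt <- with_seed_helper(seed0 + i, lt50 * exp(stats::rnorm(1, 0, well_cv)))
    sim_turbidity_trace(
      turbidity_params(lt50_true = lt, noise_sd = noise_sd, duration = 4500),
      seed = seed0 + i)
  })
}

# seed-scoped RNG for helpers (mirrors the package-internal discipline)
with_seed_helper <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# brute-force two-sample KS null by full enumeration of group assignments;
# returns P(D >= d_obs) over all C(m+n, m) tie-free partitions
ks_enumeration_pvalue <- function(pooled, m, d_obs) {
  n <- length(pooled) - m
  combs <- utils::combn(length(pooled), m)
  ds <- apply(combs, 2L, function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    z <- sort(pooled)
    max(abs(vapply(z, function(t) sum(a <= t) / m - sum(b <= t) / n,
                   numeric(1))))
  })
  mean(ds >= d_obs - 1e-12)
}
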