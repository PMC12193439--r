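#' Parameters for the synthetic turbidity generator
#'
#' Describes a clot-formation (and optional lysis) turbidity waveform with
#' analytically placed half-maximum crossings, so that every waveform metric
#' has a known ground truth.  Defaults sketch a typical intrinsic-lysis well:
#' a 0.8 AU rise with CT50 at 300 s and LT50 at 2400 s over a one-hour read
#' at 10 s intervals.
#'
#' @param baseline baseline absorbance (AU), `>= 0`.
#' @param a_max maximal absorbance (AU), `> baseline`.
#' @param ct50_true true half-maximum crossing time on the ascending branch (s).
#' @param formation_steepness logistic rate of the ascending branch (1/s).
#' @param lt50_true true half-maximum crossing time on the descending branch
#'   (s); `NULL` for a formation-only (no lysis) trace.
#' @param lysis_steepness logistic rate of the descending branch (1/s).
#' @param noise_sd SD of additive i.i.d. Gaussian noise on absorbance (AU).
#' @param sample_interval plate-reader sampling interval (s).
#' @param duration total recording time (s); must exceed `lt50_true` when lysis
#'   is requested.
#' @param seed integer seed; every generated trace is bit-reproducible given
#'   `(params, seed)`.
#' @return A list of class `turbidity_params`.
#' @seealso [sim_turbidity_trace()]
#' @export
turbidity_params <- function(baseline = 0.05, a_max = 0.85, ct50_true = 300,
                             formation_steepness = 0.02, lt50_true = 2400,
                             lysis_steepness = 0.005, noise_sd = 0,
                             sample_interval = 10, duration = 3600,
                             seed = 1L) {
  stopifnot_scalar(baseline, "baseline", nonneg = TRUE)
  stopifnot_scalar(a_max, "a_max", positive = TRUE)
  if (a_max <= baseline)
    cm_stop("a_max must exceed baseline", "clotmetrics_bad_params")
  stopifnot_scalar(ct50_true, "ct50_true", positive = TRUE)
  stopifnot_scalar(formation_steepness, "formation_steepness", positive = TRUE)
  if (!is.null(lt50_true)) {
    stopifnot_scalar(lt50_true, "lt50_true", positive = TRUE)
    stopifnot_scalar(lysis_steepness, "lysis_steepness", positive = TRUE)
    if (ct50_true >= lt50_true)
      cm_stop("ct50_true must precede lt50_true", "clotmetrics_bad_params")
  }
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar(sample_interval, "sample_interval", positive = TRUE)
  stopifnot_scalar(duration, "duration", positive = TRUE)
  structure(list(baseline = baseline, a_max = a_max, ct50_true = ct50_true,
                 formation_steepness = formation_steepness,
                 lt50_true = lt50_true, lysis_steepness = lysis_steepness,
                 noise_sd = noise_sd, sample_interval = sample_interval,
                 duration = duration, seed = seed),
            class = "turbidity_params")
}

#' Simulate a turbidity trace with known waveform ground truth
#'
#' The noiseless waveform is the pointwise minimum of two logistic branches
#' (rise centered at `ct50_true`, fall centered at `lt50_true`), rescaled so
#' the sampled maximum equals `a_max` exactly.  With well-separated branches
#' the half-maximum crossings sit at `ct50_true` and `lt50_true` to far below
#' one sampling interval, which makes noiseless generation followed by
#' [clotting_time()] / [lysis_time()] an exact round trip at the sampling
#' resolution.
#'
#' @param params a [turbidity_params()] object.
#' @param seed optional override of `params$seed`.
#' @return A [kinetic_trace()] with attribute `ground_truth`, a list holding
#'   the programmed `a_max`, `ct50`, `ct90` (from the logistic inverse),
#'   `lt50` and the full parameter echo.
#' @export
sim_turbidity_trace <- function(params, seed = NULL) {
  stopifnot(inherits(params, "turbidity_params"))
  if (is.null(seed)) seed <- params$seed
  lysis <- !is.null(params$lt50_true)
  if (lysis && params$duration < params$lt50_true)
    cm_stop("duration is shorter than lt50_true: lysis cannot be recorded",
            "clotmetrics_bad_params")
  times <- seq(0, params$duration, by = params$sample_interval)
  rise <- stats::plogis(times, location = params$ct50_true,
                        scale = 1 / params$formation_steepness)
  g <- if (lysis) {
    fall <- stats::plogis(times, location = params$lt50_true,
                          scale = 1 / params$lysis_steepness,
                          lower.tail = FALSE)
    pmin(rise, fall)
  } else rise
  amp <- params$a_max - params$baseline
  signal <- params$baseline + amp * g / max(g)
  noisy <- with_seed(seed, signal + stats::rnorm(length(signal), 0, params$noise_sd))
  trace <- kinetic_trace(times, noisy, assay_mode = "intrinsic",
                         baseline = params$baseline)
  attr(trace, "ground_truth") <- list(
    a_max = params$a_max,
    ct50 = params$ct50_true,
    ct90 = params$ct50_true + log(9) / params$formation_steepness,
    lt50 = if (lysis) params$lt50_true else NA_real_,
    params = unclass(params), seed = seed)
  trace
}

#' Geometry constants of a clot permeation experiment
#'
#' Defaults are the printed constants of the assay: buffer viscosity
#' `1e-7` N·s/cm² (0.01 poise), clot length 1.5 cm, clot cross-section
#' 0.09 cm², pressure drop 0.170 N/cm².  The inner diameter of the collection
#' tubing is apparatus-specific and has no default: it must be supplied.
#'
#' @param tubing_inner_diameter inner diameter of the throughput tubing (cm);
#'   mandatory.
#' @param viscosity_n buffer viscosity (N·s/cm²).
#' @param clot_length_L clot length (cm).
#' @param clot_area_A clot cross-sectional area (cm²).
#' @param pressure_drop_dP hydrostatic pressure drop across the clot (N/cm²).
#' @return A list of class `permeation_geometry`.
#' @export
permeation_geometry <- function(tubing_inner_diameter, viscosity_n = 1e-7,
                                clot_length_L = 1.5, clot_area_A = 0.09,
                                pressure_drop_dP = 0.170) {
  if (missing(tubing_inner_diameter))
    cm_stop("tubing_inner_diameter must be supplied (no default exists)",
            "clotmetrics_bad_params")
  stopifnot_scalar(tubing_inner_diameter, "tubing_inner_diameter", positive = TRUE)
  stopifnot_scalar(viscosity_n, "viscosity_n", positive = TRUE)
  stopifnot_scalar(clot_length_L, "clot_length_L", positive = TRUE)
  stopifnot_scalar(clot_area_A, "clot_area_A", positive = TRUE)
  stopifnot_scalar(pressure_drop_dP, "pressure_drop_dP", positive = TRUE)
  structure(list(tubing_inner_diameter = tubing_inner_diameter,
                 viscosity_n = viscosity_n, clot_length_L = clot_length_L,
                 clot_area_A = clot_area_A, pressure_drop_dP = pressure_drop_dP),
            class = "permeation_geometry")
}

#' Simulate cumulative permeation throughput readings
#'
#' Under Darcy flow at constant pressure the permeated volume grows linearly in
#' time; the generator converts the flow implied by `ks_true` into the mm
#' advance of the liquid front in the collection tubing and adds optional
#' Gaussian reading noise.  A noiseless series run through
#' [volumetric_flow()] + [darcy_constant()] recovers `ks_true` exactly.
#'
#' @param ks_true true Darcy constant (cm²); the generator default elsewhere in
#'   the package is `0.29e-9` cm², the permeability scale of a plain fibrin gel.
#' @param geometry a [permeation_geometry()].
#' @param read_interval time between readings (s); default 600 s (10 min).
#' @param n_reads number of readings after the time origin.
#' @param noise_sd SD of Gaussian noise on each cumulative length reading (mm).
#' @param seed integer seed.
#' @return A `permeation_experiment` (see [permeation_experiment()]) with
#'   attribute `ground_truth` echoing `ks_true` and the parameters.
#' @export
sim_permeation_readings <- function(ks_true, geometry, read_interval = 600,
                                    n_reads = 12, noise_sd = 0, seed = 1L) {
  stopifnot_scalar(ks_true, "ks_true", positive = TRUE)
  stopifnot(inherits(geometry, "permeation_geometry"))
  stopifnot_scalar(read_interval, "read_interval", positive = TRUE)
  if (n_reads < 1L) cm_stop("n_reads must be >= 1", "clotmetrics_bad_params")
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  # Darcy: Q/t = ks * A * dP / (n * L)   [cm^3/s]
  q_rate <- ks_true * geometry$clot_area_A * geometry$pressure_drop_dP /
    (geometry$viscosity_n * geometry$clot_length_L)
  tube_area <- pi * (geometry$tubing_inner_diameter / 2)^2   # cm^2
  len_rate_mm <- q_rate / tube_area * 10                     # mm/s
  times <- read_interval * seq_len(n_reads)
  lengths <- len_rate_mm * times
  if (noise_sd > 0)
    lengths <- with_seed(seed, lengths + stats::rnorm(n_reads, 0, noise_sd))
  lengths <- cummax(pmax(lengths, 0))  # a front cannot recede: keep readings physical
  pe <- permeation_experiment(geometry,
                              times_s = c(0, times),
                              cumlength_mm = c(0, lengths))
  attr(pe, "ground_truth") <- list(ks = ks_true, noise_sd = noise_sd,
                                   read_interval = read_interval, seed = seed)
  pe
}

#' Simulate an oscillation rheometry record with a programmed gel-fluid
#' transition
#'
#' The clotting phase shows storage and loss moduli rising smoothly and
#' reaching their plateaus exactly (so plateau recovery is exact on noiseless
#' records).  The stress-ramp phase is Hookean in the effective secant modulus
#' `tau0_true / gamma_max_true` up to the last ramp stress at or below
#' `tau0_true`, where the strain equals `gamma_max_true`; beyond it the gel
#' flows as a Newtonian fluid whose viscosity is lower than the pre-yield
#' apparent viscosity by `fall_factor_true` (default 1000, i.e. far beyond the
#' "abrupt fall" detection threshold).
#'
#' Defaults are the plateau and flow-limit values of a plain fibrin gel:
#' G' = 34.6 Pa, G'' = 2.8 Pa, gamma_max = 1.9, tau0 = 100.4 Pa.
#'
#' @param gprime_plateau plateau storage modulus (Pa).
#' @param gdoubleprime_plateau plateau loss modulus (Pa).
#' @param tau0_true critical shear stress of the transition (Pa); `NULL`
#'   programs a record with no gel-fluid transition.
#' @param gamma_max_true maximal bearable strain (dimensionless) at the last
#'   pre-transition ramp point.
#' @param ramp_stress stress schedule (Pa), non-decreasing; default 100
#'   logarithmic steps from 0.01 to 1000 Pa.
#' @param ramp_duration duration of the ramp (s).
#' @param clot_duration duration of the clotting phase (s).
#' @param clot_dt sampling interval of the clotting phase (s).
#' @param modulus_rise_time time (s) at which the moduli reach their plateau.
#' @param fall_factor_true factor by which the viscosity falls at the
#'   transition (must be `>= 100` so the fall is unambiguous).
#' @param noise_sd SD of Gaussian noise added to the clotting-phase moduli (Pa).
#' @param consistency_factor largest tolerated ratio between the ramp secant
#'   modulus `tau0_true/gamma_max_true` and `gprime_plateau`; combinations
#'   outside it are rejected as physically inconsistent.
#' @param seed integer seed.
#' @return A [rheo_record()] with attribute `ground_truth` (programmed
#'   plateaus, `tau0`, `gamma_max`, and the ramp stress actually carrying
#'   `gamma_max`).
#' @export
sim_rheo_record <- function(gprime_plateau = 34.6, gdoubleprime_plateau = 2.8,
                            tau0_true = 100.4, gamma_max_true = 1.9,
                            ramp_stress = NULL, ramp_duration = 300,
                            clot_duration = 600, clot_dt = 2,
                            modulus_rise_time = 240, fall_factor_true = 1000,
                            noise_sd = 0, consistency_factor = 10,
                            seed = 1L) {
  stopifnot_scalar(gprime_plateau, "gprime_plateau", positive = TRUE)
  stopifnot_scalar(gdoubleprime_plateau, "gdoubleprime_plateau", nonneg = TRUE)
  if (is.null(ramp_stress))
    ramp_stress <- 10^seq(log10(0.01), log10(1000), length.out = 100L)
  if (any(diff(ramp_stress) < 0))
    cm_stop("ramp_stress must be non-decreasing", "clotmetrics_bad_params")
  n_ramp <- length(ramp_stress)
  ramp_times <- seq(0, ramp_duration, length.out = n_ramp)

  # clotting phase: smoothstep rise reaching the plateau exactly at rise_time
  t_clot <- seq(0, clot_duration, by = clot_dt)
  x <- pmin(t_clot / modulus_rise_time, 1)
  s <- x * x * (3 - 2 * x)
  gp <- gprime_plateau * s
  gpp <- gdoubleprime_plateau * s
  if (noise_sd > 0) {
    noise <- with_seed(seed, list(stats::rnorm(length(gp), 0, noise_sd),
                                  stats::rnorm(length(gpp), 0, noise_sd)))
    gp <- gp + noise[[1L]]; gpp <- gpp + noise[[2L]]
  }

  if (is.null(tau0_true)) {
    gamma <- ramp_stress / gprime_plateau   # Hookean throughout, no transition
    tau_star <- NA_real_
  } else {
    stopifnot_scalar(tau0_true, "tau0_true", positive = TRUE)
    stopifnot_scalar(gamma_max_true, "gamma_max_true", positive = TRUE)
    if (tau0_true < min(ramp_stress) || tau0_true > max(ramp_stress))
      cm_stop("tau0_true lies outside the ramp stress range",
              "clotmetrics_bad_params")
    if (fall_factor_true < 100)
      cm_stop("fall_factor_true must be >= 100 for an unambiguous transition",
              "clotmetrics_bad_params")
    pre <- which(ramp_stress <= tau0_true)
    idx_star <- pre[length(pre)]
    tau_star <- ramp_stress[idx_star]
    g_ramp <- tau_star / gamma_max_true   # secant modulus at the flow limit
    ratio <- max(g_ramp / gprime_plateau, gprime_plateau / g_ramp)
    if (ratio > consistency_factor)
      cm_stop(sprintf(paste0(
        "gamma_max_true is inconsistent with the tau0_true/gprime relation: ",
        "secant modulus tau0/gamma_max = %.3g Pa differs from gprime_plateau ",
        "= %.3g Pa by more than a factor %g"),
        g_ramp, gprime_plateau, consistency_factor),
        "clotmetrics_inconsistent_params")
    gamma <- ramp_stress / g_ramp
    if (idx_star < n_ramp) {
      # pre-yield apparent viscosity at the flow limit (backward difference),
      # then Newtonian flow at eta_pre / fall_factor_true
      dt_step <- ramp_times[2L] - ramp_times[1L]
      dgamma_pre <- gamma[idx_star] -
        if (idx_star > 1L) gamma[idx_star - 1L] else 0
      eta_pre <- tau_star * dt_step / max(dgamma_pre, .Machine$double.eps)
      eta_post <- eta_pre / fall_factor_true
      post <- (idx_star + 1L):n_ramp
      gamma[post] <- gamma[idx_star] +
        cumsum(ramp_stress[post] / eta_post * dt_step)
    }
  }

  rec <- rheo_record(
    clotting_phase = data.frame(time = t_clot, gprime = gp, gdoubleprime = gpp),
    ramp_phase = data.frame(time = clot_duration + ramp_times,
                            tau = ramp_stress, gamma = gamma))
  attr(rec, "ground_truth") <- list(
    gprime_plateau = gprime_plateau,
    gdoubleprime_plateau = gdoubleprime_plateau,
    tau0 = if (is.null(tau0_true)) NA_real_ else tau0_true,
    gamma_max = if (is.null(tau0_true)) NA_real_ else gamma_max_true,
    tau_star = tau_star, seed = seed)
  rec
}

#' Simulate a fibrinogen clottability time course
#'
#' Emulates withdrawal sampling during fibrinogen digestion by a fibrinolytic
#' protease: the clotting time of the residual clottable fibrinogen starts at
#' `initial_ct` (10 s with undegraded fibrinogen) and is prolonged
#' exponentially at `prolongation_rate` as digestion proceeds.  Readings
#' exceeding `censor_threshold` are censored (non-clottable) and displayed as
#' `censor_threshold + 1` seconds.
#'
#' @param initial_ct clotting time of undegraded fibrinogen (s).
#' @param prolongation_rate exponential prolongation rate (1/min); 0 yields a
#'   flat course.
#' @param censor_threshold censoring threshold (s); default 120 s.
#' @param sampling_times digestion sampling times (min), non-empty, strictly
#'   increasing.
#' @param noise_sd SD of multiplicative lognormal reading noise (on the log
#'   scale); default 0.
#' @param seed integer seed.
#' @return A `clottability_course` (see [censor_course()]) with attribute
#'   `ground_truth` holding the true threshold-crossing digestion time (min,
#'   `Inf` when the course never crosses).
#' @export
sim_clottability_course <- function(initial_ct = 10, prolongation_rate = 0.2,
                                    censor_threshold = 120,
                                    sampling_times = c(0, 2, 5, 10, 15, 20,
                                                       30, 45, 60),
                                    noise_sd = 0, seed = 1L) {
  stopifnot_scalar(initial_ct, "initial_ct", positive = TRUE)
  stopifnot_scalar(prolongation_rate, "prolongation_rate", nonneg = TRUE)
  stopifnot_scalar(censor_threshold, "censor_threshold", positive = TRUE)
  if (length(sampling_times) == 0L)
    cm_stop("sampling_times must be non-empty", "clotmetrics_bad_params")
  if (any(diff(sampling_times) <= 0))
    cm_stop("sampling_times must be strictly increasing", "clotmetrics_bad_params")
  ct <- initial_ct * exp(prolongation_rate * sampling_times)
  if (noise_sd > 0)
    ct <- with_seed(seed,
                    ct * exp(stats::rnorm(length(ct), 0, noise_sd)))
  course <- censor_course(digestion_min = sampling_times, clotting_s = ct,
                          threshold = censor_threshold)
  cross <- if (prolongation_rate > 0 && censor_threshold > initial_ct)
    log(censor_threshold / initial_ct) / prolongation_rate else
      if (censor_threshold <= initial_ct) 0 else Inf
  attr(course, "ground_truth") <- list(crossing_min = cross,
                                       initial_ct = initial_ct,
                                       prolongation_rate = prolongation_rate,
                                       seed = seed)
  course
}
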