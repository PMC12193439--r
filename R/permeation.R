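#' Construct a clot permeation experiment
#'
#' Pairs the assay geometry with the cumulative throughput-length readings of
#' the liquid front in the collection tubing.
#'
#' @param geometry a [permeation_geometry()].
#' @param times_s reading times (s), strictly increasing, `>= 2` readings.
#' @param cumlength_mm cumulative throughput lengths (mm), non-decreasing.
#' @return A list of class `permeation_experiment`.
#' @export
permeation_experiment <- function(geometry, times_s, cumlength_mm) {
  stopifnot(inherits(geometry, "permeation_geometry"))
  times_s <- as.numeric(times_s); cumlength_mm <- as.numeric(cumlength_mm)
  if (length(times_s) < 2L)
    cm_stop("at least 2 readings are required", "clotmetrics_bad_readings")
  if (length(times_s) != length(cumlength_mm))
    cm_stop("times and lengths must have equal length", "clotmetrics_bad_readings")
  if (any(diff(times_s) <= 0))
    cm_stop("reading times must be strictly increasing", "clotmetrics_bad_readings")
  if (any(diff(cumlength_mm) < 0))
    cm_stop("cumulative throughput length decreased: reading error",
            "clotmetrics_bad_readings")
  structure(list(geometry = geometry, times_s = times_s,
                 cumlength_mm = cumlength_mm),
            class = "permeation_experiment")
}

#' Volumetric flow from throughput-length readings
#'
#' Converts the mm advance of the liquid front in the collection tubing into
#' the permeated buffer volume, `Q = pi (d/2)^2 * length`, and reports
#' per-interval flow rates for a steadiness check.
#'
#' @param experiment a [permeation_experiment()].
#' @param start_offset readings earlier than this time (s) are dropped before
#'   analysis (e.g. to exclude an initial wash); default 0.
#' @return A list with `Q` (cm³ permeated over the analysis window),
#'   `elapsed_s`, `mean_rate` (cm³/s) and `interval_rates` (cm³/s per reading
#'   interval).
#' @export
volumetric_flow <- function(experiment, start_offset = 0) {
  stopifnot(inherits(experiment, "permeation_experiment"))
  keep <- experiment$times_s >= start_offset
  if (sum(keep) < 2L)
    cm_stop("fewer than 2 readings remain after the start offset",
            "clotmetrics_bad_readings")
  t <- experiment$times_s[keep]
  len_cm <- experiment$cumlength_mm[keep] / 10
  area <- pi * (experiment$geometry$tubing_inner_diameter / 2)^2
  vol <- area * (len_cm - len_cm[1L])
  dt <- diff(t)
  list(Q = vol[length(vol)],
       elapsed_s = t[length(t)] - t[1L],
       mean_rate = vol[length(vol)] / (t[length(t)] - t[1L]),
       interval_rates = diff(vol) / dt)
}

#' Darcy permeation coefficient
#'
#' `Ks = Q * n * L / (t * A * dP)`, the permeation (Darcy) constant of the gel
#' in cm², a proxy for network pore size: buffer viscosity `n` (N·s/cm²), clot
#' length `L` (cm), cross-sectional area `A` (cm²), pressure drop `dP` (N/cm²).
#'
#' @param Q permeated volume (cm³).
#' @param t elapsed time (s), `> 0`.
#' @param geometry a [permeation_geometry()].
#' @return Darcy constant Ks in cm².
#' @examples
#' geo <- permeation_geometry(tubing_inner_diameter = 0.2)
#' darcy_constant(Q = 0.0918, t = 6000, geometry = geo)  # 1.5e-10 cm^2
#' @export
darcy_constant <- function(Q, t, geometry) {
  stopifnot(inherits(geometry, "permeation_geometry"))
  stopifnot_scalar(Q, "Q", nonneg = TRUE)
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0)
    cm_stop("t must be a positive time in seconds", "clotmetrics_bad_argument")
  Q * geometry$viscosity_n * geometry$clot_length_L /
    (t * geometry$clot_area_A * geometry$pressure_drop_dP)
}

#' Full permeation analysis with steadiness QC
#'
#' Computes Q over the QC window and the Darcy constant, flagging unsteady flow
#' (coefficient of variation of the per-interval rates above `cv_limit`, e.g.
#' from clot rupture or reservoir depletion).
#'
#' @inheritParams volumetric_flow
#' @param cv_limit largest accepted coefficient of variation of interval flow
#'   rates; default 0.2.
#' @return A list with `Q`, `mean_rate`, `ks` (cm²), `rate_cv` and `qc_flags`
#'   (character vector, possibly empty).
#' @export
analyze_permeation <- function(experiment, start_offset = 0, cv_limit = 0.2) {
  fl <- volumetric_flow(experiment, start_offset)
  flags <- character(0)
  cv <- if (mean(fl$interval_rates) > 0)
    stats::sd(fl$interval_rates) / mean(fl$interval_rates) else NA_real_
  if (is.na(cv)) flags <- c(flags, "zero_flow")
  else if (cv > cv_limit) flags <- c(flags, "unsteady_flow")
  list(Q = fl$Q, mean_rate = fl$mean_rate,
       ks = darcy_constant(fl$Q, fl$elapsed_s, experiment$geometry),
       rate_cv = cv, qc_flags = flags)
}
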