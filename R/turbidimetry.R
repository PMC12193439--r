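#' Construct a turbidimetric kinetic trace
#'
#' A kinetic trace holds the absorbance signal recorded at 340 nm during clot
#' formation and (optionally) lysis, together with the metadata needed to place
#' the lysis time origin.  In the *intrinsic* layout the lytic enzyme is present
#' from time zero and lysis times are measured from zero; in the *extrinsic*
#' layout the lytic agent is added onto a preformed clot at `t_addition` and
#' lysis times are measured from that addition.
#'
#' @param times numeric vector of sampling times (s), strictly increasing.
#' @param absorbance numeric vector of absorbance readings (AU), same length.
#' @param assay_mode `"intrinsic"` or `"extrinsic"`.
#' @param t_addition time (s) of lytic-agent addition; required for extrinsic
#'   traces and must fall inside the recorded time range.
#' @param baseline baseline absorbance (AU).  Defaults to the first reading;
#'   override when a separate blank is available.
#' @return An object of class `kinetic_trace`.
#' @examples
#' tr <- kinetic_trace(seq(0, 100, 10), c(0.05, 0.05, 0.2, 0.5, 0.8,
#'                                        0.85, 0.8, 0.6, 0.4, 0.3, 0.2))
#' max_turbidity(tr)
#' @export
kinetic_trace <- function(times, absorbance,
                          assay_mode = c("intrinsic", "extrinsic"),
                          t_addition = NULL, baseline = NULL) {
  assay_mode <- match.arg(assay_mode)
  times <- as.numeric(times)
  absorbance <- as.numeric(absorbance)
  if (length(times) < 3L)
    cm_stop("a kinetic trace needs at least 3 points", "clotmetrics_bad_trace")
  if (length(times) != length(absorbance))
    cm_stop("times and absorbance must have equal length", "clotmetrics_bad_trace")
  if (any(diff(times) <= 0))
    cm_stop("times must be strictly increasing", "clotmetrics_bad_trace")
  if (assay_mode == "extrinsic") {
    if (is.null(t_addition))
      cm_stop("extrinsic traces require t_addition", "clotmetrics_bad_trace")
    stopifnot_scalar(t_addition, "t_addition")
    if (t_addition < times[1L] || t_addition > times[length(times)])
      cm_stop("t_addition must lie within the recorded time range",
              "clotmetrics_bad_trace")
  }
  if (is.null(baseline)) baseline <- absorbance[1L]
  stopifnot_scalar(baseline, "baseline")
  structure(
    list(times = times, absorbance = absorbance, assay_mode = assay_mode,
         t_addition = t_addition, baseline = baseline),
    class = "kinetic_trace"
  )
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> %d points, %.0f-%.0f s, %s mode\n",
              length(x$times), x$times[1L], x$times[length(x$times)],
              x$assay_mode))
  invisible(x)
}

#' Normalize a trace so baseline maps to 0 and the maximum to 1
#'
#' Turbidity curves are conventionally displayed with the maximal turbidity
#' scaled to 1.  Normalization is affine, so all waveform times (CT50, CT90,
#' LT50) computed on the normalized trace equal those of the raw trace.
#'
#' @param trace a [kinetic_trace()].
#' @param min_amplitude smallest absorbance rise above baseline (AU) accepted
#'   as evidence of clotting; flat traces raise a `no_clotting` error.
#' @return A `kinetic_trace` with absorbance in `[0, 1]` and baseline 0.
#' @export
normalize_trace <- function(trace, min_amplitude = 0.05) {
  stopifnot(inherits(trace, "kinetic_trace"))
  amp <- max(trace$absorbance) - trace$baseline
  if (amp < min_amplitude)
    cm_stop("trace never rises above baseline: no clotting detected",
            "clotmetrics_no_clotting")
  kinetic_trace((trace$times), (trace$absorbance - trace$baseline) / amp,
                assay_mode = trace$assay_mode, t_addition = trace$t_addition,
                baseline = 0)
}

#' Maximal turbidity and its time
#'
#' @param trace a [kinetic_trace()].
#' @return A list with `a_max` (AU, absolute), `t_amax` (s; ties broken by the
#'   earliest time) and `amplitude` (`a_max` minus baseline).
#' @export
max_turbidity <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  i <- which.max(trace$absorbance)   # which.max takes the first of ties
  list(a_max = trace$absorbance[i], t_amax = trace$times[i],
       amplitude = trace$absorbance[i] - trace$baseline)
}

#' Clotting time: time to a fraction of maximal turbidity on the ascending branch
#'
#' CT90 (`fraction = 0.9`) and CT50 (`fraction = 0.5`) are the times, measured
#' from time zero, at which the turbidity first reaches 90% or 50% of the
#' maximal turbidity above baseline on the ascending part of the curve.
#' Crossings are refined by linear interpolation between samples, so the
#' resolution is finer than the sampling interval.
#'
#' @param trace a [kinetic_trace()].
#' @param fraction fraction of the maximal amplitude, in (0, 1); conventionally
#'   0.9 or 0.5.
#' @param smooth_window optional odd integer width of a centered moving-average
#'   filter applied before threshold detection (default: none).
#' @param min_amplitude smallest rise above baseline (AU) accepted as clotting.
#' @return Clotting time in seconds.
#' @export
clotting_time <- function(trace, fraction = 0.9, smooth_window = NULL,
                          min_amplitude = 0.05) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    cm_stop("fraction must lie strictly between 0 and 1",
            "clotmetrics_bad_argument")
  a <- moving_average(trace$absorbance, smooth_window)
  peak <- which.max(a)
  amp <- a[peak] - trace$baseline
  if (amp < min_amplitude)
    cm_stop("trace never rises above baseline: no clotting detected",
            "clotmetrics_no_clotting")
  asc <- seq_len(peak)
  first_crossing(trace$times[asc], a[asc],
                 trace$baseline + fraction * amp, "up")
}

#' Lysis time: time from the assay origin to half-maximal turbidity on the
#' descending branch
#'
#' LT50 is the time elapsed from time zero (intrinsic lysis) or from the lytic
#' agent addition (`t_addition`, extrinsic lysis) until turbidity first falls
#' to half of its maximal value above baseline after the peak.  If the signal
#' never falls to half-max the trace is flagged `incomplete_lysis` and
#' `NA` is returned (with the flag attached as an attribute).
#'
#' @inheritParams clotting_time
#' @return LT50 in seconds, or `NA_real_` carrying attribute
#'   `flag = "incomplete_lysis"` when the descending branch never reaches
#'   half-max.
#' @export
lysis_time <- function(trace, smooth_window = NULL, min_amplitude = 0.05) {
  stopifnot(inherits(trace, "kinetic_trace"))
  a <- moving_average(trace$absorbance, smooth_window)
  peak <- which.max(a)
  amp <- a[peak] - trace$baseline
  if (amp < min_amplitude)
    cm_stop("trace never rises above baseline: no clotting detected",
            "clotmetrics_no_clotting")
  origin <- if (trace$assay_mode == "extrinsic") trace$t_addition else 0
  desc <- peak:length(a)
  t_half <- first_crossing(trace$times[desc], a[desc],
                           trace$baseline + 0.5 * amp, "down")
  if (is.na(t_half))
    return(structure(NA_real_, flag = "incomplete_lysis"))
  t_half - origin
}

#' All clot-waveform metrics of a trace
#'
#' Convenience wrapper computing `a_max`, `t_amax`, CT90, CT50 and LT50 in one
#' pass, together with quality flags (`no_clotting`, `no_lysis`,
#' `incomplete_lysis`).
#'
#' @inheritParams clotting_time
#' @return A list of class `clot_lysis_metrics` with fields `a_max`, `t_amax`,
#'   `ct90`, `ct50`, `lt50` and `flags` (character vector, possibly empty).
#' @export
clot_lysis_metrics <- function(trace, smooth_window = NULL,
                               min_amplitude = 0.05) {
  stopifnot(inherits(trace, "kinetic_trace"))
  flags <- character(0)
  # peak located on the same (optionally smoothed) signal as the crossing
  # times, so ct50 <= ct90 <= t_amax holds under noise as well
  sm <- moving_average(trace$absorbance, smooth_window)
  peak <- which.max(sm)
  mt <- list(a_max = sm[peak], t_amax = trace$times[peak],
             amplitude = sm[peak] - trace$baseline)
  if (mt$amplitude < min_amplitude) {
    return(structure(list(a_max = NA_real_, t_amax = NA_real_,
                          ct90 = NA_real_, ct50 = NA_real_, lt50 = NA_real_,
                          flags = "no_clotting"),
                     class = "clot_lysis_metrics"))
  }
  ct90 <- clotting_time(trace, 0.9, smooth_window, min_amplitude)
  ct50 <- clotting_time(trace, 0.5, smooth_window, min_amplitude)
  lt50 <- lysis_time(trace, smooth_window, min_amplitude)
  if (is.na(lt50)) {
    # distinguish a monotone trace (no descending branch at all) from a
    # descending branch that stalls above half-max
    flags <- if (peak == length(trace$absorbance)) "no_lysis" else
      "incomplete_lysis"
    lt50 <- NA_real_
  }
  structure(list(a_max = mt$a_max, t_amax = mt$t_amax,
                 ct90 = ct90, ct50 = ct50, lt50 = as.numeric(lt50),
                 flags = flags),
            class = "clot_lysis_metrics")
}

#' @export
print.clot_lysis_metrics <- function(x, ...) {
  cat(sprintf("A_max %.3f AU at %.0f s | CT50 %.1f s | CT90 %.1f s | LT50 %s\n",
              x$a_max, x$t_amax, x$ct50, x$ct90,
              if (is.na(x$lt50)) paste0("-- (", paste(x$flags, collapse = ","), ")")
              else sprintf("%.1f s", x$lt50)))
  invisible(x)
}

#' Express a metric in relative units against a reference
#'
#' Waveform metrics are conventionally reported in relative units (RU), the
#' ratio of a value to the corresponding value for the reference condition
#' (pure fibrin), so the reference maps to 1.00 and a doubled value to 2.00
#' (a 100% prolongation).
#'
#' @param value numeric value(s).
#' @param reference positive reference value on the same scale.
#' @return `value / reference`.
#' @export
relative_units <- function(value, reference) {
  if (!is.numeric(reference) || length(reference) != 1L ||
      !is.finite(reference) || reference <= 0)
    cm_stop("reference must be a positive scalar", "clotmetrics_bad_argument")
  value / reference
}
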