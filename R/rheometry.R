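#' Construct an oscillation rheometry record
#'
#' Holds the two phases of the assay: the clotting phase (storage and loss
#' moduli under small-amplitude oscillation, strain 0.015 at 1 Hz) and the
#' stress-ramp phase (applied shear stress tau and resulting strain gamma).
#'
#' @param clotting_phase data frame with columns `time` (s), `gprime` (Pa),
#'   `gdoubleprime` (Pa).
#' @param ramp_phase data frame with columns `time` (s), `tau` (Pa,
#'   non-decreasing), `gamma` (dimensionless).
#' @param oscillation metadata list; default records the strain 0.015 / 1 Hz
#'   oscillation settings.
#' @return A list of class `rheo_record`.
#' @export
rheo_record <- function(clotting_phase, ramp_phase,
                        oscillation = list(strain = 0.015, freq_hz = 1)) {
  stopifnot(is.data.frame(clotting_phase),
            all(c("time", "gprime", "gdoubleprime") %in% names(clotting_phase)))
  stopifnot(is.data.frame(ramp_phase),
            all(c("time", "tau", "gamma") %in% names(ramp_phase)))
  if (any(diff(ramp_phase$tau) < 0))
    cm_stop("ramp stress must be non-decreasing", "clotmetrics_bad_record")
  if (nrow(clotting_phase) > 0L && nrow(ramp_phase) > 0L &&
      max(clotting_phase$time) > min(ramp_phase$time))
    cm_stop("clotting and ramp phases overlap in time", "clotmetrics_bad_record")
  structure(list(clotting_phase = clotting_phase, ramp_phase = ramp_phase,
                 oscillation = oscillation),
            class = "rheo_record")
}

#' Plateau storage and loss moduli of the clotting phase
#'
#' The plateau is the mean of each modulus over the final fraction of the
#' clotting phase (default the last 20%), by which time the turbidimetric and
#' rheometric signals of a fully formed gel have levelled off.  The loss
#' tangent G''/G' quantifies how dissipative (versus elastic) the gel is.
#'
#' @param clotting_phase data frame with `time`, `gprime`, `gdoubleprime`, or a
#'   [rheo_record()].
#' @param window_frac fraction of the phase, from the end, averaged for the
#'   plateau; in (0, 1].
#' @return A list with `gprime_plateau`, `gdoubleprime_plateau` (Pa) and
#'   `loss_tangent`.
#' @export
plateau_moduli <- function(clotting_phase, window_frac = 0.2) {
  if (inherits(clotting_phase, "rheo_record"))
    clotting_phase <- clotting_phase$clotting_phase
  stopifnot(is.data.frame(clotting_phase))
  if (window_frac <= 0 || window_frac > 1)
    cm_stop("window_frac must be in (0, 1]", "clotmetrics_bad_argument")
  t <- clotting_phase$time
  if (length(t) < 2L || (t[length(t)] - t[1L]) < 60)
    cm_stop("at least 1 min of clotting-phase data is required",
            "clotmetrics_bad_record")
  t_lo <- t[length(t)] - window_frac * (t[length(t)] - t[1L])
  keep <- t >= t_lo
  gp <- mean(clotting_phase$gprime[keep])
  gpp <- mean(clotting_phase$gdoubleprime[keep])
  if (gp <= 0)
    cm_stop("plateau storage modulus is not positive: no gel formed",
            "clotmetrics_no_gel")
  list(gprime_plateau = gp, gdoubleprime_plateau = gpp,
       loss_tangent = gpp / gp)
}

#' Apparent dynamic viscosity along the stress ramp
#'
#' `eta(t) = tau(t) / (dgamma/dt)(t)` with the strain rate estimated by
#' centered finite differences (one-sided at the ends).  Intervals with zero
#' strain rate yield `Inf` with a `no_creep` flag.
#'
#' @param ramp_phase data frame with `time`, `tau`, `gamma`, or a
#'   [rheo_record()].
#' @return A data frame with columns `time`, `eta` (Pa·s) and logical
#'   `no_creep`.
#' @export
apparent_viscosity <- function(ramp_phase) {
  if (inherits(ramp_phase, "rheo_record")) ramp_phase <- ramp_phase$ramp_phase
  stopifnot(is.data.frame(ramp_phase))
  n <- nrow(ramp_phase)
  if (n < 3L)
    cm_stop("at least 3 ramp points are required", "clotmetrics_bad_record")
  t <- ramp_phase$time; g <- ramp_phase$gamma
  rate <- numeric(n)
  rate[1L] <- (g[2L] - g[1L]) / (t[2L] - t[1L])
  rate[n] <- (g[n] - g[n - 1L]) / (t[n] - t[n - 1L])
  mid <- 2:(n - 1L)
  rate[mid] <- (g[mid + 1L] - g[mid - 1L]) / (t[mid + 1L] - t[mid - 1L])
  no_creep <- rate == 0
  eta <- ifelse(no_creep, Inf, ramp_phase$tau / rate)
  data.frame(time = t, eta = eta, no_creep = no_creep)
}

#' Detect the gel-fluid transition on a stress ramp
#'
#' The transition is an abrupt fall in apparent viscosity: the first ramp point
#' at which viscosity drops below the running maximum divided by `fall_factor`
#' (default 10; a genuine gel-to-flow transition spans orders of magnitude, so
#' the detected stress is insensitive to the exact factor).  The maximal
#' bearable strain `gamma_max` and the critical shear stress `tau0` are read at
#' the last point before that index.
#'
#' Internally the detection uses a backward-difference strain rate so the last
#' pre-transition point is not contaminated by the post-yield strain jump
#' (centered differences smear the discontinuity one sample backwards, which
#' would bias the recovered `tau0` an extra ramp step low).
#'
#' @param record a [rheo_record()] (plateau moduli are then filled in) or a
#'   ramp-phase data frame.
#' @param fall_factor viscosity drop, relative to the running maximum, declared
#'   a transition; default 10.
#' @param window_frac plateau window for the moduli when a full record is
#'   given.
#' @return A list of class `flow_limit`: `gprime_plateau`,
#'   `gdoubleprime_plateau`, `loss_tangent` (NA when only a ramp is supplied),
#'   `gamma_max`, `tau0`, `transition_found`.
#' @export
flow_limit <- function(record, fall_factor = 10, window_frac = 0.2) {
  moduli <- list(gprime_plateau = NA_real_, gdoubleprime_plateau = NA_real_,
                 loss_tangent = NA_real_)
  if (inherits(record, "rheo_record")) {
    moduli <- plateau_moduli(record, window_frac)
    ramp <- record$ramp_phase
  } else ramp <- record
  stopifnot(is.data.frame(ramp))
  if (fall_factor <= 1)
    cm_stop("fall_factor must exceed 1", "clotmetrics_bad_argument")
  n <- nrow(ramp)
  if (n < 3L)
    cm_stop("at least 3 ramp points are required", "clotmetrics_bad_record")
  t <- ramp$time; g <- ramp$gamma
  rate <- c(NA_real_, diff(g) / diff(t))          # backward differences
  eta <- ramp$tau / rate
  eta[!is.na(rate) & rate == 0] <- Inf
  finite <- is.finite(eta)
  if (sum(finite) < 3L)
    cm_stop("fewer than 3 finite viscosity values on the ramp",
            "clotmetrics_bad_record")
  idx_f <- which(finite)
  run_max <- cummax(eta[idx_f])
  drop <- which(eta[idx_f] < run_max / fall_factor)
  if (length(drop) == 0L || idx_f[drop[1L]] <= 1L) {
    res <- c(moduli, list(gamma_max = NA_real_, tau0 = NA_real_,
                          transition_found = FALSE))
  } else {
    i <- idx_f[drop[1L]] - 1L   # last point before the transition index
    res <- c(moduli, list(gamma_max = g[i], tau0 = ramp$tau[i],
                          transition_found = TRUE))
  }
  structure(res, class = "flow_limit")
}

#' @export
print.flow_limit <- function(x, ...) {
  if (isTRUE(x$transition_found))
    cat(sprintf("gel-fluid transition: gamma_max = %.3g, tau0 = %.4g Pa\n",
                x$gamma_max, x$tau0))
  else cat("no gel-fluid transition detected\n")
  if (is.finite(x$gprime_plateau))
    cat(sprintf("plateau G' = %.3g Pa, G'' = %.3g Pa, G''/G' = %.4g\n",
                x$gprime_plateau, x$gdoubleprime_plateau, x$loss_tangent))
  invisible(x)
}
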