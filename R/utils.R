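# Internal helpers shared across modules.

# Classed error so callers can test on condition class rather than message text.
cm_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "clotmetrics_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

cm_warn <- function(msg, class) {
  warning(structure(
    class = c(class, "clotmetrics_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
# All generator randomness flows through this; no global state leaks.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# First threshold crossing of a sampled signal, refined by linear interpolation
# between the two bracketing samples.  direction "up": first i with
# v[i-1] < thr <= v[i]; "down": first i with v[i-1] > thr >= v[i].
# Returns NA_real_ when the signal never crosses.
first_crossing <- function(times, values, threshold, direction = c("up", "down")) {
  direction <- match.arg(direction)
  n <- length(values)
  if (n == 0L) return(NA_real_)
  if (direction == "up") {
    if (values[1L] >= threshold) return(times[1L])
    idx <- which(values[-1L] >= threshold & values[-n] < threshold)
  } else {
    if (values[1L] <= threshold) return(times[1L])
    idx <- which(values[-1L] <= threshold & values[-n] > threshold)
  }
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1L] + 1L
  v0 <- values[i - 1L]; v1 <- values[i]
  if (v1 == v0) return(times[i])
  times[i - 1L] + (threshold - v0) / (v1 - v0) * (times[i] - times[i - 1L])
}

# Centered moving average with an odd window; ends use shrunken windows so the
# series keeps its length and its endpoints are not biased towards the interior.
moving_average <- function(x, window) {
  if (is.null(window) || window <= 1L) return(x)
  window <- as.integer(window)
  if (window %% 2L == 0L) cm_stop("smoothing window must be odd", "clotmetrics_bad_argument")
  h <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}

# Minitab/SPSS-style quantiles (R type 6).  Chosen because the exclusive
# convention reproduces the quartile arithmetic used throughout the reporting
# (e.g. {90, 95, 100} -> Q1 = 90, Q3 = 100, IQR = 10).
cm_quantile <- function(x, probs) {
  unname(stats::quantile(x, probs = probs, type = 6, names = FALSE))
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    cm_stop(sprintf("'%s' must be a finite numeric scalar", name),
            "clotmetrics_bad_argument")
  if (positive && x <= 0)
    cm_stop(sprintf("'%s' must be > 0", name), "clotmetrics_bad_argument")
  if (nonneg && x < 0)
    cm_stop(sprintf("'%s' must be >= 0", name), "clotmetrics_bad_argument")
  invisible(x)
}
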