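#' Apply the non-clottability censoring rule to a clottability course
#'
#' During progressive fibrinogen digestion, the clotting time of withdrawn
#' samples lengthens until the sample no longer clots.  Readings strictly
#' longer than the threshold (120 s by convention), and instrument "no clot
#' detected" readings, are censored as non-clottable and displayed as
#' `threshold + 1` seconds (121 s); a reading of exactly 120 s is *not*
#' censored.
#'
#' @param digestion_min digestion times (min), strictly increasing.
#' @param clotting_s raw clotting times (s), positive; `NA` allowed only where
#'   `no_clot` is `TRUE`.
#' @param no_clot optional logical vector flagging instrument no-clot readings.
#' @param threshold censoring threshold (s); default 120.
#' @return A list of class `clottability_course`: `digestion_min`,
#'   `clotting_s` (raw), `censored` (logical), `display_s` (censored values
#'   replaced by `threshold + 1`), `threshold`.
#' @examples
#' censor_course(c(0, 5, 10, 20), c(10, 14, 35, 130))
#' @export
censor_course <- function(digestion_min, clotting_s, no_clot = NULL,
                          threshold = 120) {
  digestion_min <- as.numeric(digestion_min)
  clotting_s <- as.numeric(clotting_s)
  if (length(digestion_min) != length(clotting_s))
    cm_stop("digestion and clotting time vectors must have equal length",
            "clotmetrics_bad_course")
  if (length(digestion_min) == 0L)
    cm_stop("empty clottability course", "clotmetrics_bad_course")
  if (any(diff(digestion_min) <= 0))
    cm_stop("digestion times must be strictly increasing",
            "clotmetrics_bad_course")
  if (is.null(no_clot)) no_clot <- rep(FALSE, length(clotting_s))
  if (any(is.na(clotting_s) & !no_clot) ||
      any(!is.na(clotting_s) & clotting_s < 0))
    cm_stop("clotting times must be positive (or flagged no-clot)",
            "clotmetrics_bad_course")
  stopifnot_scalar(threshold, "threshold", positive = TRUE)
  censored <- no_clot | (!is.na(clotting_s) & clotting_s > threshold)
  display <- ifelse(censored, threshold + 1, clotting_s)
  structure(list(digestion_min = digestion_min, clotting_s = clotting_s,
                 censored = censored, display_s = display,
                 threshold = threshold),
            class = "clottability_course")
}

#' Time to loss of clottability
#'
#' The earliest digestion time at which a reading is censored (non-clottable).
#' No interpolation between sampling times is attempted: the discrete
#' withdrawal grid is authoritative.
#'
#' @param course a [censor_course()] result with at least 2 points.
#' @return Digestion time (min), or `NA_real_` with attribute
#'   `flag = "clottable_throughout"` when no reading is censored.
#' @export
time_to_nonclottability <- function(course) {
  stopifnot(inherits(course, "clottability_course"))
  if (length(course$digestion_min) < 2L)
    cm_stop("at least 2 course points are required", "clotmetrics_bad_course")
  i <- which(course$censored)
  if (length(i) == 0L)
    return(structure(NA_real_, flag = "clottable_throughout"))
  course$digestion_min[min(i)]
}

#' @export
print.clottability_course <- function(x, ...) {
  cat(sprintf("<clottability_course> %d samplings, threshold %g s, %d censored\n",
              length(x$digestion_min), x$threshold, sum(x$censored)))
  invisible(x)
}
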