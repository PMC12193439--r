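#' Configuration of a grouped assay analysis
#'
#' Binds the per-series data of one assay to a condition grouping and a
#' reference condition, plus the analysis options the relevant module needs.
#'
#' @param assay `"turbidity"` or `"clottability"`.
#' @param data named list of per-series objects: [kinetic_trace()]s for a
#'   turbidity assay, `clottability_course`s for a clottability assay.
#' @param grouping named list mapping condition labels to character vectors of
#'   series ids (names of `data`); every id must exist, groups must be
#'   non-empty.
#' @param reference label of the reference condition (e.g. pure fibrin); must
#'   be one of the grouping labels.
#' @param options list of analysis options: `smooth_window`, `min_amplitude`
#'   (turbidity), `alpha` (significance level for the KS marks, default 0.05).
#' @return A list of class `study_config`.
#' @export
study_config <- function(assay = c("turbidity", "clottability"), data,
                         grouping, reference, options = list()) {
  assay <- match.arg(assay)
  if (is.null(names(data)) || any(names(data) == ""))
    cm_stop("data must be a fully named list of series", "clotmetrics_bad_config")
  if (is.null(names(grouping)) || any(names(grouping) == ""))
    cm_stop("grouping must be a named list of condition -> series ids",
            "clotmetrics_bad_config")
  if (!reference %in% names(grouping))
    cm_stop("the reference condition is missing from the grouping",
            "clotmetrics_bad_config")
  ids <- unlist(grouping)
  if (any(lengths(grouping) == 0L))
    cm_stop("grouping contains an empty group", "clotmetrics_bad_config")
  if (!all(ids %in% names(data)))
    cm_stop("grouping refers to series ids absent from the data",
            "clotmetrics_bad_config")
  defaults <- list(smooth_window = NULL, min_amplitude = 0.05, alpha = 0.05)
  options <- utils::modifyList(defaults, options)
  structure(list(assay = assay, data = data, grouping = grouping,
                 reference = reference, options = options),
            class = "study_config")
}

#' Run a grouped assay analysis
#'
#' Computes per-series metrics with the relevant module, expresses each metric
#' in relative units (RU) against the mean of the reference condition, and
#' summarizes each group as mean (SD) in RU with a two-sample
#' Kolmogorov-Smirnov comparison against the reference.  Per-series failures
#' (e.g. a well that never clotted) are flagged in the detail table, not
#' fatal.  The whole analysis is deterministic: identical config yields
#' byte-identical output tables.
#'
#' @param config a [study_config()].
#' @return A list of class `assay_report`: `detail` (per-series data frame),
#'   `summary` (per-group, per-metric mean/SD in RU with KS p-values),
#'   `reference` and `config_echo`.
#' @export
run_assay <- function(config) {
  stopifnot(inherits(config, "study_config"))
  metrics <- switch(config$assay,
    turbidity = c("a_max", "ct50", "ct90", "lt50"),
    clottability = "nonclottability_min")
  rows <- lapply(names(config$grouping), function(cond) {
    ids <- config$grouping[[cond]]
    do.call(rbind, lapply(ids, function(id) {
      out <- data.frame(series_id = id, condition = cond,
                        stringsAsFactors = FALSE)
      vals <- rep(NA_real_, length(metrics)); names(vals) <- metrics
      flag <- ""
      res <- tryCatch({
        if (config$assay == "turbidity") {
          m <- clot_lysis_metrics(config$data[[id]],
                                  smooth_window = config$options$smooth_window,
                                  min_amplitude = config$options$min_amplitude)
          vals[] <- c(m$a_max, m$ct50, m$ct90, m$lt50)
          flag <- paste(m$flags, collapse = ";")
        } else {
          v <- time_to_nonclottability(config$data[[id]])
          vals[] <- as.numeric(v)
          if (is.na(v)) flag <- attr(v, "flag")
        }
        NULL
      }, clotmetrics_error = function(e) conditionMessage(e))
      if (!is.null(res)) flag <- res
      cbind(out, as.data.frame(as.list(vals)), flags = flag)
    }))
  })
  detail <- do.call(rbind, rows)
  ref_rows <- detail$condition == config$reference
  ref_means <- vapply(metrics, function(m)
    mean(detail[[m]][ref_rows], na.rm = TRUE), numeric(1))
  for (m in metrics) {
    ru_col <- paste0(m, "_ru")
    detail[[ru_col]] <- if (is.finite(ref_means[[m]]) && ref_means[[m]] > 0)
      relative_units(detail[[m]], ref_means[[m]]) else NA_real_
  }
  summary <- do.call(rbind, lapply(names(config$grouping), function(cond) {
    do.call(rbind, lapply(metrics, function(m) {
      v <- detail[[paste0(m, "_ru")]][detail$condition == cond]
      v <- v[!is.na(v)]
      ref <- detail[[paste0(m, "_ru")]][ref_rows]
      ref <- ref[!is.na(ref)]
      p <- if (cond != config$reference && length(v) > 0 && length(ref) > 0)
        ks_two_sample(v, ref)$p_value else NA_real_
      data.frame(condition = cond, metric = m, n = length(v),
                 mean_ru = if (length(v)) mean(v) else NA_real_,
                 sd_ru = if (length(v) > 1L) stats::sd(v) else
                   if (length(v) == 1L) 0 else NA_real_,
                 median_ru = if (length(v)) cm_quantile(v, 0.5) else NA_real_,
                 iqr_ru = if (length(v))
                   cm_quantile(v, 0.75) - cm_quantile(v, 0.25) else NA_real_,
                 ks_p = p, stringsAsFactors = FALSE)
    }))
  }))
  rownames(detail) <- rownames(summary) <- NULL
  structure(list(detail = detail, summary = summary,
                 reference = config$reference,
                 alpha = config$options$alpha,
                 assay = config$assay),
            class = "assay_report")
}

#' Format a grouped summary as a publication-style table
#'
#' Cells are `"mean (SD)"` in relative units (2 decimals) or
#' `"median [IQR]"` (1 decimal); empty groups render as `"n.a."`.
#' Significant Kolmogorov-Smirnov differences from the reference condition
#' (p below the report's alpha) are marked with `mark` after the mean.
#'
#' @param report an [run_assay()] result (or its `summary` data frame plus
#'   `alpha`).
#' @param style `"mean_sd_ru"` (default) or `"median_iqr"`.
#' @param mark significance symbol; default `"*"`.
#' @return A data frame with conditions as rows and metrics as columns, all
#'   cells formatted text.
#' @export
format_table <- function(report, style = c("mean_sd_ru", "median_iqr"),
                         mark = "*") {
  style <- match.arg(style)
  if (inherits(report, "assay_report")) {
    s <- report$summary; alpha <- report$alpha
  } else { s <- report; alpha <- 0.05 }
  conds <- unique(s$condition)
  mets <- unique(s$metric)
  cells <- vapply(mets, function(m) vapply(conds, function(cond) {
    row <- s[s$condition == cond & s$metric == m, ]
    if (nrow(row) == 0L || row$n == 0L || !is.finite(row$mean_ru))
      return("n.a.")
    sig <- !is.na(row$ks_p) && row$ks_p < alpha
    if (style == "mean_sd_ru")
      sprintf("%.2f%s (%.2f)", row$mean_ru, if (sig) paste0(" ", mark) else "",
              row$sd_ru)
    else
      sprintf("%.1f%s [%.1f]", row$median_ru,
              if (sig) paste0(" ", mark) else "", row$iqr_ru)
  }, character(1)), character(length(conds)))
  out <- data.frame(condition = conds,
                    matrix(cells, nrow = length(conds),
                           dimnames = list(NULL, mets)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Write an assay report to CSV files
#'
#' Emits `detail.csv` (one row per series; every summary cell is traceable to
#' these rows) and `summary.csv` into `dir`.  Output is deterministic:
#' identical reports produce byte-identical files.
#'
#' @param report an [run_assay()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_assay_report <- function(report, dir) {
  stopifnot(inherits(report, "assay_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("detail.csv", "summary.csv"))
  utils::write.csv(report$detail, paths[1L], row.names = FALSE)
  utils::write.csv(report$summary, paths[2L], row.names = FALSE)
  invisible(paths)
}
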