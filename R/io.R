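# Readers and writers for the plain-text interchange formats of each module.

#' Read kinetic traces from a plate-reader CSV export
#'
#' Long format: columns `series_id`, `time` (s), `value` (AU).  Wide format:
#' a `time` column plus one column per well.
#'
#' @param path CSV file.
#' @param format `"long"` or `"wide"`.
#' @param assay_mode,t_addition passed to [kinetic_trace()] for every series.
#' @return Named list of [kinetic_trace()] objects.
#' @export
read_traces_csv <- function(path, format = c("long", "wide"),
                            assay_mode = "intrinsic", t_addition = NULL) {
  format <- match.arg(format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (format == "long") {
    need <- c("series_id", "time", "value")
    if (!all(need %in% names(df)))
      cm_stop("long traces need columns series_id, time, value",
              "clotmetrics_bad_file")
    split_df <- split(df, df$series_id)
    lapply(split_df, function(d)
      kinetic_trace(d$time[order(d$time)], d$value[order(d$time)],
                    assay_mode = assay_mode, t_addition = t_addition))
  } else {
    if (!"time" %in% names(df))
      cm_stop("wide traces need a time column", "clotmetrics_bad_file")
    wells <- setdiff(names(df), "time")
    out <- lapply(wells, function(w)
      kinetic_trace(df$time, df[[w]], assay_mode = assay_mode,
                    t_addition = t_addition))
    names(out) <- wells
    out
  }
}

#' Write kinetic traces (or any per-series values) as a long CSV
#'
#' Columns `series_id`, `time`, `value`, `flag`, the package's common
#' long-format interchange layout.
#'
#' @param traces named list of [kinetic_trace()] objects.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(length(traces) > 0L, !is.null(names(traces)))
  df <- do.call(rbind, lapply(names(traces), function(id) {
    tr <- traces[[id]]
    data.frame(series_id = id, time = tr$times, value = tr$absorbance,
               flag = "", stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read permeation readings (time_min, length_mm) from CSV
#'
#' @param path CSV with columns `time_min` and `length_mm`.
#' @param geometry a [permeation_geometry()].
#' @return A [permeation_experiment()].
#' @export
read_permeation_csv <- function(path, geometry) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_min", "length_mm") %in% names(df)))
    cm_stop("permeation CSV needs columns time_min, length_mm",
            "clotmetrics_bad_file")
  permeation_experiment(geometry, df$time_min * 60, df$length_mm)
}

#' Read a two-phase rheometer export
#'
#' @param clotting_path CSV with columns `time`, `gprime`, `gdoubleprime`.
#' @param ramp_path CSV with columns `time`, `tau`, `gamma`.
#' @return A [rheo_record()].
#' @export
read_rheo_csv <- function(clotting_path, ramp_path) {
  rheo_record(utils::read.csv(clotting_path, stringsAsFactors = FALSE),
              utils::read.csv(ramp_path, stringsAsFactors = FALSE))
}

#' Read a clottability course from CSV
#'
#' @param path CSV with columns `digestion_min`, `clotting_s` and optionally
#'   logical `no_clot`.
#' @param threshold censoring threshold (s).
#' @return A [censor_course()] result.
#' @export
read_clottability_csv <- function(path, threshold = 120) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("digestion_min", "clotting_s") %in% names(df)))
    cm_stop("clottability CSV needs columns digestion_min, clotting_s",
            "clotmetrics_bad_file")
  censor_course(df$digestion_min, df$clotting_s,
                no_clot = if ("no_clot" %in% names(df))
                  as.logical(df$no_clot) else NULL,
                threshold = threshold)
}

#' Write a grayscale image as plain-text ASCII PGM (P2)
#'
#' PGM P2 is the text-only grayscale interchange format; gray levels are
#' rounded to integers in 0-255.
#'
#' @param img numeric matrix or [fiber_image()].
#' @param path output `.pgm` path.
#' @return Invisibly, `path`.
#' @export
write_pgm <- function(img, path) {
  px <- if (inherits(img, "fiber_image")) img$pixels else img
  stopifnot(is.matrix(px))
  v <- round(pmin(pmax(px, 0), 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(v), nrow(v)), "255"), con)
  apply_rows <- apply(v, 1L, paste, collapse = " ")
  writeLines(apply_rows, con)
  invisible(path)
}

#' Read a plain-text ASCII PGM (P2) image
#'
#' @param path `.pgm` file.
#' @param nm_per_pixel optional scale; when given a [fiber_image()] is
#'   returned, otherwise a bare matrix.
#' @return Numeric matrix or [fiber_image()].
#' @export
read_pgm <- function(path, nm_per_pixel = NULL) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  if (txt[1L] != "P2") cm_stop("not an ASCII PGM (P2) file", "clotmetrics_bad_file")
  tokens <- as.numeric(unlist(strsplit(paste(txt[-1L], collapse = " "), "\\s+")))
  tokens <- tokens[!is.na(tokens)]
  nc <- tokens[1L]; nr <- tokens[2L]
  px <- matrix(tokens[-(1:3)], nrow = nr, ncol = nc, byrow = TRUE)
  if (is.null(nm_per_pixel)) px else fiber_image(px, nm_per_pixel)
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param img numeric matrix (0-255) or [fiber_image()].
#' @param path output `.png` path.
#' @return Invisibly, `path`.
#' @export
write_image_png <- function(img, path) {
  px <- if (inherits(img, "fiber_image")) img$pixels else img
  png::writePNG(pmin(pmax(px, 0), 255) / 255, path)
  invisible(path)
}

#' Read a grayscale PNG as a fiber image
#'
#' Color images are converted to luminance; gray levels are rescaled to 0-255.
#'
#' @param path `.png` file.
#' @param nm_per_pixel physical pixel size (nm); if `NULL`, looked up from a
#'   JSON sidecar `<path>.json` with field `nm_per_pixel`.
#' @return A [fiber_image()].
#' @export
read_image_png <- function(path, nm_per_pixel = NULL) {
  a <- png::readPNG(path)
  px <- if (length(dim(a)) == 3L)
    0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L] else a
  if (is.null(nm_per_pixel)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      cm_stop("nm_per_pixel not given and no JSON sidecar found",
              "clotmetrics_bad_file")
    nm_per_pixel <- jsonlite::read_json(sidecar)$nm_per_pixel
  }
  fiber_image(px * 255, nm_per_pixel)
}

#' Write a JSON sidecar with ground truth and the full parameter echo
#'
#' Synthetic-data writers pair every artifact with a sidecar carrying the
#' generator parameters and ground truth, so downstream parameter-recovery
#' checks need no out-of-band bookkeeping.
#'
#' @param x a generated object carrying a `ground_truth` attribute.
#' @param path output `.json` path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth_json <- function(x, path) {
  gt <- attr(x, "ground_truth")
  if (is.null(gt))
    cm_stop("object carries no ground_truth attribute", "clotmetrics_bad_argument")
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
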