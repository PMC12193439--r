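#' Construct a fiber image
#'
#' A grayscale electron-micrograph-like image together with its physical pixel
#' scale.
#'
#' @param pixels numeric matrix of gray levels (rows = y, cols = x), at least
#'   64 x 64.
#' @param nm_per_pixel physical size of one pixel (nm), `> 0`.
#' @return A list of class `fiber_image`.
#' @export
fiber_image <- function(pixels, nm_per_pixel) {
  stopifnot(is.matrix(pixels))
  if (nrow(pixels) < 64L || ncol(pixels) < 64L)
    cm_stop("fiber images must be at least 64 x 64 pixels",
            "clotmetrics_bad_image")
  stopifnot_scalar(nm_per_pixel, "nm_per_pixel", positive = TRUE)
  structure(list(pixels = pixels, nm_per_pixel = nm_per_pixel),
            class = "fiber_image")
}

#' Parameters for the synthetic fiber-field generator
#'
#' Describes a rendered field of straight fibers whose widths are drawn from a
#' named diameter distribution, blurred and corrupted with Gaussian noise.
#' Defaults emulate a plain fibrin network: lognormal diameters with median
#' 95 nm at 8 nm/pixel in a 256 x 256 field.
#'
#' @param image_size `c(rows, cols)` in pixels.
#' @param nm_per_pixel physical pixel size (nm).
#' @param n_fibers number of fibers rendered, `>= 1`.
#' @param diameter_law list naming the diameter distribution: either
#'   `list(family = "lognormal", meanlog, sdlog)` (nm) or
#'   `list(family = "constant", value)` (nm).
#' @param blur_sigma Gaussian blur SD (pixels).
#' @param noise_sd SD of additive Gaussian pixel noise (gray levels, 0-255
#'   scale).
#' @param fg,bg foreground (fiber) and background gray levels.
#' @param seed integer seed.
#' @return A list of class `fiber_field_params`.
#' @export
fiber_field_params <- function(image_size = c(256L, 256L), nm_per_pixel = 8,
                               n_fibers = 12L,
                               diameter_law = list(family = "lognormal",
                                                   meanlog = log(95),
                                                   sdlog = 0.35),
                               blur_sigma = 1, noise_sd = 8,
                               fg = 200, bg = 20, seed = 1L) {
  stopifnot_scalar(nm_per_pixel, "nm_per_pixel", positive = TRUE)
  if (!is.numeric(n_fibers) || n_fibers < 1L)
    cm_stop("n_fibers must be >= 1", "clotmetrics_bad_params")
  stopifnot_scalar(blur_sigma, "blur_sigma", nonneg = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (!diameter_law$family %in% c("lognormal", "constant"))
    cm_stop("diameter_law family must be 'lognormal' or 'constant'",
            "clotmetrics_bad_params")
  structure(list(image_size = as.integer(image_size),
                 nm_per_pixel = nm_per_pixel, n_fibers = as.integer(n_fibers),
                 diameter_law = diameter_law, blur_sigma = blur_sigma,
                 noise_sd = noise_sd, fg = fg, bg = bg, seed = seed),
            class = "fiber_field_params")
}

# anti-aliased rendering: pixel coverage from the distance to the fiber axis
render_fibers <- function(image_size, centers, angles, widths_px, fg, bg) {
  nr <- image_size[1L]; nc <- image_size[2L]
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), nc), nr, nc)
  cov <- matrix(0, nr, nc)
  half_len <- sqrt(nr^2 + nc^2)   # long enough to span the frame
  for (i in seq_along(angles)) {
    dx <- cos(angles[i]); dy <- sin(angles[i])
    rx <- xs - centers[i, 1L]; ry <- ys - centers[i, 2L]
    tproj <- rx * dx + ry * dy                       # along the axis
    dist <- abs(-rx * dy + ry * dx)                  # perpendicular distance
    dist[abs(tproj) > half_len] <- Inf
    cov_i <- pmin(pmax(widths_px[i] / 2 + 0.5 - dist, 0), 1)
    cov <- pmax(cov, cov_i)                          # opaque overlap
  }
  list(image = bg + (fg - bg) * cov, mask = cov >= 0.5)
}

#' Simulate a fiber-field image with known diameter ground truth
#'
#' Renders `n_fibers` anti-aliased straight fibers with uniformly random
#' centers and orientations and widths drawn from `diameter_law`, applies
#' Gaussian blur and additive pixel noise.  Straightness keeps the ground
#' truth exact: every rendered width is returned in nm.
#'
#' @param params a [fiber_field_params()].
#' @param seed optional override of `params$seed`.
#' @return A [fiber_image()] with attributes `ground_truth` (list with
#'   `widths_nm` and the parameter echo) and `true_mask` (logical matrix, the
#'   noiseless half-coverage mask).
#' @export
sim_fiber_image <- function(params, seed = NULL) {
  stopifnot(inherits(params, "fiber_field_params"))
  if (is.null(seed)) seed <- params$seed
  with_seed(seed, {
    n <- params$n_fibers
    law <- params$diameter_law
    widths_nm <- switch(law$family,
      lognormal = stats::rlnorm(n, law$meanlog, law$sdlog),
      constant  = rep(law$value, n))
    widths_px <- widths_nm / params$nm_per_pixel
    if (any(widths_px < 2))
      cm_warn("some fibers are narrower than 2 pixels (sub-resolution)",
              "clotmetrics_subresolution")
    centers <- cbind(stats::runif(n, 1, params$image_size[2L]),
                     stats::runif(n, 1, params$image_size[1L]))
    angles <- stats::runif(n, 0, pi)
    r <- render_fibers(params$image_size, centers, angles, widths_px,
                       params$fg, params$bg)
    img <- gaussian_blur(r$image, params$blur_sigma)
    if (params$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, params$noise_sd)
    img <- matrix(pmin(pmax(img, 0), 255), nrow(img), ncol(img))
    out <- fiber_image(img, params$nm_per_pixel)
    attr(out, "ground_truth") <- list(widths_nm = widths_nm,
                                      params = unclass(params), seed = seed)
    attr(out, "true_mask") <- r$mask
    out
  })
}

#' Segment fibers from a grayscale image
#'
#' Optional Gaussian denoising, Otsu global threshold, removal of small
#' objects.  Fibers are assumed brighter than background; set
#' `invert = TRUE` for inverted-contrast micrographs.
#'
#' @param image a [fiber_image()] or numeric matrix.
#' @param denoise_sigma Gaussian denoise SD (pixels) before thresholding;
#'   default 0 (none).
#' @param min_area smallest object (pixels) retained; default 20.
#' @param invert set `TRUE` when fibers are darker than background.
#' @return Logical matrix (fiber mask).
#' @export
segment_fibers <- function(image, denoise_sigma = 0, min_area = 20L,
                           invert = FALSE) {
  px <- if (inherits(image, "fiber_image")) image$pixels else image
  stopifnot(is.matrix(px))
  if (invert) px <- max(px) + min(px) - px
  if (denoise_sigma > 0) px <- gaussian_blur(px, denoise_sigma)
  thr <- otsu_threshold(px)
  mask <- px > thr
  mask <- remove_small_objects(mask, min_area)
  if (!any(mask))
    cm_stop("no fiber pixels found after segmentation", "clotmetrics_no_fibers")
  mask
}

#' Measure fiber diameters on a segmented mask
#'
#' The mask is skeletonized; the local fiber diameter at a skeleton point is
#' twice the Euclidean distance-transform value there, converted to nm.
#' `n_target` skeleton points are sampled uniformly at random (seeded),
#' excluding points within one local radius of skeleton branch points (fiber
#' crossings are not fibers) and points hugging the image border.
#'
#' @param mask logical matrix from [segment_fibers()].
#' @param nm_per_pixel physical pixel size (nm).
#' @param n_target number of diameter measurements; default 300, the
#'   conventional per-clot sample size.
#' @param seed integer seed for the point sampling.
#' @return A list of class `diameter_sample`: `diameters` (nm), `n`, `median`,
#'   `q1`, `q3`, `iqr` (nm, type-6 quantiles), `source_images = 1L`, and
#'   `shortfall` (`TRUE` when fewer than `n_target` valid skeleton points
#'   existed).
#' @export
measure_diameters <- function(mask, nm_per_pixel, n_target = 300L, seed = 1L) {
  stopifnot(is.matrix(mask))
  stopifnot_scalar(nm_per_pixel, "nm_per_pixel", positive = TRUE)
  if (!any(mask))
    cm_stop("empty mask: nothing to measure", "clotmetrics_no_fibers")
  skel <- thin_mask(mask)
  edt <- distance_transform(mask)
  pts <- which(skel, arr.ind = TRUE)
  radii <- edt[skel]
  # junction exclusion: drop skeleton points within one local radius of a branch
  bp <- which(branch_points(skel), arr.ind = TRUE)
  keep <- rep(TRUE, nrow(pts))
  if (nrow(bp) > 0L) {
    for (b in seq_len(nrow(bp))) {
      d2 <- (pts[, 1L] - bp[b, 1L])^2 + (pts[, 2L] - bp[b, 2L])^2
      keep <- keep & d2 > radii^2
    }
  }
  # border exclusion: the frame clips fibers, shrinking the distance transform
  margin <- pmax(radii, 2)
  keep <- keep & pts[, 1L] > margin & pts[, 1L] <= nrow(mask) - margin &
    pts[, 2L] > margin & pts[, 2L] <= ncol(mask) - margin
  pts <- pts[keep, , drop = FALSE]
  radii <- radii[keep]
  if (nrow(pts) == 0L)
    cm_stop("no valid skeleton points after junction/border exclusion",
            "clotmetrics_no_fibers")
  shortfall <- nrow(pts) < n_target
  idx <- if (shortfall) seq_len(nrow(pts)) else
    with_seed(seed, sample.int(nrow(pts), n_target))
  d <- 2 * radii[idx] * nm_per_pixel
  structure(list(diameters = d, n = length(d),
                 median = cm_quantile(d, 0.5), q1 = cm_quantile(d, 0.25),
                 q3 = cm_quantile(d, 0.75),
                 iqr = cm_quantile(d, 0.75) - cm_quantile(d, 0.25),
                 source_images = 1L, shortfall = shortfall,
                 points = pts[idx, , drop = FALSE]),
            class = "diameter_sample")
}

#' Pool diameter samples across images and summarize
#'
#' Diameters from several micrographs of the same clot are pooled and
#' summarized by the median and quartiles (type-6 convention), formatted as
#' `"median [IQR]"` with one decimal.  The lower quartile is reported
#' alongside the IQR because both readings of a "low-bottom quartile" are in
#' use.
#'
#' @param samples a `diameter_sample` or a list of them.
#' @return A list of class `diameter_summary`: pooled `diameters`, `n`,
#'   `median`, `q1`, `iqr`, `source_images`, `per_image` (data frame of
#'   per-image medians/IQRs) and `label` (the formatted string).
#' @examples
#' s <- structure(list(diameters = c(90, 95, 100)), class = "diameter_sample")
#' summarize_diameters(s)$label   # "95.0 [10.0]"
#' @export
summarize_diameters <- function(samples) {
  if (inherits(samples, "diameter_sample")) samples <- list(samples)
  if (length(samples) < 1L)
    cm_stop("at least one diameter sample is required", "clotmetrics_bad_argument")
  stopifnot(all(vapply(samples, inherits, logical(1), "diameter_sample")))
  pooled <- unlist(lapply(samples, `[[`, "diameters"))
  per_image <- data.frame(
    image = seq_along(samples),
    n = vapply(samples, function(s) length(s$diameters), numeric(1)),
    median = vapply(samples, function(s) cm_quantile(s$diameters, 0.5), numeric(1)),
    iqr = vapply(samples, function(s)
      cm_quantile(s$diameters, 0.75) - cm_quantile(s$diameters, 0.25), numeric(1)))
  med <- cm_quantile(pooled, 0.5)
  q1 <- cm_quantile(pooled, 0.25)
  iqr <- cm_quantile(pooled, 0.75) - q1
  structure(list(diameters = pooled, n = length(pooled), median = med,
                 q1 = q1, iqr = iqr, source_images = length(samples),
                 per_image = per_image,
                 label = sprintf("%.1f [%.1f]", med, iqr)),
            class = "diameter_summary")
}

#' @export
print.diameter_summary <- function(x, ...) {
  cat(sprintf("fiber diameter, nm: %s (n = %d on %d image%s)\n", x$label,
              x$n, x$source_images, if (x$source_images > 1L) "s" else ""))
  invisible(x)
}
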