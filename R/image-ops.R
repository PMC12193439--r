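# Grayscale image primitives used by the fiber morphometry module.
# Images are plain numeric matrices (rows = y, cols = x), gray levels 0-255.
# All of these are small, dependency-free reimplementations of textbook
# algorithms: separable Gaussian blur, Otsu's threshold, two-pass connected
# component labelling, the exact Euclidean distance transform of
# Felzenszwalb & Huttenlocher, and Zhang-Suen thinning.

# the 8 neighbors of every pixel, in circular order around the ring
ring_neighbors <- function(m) {
  list(p2 = shift_mat(m, 1, 0),  p3 = shift_mat(m, 1, -1),
       p4 = shift_mat(m, 0, -1), p5 = shift_mat(m, -1, -1),
       p6 = shift_mat(m, -1, 0), p7 = shift_mat(m, -1, 1),
       p8 = shift_mat(m, 0, 1),  p9 = shift_mat(m, 1, 1))
}

# shift a matrix by (dy, dx), padding with `fill`
shift_mat <- function(m, dy, dx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ys <- seq_len(nr) - dy; xs <- seq_len(nc) - dx
  ok_y <- ys >= 1L & ys <= nr; ok_x <- xs >= 1L & xs <= nc
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}

#' Separable Gaussian blur of a grayscale image
#'
#' @param img numeric matrix.
#' @param sigma Gaussian SD in pixels; `0` returns the image unchanged.
#' @return Blurred matrix of the same dimensions (replicate-edge padding).
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img))
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(m) {   # convolve rows of m with k, replicate edges
    nc <- ncol(m)
    padded <- cbind(m[, rep(1L, r), drop = FALSE], m,
                    m[, rep(nc, r), drop = FALSE])
    out <- matrix(0, nrow(m), nc)
    for (j in seq_along(k))
      out <- out + k[j] * padded[, j:(j + nc - 1L), drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

#' Otsu's automatic global threshold
#'
#' Maximizes between-class variance over a 256-bin histogram of the image's
#' intensity range.
#'
#' @param img numeric matrix with a non-degenerate intensity range.
#' @return The threshold on the image's intensity scale; pixels strictly above
#'   it are foreground.
#' @export
otsu_threshold <- function(img) {
  stopifnot(is.matrix(img))
  v <- as.numeric(img)
  lo <- min(v); hi <- max(v)
  if (hi - lo <= .Machine$double.eps)
    cm_stop("image has a degenerate intensity range", "clotmetrics_no_fibers")
  nb <- 256L
  bins <- pmin(floor((v - lo) / (hi - lo) * nb) + 1L, nb)
  h <- as.numeric(tabulate(bins, nb))
  w <- cumsum(h)
  mu <- cumsum(h * seq_len(nb))
  tot_w <- w[nb]; tot_mu <- mu[nb]
  w0 <- w[-nb]; w1 <- tot_w - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, nb - 1L)
  between[valid] <- (tot_mu * w0[valid] - tot_w * mu[-nb][valid])^2 /
    (w0[valid] * w1[valid])
  k <- which.max(between)
  lo + k / nb * (hi - lo)
}

# two-pass 8-connected component labelling; mask is logical
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (x in seq_len(nc)) for (y in seq_len(nr)) {
    if (!mask[y, x]) next
    nb <- integer(0)
    if (y > 1L && labels[y - 1L, x] > 0L) nb <- c(nb, labels[y - 1L, x])
    if (x > 1L) {
      if (labels[y, x - 1L] > 0L) nb <- c(nb, labels[y, x - 1L])
      if (labels[y - 1L, x - 1L] > 0L && y > 1L)
        nb <- c(nb, labels[y - 1L, x - 1L])
      if (y < nr && labels[y + 1L, x - 1L] > 0L)
        nb <- c(nb, labels[y + 1L, x - 1L])
    }
    if (length(nb) == 0L) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; labels[y, x] <- nxt
    } else {
      roots <- vapply(unique(nb), find, integer(1))
      r <- min(roots)
      labels[y, x] <- r
      for (o in roots) parent[o] <- r
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    relab <- match(roots, sort(unique(roots)))
    pos <- labels > 0L
    labels[pos] <- relab[labels[pos]]
  }
  labels
}

# drop connected components smaller than min_area pixels
remove_small_objects <- function(mask, min_area) {
  if (min_area <= 1L || !any(mask)) return(mask)
  labels <- label_components(mask)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= min_area)
  labels > 0L & labels %in% keep
}

# exact squared Euclidean 1-D distance transform (lower envelope of parabolas);
# infinite costs never enter the envelope
dt1d <- function(f) {
  n <- length(f)
  d <- rep(Inf, n)
  cand <- which(is.finite(f))
  if (length(cand) == 0L) return(d)
  v <- integer(length(cand)); z <- numeric(length(cand) + 1L)
  k <- 1L; v[1L] <- cand[1L]; z[1L] <- -Inf; z[2L] <- Inf
  for (q in cand[-1L]) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * (q - v[k]))
      if (s <= z[k]) k <- k - 1L   # z[1] = -Inf guarantees k >= 1
      else { k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf; break }
    }
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Exact Euclidean distance transform of a binary mask
#'
#' For each foreground pixel, the Euclidean distance (in pixels) to the nearest
#' background pixel.  The image border is treated as background, so objects
#' clipped by the frame are not credited with width beyond it.
#'
#' @param mask logical matrix (`TRUE` = foreground).
#' @return Numeric matrix of distances; 0 on background.
#' @export
distance_transform <- function(mask) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  # pad with a background ring so the frame counts as background
  f <- matrix(Inf, nr + 2L, nc + 2L)
  f[2:(nr + 1L), 2:(nc + 1L)][!mask] <- 0
  f[1L, ] <- 0; f[nr + 2L, ] <- 0; f[, 1L] <- 0; f[, nc + 2L] <- 0
  for (i in seq_len(nrow(f))) if (any(is.finite(f[i, ]))) f[i, ] <- dt1d(f[i, ])
  for (j in seq_len(ncol(f))) f[, j] <- dt1d(f[, j])
  sqrt(f[2:(nr + 1L), 2:(nc + 1L)])
}

#' Topological skeleton of a binary mask (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels until a one-pixel-wide, 8-connected
#' skeleton remains.
#'
#' @param mask logical matrix.
#' @return Logical matrix of the same size containing the skeleton.
#' @export
thin_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- mask * 1L
  neighbors <- ring_neighbors
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- neighbors(m)
      b <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      seqs <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
      a <- 0
      for (i in 1:8) a <- a + (seqs[[i]] == 0L & seqs[[i + 1L]] == 1L)
      cond <- m == 1L & b >= 2 & b <= 6 & a == 1
      if (step == 1L)
        cond <- cond & (nb$p2 * nb$p4 * nb$p6 == 0L) &
          (nb$p4 * nb$p6 * nb$p8 == 0L)
      else
        cond <- cond & (nb$p2 * nb$p4 * nb$p8 == 0L) &
          (nb$p2 * nb$p6 * nb$p8 == 0L)
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

# skeleton pixels where 3 or more skeleton arms meet (fiber crossings).
# Uses the crossing number (distinct neighbor runs around the 8-neighborhood)
# rather than the raw neighbor count, which would misflag staircase diagonals.
branch_points <- function(skel) {
  s <- skel * 1L
  nb <- ring_neighbors(s)
  runs <- 0
  for (i in 1:8)
    runs <- runs + (nb[[i]] == 0L & nb[[if (i == 8L) 1L else i + 1L]] == 1L)
  skel & runs >= 3L
}
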