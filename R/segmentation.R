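# From feature image to region of interest: adaptive binarization, the
# two-scale block morphology, largest 8-connected component, convex hull.

#' Binarize a feature image at an adaptive threshold
#'
#' Thresholds the feature image at \eqn{C \cdot \max_k \tilde f[k]}: a pixel
#' is foreground when \eqn{\tilde f[k] \ge C \max \tilde f}. When the feature
#' image carries no positive response (\eqn{\max \tilde f \le 0}, e.g. a
#' blank input) the rule would mark every pixel; that degenerate case returns
#' an empty mask instead.
#'
#' @param feature numeric matrix (the feature image).
#' @param C constant in (0,1).
#' @return logical matrix, \code{TRUE} = foreground.
#' @export
binarizeFeature <- function(feature, C) {
  stopifnot(is.matrix(feature))
  if (!all(is.finite(feature))) stop("feature image has non-finite values")
  if (length(C) != 1L || !is.finite(C) || C <= 0 || C >= 1)
    stop("'C' must lie strictly between 0 and 1")
  mx <- max(feature)
  if (mx <= 0)
    return(matrix(FALSE, nrow(feature), ncol(feature)))
  feature >= C * mx
}

# box sum of an s x s window centered at each pixel, zero-padded borders
# (equivalently: windows clipped at the image edge), via an integral image
.boxSum <- function(mask, s) {
  h <- (s - 1L) %/% 2L
  nr <- nrow(mask); nc <- ncol(mask)
  ii <- matrix(0, nr + 1L, nc + 1L)
  ii[-1L, -1L] <- t(apply(apply(mask, 2L, cumsum), 1L, cumsum))
  r <- seq_len(nr); cl <- seq_len(nc)
  r2 <- pmin(r + h, nr) + 1L; r1 <- pmax(r - h - 1L, 0L) + 1L
  c2 <- pmin(cl + h, nc) + 1L; c1 <- pmax(cl - h - 1L, 0L) + 1L
  ii[r2, c2] - ii[r1, c2] - ii[r2, c1] + ii[r1, c1]
}

#' Two-scale block morphology
#'
#' The voting operator that turns the striped binarized texture into a solid
#' foreground: around each pixel, consider the \eqn{s \times s} cell centered
#' on it and its 8 neighboring cells at offsets \eqn{(m_1, m_2) \in
#' \{-s, 0, s\}^2}. A cell votes when its white-pixel count is at least
#' \eqn{s^2/t}; the pixel becomes foreground when at least \code{b} of the 9
#' cells vote. Pixels outside the image count as black (zero padding).
#' Operating on two scales (cells, then a 3x3 block of cells) fills the gaps
#' between binarized ridge crests without bridging to detached noise blobs
#' the way plain closing does.
#'
#' @param mask logical matrix.
#' @param s odd cell size >= 3, smaller than both image dimensions.
#' @param t threshold divisor > 1 (a cell needs \eqn{\ge s^2/t} white
#'   pixels).
#' @param b required number of voting cells, 1..9.
#' @return logical matrix.
#' @export
twoScaleMorphology <- function(mask, s, t, b) {
  stopifnot(is.matrix(mask))
  s <- as.integer(s)
  if (s < 3L || s %% 2L == 0L) stop("'s' must be odd and >= 3")
  if (s >= min(dim(mask))) stop("'s' must be smaller than the image")
  if (!(t > 1)) stop("'t' must be > 1")
  b <- as.integer(b)
  if (b < 1L || b > 9L) stop("'b' must be in 1..9")
  # cells centered up to s px outside the image still count their in-image
  # pixels, so compute occupancies on a zero-extended domain
  nr <- nrow(mask); nc <- ncol(mask)
  ext <- matrix(0, nr + 2L * s, nc + 2L * s)
  ext[s + seq_len(nr), s + seq_len(nc)] <- mask
  votes <- .boxSum(ext, s) >= s^2 / t
  acc <- matrix(0L, nr, nc)
  for (dr in c(-s, 0L, s))
    for (dc in c(-s, 0L, s))
      acc <- acc + votes[s + dr + seq_len(nr), s + dc + seq_len(nc)]
  acc >= b
}

# 8-connected component labels of a logical mask via an explicit pixel graph
.labelComponents <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (!length(fg)) return(list(labels = idx, sizes = integer()))
  idx[fg] <- seq_along(fg)
  edges <- integer()
  for (off in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    dr <- off[1L]; dc <- off[2L]
    r1 <- seq_len(nr - abs(dr)); c1 <- seq_len(nc - abs(dc))
    r2 <- r1 + abs(dr)
    if (dc >= 0L) { ca <- c1; cb <- c1 + dc } else { ca <- c1 - dc; cb <- c1 }
    a <- idx[r1, ca, drop = FALSE]; bb <- idx[r2, cb, drop = FALSE]
    both <- a > 0L & bb > 0L
    edges <- c(edges, rbind(a[both], bb[both]))
  }
  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  memb <- igraph::components(g)$membership
  idx[fg] <- memb
  list(labels = idx, sizes = tabulate(memb))
}

# rasterize the convex hull of integer pixel coordinates (row, col) pairs;
# returns a logical matrix of dimension dm
.rasterizeHull <- function(rows, cols, dm) {
  out <- matrix(FALSE, dm[1L], dm[2L])
  pts <- unique(cbind(cols, rows))          # (x, y)
  if (nrow(pts) <= 2L) { out[cbind(rows, cols)] <- TRUE; return(out) }
  hull <- grDevices::chull(pts[, 1L], pts[, 2L])
  hx <- pts[hull, 1L]; hy <- pts[hull, 2L]
  nh <- length(hull)
  if (nh <= 2L) { out[cbind(rows, cols)] <- TRUE; return(out) }
  rr <- max(1L, min(rows)):min(dm[1L], max(rows))
  cc <- max(1L, min(cols)):min(dm[2L], max(cols))
  px <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  py <- matrix(rr, length(rr), length(cc))
  inside <- matrix(TRUE, length(rr), length(cc))
  # chull vertices are listed clockwise in (x, y); a point is inside the
  # convex polygon iff it is on the non-positive side of every directed edge
  area2 <- sum(hx * hy[c(2:nh, 1L)] - hx[c(2:nh, 1L)] * hy)
  orient <- if (area2 >= 0) 1 else -1
  eps <- 1e-9
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    inside <- inside & (orient * cross >= -eps)
  }
  out[rr, cc] <- inside
  out
}

#' Largest component and its convex hull
#'
#' Selects the largest 8-connected foreground component of a mask and returns
#' the filled convex hull of its pixel set: the region of interest. Interior
#' holes are inside the hull by convexity, so no separate region filling is
#' needed. An empty mask yields an empty ROI.
#'
#' @param mask logical matrix.
#' @return logical matrix, a convex pixel set.
#' @export
largestComponentHull <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask & !is.na(mask)
  lab <- .labelComponents(mask)
  if (!length(lab$sizes))
    return(matrix(FALSE, nrow(mask), ncol(mask)))
  keep <- which.max(lab$sizes)
  px <- which(lab$labels == keep, arr.ind = TRUE)
  .rasterizeHull(px[, 1L], px[, 2L], dim(mask))
}

#' Segment a fingerprint image
#'
#' The full FDB segmentation chain: feature image by the factorized
#' directional bandpass transform, adaptive binarization, two-scale
#' morphology, largest 8-connected component, convex hull. The result is the
#' convex region of interest containing the ridge pattern. The chain is
#' deterministic, and invariant to positive rescaling of the input
#' intensities (all thresholds are relative).
#'
#' @param image numeric matrix, intensities in [0,1] (use [readGrayImage()]
#'   for files).
#' @param params a [FDBParams-class] object.
#' @param bank optional pre-built [FilterBank-class] for the padded shape.
#' @return logical matrix, \code{TRUE} = region of interest.
#' @examples
#' fp <- makeFingerprint(synthSpec(shape = c(96, 96), wavelength = 8,
#'                                 seed = 7))
#' roi <- segmentFingerprint(fp$image, fdbParams(L = 8))
#' errorRate(roi, fp$truth)$err
#' @export
segmentFingerprint <- function(image, params, bank = NULL) {
  stopifnot(is(params, "FDBParams"))
  feature <- fdbFeatureImage(image, params, bank = bank)
  # a featureless (blank) image leaves only rounding noise in the feature
  # image; treat it as background rather than thresholding noise. The floor
  # is relative to the input scale so segmentation stays scale-invariant.
  if (max(feature) <= 1e-10 * max(abs(image)))
    return(matrix(FALSE, nrow(image), ncol(image)))
  segmentFromFeature(feature, params)
}

#' Segment from a precomputed feature image
#'
#' The post-transform half of the pipeline (binarization, morphology, largest
#' component, hull). Exposed separately so alternative reconstructions (see
#' [synthesizeMax()], [synthesizeSum()]) can be compared downstream.
#'
#' @param feature numeric matrix.
#' @param params a [FDBParams-class] object.
#' @return logical matrix.
#' @export
segmentFromFeature <- function(feature, params) {
  stopifnot(is(params, "FDBParams"))
  bin <- binarizeFeature(feature, params@C)
  if (!any(bin)) return(bin)
  morph <- twoScaleMorphology(bin, params@s, params@t, params@b)
  if (!any(morph)) return(morph)
  largestComponentHull(morph)
}
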