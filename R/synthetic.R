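# Synthetic fingerprint-like fixtures with exact ground truth: oscillatory
# ridge patterns inside a known elliptical ROI, optional noise and artifact
# models (ghost print, dry breaks, large-scale structure noise), so the whole
# pipeline is testable without external databases.

#' Specification of a synthetic fingerprint image
#'
#' @param shape integer(2), image size (rows, cols); default 256 x 256.
#' @param wavelength interridge distance in pixels, in [3, 25]; the pattern's
#'   spectral peak sits at \eqn{2\pi/\lambda} radians/sample, inside the
#'   default passband [0.3, 1] for roughly \eqn{\lambda} in 6--21 px.
#' @param orientation ridge geometry: \code{"constant"} (parallel ridges at
#'   angle \code{theta}), \code{"arcs"} (concentric arcs around a point below
#'   the ROI, loop-like), or \code{"varying"} (smoothly bending ridges).
#' @param theta ridge normal direction for \code{"constant"} (radians).
#' @param roi list with \code{center} (row, col; defaults to the image
#'   center), \code{axes} (semi-axes in px; default 0.33/0.40 of the image),
#'   \code{rotation} (radians, default 0) describing the ground-truth
#'   ellipse.
#' @param amplitude peak-to-trough ridge contrast in [0,1] intensity units
#'   (default 0.7).
#' @param noiseSigma standard deviation of additive white Gaussian noise
#'   (default 0).
#' @param artifacts list of optional artifact switches:
#'   \code{ghost = list(offset, theta, attenuation)} adds an attenuated
#'   second print outside the ROI; \code{dryBreaks = k} punches \code{k}
#'   random blank discs into the pattern (dry-finger contact failures);
#'   \code{structureNoise = k} adds \code{k} smooth large-scale intensity
#'   blobs.
#' @param seed integer RNG seed; a fixed seed makes the image bit-identical
#'   across calls.
#' @return a validated list of class \code{"synthSpec"}.
#' @export
synthSpec <- function(shape = c(256, 256), wavelength = 8,
                      orientation = c("constant", "arcs", "varying"),
                      theta = pi / 4, roi = list(),
                      amplitude = 0.7, noiseSigma = 0,
                      artifacts = list(), seed = 1) {
  orientation <- match.arg(orientation)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 32L))
    stop("'shape' must be two integers >= 32")
  if (wavelength < 3 || wavelength > 25)
    stop("'wavelength' must lie in [3, 25] pixels")
  if (amplitude <= 0 || amplitude > 1) stop("'amplitude' must be in (0, 1]")
  if (noiseSigma < 0) stop("'noiseSigma' must be >= 0")
  known <- c("ghost", "dryBreaks", "structureNoise")
  if (length(artifacts) && !all(names(artifacts) %in% known))
    stop("unknown artifact: ",
         paste(setdiff(names(artifacts), known), collapse = ", "))
  roiDef <- list(center = (shape + 1) / 2,
                 axes = c(0.33, 0.40) * min(shape), rotation = 0)
  roiDef[names(roi)] <- roi
  structure(list(shape = shape, wavelength = wavelength,
                 orientation = orientation, theta = theta, roi = roiDef,
                 amplitude = amplitude, noiseSigma = noiseSigma,
                 artifacts = artifacts, seed = as.integer(seed)),
            class = "synthSpec")
}

# raster of an ellipse (center/axes/rotation in pixel units)
.ellipseMask <- function(shape, roi) {
  r <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  cl <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  dy <- r - roi$center[1L]; dx <- cl - roi$center[2L]
  co <- cos(roi$rotation); si <- sin(roi$rotation)
  u <- dx * co + dy * si
  v <- -dx * si + dy * co
  (u / roi$axes[2L])^2 + (v / roi$axes[1L])^2 <= 1
}

# scalar phase field whose gradient magnitude is ~1, so cos(2*pi*phase/lambda)
# oscillates with wavelength ~lambda everywhere
.phaseField <- function(spec) {
  shape <- spec$shape
  r <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  cl <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  switch(spec$orientation,
    constant = cl * cos(spec$theta) + r * sin(spec$theta),
    arcs = {
      ctr <- c(spec$roi$center[1L] + 1.3 * spec$roi$axes[1L],
               spec$roi$center[2L])
      sqrt((r - ctr[1L])^2 + (cl - ctr[2L])^2)
    },
    varying = {
      # ridges bend parabolically; curvature kept small enough that the
      # local wavelength stays within ~15% of nominal
      y <- r - spec$roi$center[1L]
      kappa <- 0.55 / shape[1L]
      cl + kappa * y^2
    })
}

#' Generate a synthetic fingerprint image with ground truth
#'
#' Renders \code{0.5 + (amplitude/2) cos(2\pi \cdot \mathrm{phase}/\lambda)}
#' inside the ROI ellipse over a flat 0.5 background, applies the requested
#' artifacts and additive noise, and clips to [0,1]. The ground-truth mask is
#' the ellipse raster, exact by construction. All randomness flows from the
#' spec's single seed, so output is deterministic.
#'
#' @param spec a [synthSpec()] object.
#' @return list with \code{image} (numeric matrix in [0,1]) and \code{truth}
#'   (logical matrix).
#' @examples
#' fp <- makeFingerprint(synthSpec(shape = c(64, 64), wavelength = 8))
#' range(fp$image)
#' @export
makeFingerprint <- function(spec) {
  if (!inherits(spec, "synthSpec")) stop("'spec' must come from synthSpec()")
  set.seed(spec$seed)
  shape <- spec$shape
  truth <- .ellipseMask(shape, spec$roi)
  phase <- .phaseField(spec)
  ridge <- (spec$amplitude / 2) * cos(2 * pi * phase / spec$wavelength)
  amp <- truth * 1
  art <- spec$artifacts
  if (!is.null(art$dryBreaks)) {
    r <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
    cl <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
    for (i in seq_len(art$dryBreaks)) {
      ctr <- spec$roi$center + stats::runif(2, -0.6, 0.6) * spec$roi$axes
      rad <- stats::runif(1, 5, 12)
      amp[(r - ctr[1L])^2 + (cl - ctr[2L])^2 <= rad^2] <- 0
    }
  }
  img <- 0.5 + ridge * amp
  if (!is.null(art$ghost)) {
    g <- art$ghost
    off <- if (!is.null(g$offset)) g$offset else c(0.42, 0.42) * shape
    gtheta <- if (!is.null(g$theta)) g$theta else spec$theta + pi / 3
    att <- if (!is.null(g$attenuation)) g$attenuation else 0.6
    groi <- list(center = spec$roi$center + off,
                 axes = 0.45 * spec$roi$axes, rotation = 0)
    gmask <- .ellipseMask(shape, groi) & !truth
    r <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
    cl <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
    gphase <- cl * cos(gtheta) + r * sin(gtheta)
    img <- img + gmask * att * (spec$amplitude / 2) *
      cos(2 * pi * gphase / spec$wavelength)
  }
  if (!is.null(art$structureNoise)) {
    r <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
    cl <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
    for (i in seq_len(art$structureNoise)) {
      ctr <- c(stats::runif(1, 1, shape[1L]), stats::runif(1, 1, shape[2L]))
      sg <- stats::runif(1, 20, 40)
      a <- stats::runif(1, -0.25, 0.25)
      img <- img + a * exp(-((r - ctr[1L])^2 + (cl - ctr[2L])^2) / (2 * sg^2))
    }
  }
  if (spec$noiseSigma > 0)
    img <- img + matrix(stats::rnorm(prod(shape), 0, spec$noiseSigma),
                        shape[1L], shape[2L])
  img[img < 0] <- 0
  img[img > 1] <- 1
  list(image = img, truth = truth)
}

#' Generate an evaluation suite on disk
#'
#' Writes \code{n} synthetic image / ground-truth pairs plus a TSV manifest
#' under \code{dir}. Images cycle over wavelengths \{4, 8, 12, 20\} px and
#' the three ridge geometries. Difficulty tiers model acquisition quality:
#' \describe{
#'   \item{clean}{mild sensor noise (sigma 0.03).}
#'   \item{noisy}{heavy white noise (sigma 0.15).}
#'   \item{artifacts}{the noisy tier's noise plus a ghost print, smooth
#'     large-scale structure noise, and dry-contact breaks, so the tiers are
#'     nested in difficulty.}
#' }
#' Regeneration with the same seed is byte-identical.
#'
#' @param n number of image pairs (>= 1).
#' @param difficulty \code{"clean"}, \code{"noisy"} or \code{"artifacts"}.
#' @param seed base RNG seed; per-image seeds are derived from it.
#' @param dir output directory (created if needed).
#' @param shape image size, default 256 x 256.
#' @return the manifest path (invisibly the data.frame as attribute
#'   \code{"pairs"}).
#' @export
makeSuite <- function(n, difficulty = c("clean", "noisy", "artifacts"),
                      seed = 1, dir = tempfile("suite"),
                      shape = c(256, 256)) {
  difficulty <- match.arg(difficulty)
  if (n < 1) stop("'n' must be >= 1")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  lambdas <- c(4, 8, 12, 20)
  fields <- c("constant", "arcs", "varying")
  pairs <- data.frame(image = character(n), mask = character(n),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    spec <- synthSpecForSuite(i, difficulty, seed, shape, lambdas, fields)
    fp <- makeFingerprint(spec)
    imgPath <- file.path(dir, sprintf("%s_%03d.png", difficulty, i))
    maskPath <- file.path(dir, sprintf("%s_%03d_mask.png", difficulty, i))
    writeGrayImage(fp$image, imgPath)
    writeMask(fp$truth, maskPath)
    pairs$image[i] <- imgPath
    pairs$mask[i] <- maskPath
  }
  manifest <- file.path(dir, paste0(difficulty, "_manifest.tsv"))
  writeManifest(pairs, manifest)
  structure(manifest, pairs = pairs)
}

# deterministic per-image spec for makeSuite (exported for reproducibility
# of individual suite members without writing files)
#' @rdname makeSuite
#' @param i image index within the suite.
#' @param lambdas,fields cycles of wavelengths and ridge geometries.
#' @export
synthSpecForSuite <- function(i, difficulty, seed, shape = c(256, 256),
                              lambdas = c(4, 8, 12, 20),
                              fields = c("constant", "arcs", "varying")) {
  lam <- lambdas[(i - 1L) %% length(lambdas) + 1L]
  field <- fields[(i - 1L) %/% length(lambdas) %% length(fields) + 1L]
  # difficulty tiers are nested: artifacts adds structured perturbations on
  # top of the noisy tier's noise level, so difficulty is monotone by design
  noise <- switch(difficulty, clean = 0.03, noisy = 0.15, artifacts = 0.15)
  arts <- if (difficulty == "artifacts")
    list(ghost = list(), dryBreaks = 3L, structureNoise = 3L) else list()
  synthSpec(shape = shape, wavelength = lam, orientation = field,
            theta = pi * ((i * 5L) %% 8L) / 8,
            amplitude = 0.7, noiseSigma = noise, artifacts = arts,
            seed = (seed * 1000L + i) %% .Machine$integer.max)
}
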