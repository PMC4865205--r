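# The factorized analysis -> soft-threshold -> synthesis transform producing
# the feature image, plus the alternative max/sum synthesis operators used in
# the comparison study. All filtering is circular via the DFT on the
# mirror-padded image; the pad absorbs wrap-around.

#' Construct the FDB parameter set
#'
#' @param C relative threshold constant in (0,1) used both for the adaptive
#'   coefficient threshold and the feature-image binarization. Default 0.05,
#'   the mid-range of per-sensor trained values.
#' @param n directional Hilbert order (default 20).
#' @param L number of orientations (default 16).
#' @param gamma Butterworth order (default 2).
#' @param omegaLow,omegaHigh bandpass cutoffs in radians/sample (defaults
#'   0.3 and 1).
#' @param s odd morphology cell size in pixels (default 9).
#' @param t morphology threshold divisor, > 1 (default 5).
#' @param b required number of voting cells, 1..9 (default 6).
#' @param pad mirror-pad width in pixels (default 15).
#' @param variant Butterworth variant (default \code{"bilinear"}).
#' @return a validated [FDBParams-class] object.
#' @examples
#' fdbParams()
#' fdbParams(C = 0.06, gamma = 4, t = 5)
#' @export
fdbParams <- function(C = 0.05, n = 20, L = 16, gamma = 2,
                      omegaLow = 0.3, omegaHigh = 1, s = 9, t = 5, b = 6,
                      pad = 15, variant = c("bilinear", "original")) {
  variant <- match.arg(variant)
  # slots are assigned (not passed to new()) because a named argument "C"
  # would partially match new()'s 'Class' formal
  obj <- new("FDBParams")
  obj@C <- as.numeric(C); obj@n <- as.integer(n); obj@L <- as.integer(L)
  obj@gamma <- as.integer(gamma)
  obj@omegaLow <- as.numeric(omegaLow); obj@omegaHigh <- as.numeric(omegaHigh)
  obj@s <- as.integer(s); obj@t <- as.numeric(t); obj@b <- as.integer(b)
  obj@pad <- as.integer(pad); obj@variant <- variant
  validObject(obj)
  obj
}

#' Mirror-pad an image
#'
#' Pads a matrix on all four sides by reflection that does not repeat the edge
#' sample (a row \code{a b c} padded by 2 becomes \code{c b a b c b a}).
#' Used to suppress boundary effects of the circular (DFT) filtering.
#'
#' @param image numeric matrix.
#' @param pad pad width in pixels, \code{0 <= pad < min(dim(image))}.
#' @return matrix of dimension \code{dim(image) + 2*pad}.
#' @seealso [cropPad()] for the inverse.
#' @export
mirrorPad <- function(image, pad) {
  stopifnot(is.matrix(image))
  pad <- as.integer(pad)
  if (pad < 0L) stop("'pad' must be >= 0")
  if (pad == 0L) return(image)
  if (pad >= min(dim(image)))
    stop("'pad' must be smaller than both image dimensions")
  reflIdx <- function(n, p) {
    j <- (1L - p):(n + p)
    j[j < 1L] <- 2L - j[j < 1L]
    j[j > n] <- 2L * n - j[j > n]
    j
  }
  image[reflIdx(nrow(image), pad), reflIdx(ncol(image), pad)]
}

#' Crop the pad of a mirror-padded image
#'
#' @param image padded matrix.
#' @param pad pad width that was applied.
#' @return the central \code{dim(image) - 2*pad} matrix.
#' @export
cropPad <- function(image, pad) {
  pad <- as.integer(pad)
  if (pad == 0L) return(image)
  if (2L * pad >= min(dim(image))) stop("'pad' larger than the image")
  image[(pad + 1L):(nrow(image) - pad), (pad + 1L):(ncol(image) - pad),
        drop = FALSE]
}

# index-reversed spectrum phi-hat(-omega) on the DFT grid
.reverseSpectrum <- function(s) {
  nr <- nrow(s); nc <- ncol(s)
  s[c(1L, if (nr > 1L) nr:2L), c(1L, if (nc > 1L) nc:2L), drop = FALSE]
}

.fft2 <- function(x) stats::fft(x)
.ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Forward analysis: directional subband coefficients
#'
#' Correlates the (padded) image with every DHBB subband kernel, i.e. filters
#' with the argument-reversed transfer function:
#' \eqn{c_l = F^{-1}[F[f] \cdot \hat\phi_l(-\omega)]}. Computed by FFT; for
#' even Hilbert order the composite spectra are Hermitian and the
#' coefficients are real up to rounding.
#'
#' @param image numeric matrix whose dimension equals the bank's grid shape
#'   (pad first with [mirrorPad()]).
#' @param bank a [FilterBank-class] object.
#' @return a [SubbandCoefficients-class] object (coefficients stored complex).
#' @export
fdbAnalyze <- function(image, bank) {
  stopifnot(is.matrix(image), is(bank, "FilterBank"))
  if (!all(dim(image) == bank@grid@dim))
    stop("image dimension does not match the filter bank grid")
  fhat <- .fft2(image)
  cl <- lapply(bank@spectra,
               function(s) .ifft2(fhat * .reverseSpectrum(s)))
  new("SubbandCoefficients", c = cl, d = list(),
      dim = bank@grid@dim)
}

#' Adaptive shrinkage threshold
#'
#' \eqn{\beta = C \cdot \max_{l,m} |c_l[m]|}: the threshold adapts to the
#' strongest coefficient over all subbands and positions, so only the scale-
#' free constant \code{C} needs training per sensor.
#'
#' @param coeffs a [SubbandCoefficients-class] object.
#' @param C constant in [0, 1).
#' @return the threshold \eqn{\beta \ge 0}.
#' @export
adaptiveBeta <- function(coeffs, C) {
  stopifnot(is(coeffs, "SubbandCoefficients"))
  if (!length(coeffs@c)) stop("no coefficients")
  C * max(vapply(coeffs@c, function(m) max(Mod(m)), numeric(1)))
}

#' Backward synthesis of the feature image
#'
#' Applies the (non-reversed) subband filters to the thresholded coefficients
#' and sums over orientations:
#' \eqn{\tilde f = \mathrm{Re}\sum_l F^{-1}[F[d_l]\,\hat\phi_l(\omega)]},
#' optionally cropping the mirror pad. With a zero threshold (\eqn{d_l =
#' c_l}) this reduces exactly to filtering the image by
#' \eqn{\sum_l \hat\phi_l(-\omega)\hat\phi_l(\omega)}.
#'
#' @param coeffs a [SubbandCoefficients-class] object carrying thresholded
#'   coefficients (slot \code{d}; if absent the raw coefficients are used,
#'   i.e. the zero-threshold limit).
#' @param bank the [FilterBank-class] used for analysis.
#' @param pad pad width to crop from the result (default 0: no crop).
#' @return numeric matrix, the feature image.
#' @export
fdbSynthesize <- function(coeffs, bank, pad = 0) {
  stopifnot(is(coeffs, "SubbandCoefficients"), is(bank, "FilterBank"))
  if (!all(coeffs@dim == bank@grid@dim))
    stop("coefficient dimension does not match the filter bank grid")
  dl <- if (length(coeffs@d)) coeffs@d else coeffs@c
  acc <- matrix(0 + 0i, coeffs@dim[1L], coeffs@dim[2L])
  for (l in seq_along(dl))
    acc <- acc + .fft2(dl[[l]]) * bank@spectra[[l]]
  out <- Re(.ifft2(acc))
  cropPad(out, pad)
}

#' Apply a shrinkage operator to all subbands
#'
#' Stores \eqn{d_l = T(c_l, \beta)} in the coefficient object using the
#' selected operator from [softThreshold()] / [comparisonThreshold()].
#'
#' @param coeffs a [SubbandCoefficients-class] object.
#' @param beta threshold \eqn{\beta \ge 0}.
#' @param kind one of \code{"soft"} (the method's operator), \code{"hard"},
#'   \code{"semisoft"}, \code{"nonlinear"}.
#' @param beta2 secondary threshold for \code{"semisoft"} (default
#'   \code{2*beta}).
#' @return the updated [SubbandCoefficients-class] object.
#' @export
thresholdCoefficients <- function(coeffs, beta,
                                  kind = c("soft", "hard", "semisoft",
                                           "nonlinear"),
                                  beta2 = 2 * beta) {
  stopifnot(is(coeffs, "SubbandCoefficients"))
  kind <- match.arg(kind)
  coeffs@d <- lapply(coeffs@c, function(m) {
    if (kind == "soft") softThreshold(m, beta)
    else comparisonThreshold(m, beta, kind, beta2)
  })
  validObject(coeffs)
  coeffs
}

#' Feature image by the factorized directional bandpass transform
#'
#' The full texture-extraction transform: mirror-pad, build the DHBB bank on
#' the padded grid, analyze into \code{L} directional subbands, soft-threshold
#' at the adaptive level \eqn{\beta = C\max|c_l|}, synthesize, and crop back.
#' The result is a smoothed sparse image carrying the oscillatory ridge
#' texture and suppressing background.
#'
#' @param image numeric matrix with values in [0,1].
#' @param params a [FDBParams-class] object.
#' @param bank optional pre-built [FilterBank-class] matching the padded
#'   shape (a cache for repeated calls on equal-sized images).
#' @return numeric matrix of the input's dimension.
#' @examples
#' img <- makeFingerprint(synthSpec(shape = c(64, 64), seed = 1))$image
#' ft <- fdbFeatureImage(img, fdbParams(L = 8, pad = 8))
#' @export
fdbFeatureImage <- function(image, params, bank = NULL) {
  stopifnot(is.matrix(image), is(params, "FDBParams"))
  validObject(params)
  padded <- mirrorPad(image, params@pad)
  if (is.null(bank)) bank <- dhbbFilterBank(dim(padded), params)
  else if (!all(bank@grid@dim == dim(padded)))
    stop("supplied bank does not match the padded image shape")
  co <- fdbAnalyze(padded, bank)
  beta <- adaptiveBeta(co, params@C)
  co <- thresholdCoefficients(co, beta, kind = "soft")
  fdbSynthesize(co, bank, pad = params@pad)
}

# shared core of the appendix max/sum reconstruction operators
.altSynthArrays <- function(coeffs, useShrinkage) {
  arr <- if (useShrinkage) {
    if (!length(coeffs@d))
      stop("shrinkage requested but coefficients are not thresholded")
    coeffs@d
  } else coeffs@c
  lapply(arr, Re)
}

#' Maximum-operator reconstruction (comparison study)
#'
#' Alternative synthesis used only for comparison with the factorized
#' transform: at each pixel take the maximum over orientations of the
#' positive coefficients plus the minimum over orientations of the negative
#' ones,
#' \eqn{\tilde f[k] = \max_l c_l[k] 1\{c_l[k] > 0\} +
#'   \min_l c_l[k] 1\{c_l[k] < 0\}}
#' (with \eqn{d_l} in place of \eqn{c_l} when \code{useShrinkage}).
#'
#' @param coeffs a [SubbandCoefficients-class] object.
#' @param bank the matching [FilterBank-class] (shape check only).
#' @param useShrinkage use the thresholded coefficients.
#' @param pad pad width to crop (default 0).
#' @return numeric matrix.
#' @export
synthesizeMax <- function(coeffs, bank, useShrinkage = FALSE, pad = 0) {
  stopifnot(is(coeffs, "SubbandCoefficients"), is(bank, "FilterBank"))
  if (!all(coeffs@dim == bank@grid@dim)) stop("shape mismatch")
  arr <- .altSynthArrays(coeffs, useShrinkage)
  posMax <- Reduce(pmax, lapply(arr, function(m) m * (m > 0)))
  negMin <- Reduce(pmin, lapply(arr, function(m) m * (m < 0)))
  cropPad(posMax + negMin, pad)
}

#' Summation-operator reconstruction (comparison study)
#'
#' Naive reconstruction by plain summation of the subband coefficients over
#' orientations, \eqn{\tilde f[k] = \sum_l c_l[k]} (or \eqn{d_l} when
#' \code{useShrinkage}).
#'
#' @inheritParams synthesizeMax
#' @return numeric matrix.
#' @export
synthesizeSum <- function(coeffs, bank, useShrinkage = FALSE, pad = 0) {
  stopifnot(is(coeffs, "SubbandCoefficients"), is(bank, "FilterBank"))
  if (!all(coeffs@dim == bank@grid@dim)) stop("shape mismatch")
  arr <- .altSynthArrays(coeffs, useShrinkage)
  cropPad(Reduce(`+`, arr), pad)
}
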