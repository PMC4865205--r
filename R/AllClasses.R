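#' @import methods
NULL

#' Butterworth bandpass specification
#'
#' Holds the parameters of the 1D Butterworth bandpass prototype: the filter
#' order \eqn{\gamma}, the cutoff frequencies \eqn{\omega_L < \omega_H} (in
#' radians per sample), and the variant used when the filter is evaluated on a
#' discrete frequency grid. The derived quantities \eqn{\Delta = \omega_H -
#' \omega_L} and the geometric-mean peak frequency \eqn{p =
#' \sqrt{\omega_L\omega_H}} are available through accessors.
#'
#' @slot gamma integer(1), filter order, >= 1. Larger orders approach the
#'   ideal (brick-wall) bandpass.
#' @slot omegaLow,omegaHigh numeric(1), cutoffs with
#'   \code{0 < omegaLow < omegaHigh <= pi}.
#' @slot variant character(1), \code{"bilinear"} (discrete approximation via
#'   the bilinear transform, the default used by the filter bank) or
#'   \code{"original"} (the analog magnitude response evaluated directly).
#'
#' @seealso [butterworthSpec()], [butterworth1d()], [butterworthBilinear1d()]
#' @exportClass ButterworthSpec
setClass("ButterworthSpec",
  representation(gamma = "integer", omegaLow = "numeric",
                 omegaHigh = "numeric", variant = "character"),
  prototype(gamma = 2L, omegaLow = 0.3, omegaHigh = 1, variant = "bilinear"))

setValidity("ButterworthSpec", function(object) {
  msg <- character()
  if (length(object@gamma) != 1L || is.na(object@gamma) || object@gamma < 1L)
    msg <- c(msg, "'gamma' must be a single integer >= 1")
  if (length(object@omegaLow) != 1L || length(object@omegaHigh) != 1L ||
      !is.finite(object@omegaLow) || !is.finite(object@omegaHigh))
    msg <- c(msg, "cutoffs must be single finite numbers")
  else if (!(object@omegaLow > 0 && object@omegaLow < object@omegaHigh &&
             object@omegaHigh <= pi))
    msg <- c(msg, "cutoffs must satisfy 0 < omegaLow < omegaHigh <= pi")
  if (!object@variant %in% c("bilinear", "original"))
    msg <- c(msg, "'variant' must be \"bilinear\" or \"original\"")
  if (length(msg)) msg else TRUE
})

#' Discrete frequency grid of a padded image
#'
#' The 2D angular frequencies of the discrete Fourier transform of an image of
#' a given size, laid out exactly as [stats::fft()] lays out its output (DC in
#' the [1,1] cell, no shifting), with frequencies mapped to \eqn{[-\pi,\pi)}.
#' \code{omega1} varies along columns (horizontal spatial axis), \code{omega2}
#' along rows (vertical axis). The domain half-widths used by the Cartesian
#' indicator tiling are \code{a = ncol/2} and \code{b = nrow/2}.
#'
#' @slot omega1,omega2 numeric matrices of dimension \code{dim}.
#' @slot dim integer(2), (rows, cols) of the padded image.
#' @seealso [frequencyGrid()]
#' @exportClass FrequencyGrid
setClass("FrequencyGrid",
  representation(omega1 = "matrix", omega2 = "matrix", dim = "integer"))

setValidity("FrequencyGrid", function(object) {
  if (!all(dim(object@omega1) == object@dim) ||
      !all(dim(object@omega2) == object@dim))
    return("omega matrices must match 'dim'")
  if (sum(object@omega1 == 0 & object@omega2 == 0) != 1L)
    return("DC must be present exactly once")
  TRUE
})

#' Directional Hilbert Butterworth bandpass (DHBB) filter bank
#'
#' A bank of \code{L} oriented bandpass spectra
#' \eqn{\hat\phi_l^{\gamma,n}(\omega) = \hat h_l^n(\omega)\,
#' \hat g^\gamma(\omega)} on the frequency grid of a padded image: the n-th
#' order directional Hilbert (angularpass) spectrum times the 2D Butterworth
#' bandpass spectrum. Orientations are \eqn{\theta_l = \pi l / L},
#' \eqn{l = 0, \dots, L-1}.
#'
#' @slot spectra list of \code{L} complex matrices, the subband transfer
#'   functions in [stats::fft()] layout.
#' @slot n integer(1), directional Hilbert order (angular sharpness).
#' @slot L integer(1), number of orientations.
#' @slot theta numeric(L), the orientation angles.
#' @slot butterworth a [ButterworthSpec-class] object.
#' @slot grid the [FrequencyGrid-class] the spectra live on.
#' @seealso [dhbbFilterBank()], [fdbAnalyze()]
#' @exportClass FilterBank
setClass("FilterBank",
  representation(spectra = "list", n = "integer", L = "integer",
                 theta = "numeric", butterworth = "ButterworthSpec",
                 grid = "FrequencyGrid"))

setValidity("FilterBank", function(object) {
  if (length(object@spectra) != object@L)
    return("number of spectra must equal L")
  d <- object@grid@dim
  for (s in object@spectra) {
    if (!all(dim(s) == d)) return("every spectrum must match the grid shape")
    if (!all(is.finite(Re(s))) || !all(is.finite(Im(s))))
      return("spectra must be finite everywhere")
    if (Mod(s[1L, 1L]) > 1e-12) return("spectra must vanish at DC")
  }
  if (length(object@theta) != object@L) return("theta must have length L")
  TRUE
})

#' Full parameter set of the FDB segmentation method
#'
#' All tunable parameters of the pipeline. \code{C}, \code{gamma} and \code{t}
#' are the per-sensor trained parameters; \code{n}, \code{L}, \code{s},
#' \code{b}, the cutoffs and the pad width are held fixed across sensors.
#'
#' @slot C numeric(1) in (0,1): relative level of both the adaptive
#'   coefficient threshold \eqn{\beta = C \max_{l,m} |c_l[m]|} and the feature
#'   image binarization threshold.
#' @slot n integer(1), directional Hilbert order (default 20).
#' @slot L integer(1), number of orientations (default 16).
#' @slot gamma integer(1), Butterworth order.
#' @slot omegaLow,omegaHigh numeric(1), bandpass cutoffs in radians/sample
#'   (defaults 0.3 and 1, matching interridge distances of roughly 6--21
#'   pixels at 500 DPI).
#' @slot s integer(1), odd morphology cell size in pixels (default 9).
#' @slot t numeric(1) > 1, morphology threshold divisor: a cell votes
#'   "textured" when it contains at least \eqn{s^2/t} white pixels.
#' @slot b integer(1) in 1..9, number of voting cells required (default 6).
#' @slot pad integer(1), mirror-pad width in pixels (default 15).
#' @slot variant character(1), Butterworth variant, see
#'   [ButterworthSpec-class].
#' @seealso [fdbParams()], [segmentFingerprint()]
#' @exportClass FDBParams
setClass("FDBParams",
  representation(C = "numeric", n = "integer", L = "integer",
                 gamma = "integer", omegaLow = "numeric",
                 omegaHigh = "numeric", s = "integer", t = "numeric",
                 b = "integer", pad = "integer", variant = "character"),
  prototype(C = 0.05, n = 20L, L = 16L, gamma = 2L, omegaLow = 0.3,
            omegaHigh = 1, s = 9L, t = 5, b = 6L, pad = 15L,
            variant = "bilinear"))

setValidity("FDBParams", function(object) {
  msg <- character()
  if (!(length(object@C) == 1L && is.finite(object@C) &&
        object@C > 0 && object@C < 1))
    msg <- c(msg, "'C' must lie strictly between 0 and 1")
  if (object@n < 1L) msg <- c(msg, "'n' must be >= 1")
  if (object@L < 1L) msg <- c(msg, "'L' must be >= 1")
  if (object@s < 3L || object@s %% 2L == 0L)
    msg <- c(msg, "'s' must be odd and >= 3")
  if (!(is.finite(object@t) && object@t > 1)) msg <- c(msg, "'t' must be > 1")
  if (object@b < 1L || object@b > 9L) msg <- c(msg, "'b' must be in 1..9")
  if (object@pad < 0L) msg <- c(msg, "'pad' must be >= 0")
  bw <- try(butterworthSpec(object@gamma, object@omegaLow, object@omegaHigh,
                            object@variant), silent = TRUE)
  if (inherits(bw, "try-error"))
    msg <- c(msg, "invalid Butterworth sub-specification")
  if (length(msg)) msg else TRUE
})

#' Subband coefficients of the FDB analysis step
#'
#' The \code{L} arrays of analysis coefficients \eqn{c_l[m]} of a (padded)
#' image under the DHBB filter bank, and, once thresholding has been applied,
#' the shrunk coefficients \eqn{d_l[m]}.
#'
#' @slot c list of \code{L} complex matrices (analysis coefficients).
#' @slot d list of \code{L} complex matrices (thresholded coefficients), or an
#'   empty list before thresholding.
#' @slot dim integer(2), the common (padded) array dimension.
#' @seealso [fdbAnalyze()], [thresholdCoefficients()], [fdbSynthesize()]
#' @exportClass SubbandCoefficients
setClass("SubbandCoefficients",
  representation(c = "list", d = "list", dim = "integer"))

setValidity("SubbandCoefficients", function(object) {
  if (!length(object@c)) return("at least one subband required")
  for (m in object@c)
    if (!all(dim(m) == object@dim)) return("subband shapes must agree")
  if (length(object@d)) {
    if (length(object@d) != length(object@c))
      return("'d' must have the same number of subbands as 'c'")
    for (i in seq_along(object@d)) {
      if (!all(dim(object@d[[i]]) == object@dim))
        return("thresholded subband shapes must agree")
    }
  }
  TRUE
})
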