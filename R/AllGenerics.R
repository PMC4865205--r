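#' Accessors for filter and parameter objects
#'
#' Small accessor generics: \code{filterOrder} returns the Butterworth order
#' \eqn{\gamma}; \code{cutoffs} the \code{c(omegaLow, omegaHigh)} pair;
#' \code{bandwidth} \eqn{\Delta = \omega_H-\omega_L}; \code{peakFrequency}
#' the geometric mean \eqn{p = \sqrt{\omega_L \omega_H}} at which the 1D
#' bandpass attains its maximum of 1; \code{nOrientations} the number of
#' subband orientations \code{L}; \code{orientationAngles} the angles
#' \eqn{\theta_l}; \code{filterSpectra} the list of subband transfer
#' functions; and \code{coefficients}/\code{thresholded} the analysis and
#' shrunk coefficient arrays of a [SubbandCoefficients-class] object.
#'
#' @param object a [ButterworthSpec-class], [FilterBank-class],
#'   [FDBParams-class] or [SubbandCoefficients-class] object, as applicable.
#' @return see the individual descriptions above.
#' @name accessors
#' @aliases filterOrder cutoffs bandwidth peakFrequency nOrientations
#'   orientationAngles filterSpectra thresholded
NULL

#' @rdname accessors
#' @export
setGeneric("filterOrder", function(object) standardGeneric("filterOrder"))
#' @rdname accessors
#' @export
setGeneric("cutoffs", function(object) standardGeneric("cutoffs"))
#' @rdname accessors
#' @export
setGeneric("bandwidth", function(object) standardGeneric("bandwidth"))
#' @rdname accessors
#' @export
setGeneric("peakFrequency", function(object) standardGeneric("peakFrequency"))
#' @rdname accessors
#' @export
setGeneric("nOrientations", function(object) standardGeneric("nOrientations"))
#' @rdname accessors
#' @export
setGeneric("orientationAngles",
           function(object) standardGeneric("orientationAngles"))
#' @rdname accessors
#' @export
setGeneric("filterSpectra", function(object) standardGeneric("filterSpectra"))
#' @rdname accessors
#' @export
setGeneric("thresholded", function(object) standardGeneric("thresholded"))

#' @rdname accessors
setMethod("filterOrder", "ButterworthSpec", function(object) object@gamma)
#' @rdname accessors
setMethod("filterOrder", "FDBParams", function(object) object@gamma)
#' @rdname accessors
setMethod("cutoffs", "ButterworthSpec",
          function(object) c(object@omegaLow, object@omegaHigh))
#' @rdname accessors
setMethod("cutoffs", "FDBParams",
          function(object) c(object@omegaLow, object@omegaHigh))
#' @rdname accessors
setMethod("bandwidth", "ButterworthSpec",
          function(object) object@omegaHigh - object@omegaLow)
#' @rdname accessors
setMethod("peakFrequency", "ButterworthSpec",
          function(object) sqrt(object@omegaLow * object@omegaHigh))
#' @rdname accessors
setMethod("nOrientations", "FilterBank", function(object) object@L)
#' @rdname accessors
setMethod("nOrientations", "FDBParams", function(object) object@L)
#' @rdname accessors
setMethod("orientationAngles", "FilterBank", function(object) object@theta)
#' @rdname accessors
setMethod("filterSpectra", "FilterBank", function(object) object@spectra)
#' @rdname accessors
#' @param ... unused.
#' @importFrom stats coefficients
#' @exportMethod coefficients
setMethod("coefficients", "SubbandCoefficients", function(object, ...) object@c)
#' @rdname accessors
setMethod("thresholded", "SubbandCoefficients", function(object) {
  if (!length(object@d)) stop("coefficients have not been thresholded yet")
  object@d
})

#' @describeIn accessors display a Butterworth specification
#' @export
setMethod("show", "ButterworthSpec", function(object) {
  cat(sprintf(
    "ButterworthSpec: gamma=%d, omega in [%.3g, %.3g] (Delta=%.3g, p=%.4g), %s variant\n",
    object@gamma, object@omegaLow, object@omegaHigh,
    bandwidth(object), peakFrequency(object), object@variant))
})

setMethod("show", "FrequencyGrid", function(object) {
  cat(sprintf("FrequencyGrid: %d x %d, omega in [-pi, pi)\n",
              object@dim[1L], object@dim[2L]))
})

setMethod("show", "FilterBank", function(object) {
  cat(sprintf("DHBB FilterBank: L=%d orientations, Hilbert order n=%d, grid %d x %d\n",
              object@L, object@n, object@grid@dim[1L], object@grid@dim[2L]))
  show(object@butterworth)
})

setMethod("show", "FDBParams", function(object) {
  cat("FDBParams (factorized directional bandpass segmentation)\n")
  cat(sprintf("  filter bank : n=%d, L=%d, gamma=%d, omega=[%.3g, %.3g], %s\n",
              object@n, object@L, object@gamma, object@omegaLow,
              object@omegaHigh, object@variant))
  cat(sprintf("  thresholds  : C=%.3g (beta and binarization)\n", object@C))
  cat(sprintf("  morphology  : s=%d, t=%.3g, b=%d\n",
              object@s, object@t, object@b))
  cat(sprintf("  padding     : %d px mirror\n", object@pad))
})

setMethod("show", "SubbandCoefficients", function(object) {
  cat(sprintf("SubbandCoefficients: %d subbands of %d x %d, %s\n",
              length(object@c), object@dim[1L], object@dim[2L],
              if (length(object@d)) "thresholded" else "not thresholded"))
})
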