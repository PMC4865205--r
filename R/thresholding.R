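# Shrinkage operators applied to analysis coefficients. Soft-thresholding is
# the method's operator (the proximal operator of the l1 norm); hard,
# semi-soft and nonlinear (garrote) shrinkage are comparison-only.

#' Soft-thresholding
#'
#' \deqn{T(x, \beta) = \frac{x}{|x|}\,\max\{|x| - \beta,\, 0\}:}
#' shrinks the magnitude by \eqn{\beta}, clips at zero, and preserves the
#' sign (real input) or phase (complex input); \eqn{T(0, \beta) = 0}. The
#' output is the minimizer of the l1-shrinkage problem
#' \eqn{\min_u \beta\|u\|_1 + \frac12 \|u - x\|_2^2} (the proximal operator
#' of \eqn{\beta\|\cdot\|_1}), and the operator is non-expansive.
#'
#' @param x numeric or complex array.
#' @param beta threshold, a single number >= 0.
#' @return array of the same shape and mode as \code{x} with
#'   \code{abs(out) <= abs(x)} elementwise.
#' @examples
#' softThreshold(c(-5, -1, 0, 1, 5), 2)  # -3 0 0 0 3
#' @export
softThreshold <- function(x, beta) {
  if (length(beta) != 1L || !is.finite(beta) || beta < 0)
    stop("'beta' must be a single number >= 0")
  a <- Mod(x)
  shrink <- pmax(a - beta, 0)
  out <- x
  nz <- a > 0
  out[nz] <- x[nz] * (shrink[nz] / a[nz])
  out[!nz] <- 0
  out
}

#' Comparison thresholding operators
#'
#' The three shrinkage rules compared against soft-thresholding:
#' \describe{
#'   \item{hard}{\eqn{x \cdot 1\{|x| > \beta\}}: keep-or-kill, discontinuous
#'     at \eqn{\pm\beta}.}
#'   \item{semisoft}{0 below \eqn{\beta}, the linear ramp
#'     \eqn{\frac{\beta_2}{\beta_2-\beta}\,\mathrm{sgn}(x)(|x|-\beta)} between
#'     \eqn{\beta} and \eqn{\beta_2}, identity above \eqn{\beta_2};
#'     continuous, interpolating hard and soft.}
#'   \item{nonlinear}{the garrote \eqn{x \max\{1 - \beta^2/x^2,\, 0\}};
#'     continuous, approaching the identity quadratically for large
#'     \eqn{|x|}.}
#' }
#' All are odd, magnitude non-increasing, and equal the identity for
#' \eqn{|x| \gg \beta}. For complex input the rules act on the magnitude and
#' preserve phase.
#'
#' @param x numeric or complex array.
#' @param beta primary threshold >= 0.
#' @param kind \code{"hard"}, \code{"semisoft"} or \code{"nonlinear"}.
#' @param beta2 secondary threshold for \code{"semisoft"}; must exceed
#'   \code{beta} (default \code{2*beta}).
#' @return array of the same shape as \code{x}.
#' @seealso [softThreshold()]
#' @export
comparisonThreshold <- function(x, beta,
                                kind = c("hard", "semisoft", "nonlinear"),
                                beta2 = 2 * beta) {
  kind <- match.arg(kind)
  if (length(beta) != 1L || !is.finite(beta) || beta < 0)
    stop("'beta' must be a single number >= 0")
  a <- Mod(x)
  gain <- switch(kind,
    hard = as.numeric(a > beta),
    semisoft = {
      if (!(beta2 > beta) && beta > 0)
        stop("'beta2' must exceed 'beta' for semisoft thresholding")
      g <- numeric(length(a))
      mid <- a > beta & a <= beta2
      hi <- a > beta2
      if (beta2 > beta)
        g[mid] <- (beta2 / (beta2 - beta)) * (a[mid] - beta) / a[mid]
      g[hi] <- 1
      g
    },
    nonlinear = {
      g <- numeric(length(a))
      nz <- a > 0
      g[nz] <- pmax(1 - beta^2 / a[nz]^2, 0)
      g
    })
  out <- x * gain
  dim(out) <- dim(x)
  out
}
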