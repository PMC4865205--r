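# Spectral construction of the DHBB filter bank: 1D/2D Butterworth bandpass,
# n-th order directional Hilbert (angularpass) spectra, and their composition.

#' Construct a Butterworth bandpass specification
#'
#' @param gamma filter order (integer >= 1).
#' @param omegaLow,omegaHigh cutoff frequencies in radians per sample,
#'   \code{0 < omegaLow < omegaHigh <= pi}.
#' @param variant \code{"bilinear"} or \code{"original"}.
#' @return a [ButterworthSpec-class] object.
#' @examples
#' sp <- butterworthSpec(2, 0.3, 1)
#' peakFrequency(sp)   # sqrt(0.3)
#' @export
butterworthSpec <- function(gamma, omegaLow = 0.3, omegaHigh = 1,
                            variant = c("bilinear", "original")) {
  variant <- match.arg(variant)
  if (length(gamma) != 1L || !is.finite(gamma) || gamma < 1 ||
      gamma != round(gamma))
    stop("'gamma' must be a single integer >= 1")
  new("ButterworthSpec", gamma = as.integer(gamma),
      omegaLow = as.numeric(omegaLow), omegaHigh = as.numeric(omegaHigh),
      variant = variant)
}

#' 1D Butterworth bandpass transfer function
#'
#' Evaluates the analog-prototype magnitude response
#' \deqn{\hat b(\omega) = \frac{(\omega\Delta)^{2\gamma}}
#'   {(\omega\Delta)^{2\gamma} + (\omega^2 - p^2)^{2\gamma}}}
#' with \eqn{\Delta = \omega_H - \omega_L} and \eqn{p^2 = \omega_H\omega_L}.
#' The response lies in [0,1], vanishes in the limits \eqn{\omega \to 0} and
#' \eqn{\omega \to \infty}, and attains its unique maximum 1 at the geometric
#' mean \eqn{p}. It is computed as \eqn{1/(1 + r^{2\gamma})} with
#' \eqn{r = (\omega^2-p^2)/(\omega\Delta)}, which is exact away from 0 and
#' avoids overflow for large orders; \eqn{\hat b(0) = 0} is set explicitly
#' (removable limit).
#'
#' @param omega numeric vector/array of frequencies (any sign; the response
#'   is even).
#' @param spec a [ButterworthSpec-class] object.
#' @return numeric array of the same shape as \code{omega}, values in [0,1].
#' @examples
#' sp <- butterworthSpec(2, 0.3, 1)
#' butterworth1d(peakFrequency(sp), sp)  # exactly 1
#' @export
butterworth1d <- function(omega, spec) {
  stopifnot(is(spec, "ButterworthSpec"))
  validObject(spec)
  if (!all(is.finite(omega))) stop("'omega' must be finite")
  delta <- bandwidth(spec)
  p2 <- spec@omegaLow * spec@omegaHigh
  g2 <- 2L * spec@gamma
  out <- omega  # keep shape
  nz <- omega != 0
  r <- (omega[nz]^2 - p2) / (omega[nz] * delta)
  rp <- abs(r)^g2
  out[nz] <- 1 / (1 + rp)
  out[!nz] <- 0
  out
}

#' Ideal (brick-wall) bandpass
#'
#' The limiting filter of the Butterworth family for large orders: 1 on
#' \eqn{[\omega_L, \omega_H]} (in absolute value), 0 elsewhere.
#'
#' @inheritParams butterworth1d
#' @return numeric array of 0/1 values.
#' @export
butterworthIdeal1d <- function(omega, spec) {
  stopifnot(is(spec, "ButterworthSpec"))
  aw <- abs(omega)
  as.numeric(aw >= spec@omegaLow & aw <= spec@omegaHigh)
}

#' Roots used in the Butterworth factorization
#'
#' Returns \eqn{t_k = e^{\pi j (\gamma + 2k - 1)/(2\gamma)}},
#' \eqn{k = 1, \dots, \gamma}: unit-circle points whose negative squares
#' \eqn{-t_k^2} enumerate the \eqn{\gamma} complex roots of \eqn{-1}, so that
#' \eqn{\prod_k (t^2 - t_k^2) = t^{2\gamma} + (-1)^\gamma}.
#'
#' @param gamma filter order (integer >= 1).
#' @return complex vector of length \code{gamma}.
#' @examples
#' butterworthRoots(1)  # -1
#' @export
butterworthRoots <- function(gamma) {
  if (length(gamma) != 1L || !is.finite(gamma) || gamma < 1 ||
      gamma != round(gamma))
    stop("'gamma' must be a single integer >= 1")
  k <- seq_len(gamma)
  exp(pi * 1i * (gamma + 2 * k - 1) / (2 * gamma))
}

#' Bilinear-transform Butterworth bandpass
#'
#' The discrete-frequency approximation of the bandpass transfer function
#' obtained by substituting \eqn{j\omega \approx 2(e^{j\omega}-1)/
#' (e^{j\omega}+1)} (the bilinear transform) into the factorized analog
#' transfer function \eqn{B(j\omega) = \prod_k \Delta j\omega /
#' ((j\omega)^2 - \Delta t_k j\omega + p^2)}:
#' \deqn{B^\gamma(e^{j\omega}) = \prod_{k=1}^{\gamma}
#'   \frac{2\Delta (e^{2j\omega} - 1)}
#'   {(4 + p^2 - 2\Delta t_k) e^{2j\omega} + (2p^2 - 8) e^{j\omega}
#'    + 4 + p^2 + 2\Delta t_k}.}
#' The approximation narrows the passband relative to [butterworth1d()];
#' its magnitude peaks near \eqn{p} and it vanishes at \eqn{\omega = 0}.
#'
#' @inheritParams butterworth1d
#' @return complex array of the same shape as \code{omega}.
#' @export
butterworthBilinear1d <- function(omega, spec) {
  stopifnot(is(spec, "ButterworthSpec"))
  validObject(spec)
  delta <- bandwidth(spec)
  p2 <- spec@omegaLow * spec@omegaHigh
  tk <- butterworthRoots(spec@gamma)
  z <- exp(1i * omega)
  z2 <- z * z
  out <- rep_len(1 + 0i, length(omega))
  for (k in seq_along(tk)) {
    den <- (4 + p2 - 2 * delta * tk[k]) * z2 + (2 * p2 - 8) * z +
      (4 + p2 + 2 * delta * tk[k])
    bad <- Mod(den) == 0
    if (any(bad))
      stop(sprintf("bilinear factor %d has a pole at omega = %g",
                   k, omega[which(bad)[1L]]))
    out <- out * (2 * delta * (z2 - 1)) / den
  }
  dim(out) <- dim(omega)
  out
}

#' Frequency grid for a padded image
#'
#' Builds the [FrequencyGrid-class] of DFT sample frequencies for an image of
#' size \code{shape = c(rows, cols)}, in the unshifted layout of
#' [stats::fft()], mapped to \eqn{[-\pi, \pi)}.
#'
#' @param shape integer(2), (rows, cols); both >= 2.
#' @return a [FrequencyGrid-class] object.
#' @export
frequencyGrid <- function(shape) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 2L))
    stop("'shape' must be two integers >= 2")
  wOf <- function(n) {
    k <- 0:(n - 1L)
    k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
    2 * pi * k / n
  }
  w2 <- matrix(wOf(shape[1L]), shape[1L], shape[2L])          # rows, vertical
  w1 <- matrix(wOf(shape[2L]), shape[1L], shape[2L], byrow = TRUE)  # cols
  new("FrequencyGrid", omega1 = w1, omega2 = w2, dim = shape)
}

#' 2D Butterworth bandpass spectrum on a Cartesian tiling
#'
#' Extends the 1D bandpass to 2D by splitting the frequency plane into a
#' horizontal and a vertical sector with the indicator pair
#' \eqn{\chi_h(\omega_1,\omega_2) = 1\{b|\omega_1| \ge a|\omega_2|\}} and
#' \eqn{\chi_v = 1 - \chi_h} (ties assigned to the horizontal sector so the
#' two indicators partition the plane), where \eqn{a} and \eqn{b} are the
#' half-widths of the image domain (cols/2 and rows/2; for square images this
#' reduces to comparing \eqn{|\omega_1|} with \eqn{|\omega_2|}):
#' \deqn{\hat g^\gamma(\omega_1,\omega_2) = B^\gamma(e^{j\omega_1})
#'   \chi_h + B^\gamma(e^{j\omega_2}) \chi_v.}
#' For \code{variant = "original"} the analog response
#' \code{butterworth1d} of each axis frequency is substituted for
#' \eqn{B^\gamma(e^{j\omega_i})}.
#'
#' @param grid a [FrequencyGrid-class] object.
#' @param spec a [ButterworthSpec-class] object.
#' @return a complex (bilinear) or numeric (original) matrix of the grid's
#'   dimension.
#' @export
butterworth2dSpectrum <- function(grid, spec) {
  stopifnot(is(grid, "FrequencyGrid"), is(spec, "ButterworthSpec"))
  validObject(spec)
  a <- grid@dim[2L] / 2
  b <- grid@dim[1L] / 2
  chiH <- b * abs(grid@omega1) >= a * abs(grid@omega2)
  f1 <- if (spec@variant == "bilinear") butterworthBilinear1d else butterworth1d
  s1 <- f1(grid@omega1, spec)
  s2 <- f1(grid@omega2, spec)
  out <- s2
  out[chiH] <- s1[chiH]
  out
}

#' n-th order directional Hilbert (angularpass) spectrum
#'
#' The transfer function of the n-fold iterated directional Hilbert transform
#' along the unit vector \eqn{u = (\cos\theta_l, \sin\theta_l)},
#' \eqn{\theta_l = \pi l / L}:
#' \deqn{\hat h_l^n(\omega) = (-j)^n
#'   \left(\frac{\langle u, \omega\rangle}{\|\omega\|}\right)^n
#'   = (-j)^n \cos^n(\angle\omega - \theta_l),}
#' with magnitude at most 1, equal to 1 along the orientation, 0 across it,
#' real-valued for even \code{n}, and set to 0 at DC where the direction
#' cosine is undefined. Large \code{n} concentrates the response near the
#' orientation axis.
#'
#' @param grid a [FrequencyGrid-class] object.
#' @param l orientation index in \code{0:(L-1)}.
#' @param L number of orientations.
#' @param n Hilbert order (integer >= 1).
#' @return complex matrix of the grid's dimension.
#' @export
directionalHilbertSpectrum <- function(grid, l, L, n) {
  stopifnot(is(grid, "FrequencyGrid"))
  if (length(l) != 1L || l < 0 || l >= L || l != round(l))
    stop("'l' must be an integer in 0:(L-1)")
  if (n < 1 || n != round(n)) stop("'n' must be an integer >= 1")
  ang <- atan2(grid@omega2, grid@omega1)
  # (-j)^n cycles with period 4; take it exactly to keep even orders real
  const <- c(1 + 0i, 0 - 1i, -1 + 0i, 0 + 1i)[(n %% 4) + 1]
  out <- const * cos(ang - pi * l / L)^n
  out[grid@omega1 == 0 & grid@omega2 == 0] <- 0
  out
}

#' Build the DHBB filter bank
#'
#' Composes the 2D Butterworth bandpass and the \code{L} angularpass spectra
#' into the bank of oriented subband transfer functions
#' \eqn{\hat\phi_l^{\gamma,n}(\omega) = \hat h_l^n(\omega)
#' \hat g^\gamma(\omega)} on the frequency grid of an image of size
#' \code{shape} (normally the mirror-padded size).
#'
#' @param shape integer(2), (rows, cols) of the padded image.
#' @param params a [FDBParams-class] object.
#' @return a [FilterBank-class] object.
#' @examples
#' bank <- dhbbFilterBank(c(64, 64), fdbParams(L = 4))
#' bank
#' @export
dhbbFilterBank <- function(shape, params) {
  stopifnot(is(params, "FDBParams"))
  validObject(params)
  grid <- frequencyGrid(shape)
  spec <- butterworthSpec(params@gamma, params@omegaLow, params@omegaHigh,
                          params@variant)
  g2 <- butterworth2dSpectrum(grid, spec)
  spectra <- lapply(seq_len(params@L) - 1L, function(l) {
    h <- directionalHilbertSpectrum(grid, l, params@L, params@n)
    s <- h * g2
    if (!is.complex(s)) s <- s + 0i
    s
  })
  new("FilterBank", spectra = spectra, n = params@n, L = params@L,
      theta = pi * (seq_len(params@L) - 1L) / params@L,
      butterworth = spec, grid = grid)
}
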