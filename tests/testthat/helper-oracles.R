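# Independent brute-force oracles used across tests. These deliberately avoid
# the package's vectorized code paths.

# per-pixel 9-block voting morphology, O(N * s^2)
naiveMorphology <- function(mask, s, t, b) {
  nr <- nrow(mask); nc <- ncol(mask)
  h <- (s - 1L) %/% 2L
  cellCount <- function(r, c) {
    if (r + h < 1L || r - h > nr || c + h < 1L || c - h > nc) return(0L)
    rs <- max(1L, r - h):min(nr, r + h)
    cs <- max(1L, c - h):min(nc, c + h)
    sum(mask[rs, cs])
  }
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    votes <- 0L
    for (m1 in c(-s, 0L, s)) for (m2 in c(-s, 0L, s))
      if (cellCount(r + m1, c + m2) >= s^2 / t) votes <- votes + 1L
    out[r, c] <- votes >= b
  }
  out
}

# circular shift of a matrix by (dr, dc)
circShift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1L - dr) %% nr) + 1L,
    ((seq_len(nc) - 1L - dc) %% nc) + 1L, drop = FALSE]
}

# brute-force circular correlation of an image with a spatial kernel:
# c[m] = sum_k f[k] * kernel[k - m]
naiveCorrelate <- function(img, kernel) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0 + 0i, nr, nc)
  for (mr in 0:(nr - 1L)) for (mc in 0:(nc - 1L))
    out[mr + 1L, mc + 1L] <- sum(img * circShift(kernel, mr, mc))
  out
}

# grid-search minimizer of the l1-shrinkage objective
# beta*|u| + 0.5*(u - c)^2 over a dense grid of u
naiveProx <- function(cc, beta, gridN = 2001L) {
  u <- seq(-abs(cc) - beta - 1, abs(cc) + beta + 1, length.out = gridN)
  u[which.min(beta * abs(u) + 0.5 * (u - cc)^2)]
}

# a small, fast parameter set for unit tests (few orientations, thin pad)
smallParams <- function(...) {
  args <- list(...)
  defaults <- list(L = 8, n = 20, pad = 8)
  defaults[names(args)] <- args
  do.call(fdbParams, defaults)
}

# a compact clean fixture with known ROI
smallFingerprint <- function(shape = c(96, 96), wavelength = 8, seed = 5,
                             ...) {
  makeFingerprint(synthSpec(shape = shape, wavelength = wavelength,
                            seed = seed, ...))
}
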