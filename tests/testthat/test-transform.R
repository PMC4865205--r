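# Padding, analysis, adaptive threshold, synthesis, and the alternative
# reconstruction operators.

test_that("mirror padding reflects without repeating the edge sample", {
  m <- matrix(1:3, 1, 3)
  expect_identical(mirrorPad(m, 0), m)
  # a b c padded by 2 becomes c b a b c b a, in both directions
  abc <- outer(1:3, 1:3, function(r, c) 10 * r + c)
  p <- mirrorPad(abc, 2)
  expect_identical(dim(p), c(7L, 7L))
  expect_equal(p[3, ], c(13, 12, 11, 12, 13, 12, 11))
  expect_equal(p[, 3], c(31, 21, 11, 21, 31, 21, 11))
  img <- matrix(rnorm(7 * 5), 7, 5)
  padded <- mirrorPad(img, 3)
  expect_identical(dim(padded), c(13L, 11L))
  expect_identical(cropPad(padded, 3), img)         # exact round trip
  expect_error(mirrorPad(img, 5), "pad")
})

test_that("analysis of a constant image is zero and a plane wave lands in
           its own subband", {
  params <- smallParams(pad = 0, variant = "original")
  bank <- dhbbFilterBank(c(48, 48), params)
  co <- fdbAnalyze(matrix(0.7, 48, 48), bank)
  expect_lt(max(vapply(coefficients(co), function(m) max(Mod(m)), 1)), 1e-12)
  # plane wave along theta_l at the peak frequency
  p <- peakFrequency(bank@butterworth)
  x <- matrix(seq_len(48) - 1, 48, 48, byrow = TRUE)
  y <- matrix(seq_len(48) - 1, 48, 48)
  kcyc <- round(p * 48 / (2 * pi))                  # exact grid frequency
  for (l in c(0, 4)) {                              # theta = 0, pi/2
    th <- pi * l / 8
    wave <- 0.5 + 0.4 * cos(2 * pi * kcyc / 48 * (x * cos(th) + y * sin(th)))
    en <- vapply(coefficients(fdbAnalyze(wave, bank)),
                 function(m) sum(Mod(m)^2), 1)
    expect_identical(which.max(en), as.integer(l) + 1L)
  }
})

test_that("FFT analysis equals brute-force circular correlation", {
  set.seed(77)
  img <- matrix(runif(16 * 16), 16, 16)
  params <- fdbParams(L = 4, pad = 0)               # bilinear default
  bank <- dhbbFilterBank(c(16, 16), params)
  co <- fdbAnalyze(img, bank)
  for (l in 1:4) {
    kernel <- stats::fft(bank@spectra[[l]], inverse = TRUE) / 256
    expect_lt(max(Mod(coefficients(co)[[l]] - naiveCorrelate(img, kernel))),
              1e-8)
  }
})

test_that("analysis is linear and translation-covariant", {
  set.seed(78)
  img <- matrix(runif(32 * 32), 32, 32)
  params <- smallParams(pad = 0)
  bank <- dhbbFilterBank(c(32, 32), params)
  c1 <- coefficients(fdbAnalyze(img, bank))
  c3 <- coefficients(fdbAnalyze(3 * img, bank))
  for (l in seq_along(c1))
    expect_equal(c3[[l]], 3 * c1[[l]], tolerance = 1e-12)
  cs <- coefficients(fdbAnalyze(circShift(img, 5, -7), bank))
  for (l in seq_along(c1))
    expect_equal(cs[[l]], circShift(c1[[l]], 5, -7), tolerance = 1e-10)
})

test_that("adaptive beta scales with the coefficients and vanishes for C=0", {
  set.seed(79)
  img <- matrix(runif(32 * 32), 32, 32)
  params <- smallParams(pad = 0)
  bank <- dhbbFilterBank(c(32, 32), params)
  co <- fdbAnalyze(img, bank)
  expect_identical(adaptiveBeta(co, 0), 0)
  b1 <- adaptiveBeta(co, 0.05)
  expect_gt(b1, 0)
  co2 <- fdbAnalyze(2 * img, bank)
  expect_equal(adaptiveBeta(co2, 0.05), 2 * b1, tolerance = 1e-12)
  zero <- fdbAnalyze(matrix(0, 32, 32), bank)
  expect_equal(adaptiveBeta(zero, 0.5), 0)
})

test_that("shrinkage never increases subband energy", {
  set.seed(80)
  img <- matrix(runif(32 * 32), 32, 32)
  params <- smallParams(pad = 0)
  bank <- dhbbFilterBank(c(32, 32), params)
  co <- fdbAnalyze(img, bank)
  for (C in c(0.01, 0.1, 0.9)) {
    beta <- adaptiveBeta(co, C)
    cot <- thresholdCoefficients(co, beta)
    for (l in seq_along(cot@c)) {
      expect_lte(sum(Mod(thresholded(cot)[[l]])^2),
                 sum(Mod(coefficients(cot)[[l]])^2))
      expect_true(all(Mod(thresholded(cot)[[l]]) <=
                        Mod(coefficients(cot)[[l]]) + 1e-14))
    }
  }
})

test_that("zero-threshold synthesis satisfies the closed-form spectrum
           identity", {
  set.seed(81)
  for (variant in c("bilinear", "original")) {
    img <- matrix(runif(24 * 24), 24, 24)
    params <- smallParams(pad = 0, variant = variant)
    bank <- dhbbFilterBank(c(24, 24), params)
    co <- thresholdCoefficients(fdbAnalyze(img, bank), 0)
    ft <- fdbSynthesize(co, bank)
    comp <- Reduce(`+`, lapply(bank@spectra,
                               function(s) fdbseg:::.reverseSpectrum(s) * s))
    expect_lt(max(Mod(stats::fft(ft) - stats::fft(img) * comp)), 1e-10)
  }
})

test_that("all-zero thresholded coefficients synthesize to zero and the
           full transform is deterministic", {
  fp <- smallFingerprint(shape = c(64, 64))
  params <- smallParams()
  bank <- dhbbFilterBank(c(80, 80), params)
  co <- fdbAnalyze(mirrorPad(fp$image, 8), bank)
  co@d <- lapply(co@c, function(m) m * 0)
  expect_equal(max(abs(fdbSynthesize(co, bank, pad = 8))), 0)
  # zero image in, zero feature image out
  expect_equal(max(abs(fdbFeatureImage(matrix(0, 64, 64), params))), 0)
  # bit-stability across runs
  f1 <- fdbFeatureImage(fp$image, params)
  f2 <- fdbFeatureImage(fp$image, params)
  expect_identical(f1, f2)
  expect_identical(dim(f1), dim(fp$image))
})

test_that("the feature image concentrates energy inside the true ROI", {
  fp <- smallFingerprint(shape = c(96, 96), wavelength = 8)
  ft <- fdbFeatureImage(fp$image, smallParams())
  ratio <- mean(abs(ft[fp$truth])) / mean(abs(ft[!fp$truth]))
  expect_gt(ratio, 5)
})

test_that("max/sum reconstructions reduce to the coefficients for a single
           subband and max splits signs correctly", {
  set.seed(82)
  img <- matrix(runif(24 * 24), 24, 24)
  params <- fdbParams(L = 1, pad = 0)
  bank <- dhbbFilterBank(c(24, 24), params)
  co <- fdbAnalyze(img, bank)
  re <- Re(coefficients(co)[[1]])
  expect_equal(synthesizeMax(co, bank), re)
  expect_equal(synthesizeSum(co, bank), re)
  # all-nonnegative coefficients: max operator is the elementwise maximum
  params4 <- fdbParams(L = 4, pad = 0)
  bank4 <- dhbbFilterBank(c(24, 24), params4)
  co4 <- fdbAnalyze(img, bank4)
  co4@c <- lapply(co4@c, function(m) abs(Re(m)) + 0i)
  expect_equal(synthesizeMax(co4, bank4),
               Reduce(pmax, lapply(co4@c, Re)))
  expect_error(synthesizeMax(co4, bank4, useShrinkage = TRUE), "threshold")
})
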