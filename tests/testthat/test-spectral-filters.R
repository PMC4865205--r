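# Butterworth bandpass, directional Hilbert spectra, and their composition.

test_that("1D Butterworth bandpass peaks at the geometric mean and dies at DC", {
  for (g in c(1, 2, 3, 4, 10)) {
    sp <- butterworthSpec(g, 0.3, 1)
    expect_equal(butterworth1d(peakFrequency(sp), sp), 1, tolerance = 1e-12)
    expect_identical(butterworth1d(0, sp), 0)
    expect_lt(butterworth1d(1e6, sp), 1e-6)
  }
  # frozen 50-digit reference evaluation of the closed form at omega = 0.5
  sp2 <- butterworthSpec(2, 0.3, 1)
  expect_equal(butterworth1d(0.5, sp2), 0.99958368026644462947543714,
               tolerance = 1e-14)
  # bounded in [0,1], even, and unimodal on (0, pi)
  w <- seq(1e-4, pi, length.out = 5000)
  b <- butterworth1d(w, sp2)
  expect_true(all(b >= 0 & b <= 1))
  expect_equal(butterworth1d(-w, sp2), b)
  signChanges <- sum(diff(sign(diff(b))) != 0)
  expect_identical(signChanges, 1L)   # single interior maximum
})

test_that("Butterworth roots enumerate the complex roots of -1", {
  expect_equal(butterworthRoots(1), -1 + 0i)
  expect_equal(butterworthRoots(2), exp(1i * pi * c(3, 5) / 4))
  set.seed(11)
  for (g in 1:6) {
    tk <- butterworthRoots(g)
    expect_equal(Mod(tk), rep(1, g))
    for (tt in complex(real = rnorm(3), imaginary = rnorm(3))) {
      lhs <- prod(tt^2 - tk^2)
      rhs <- tt^(2 * g) + (-1)^g
      expect_lt(Mod(lhs - rhs), 1e-8 * (1 + Mod(rhs)))
    }
  }
  expect_error(butterworthRoots(0), "gamma")
})

test_that("bilinear bandpass vanishes at DC, is unimodal, and matches the
           analog factorization under the bilinear substitution", {
  sp <- butterworthSpec(2, 0.3, 1)
  expect_equal(Mod(butterworthBilinear1d(0, sp)), 0)
  w <- seq(1e-3, pi - 1e-3, length.out = 4000)
  mag <- Mod(butterworthBilinear1d(w, sp))
  expect_identical(sum(diff(sign(diff(mag))) != 0), 1L)
  expect_lt(abs(w[which.max(mag)] - peakFrequency(sp)), 0.15)
  # product form == analog transfer function with jw -> 2(z-1)/(z+1)
  for (g in c(1, 2, 3)) {
    spg <- butterworthSpec(g, 0.3, 1)
    tk <- butterworthRoots(g)
    d <- bandwidth(spg); p2 <- 0.3
    wr <- c(0.2, 0.45, 0.9, 1.8, 2.9)
    jw <- 2 * (exp(1i * wr) - 1) / (exp(1i * wr) + 1)
    ref <- vapply(seq_along(wr), function(i)
      prod(d * jw[i] / (jw[i]^2 - d * tk * jw[i] + p2)), complex(1))
    expect_equal(butterworthBilinear1d(wr, spg), ref, tolerance = 1e-12)
  }
})

test_that("large-order Butterworth approaches the ideal brick-wall filter", {
  sp <- butterworthSpec(50, 0.3, 1)
  w <- seq(1e-3, pi, length.out = 20000)
  away <- abs(w - 0.3) > 0.05 & abs(w - 1) > 0.05
  dev <- abs(butterworth1d(w, sp) - butterworthIdeal1d(w, sp))
  expect_lt(max(dev[away]), 0.01)
})

test_that("the Cartesian indicator pair partitions every grid frequency", {
  g <- frequencyGrid(c(64, 64))
  a <- 64 / 2; b <- 64 / 2
  chiH <- b * abs(g@omega1) >= a * abs(g@omega2)
  chiV <- b * abs(g@omega1) < a * abs(g@omega2)   # ties already went to chiH
  expect_true(all(chiH + chiV == 1))
  # and the 2D spectrum equals the horizontal branch wherever chiH holds
  sp <- butterworthSpec(2, 0.3, 1, variant = "original")
  s2 <- butterworth2dSpectrum(g, sp)
  b1 <- butterworth1d(g@omega1, sp)
  b2 <- butterworth1d(g@omega2, sp)
  expect_equal(s2[chiH], b1[chiH])
  expect_equal(s2[!chiH], b2[!chiH])
  # the omega2 = 0 row is purely the horizontal response
  row0 <- g@omega2[, 1] == 0
  expect_equal(s2[row0, ], b1[row0, ])
})

test_that("directional Hilbert spectrum is a bounded direction cosine power", {
  g <- frequencyGrid(c(64, 64))
  L <- 16; n <- 20
  for (l in c(0, 3, 8, 15)) {
    h <- directionalHilbertSpectrum(g, l, L, n)
    expect_lte(max(Mod(h)), 1 + 1e-12)
    expect_identical(h[1, 1], 0 + 0i)          # DC
    expect_true(all(Im(h) == 0))               # even order => real
    ang <- atan2(g@omega2, g@omega1)
    off <- g@omega1 != 0 | g@omega2 != 0
    expect_equal(h[off], (0 - 1i)^n * cos(ang[off] - pi * l / L)^n + 0i,
                 tolerance = 1e-12)
  }
  # axis-aligned orientations attain |h| = 1 on the grid
  h0 <- directionalHilbertSpectrum(g, 0, L, n)
  expect_equal(max(Mod(h0)), 1)
  # frequencies perpendicular to the orientation respond with 0
  expect_equal(Mod(h0[g@omega1 == 0]), rep(0, 64))
  # quarter-turn-separated orientations are jointly zero along both axes
  h8 <- directionalHilbertSpectrum(g, 8, L, n)
  onAxes <- g@omega1 == 0 | g@omega2 == 0
  expect_equal(Mod(h0 * h8)[onAxes], rep(0, sum(onAxes)))
  expect_error(directionalHilbertSpectrum(g, 16, L, n), "l")
})

test_that("filter bank spectra vanish at DC, respect the bandpass envelope,
           and leave no orientation gap", {
  params <- fdbParams(L = 16, n = 20, gamma = 3, variant = "original")
  bank <- dhbbFilterBank(c(64, 64), params)
  expect_s4_class(bank, "FilterBank")
  expect_length(filterSpectra(bank), 16)
  g <- bank@grid
  env <- Mod(butterworth2dSpectrum(g, bank@butterworth))
  maxResp <- Reduce(pmax, lapply(filterSpectra(bank), Mod))
  for (s in filterSpectra(bank)) {
    expect_identical(s[1, 1], 0 + 0i)
    expect_true(all(Im(s) == 0))               # even n, original variant
    expect_true(all(Mod(s) <= env + 1e-12))
  }
  # worst orientation lies midway between two thetas: coverage bound
  expect_true(all(maxResp >= cos(pi / (2 * 16))^20 * env - 1e-12))
})

test_that("axis-aligned orientations are related by a quarter-turn of the grid", {
  params <- fdbParams(L = 4, n = 20, variant = "original")
  bank <- dhbbFilterBank(c(48, 48), params)
  phi0 <- filterSpectra(bank)[[1]]   # theta = 0
  phi2 <- filterSpectra(bank)[[3]]   # theta = pi/2
  expect_equal(phi0, t(phi2), tolerance = 1e-12)
})
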