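test_that("periodogram of an on-grid cosine concentrates A^2 T / 4", {
  e <- sineEpochs(freq = 10, Tn = 256, rate = 256, amp = 1)
  sp <- computeSpectrum(e)
  p <- periodogram(sp, 1)[1, ]
  k10 <- which(abs(trialFrequencies(sp, 1) - 10) < 1e-9)[1]
  expect_equal(p[k10], 256 / 4, tolerance = 1e-10)
  mirror <- 256 - (k10 - 1) + 1     # negative-frequency twin of the bin
  expect_lt(max(p[-c(k10, mirror)]), 1e-20)

  # all-zero trial -> identically zero periodogram
  z <- EpochSet("s1", list(matrix(0, 1, 64)), "Fz", 256)
  expect_true(all(periodogram(computeSpectrum(z), 1) == 0))
})

test_that("spectra match a brute-force DFT and satisfy Parseval", {
  set.seed(11)
  for (i in 1:10) {
    Tn <- sample(16:512, 1)
    e <- randomEpochs(nTrials = 1, M = 2, Tn = Tn, seed = 100 + i)
    sp <- computeSpectrum(e)
    p <- periodogram(sp, 1); h <- phaseSpectrum(sp, 1)
    for (m in 1:2) {
      x <- trialData(e, 1)[m, ]
      ref <- bruteDft(x)
      expect_equal(p[m, ], Mod(ref)^2 / Tn, tolerance = 1e-10)
      big <- Mod(ref) > 1e-6 * max(Mod(ref))
      dphi <- wrapPhase(h[m, big] - Arg(ref)[big])
      expect_lt(max(abs(dphi)), 1e-9)
      expect_equal(sum(p[m, ]), sum(x^2), tolerance = 1e-10)
    }
  }
})

test_that("PSD is invariant to circular shift; scaling acts as a^2 / none", {
  e <- randomEpochs(nTrials = 1, M = 2, Tn = 256, seed = 3)
  x <- trialData(e, 1)
  shifted <- EpochSet("s1", list(x[, c(41:256, 1:40)]), channelLabels(e),
                      256)
  psd1 <- bandAveragePsd(computeSpectrum(e))
  psd2 <- bandAveragePsd(computeSpectrum(shifted))
  expect_equal(psd1, psd2, tolerance = 1e-10)

  a <- 2.5
  es <- EpochSet("s1", list(a * x), channelLabels(e), 256)
  sps <- computeSpectrum(es)
  expect_equal(bandAveragePsd(sps), a^2 * psd1, tolerance = 1e-10)
  expect_equal(computePhd(sps), computePhd(computeSpectrum(e)),
               tolerance = 1e-12)
})

test_that("band averaging is the arithmetic mean over in-band bins", {
  e <- randomEpochs(nTrials = 1, M = 1, Tn = 256, seed = 9)
  sp <- computeSpectrum(e)
  p <- periodogram(sp, 1)[1, ]
  fr <- trialFrequencies(sp, 1)
  bands <- spectralBands()
  psd <- bandAveragePsd(sp, bands)
  pos <- 2:129
  for (f in seq_len(nrow(bands))) {
    idx <- pos[fr[pos] >= bands$low[f] & fr[pos] < bands$high[f]]
    expect_equal(psd[1, 1, f], mean(p[idx]), tolerance = 1e-12)
  }
  # half-open membership: a bin exactly at 8 Hz is alpha, not theta
  expect_true(8 %in% fr[pos[fr[pos] >= 8 & fr[pos] < 12]])
  expect_false(8 %in% fr[pos[fr[pos] >= 4 & fr[pos] < 8]])

  # alpha-dominated signal: alpha PSD dwarfs beta PSD
  es <- sineEpochs(10, 256, 256)
  psds <- bandAveragePsd(computeSpectrum(es))
  expect_gt(psds[1, 1, "alpha"] / psds[1, 1, "beta"], 100)

  # a band with no bins on the grid errors with band and trial names
  short <- EpochSet("s1", list(matrix(rnorm(8), 1)), "Fz", 256)
  expect_error(bandAveragePsd(computeSpectrum(short)),
               "delta.*trial 1")
})

test_that("PWD is an antisymmetric difference of band powers", {
  fs <- randomFeatureSet(nTrials = 3, M = 4, seed = 2)
  expect_equal(fs@pwd[2, 1, 3, 2], fs@psd[2, 1, 2] - fs@psd[2, 3, 2])
  expect_true(all(fs@pwd + aperm(fs@pwd, c(1, 3, 2, 4)) == 0))  # exact

  # identical signals on two channels -> PWD identically zero
  x <- matrix(rnorm(256), 1)
  e <- EpochSet("s1", list(rbind(x, x)), c("Fz", "Cz"), 256)
  fs2 <- computeFeatures(e)
  expect_true(all(abs(fs2@pwd) < 1e-12))
  expect_true(all(abs(fs2@phd) < 1e-12))
})

test_that("PHD equals the analytic phase lag of a delayed sinusoid", {
  # channel 2 delayed by a quarter cycle at an on-grid alpha frequency:
  # phase difference h1 - h2 = +pi/2 in a single-bin band
  e <- sineEpochs(freq = 10, Tn = 256, rate = 256, M = 2,
                  phase = c(0, -pi / 2))
  band10 <- data.frame(name = "alpha10", low = 9.5, high = 10.5)
  phd <- computePhd(computeSpectrum(e), band10)
  expect_equal(phd[1, 1, 2, 1], pi / 2, tolerance = 1e-6)
  expect_equal(phd[1, 2, 1, 1], -pi / 2, tolerance = 1e-6)
})

test_that("PHD is antisymmetric under the wrap convention", {
  fs <- randomFeatureSet(nTrials = 2, M = 5, seed = 21)
  expect_lt(max(abs(fs@phd + aperm(fs@phd, c(1, 3, 2, 4)))), 1e-12)
  # a channel against itself is identically zero
  for (m in 1:5) expect_true(all(fs@phd[, m, m, ] == 0))
  # wrapped differences stay bounded
  expect_true(all(abs(fs@phd) <= pi + 1e-12))
})

test_that("unwrapped phase differences reproduce literal subtraction", {
  e <- randomEpochs(nTrials = 1, M = 2, Tn = 256, seed = 5)
  sp <- computeSpectrum(e)
  band <- data.frame(name = "alpha", low = 8, high = 12)
  raw <- computePhd(sp, band, wrap = FALSE)
  h <- phaseSpectrum(sp, 1)
  fr <- trialFrequencies(sp, 1)
  idx <- (2:129)[fr[2:129] >= 8 & fr[2:129] < 12]
  expect_equal(raw[1, 1, 2, 1], mean(h[1, idx] - h[2, idx]),
               tolerance = 1e-12)
})
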