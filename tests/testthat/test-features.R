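mkSpec <- function(mag, f = resampleGrid()[seq_along(mag)],
                   ph = rep(0, length(mag))) {
  list(frequency = f, magnitudeDb = mag, phaseRad = ph)
}

test_that("peak location takes the global maximum, ties to low frequency", {
  pk <- locatePeak(mkSpec(c(-10, -2, -7)))
  expect_identical(pk$index, 2L)
  expect_identical(pk$peakMagnitude, -2)
  expect_identical(pk$peakFrequency, resampleGrid()[2])
  ## two equal maxima: the lower-frequency one wins
  tie <- locatePeak(mkSpec(c(-9, -2, -5, -2, -8)))
  expect_identical(tie$index, 2L)
  expect_error(locatePeak(mkSpec(rep(-3, 5))), "degenerate")
  ## the phase feature is read at the peak index
  pk2 <- locatePeak(mkSpec(c(-10, -2, -7), ph = c(0.1, 0.5, 0.9)))
  expect_identical(pk2$peakPhase, 0.5)
})

test_that("first-local-maximum alternative stops at the first peak", {
  m <- c(-10, -4, -6, -1, -8)
  expect_identical(locatePeak(mkSpec(m))$index, 4L)
  expect_identical(locatePeak(mkSpec(m), firstLocalMax = TRUE)$index, 2L)
})

test_that("-6 dB bandwidth of a parabolic peak matches the closed form", {
  f <- resampleGrid()
  f0 <- 6e5; a <- 6 / 5e4^2  # half-width 50 kHz at -6 dB
  spec <- mkSpec(-10 - a * (f - f0)^2, f)
  pk <- locatePeak(spec)
  bw <- bandwidthMinus6db(spec, pk$index)
  expect_equal(bw, 2 * sqrt(6 / a) / f0, tolerance = 1e-2)
})

test_that("a plateau exactly 6 dB down marks the crossing at its edge", {
  mag <- c(-16, -16, -10, -16, -16)
  spec <- mkSpec(mag)
  ## -16 is not strictly below -10 - 6; no crossing exists
  expect_true(is.na(bandwidthMinus6db(spec, 3L)))
  mag2 <- c(-16.0000001, -16, -10, -16, -16.0000001)
  bw2 <- bandwidthMinus6db(mkSpec(mag2), 3L)
  f <- resampleGrid()
  ## crossings collapse onto the plateau samples bracketing the peak
  expect_equal(bw2 * f[3], f[4] - f[2], tolerance = 1e-3)
})

test_that("peak and crossing extraction agree with the exhaustive oracle", {
  set.seed(88)
  for (i in 1:200) {
    spec <- randomSmoothSpectrum()
    pk <- locatePeak(spec)
    expect_identical(pk$index, oraclePeakIndex(spec$magnitudeDb))
    bw <- bandwidthMinus6db(spec, pk$index)
    ref <- oracleBandwidth(spec$frequency, spec$magnitudeDb, pk$index)
    if (is.na(ref)) {
      expect_true(is.na(bw))
    } else {
      expect_equal(as.numeric(bw), ref, tolerance = 1e-9)
    }
    ## determinism
    expect_identical(extractFeatures(spec), extractFeatures(spec))
  }
})

test_that("a constant dB offset shifts only the peak magnitude", {
  set.seed(12)
  spec <- randomSmoothSpectrum()
  shifted <- spec
  shifted$magnitudeDb <- spec$magnitudeDb + 12.5
  a <- extractFeatures(spec); b <- extractFeatures(shifted)
  expect_identical(b$peakFrequency, a$peakFrequency)
  expect_equal(b$normBandwidth, a$normBandwidth)
  expect_equal(b$peakMagnitude, a$peakMagnitude + 12.5)
})

test_that("drying widens the resonance monotonically (noiseless leaf)", {
  set.seed(31)
  tr <- sampleLeafTraits("L1")
  nz <- noiseConfig(0, 0)
  rwc <- seq(1.0, 0.55, by = -0.05)
  bw <- vapply(rwc, function(w) {
    cc <- concatenateBands(simulateMeasurement(tr, w, nz))
    extractFeatures(resampleSpectrum(cc, "linear"))$normBandwidth
  }, numeric(1))
  expect_true(all(diff(bw) > 0))  # bandwidth grows as rwc decreases
})

test_that("interpolated versions of one measurement agree on the peak", {
  set.seed(41)
  tr <- sampleLeafTraits("L2")
  cc <- concatenateBands(simulateMeasurement(tr, 0.85, noiseConfig(0, 0)))
  pf <- vapply(augmentSpectrum(cc), function(s)
    locatePeak(s)$peakFrequency, numeric(1))
  ## peaks are grid-quantized, so the spread across versions is a
  ## multiple of the 2.5 kHz step; two steps is the allowed envelope
  expect_lte(diff(range(pf)), 2 * 2.5e3)
})

test_that("one-sided peaks are flagged undefined and excluded downstream", {
  ## peak at the grid edge: no left crossing
  f <- resampleGrid()
  spec <- mkSpec(-(f - f[1]) / 5e4, f)
  pk <- locatePeak(spec)
  expect_identical(pk$index, 1L)
  bw <- bandwidthMinus6db(spec, pk$index)
  expect_true(is.na(bw))
  expect_identical(attr(bw, "side"), "left")
  ft <- extractFeatures(spec)
  expect_false(ft$defined)
})

test_that("the feature table carries annotations for every sample", {
  ft <- suppressMessages(featureTable(smallSpectra()))
  sp <- smallSpectra()
  expect_identical(nrow(ft), ncol(sp))
  expect_identical(ft$sample_id, colData(sp)$sample_id)
  ok <- ft$defined
  expect_true(all(is.finite(ft$norm_bandwidth[ok])))
  expect_true(all(ft$norm_bandwidth[ok] > 0))
  expect_true(all(ft$peak_frequency_hz >= 1e5 &
                  ft$peak_frequency_hz <= 1.6e6))
})
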