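mkBand <- function(id, f, mag, ph = rep(0, length(f))) {
  new("BandSpectrum", bandId = id, frequency = f, magnitudeDb = mag,
      phaseRad = ph)
}

test_that("the common grid spans 100 kHz-1.6 MHz in 2.5 kHz steps", {
  g <- resampleGrid()
  expect_length(g, 601L)
  expect_identical(g[1], 1e5)
  expect_identical(g[601], 1.6e6)
  expect_true(all(abs(diff(g) - 2.5e3) < 1e-9))
})

test_that("calibration subtraction is element-wise in both channels", {
  raw <- mkBand("low", c(0.2e6, 0.3e6), c(-3, -6), c(0.4, 0.1))
  cal <- mkBand("low", c(0.2e6, 0.3e6), c(-1, -1), c(0.1, 0.1))
  out <- applyCalibration(raw, cal)
  expect_equal(magnitudeDb(out), c(-2, -5))
  expect_equal(phaseRad(out), c(0.3, 0.0))
  expect_equal(magnitudeDb(applyCalibration(raw, raw)), c(0, 0))
  zero <- mkBand("low", c(0.2e6, 0.3e6), c(0, 0))
  expect_identical(magnitudeDb(applyCalibration(raw, zero)),
                   magnitudeDb(raw))
  bad <- mkBand("low", c(0.21e6, 0.3e6), c(-1, -1))
  expect_error(applyCalibration(raw, bad), "alignment")
})

test_that("band concatenation pools, sorts, merges and unwraps", {
  b1 <- mkBand("low", c(0.2e6, 0.35e6), c(-1, -4))
  b2 <- mkBand("mid", c(0.35e6, 0.4e6), c(-6, -7))
  b3 <- mkBand("high", c(0.6e6, 0.7e6), c(-8, -9))
  cc <- concatenateBands(list(b1, b2, b3))
  expect_equal(cc$frequency, c(0.2e6, 0.35e6, 0.4e6, 0.6e6, 0.7e6))
  expect_equal(cc$magnitudeDb[2], -5)  # mean of the shared 0.35 MHz point
  expect_true(all(diff(cc$frequency) > 0))
  ## order invariance
  cc2 <- concatenateBands(list(b3, b1, b2))
  expect_identical(cc, cc2)
  expect_error(concatenateBands(list(b1, b2)), "3 band")
  expect_error(concatenateBands(list(b1, b2, b2)), "distinct")
})

test_that("concatenating a simulated measurement merges only exact duplicates", {
  ds <- smallDataset()
  meas <- leafRecords(ds)[[1]]@measurements[[1]]
  pooled <- unlist(lapply(meas$bands, frequencies))
  nDup <- sum(duplicated(pooled))
  cc <- concatenateBands(meas$bands)
  expect_length(cc$frequency, 81 + 121 + 111 - nDup)
  expect_gte(nDup, 1L)  # at least the shared 0.35 MHz edge
})

test_that("inter-band phase offsets of 2*pi are removed before resampling", {
  b1 <- mkBand("low", c(0.2e6, 0.3e6), c(-1, -2), c(-3.0, -3.1))
  b2 <- mkBand("mid", c(0.4e6, 0.5e6), c(-3, -4), c(3.05, 2.9))
  b3 <- mkBand("high", c(0.6e6, 0.7e6), c(-5, -6), c(2.7, 2.6))
  cc <- concatenateBands(list(b1, b2, b3))
  expect_true(all(abs(diff(cc$phaseRad)) < pi))
})

.toyConcat <- function() {
  ## knots on the output grid (multiples of 2.5 kHz), spanning the
  ## full instrument range
  f <- seq(0.15e6, 1.6e6, by = 0.025e6)
  list(frequency = f,
       magnitudeDb = -20 + 15 * exp(-((f - 4e5) / 1.5e5)^2),
       phaseRad = -f / 4e5)
}

test_that("resampling yields 601 values and honours knots", {
  spec <- .toyConcat()
  for (m in interpolationMethods()) {
    rs <- resampleSpectrum(spec, m)
    expect_length(rs$magnitudeDb, 601L)
    expect_length(rs$phaseRad, 601L)
    expect_identical(rs$frequency, resampleGrid())
    expect_identical(rs$method, m)
    ## every source knot lies on the output grid: all methods must
    ## reproduce the knot values there
    at <- match(spec$frequency, rs$frequency)
    expect_true(all(abs(rs$magnitudeDb[at] - spec$magnitudeDb) < 1e-9),
                info = m)
  }
  expect_error(resampleSpectrum(spec, "quintic"), "configuration error")
})

test_that("linear resampling interpolates mid-segment values exactly", {
  spec <- .toyConcat()
  spec$magnitudeDb[spec$frequency == 0.2e6] <- 0
  spec$magnitudeDb[spec$frequency == 0.3e6] <- -10
  ## remove the knot between them so 0.25 MHz sits mid-segment
  keep <- spec$frequency != 0.225e6 & spec$frequency != 0.25e6 &
    spec$frequency != 0.275e6
  spec <- lapply(spec, `[`, keep)
  rs <- resampleSpectrum(spec, "linear")
  expect_equal(rs$magnitudeDb[rs$frequency == 0.25e6], -5)
})

test_that("values below the measured support are held, not extrapolated", {
  spec <- .toyConcat()
  for (m in interpolationMethods()) {
    rs <- resampleSpectrum(spec, m)
    low <- rs$frequency < 0.15e6
    expect_true(all(abs(rs$magnitudeDb[low] - spec$magnitudeDb[1]) < 1e-9),
                info = m)
  }
})

test_that("narrow or sparse inputs are rejected", {
  f <- seq(0.4e6, 1.0e6, by = 0.1e6)
  spec <- list(frequency = f, magnitudeDb = -f / 1e5, phaseRad = f * 0)
  expect_error(resampleSpectrum(spec), "data-quality")
  few <- lapply(.toyConcat(), `[`, 1:3)
  expect_error(resampleSpectrum(few), "at least 4")
})

test_that("augmentation produces one tagged version per method", {
  aug <- augmentSpectrum(.toyConcat())
  expect_named(aug, interpolationMethods())
  expect_length(aug, 7L)
  grids <- lapply(aug, `[[`, "frequency")
  for (g in grids) expect_identical(g, grids[[1]])  # grid immutability
  ## versions agree wherever a knot lies on the grid
  at <- match(.toyConcat()$frequency, resampleGrid())
  for (m in c("linear", "cubic", "splines", "akima"))
    expect_equal(aug[[m]]$magnitudeDb[at], aug$linear$magnitudeDb[at],
                 tolerance = 1e-9)
})

test_that("a dataset assembles into the two-channel container", {
  sp <- smallSpectra()
  ds <- smallDataset()
  nMeas <- sum(vapply(leafRecords(ds), function(r)
    length(r@measurements), integer(1)))
  expect_s4_class(sp, "RusSpectra")
  expect_identical(dim(sp), c(601L, nMeas * 7L))
  expect_setequal(unique(colData(sp)$method), interpolationMethods())
  expect_identical(rowData(sp)$frequency_hz, resampleGrid())
})
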