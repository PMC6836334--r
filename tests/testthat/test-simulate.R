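test_that("RWC follows the mass-ratio definition without clamping", {
  expect_equal(computeRwc(2.0, tm = 3.0, dm = 1.0), 0.5)
  expect_equal(computeRwc(3.0, tm = 3.0, dm = 1.0), 1.0)   # fm = TM
  expect_equal(computeRwc(1.0, tm = 3.0, dm = 1.0), 0.0)   # fm = DM
  expect_error(computeRwc(2, tm = 1, dm = 1), "turgid mass")
  expect_error(computeRwc(-1, tm = 3, dm = 1), "positive")
  expect_warning(r <- computeRwc(3.5, tm = 3, dm = 1), "artifact")
  expect_equal(r, 1.25)  # reported, not clamped
})

test_that("impedance-matched lossless plate is transparent", {
  f <- seq(1.5e5, 1.6e6, by = 1e4)
  tr <- plateTransmission(f, thickness = 4e-4, speed = 415, density = 1,
                          attenuation = 0)  # rho*c = Z_air
  expect_true(all(abs(tr$magnitudeDb) < 1e-9))
})

test_that("lossless plate transmits fully at thickness resonances", {
  h <- 4.2e-4; cc <- 320; rho <- 900
  for (n in 1:3) {
    tr <- plateTransmission(n * cc / (2 * h), h, cc, rho, attenuation = 0)
    expect_lt(abs(tr$magnitudeDb), 1e-9)
  }
})

test_that("transmitted amplitude never exceeds unity", {
  set.seed(404)
  f <- seq(1e5, 1.6e6, length.out = 60)
  for (i in 1:200) {
    tr <- plateTransmission(f,
      thickness = runif(1, 1e-4, 1e-3), speed = runif(1, 50, 1500),
      density = runif(1, 100, 1500), attenuation = runif(1, 0, 3000))
    expect_true(all(tr$magnitudeDb <= 1e-9))
  }
  expect_error(plateTransmission(f, 4e-4, 300, 800, 100,
                                 mediumImpedance = 0), "impedance")
})

test_that("lossy plate peaks at the first thickness resonance", {
  ## brute-force evaluation of the closed form on a 100 Hz grid
  f <- seq(1e5, 1.6e6, by = 100)
  tr <- plateTransmission(f, thickness = 3e-4, speed = 300, density = 800,
                          attenuation = 200)
  expect_lt(abs(f[which.max(tr$magnitudeDb)] - 5e5), 100 + 1e-9)
})

test_that("leaf state interpolates exactly between its endpoints", {
  set.seed(7)
  tr <- sampleLeafTraits("L1")
  atTurgid <- traitsAtRwc(tr, 1)
  expect_identical(atTurgid$thickness, tr@thicknessTurgid)
  expect_identical(atTurgid$speed, tr@speedTurgid)
  expect_identical(atTurgid$density, tr@densityTurgid)
  expect_identical(atTurgid$attenuation, tr@attenuationTurgid)
  atDry <- rusleaf:::.stateAtRwc(tr, 0)
  expect_identical(atDry$thickness, tr@thicknessDry)
  expect_identical(atDry$speed, tr@speedDry)
  expect_error(traitsAtRwc(tr, 0), "rwc")
  expect_error(traitsAtRwc(tr, 1.2), "rwc")
})

test_that("first-resonance frequency is strictly monotone in RWC", {
  set.seed(11)
  grid <- seq(0.5, 1.0, by = 0.025)
  for (i in 1:20) {
    tr <- sampleLeafTraits(paste0("L", i))
    f1 <- vapply(grid, function(w) {
      st <- traitsAtRwc(tr, w)
      st$speed / (2 * st$thickness)
    }, numeric(1))
    expect_true(all(diff(f1) > 0))
  }
})

test_that("measurement noise model behaves as configured", {
  set.seed(21)
  tr <- sampleLeafTraits("L1")
  grids <- bandGrids()
  ## zero noise reproduces the forward model on the band grids exactly
  clean <- simulateMeasurement(tr, 0.9, noiseConfig(0, 0))
  st <- traitsAtRwc(tr, 0.9)
  for (b in clean) {
    ref <- plateTransmission(frequencies(b), st$thickness, st$speed,
                             st$density, st$attenuation)
    expect_identical(magnitudeDb(b), ref$magnitudeDb)
    expect_identical(phaseRad(b), ref$phaseRad)
  }
  ## identical RNG state gives identical spectra
  set.seed(33); a <- simulateMeasurement(tr, 0.8)
  set.seed(33); b <- simulateMeasurement(tr, 0.8)
  expect_identical(lapply(a, magnitudeDb), lapply(b, magnitudeDb))
  ## Monte-Carlo estimate of the per-point magnitude noise sd
  cleanMid <- magnitudeDb(clean[[2]])
  reps <- replicate(100, {
    m <- simulateMeasurement(tr, 0.9)
    magnitudeDb(m[[2]]) - cleanMid
  })
  f <- frequencies(clean[[2]])
  span <- range(f)  # keep clear of the edge-inflated outer 10%
  interior <- which(f > span[1] + 0.12 * diff(span) &
                    f < span[2] - 0.12 * diff(span))
  sds <- apply(reps[interior, ], 1, sd)
  expect_lt(abs(mean(sds) - 0.5), 0.1)  # within 20% of the configured value
})

test_that("band grids cover the nominal ranges with shared edges", {
  g <- bandGrids()
  expect_identical(lengths(g), c(low = 81L, mid = 121L, high = 111L))
  expect_identical(g$low[81], g$mid[1])  # exact 0.35 MHz shared point
  expect_true(all(vapply(g, function(x) all(diff(x) > 0), logical(1))))
})

test_that("a simulated drying experiment has the documented structure", {
  ds <- smallDataset()
  expect_s4_class(ds, "RusDataset")
  expect_length(ds, 4L)
  for (rec in leafRecords(ds)) {
    rwc <- rwcValues(rec)
    expect_true(all(diff(rwc) < 0))  # drying order
    for (m in rec@measurements) {
      expect_equal(computeRwc(m$freshMass, rec@turgidMass, rec@dryMass),
                   m$rwc, tolerance = 1e-12)
      expect_setequal(vapply(m$bands, bandId, character(1)),
                      c("low", "mid", "high"))
    }
  }
  expect_error(simulateDataset(1), "at least 2")
  expect_error(simulateDataset(4, rwcMixture = list(pAbove = .6, tlp = .9,
                                                    lower = .95)),
               "configuration error")
})

test_that("RWC draws match the drying-experiment mixture", {
  set.seed(1234)
  x <- sampleRwc(10000)
  frac <- mean(x >= 0.88 & x <= 1)
  expect_gte(frac, 0.60)
  expect_lte(frac, 0.66)
  expect_true(all(x >= 0.52 & x <= 1))
})

test_that("identical seeds give byte-identical datasets", {
  a <- serialize(simulateDataset(3, seed = 55), NULL)
  b <- serialize(simulateDataset(3, seed = 55), NULL)
  expect_identical(a, b)
  c <- serialize(simulateDataset(3, seed = 56), NULL)
  expect_false(identical(a, c))
})
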