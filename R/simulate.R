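#' @useDynLib rusleaf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm approx spline splinefun cor lm coef
#'   t.test aov TukeyHSD pairwise.t.test sd predict
NULL

## characteristic acoustic impedance of air, Pa s/m
.AIR_IMPEDANCE <- 415

## reference frequency for the attenuation coefficient, Hz
.ATT_REF_FREQ <- 1e6

#' Relative water content from the three reference masses
#'
#' RWC = (FM - DM) / (TM - DM): the leaf's water mass relative to the
#' water it holds at full turgor. 1 means fully turgid, 0 oven-dry.
#' No clamping is applied; values slightly outside \[0, 1\] occur with
#' real balances and are flagged with a warning when they fall outside
#' \[-0.02, 1.05\].
#'
#' @param fm fresh mass in g, measured at the hydration state of
#'   interest.
#' @param tm turgid mass in g (start of the drying experiment).
#' @param dm oven-dry mass in g.
#' @return dimensionless RWC (vectorized over `fm`).
#' @examples
#' computeRwc(2.0, tm = 3.0, dm = 1.0)  # 0.5
#' @export
computeRwc <- function(fm, tm, dm) {
  if (any(tm <= dm))
    stop("invalid annotation: turgid mass must exceed dry mass")
  if (any(fm <= 0))
    stop("fresh mass must be positive")
  rwc <- (fm - dm) / (tm - dm)
  if (any(rwc < -0.02 | rwc > 1.05))
    warning("RWC outside [-0.02, 1.05]: possible measurement artifact")
  rwc
}

#' Normal-incidence transmission through a lossy plate
#'
#' Forward model behind the synthetic spectra: a homogeneous
#' visco-elastic plate of thickness `h` immersed in air, insonified at
#' normal incidence. With impedance ratio `z = rho*c / Z_air` and
#' complex wavenumber `k = 2*pi*f/c - i*alpha(f)` (the `e^{-ikx}`
#' wave convention, so absorption decays),
#' `alpha(f) = attenuation * f / 1 MHz`, the pressure transmission
#' coefficient is
#' `T(f) = 1 / (cos(k h) + (i/2) (z + 1/z) sin(k h))`.
#' Thickness resonances sit at `f_n = n c / (2 h)`, where a lossless
#' plate is fully transparent; `|T| <= 1` always (a matched lossy
#' plate transmits exactly `exp(-alpha h)`).
#'
#' @param frequency positive ascending frequencies in Hz.
#' @param thickness plate thickness in m.
#' @param speed sound speed in the plate in m/s.
#' @param density plate density in kg/m^3.
#' @param attenuation attenuation in Np/m at 1 MHz (scales linearly
#'   with frequency).
#' @param mediumImpedance impedance of the surrounding medium in
#'   Pa s/m; defaults to air (415).
#' @return list with `magnitudeDb` (20 log10 |T|) and `phaseRad`
#'   (arg T, unwrapped along the frequency axis).
#' @export
plateTransmission <- function(frequency, thickness, speed, density,
                              attenuation, mediumImpedance = .AIR_IMPEDANCE) {
  if (mediumImpedance <= 0)
    stop("medium impedance must be positive")
  stopifnot(all(frequency > 0), !is.unsorted(frequency),
            thickness > 0, speed > 0, density > 0, attenuation >= 0)
  z <- (density * speed) / mediumImpedance
  ## sign convention: waves carry e^{-i k x}, so absorption enters as a
  ## negative imaginary wavenumber; a matched lossy plate then
  ## transmits |T| = exp(-alpha h) <= 1 (passivity)
  k <- 2 * pi * frequency / speed -
    1i * attenuation * (frequency / .ATT_REF_FREQ)
  kh <- k * thickness
  tr <- 1 / (cos(kh) + (1i / 2) * (z + 1 / z) * sin(kh))
  list(
    magnitudeDb = 20 * log10(Mod(tr)),
    phaseRad = as.numeric(signal::unwrap(Arg(tr)))
  )
}

## leaf state (thickness, speed, density, attenuation) at a given RWC:
## linear interpolation between the dry (rwc = 0) and turgid (rwc = 1)
## trait endpoints
.stateAtRwc <- function(traits, rwc) {
  lerp <- function(dry, turgid) dry + rwc * (turgid - dry)
  list(
    thickness = lerp(traits@thicknessDry, traits@thicknessTurgid),
    speed = lerp(traits@speedDry, traits@speedTurgid),
    density = lerp(traits@densityDry, traits@densityTurgid),
    attenuation = lerp(traits@attenuationDry, traits@attenuationTurgid),
    rwc = rwc
  )
}

#' Leaf acoustic state at a given hydration level
#'
#' Interpolates thickness, sound speed, density and attenuation
#' linearly between the dry (RWC = 0) and turgid (RWC = 1) endpoints
#' of a [LeafTraits-class] object. Because the turgid-to-dry relative
#' drop in sound speed exceeds the drop in thickness under the default
#' priors, the first thickness-resonance frequency
#' `f1 = speed / (2 thickness)` is strictly increasing in RWC: drying
#' shifts the resonance down and (via rising attenuation) damps it,
#' the phenomenology the feature set exploits.
#'
#' @param traits a [LeafTraits-class] object.
#' @param rwc hydration level in (0, 1.02].
#' @return list with `thickness` (m), `speed` (m/s), `density`
#'   (kg/m^3), `attenuation` (Np/m at 1 MHz) and `rwc`.
#' @export
traitsAtRwc <- function(traits, rwc) {
  stopifnot(is(traits, "LeafTraits"))
  if (any(rwc <= 0 | rwc > 1.02))
    stop("rwc must lie in (0, 1.02]")
  .stateAtRwc(traits, rwc)
}

#' Trait priors of the synthetic leaf population
#'
#' Uniform priors over the acoustic and gravimetric endpoints of a
#' leaf population from one species of mature evergreen leaves
#' (Viburnum-like, hence deliberately narrow across leaves): turgid
#' thickness 420--480 um shrinking to 75--85% when dry, turgid sound
#' speed 310--350 m/s dropping to 18--28% (the loss of turgor
#' strongly softens the tissue, which is what moves the thickness
#' resonance down as the leaf dries), density 880--960 kg/m^3,
#' attenuation 450--650 Np/m at 1 MHz rising by a factor 2.5--3.5 on
#' drying (damping grows), dry mass 0.2--0.5 g with turgid/dry mass
#' ratio 2.2--3.2. Under these ranges the first thickness resonance
#' stays within the 0.15--1.6 MHz instrument window for all RWC in
#' \[0.5, 1\], is strictly increasing in RWC for every draw, and
#' shifts by roughly 25--35% between full turgor and the driest
#' measured states while the across-leaf spread at equal hydration
#' stays smaller than that shift.
#'
#' @return named list of `c(min, max)` ranges.
#' @export
traitPriors <- function() {
  list(
    thicknessTurgid = c(420e-6, 480e-6),
    thicknessDryFrac = c(0.75, 0.85),
    speedTurgid = c(310, 350),
    speedDryFrac = c(0.18, 0.28),
    densityTurgid = c(880, 960),
    densityDryFrac = c(0.45, 0.55),
    attenuationTurgid = c(450, 650),
    attenuationDryFactor = c(2.5, 3.5),
    dryMass = c(0.2, 0.5),
    turgidMassFactor = c(2.2, 3.2)
  )
}

#' Draw one leaf's traits from the population priors
#'
#' @param leafId identifier for the new leaf.
#' @param priors prior ranges, see [traitPriors()].
#' @return a [LeafTraits-class] object. Uses the current R RNG state.
#' @export
sampleLeafTraits <- function(leafId, priors = traitPriors()) {
  u <- function(nm) runif(1, priors[[nm]][1], priors[[nm]][2])
  hT <- u("thicknessTurgid")
  cT <- u("speedTurgid")
  dT <- u("densityTurgid")
  aT <- u("attenuationTurgid")
  dm <- u("dryMass")
  new("LeafTraits",
    leafId = as.character(leafId),
    thicknessTurgid = hT, thicknessDry = hT * u("thicknessDryFrac"),
    speedTurgid = cT, speedDry = cT * u("speedDryFrac"),
    densityTurgid = dT, densityDry = dT * u("densityDryFrac"),
    attenuationTurgid = aT, attenuationDry = aT * u("attenuationDryFactor"),
    dryMass = dm, turgidMass = dm * u("turgidMassFactor")
  )
}

#' Native frequency grids of the three transducer bands
#'
#' Log-uniform grids of 81, 121 and 111 points over the nominal band
#' ranges 0.15--0.35, 0.35--0.95 and 0.5--1.6 MHz. Endpoints are set
#' exactly, so the shared 0.35 MHz point of the low and mid bands is
#' bit-identical and merges during concatenation.
#'
#' @return named list of frequency vectors (Hz).
#' @export
bandGrids <- function() {
  mk <- function(rng, n) {
    g <- exp(seq(log(rng[1]), log(rng[2]), length.out = n))
    g[1] <- rng[1]; g[n] <- rng[2]
    g
  }
  list(
    low  = mk(.BAND_RANGES$low, 81L),
    mid  = mk(.BAND_RANGES$mid, 121L),
    high = mk(.BAND_RANGES$high, 111L)
  )
}

#' Acquisition-noise configuration
#'
#' Additive Gaussian noise on the calibrated spectra: standard
#' deviation `magnitudeSd` dB on magnitude and `phaseSd` rad on phase,
#' multiplied by `edgeFactor` over the outer `edgeFraction` of each
#' band's frequency span to mimic transducer sensitivity roll-off.
#'
#' @param magnitudeSd,phaseSd,edgeFraction,edgeFactor see description.
#' @return configuration list.
#' @export
noiseConfig <- function(magnitudeSd = 0.5, phaseSd = 0.05,
                        edgeFraction = 0.1, edgeFactor = 2) {
  stopifnot(magnitudeSd >= 0, phaseSd >= 0,
            edgeFraction >= 0, edgeFraction < 0.5, edgeFactor >= 1)
  list(magnitudeSd = magnitudeSd, phaseSd = phaseSd,
       edgeFraction = edgeFraction, edgeFactor = edgeFactor)
}

#' Simulate the three-band NC-RUS measurement of one leaf state
#'
#' Evaluates [plateTransmission()] at the interpolated leaf state on
#' each band's native grid and adds band-edge-inflated Gaussian noise.
#' With all noise standard deviations zero the output equals the
#' forward model restricted to the band grids.
#'
#' @param traits a [LeafTraits-class] object.
#' @param rwc hydration level of the measurement.
#' @param noise a [noiseConfig()] list.
#' @param grids band frequency grids, see [bandGrids()].
#' @return list of three [BandSpectrum-class] objects (low, mid,
#'   high). Uses the current R RNG state.
#' @export
simulateMeasurement <- function(traits, rwc, noise = noiseConfig(),
                                grids = bandGrids()) {
  st <- traitsAtRwc(traits, rwc)
  lapply(names(grids), function(bid) {
    f <- grids[[bid]]
    tr <- plateTransmission(f, st$thickness, st$speed, st$density,
                            st$attenuation)
    span <- range(f)
    edge <- f < span[1] + noise$edgeFraction * diff(span) |
            f > span[2] - noise$edgeFraction * diff(span)
    fac <- ifelse(edge, noise$edgeFactor, 1)
    new("BandSpectrum",
      bandId = bid,
      frequency = f,
      magnitudeDb = tr$magnitudeDb + rnorm(length(f), 0, noise$magnitudeSd) * fac,
      phaseRad = tr$phaseRad + rnorm(length(f), 0, noise$phaseSd) * fac
    )
  })
}

#' Draw RWC values from the drying-experiment mixture
#'
#' Two-component uniform mixture matching the hydration coverage of a
#' bench drying experiment: probability `pAbove` (default 0.63) of
#' falling in \[0.88, 1\] (above the turgor loss point) and the rest
#' uniform on \[0.52, 0.88).
#'
#' @param n number of draws.
#' @param pAbove mixture mass above the turgor loss point.
#' @param tlp range boundary (default 0.88).
#' @param lower lowest RWC reached by drying (default 0.52).
#' @return numeric vector of RWC values. Uses the current R RNG state.
#' @export
sampleRwc <- function(n, pAbove = 0.63, tlp = 0.88, lower = 0.52) {
  stopifnot(n >= 0, pAbove > 0, pAbove < 1, lower < tlp, tlp < 1)
  above <- runif(n) < pAbove
  ifelse(above, runif(n, tlp, 1), runif(n, lower, tlp))
}

#' Simulate a complete annotated drying experiment
#'
#' Generates `nLeaves` leaves with traits drawn from [traitPriors()],
#' a per-leaf number of drying states drawn from \{8, 9, 10\} with
#' probabilities (0.300, 0.368, 0.332) and minimally adjusted so the
#' total is exactly `round(nLeaves * 280/31)` — 280 paired
#' measurements for the default 31 leaves, RWC values from
#' [sampleRwc()] sorted in drying (descending) order, fresh masses
#' back-computed as `FM = DM + rwc * (TM - DM)` so [computeRwc()]
#' round-trips exactly, and noisy three-band spectra from
#' [simulateMeasurement()]. Fully determined by `seed`.
#'
#' @param nLeaves number of leaves (>= 2), default 31.
#' @param seed integer master seed.
#' @param noise a [noiseConfig()] list.
#' @param priors trait priors, see [traitPriors()].
#' @param measurementsPerLeaf optional fixed number of states per leaf
#'   (overrides the \{8, 9, 10\} draw).
#' @param rwcMixture list with `pAbove`, `tlp`, `lower` passed to
#'   [sampleRwc()].
#' @return a [RusDataset-class].
#' @export
simulateDataset <- function(nLeaves = 31L, seed = 1L,
                            noise = noiseConfig(),
                            priors = traitPriors(),
                            measurementsPerLeaf = NULL,
                            rwcMixture = list(pAbove = 0.63, tlp = 0.88,
                                              lower = 0.52)) {
  if (nLeaves < 2) stop("configuration error: need at least 2 leaves")
  if (!is.null(measurementsPerLeaf) && measurementsPerLeaf < 1)
    stop("configuration error: measurementsPerLeaf must be >= 1")
  if (rwcMixture$lower >= rwcMixture$tlp || rwcMixture$tlp >= 1)
    stop("configuration error: infeasible RWC mixture ranges")
  seed <- as.integer(seed)
  records <- .withSeed(seed, {
    grids <- bandGrids()
    counts <- if (is.null(measurementsPerLeaf)) {
      ## around nine drying states per leaf; the per-leaf counts are
      ## drawn from {8, 9, 10} and then minimally adjusted so the
      ## realized total equals round(nLeaves * 280/31) -- 280 paired
      ## measurements for the default 31 leaves
      cnt <- sample(8:10, nLeaves, replace = TRUE,
                    prob = c(0.300, 0.368, 0.332))
      target <- round(nLeaves * 280 / 31)
      while (sum(cnt) != target) {
        i <- sample.int(nLeaves, 1)
        if (sum(cnt) > target && cnt[i] > 8L) cnt[i] <- cnt[i] - 1L
        if (sum(cnt) < target && cnt[i] < 10L) cnt[i] <- cnt[i] + 1L
      }
      cnt
    } else rep(as.integer(measurementsPerLeaf), nLeaves)
    lapply(seq_len(nLeaves), function(i) {
      traits <- sampleLeafTraits(sprintf("leaf%02d", i), priors)
      nMeas <- counts[i]
      rwc <- sort(sampleRwc(nMeas, rwcMixture$pAbove, rwcMixture$tlp,
                            rwcMixture$lower), decreasing = TRUE)
      tm <- traits@turgidMass; dm <- traits@dryMass
      meas <- lapply(rwc, function(w) {
        list(
          freshMass = dm + w * (tm - dm),
          rwc = w,
          bands = simulateMeasurement(traits, w, noise, grids)
        )
      })
      new("LeafRecord", leafId = leafId(traits), turgidMass = tm,
          dryMass = dm, measurements = meas)
    })
  })
  cfg <- list(nLeaves = nLeaves, noise = noise, priors = priors,
              measurementsPerLeaf = measurementsPerLeaf,
              rwcMixture = rwcMixture)
  new("RusDataset", records = records, config = cfg, seed = seed)
}

## evaluate expr under a temporary RNG seed, restoring the caller's state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## derive a stage-specific child seed from a master seed by hashing the
## stage name (single-knob reproducibility; stays below 2^31)
deriveSeed <- function(seed, stage) {
  v <- as.numeric(utf8ToInt(stage))
  h <- sum(v * seq_along(v) * 1103) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
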