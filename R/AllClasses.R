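#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

.BAND_RANGES <- list(
  low  = c(0.15e6, 0.35e6),
  mid  = c(0.35e6, 0.95e6),
  high = c(0.50e6, 1.60e6)
)

#' BandSpectrum: one transducer band of a transmission coefficient
#'
#' Holds the calibrated transmission coefficient sampled over one
#' air-coupled transducer band: magnitude in dB (referenced to the
#' through-air calibration, so values are non-positive up to noise) and
#' unwrapped phase in radians. The three nominal bands are
#' `low` (0.15--0.35 MHz), `mid` (0.35--0.95 MHz) and `high`
#' (0.50--1.60 MHz).
#'
#' @slot bandId one of `"low"`, `"mid"`, `"high"`.
#' @slot frequency strictly increasing frequencies in Hz, inside the
#'   band's nominal range.
#' @slot magnitudeDb transmission magnitude in dB.
#' @slot phaseRad unwrapped transmission phase in radians.
#' @export
setClass("BandSpectrum",
  representation(
    bandId = "character",
    frequency = "numeric",
    magnitudeDb = "numeric",
    phaseRad = "numeric"
  )
)

setValidity("BandSpectrum", function(object) {
  msg <- character()
  if (length(object@bandId) != 1L || !object@bandId %in% names(.BAND_RANGES))
    msg <- c(msg, "bandId must be one of 'low', 'mid', 'high'")
  n <- length(object@frequency)
  if (n < 2L)
    msg <- c(msg, "at least 2 frequency points required")
  if (length(object@magnitudeDb) != n || length(object@phaseRad) != n)
    msg <- c(msg, "frequency, magnitudeDb, phaseRad must have equal length")
  if (n >= 2L && any(diff(object@frequency) <= 0))
    msg <- c(msg, "frequencies must be strictly increasing")
  if (length(object@bandId) == 1L && object@bandId %in% names(.BAND_RANGES)) {
    rng <- .BAND_RANGES[[object@bandId]]
    if (n > 0L && (min(object@frequency) < rng[1] - 1e-6 ||
                   max(object@frequency) > rng[2] + 1e-6))
      msg <- c(msg, sprintf("frequencies outside nominal %s band", object@bandId))
  }
  if (length(msg)) msg else TRUE
})

#' LeafTraits: acoustic and gravimetric endpoints of one leaf
#'
#' Effective single-layer acoustic properties of a leaf at its two
#' hydration endpoints (fully turgid, RWC = 1; oven-dry, RWC = 0),
#' plus the reference masses used for RWC annotation. Intermediate
#' hydration states are obtained by [traitsAtRwc()].
#'
#' @slot leafId leaf identifier.
#' @slot thicknessTurgid,thicknessDry plate thickness in m.
#' @slot speedTurgid,speedDry longitudinal sound speed in m/s.
#' @slot densityTurgid,densityDry volumetric density in kg/m^3.
#' @slot attenuationTurgid,attenuationDry attenuation in Np/m at the
#'   1 MHz reference frequency (dry exceeds turgid: drying damps the
#'   thickness resonance).
#' @slot turgidMass,dryMass reference masses in g (TM, DM).
#' @export
setClass("LeafTraits",
  representation(
    leafId = "character",
    thicknessTurgid = "numeric", thicknessDry = "numeric",
    speedTurgid = "numeric", speedDry = "numeric",
    densityTurgid = "numeric", densityDry = "numeric",
    attenuationTurgid = "numeric", attenuationDry = "numeric",
    turgidMass = "numeric", dryMass = "numeric"
  )
)

setValidity("LeafTraits", function(object) {
  msg <- character()
  vals <- c(object@thicknessTurgid, object@thicknessDry,
            object@speedTurgid, object@speedDry,
            object@densityTurgid, object@densityDry,
            object@attenuationTurgid, object@attenuationDry,
            object@turgidMass, object@dryMass)
  if (length(vals) != 10L || any(!is.finite(vals)) || any(vals <= 0))
    msg <- c(msg, "all trait quantities must be finite, positive scalars")
  else {
    if (object@thicknessDry >= object@thicknessTurgid)
      msg <- c(msg, "thicknessDry must be < thicknessTurgid")
    if (object@dryMass >= object@turgidMass)
      msg <- c(msg, "dryMass must be < turgidMass")
    if (object@attenuationDry <= object@attenuationTurgid)
      msg <- c(msg, "attenuationDry must exceed attenuationTurgid")
    ## first thickness resonance must stay observable across drying
    for (w in c(0.5, 0.75, 1.0)) {
      st <- .stateAtRwc(object, w)
      f1 <- st$speed / (2 * st$thickness)
      if (f1 < 0.15e6 || f1 > 1.6e6)
        msg <- c(msg, sprintf(
          "first resonance %.0f kHz at RWC %.2f outside [150, 1600] kHz",
          f1 / 1e3, w))
    }
  }
  if (length(msg)) msg else TRUE
})

#' LeafRecord: one leaf's annotated drying trajectory
#'
#' A leaf identity with its turgid and dry reference masses and the
#' ordered sequence of measurements taken while the leaf dried. Each
#' measurement carries the fresh mass FM, the annotated
#' RWC = (FM - DM)/(TM - DM), and the three [BandSpectrum-class]
#' objects recorded by the three transducer pairs.
#'
#' @slot leafId leaf identifier.
#' @slot turgidMass,dryMass TM and DM in g, DM < TM.
#' @slot measurements list; each element a list with components
#'   `freshMass`, `rwc` and `bands` (list of 3 [BandSpectrum-class]
#'   with distinct band ids).
#' @export
setClass("LeafRecord",
  representation(
    leafId = "character",
    turgidMass = "numeric",
    dryMass = "numeric",
    measurements = "list"
  )
)

setValidity("LeafRecord", function(object) {
  msg <- character()
  if (object@dryMass >= object@turgidMass)
    msg <- c(msg, "dryMass must be < turgidMass")
  for (i in seq_along(object@measurements)) {
    m <- object@measurements[[i]]
    if (!all(c("freshMass", "rwc", "bands") %in% names(m))) {
      msg <- c(msg, sprintf("measurement %d missing components", i)); next
    }
    rwcBack <- (m$freshMass - object@dryMass) /
      (object@turgidMass - object@dryMass)
    if (abs(rwcBack - m$rwc) > 1e-12)
      msg <- c(msg, sprintf("measurement %d: rwc does not match masses", i))
    ids <- vapply(m$bands, function(b) b@bandId, character(1))
    if (length(ids) != 3L || anyDuplicated(ids))
      msg <- c(msg, sprintf("measurement %d: need 3 distinct bands", i))
  }
  if (length(msg)) msg else TRUE
})

#' RusDataset: a simulated (or ingested) NC-RUS drying experiment
#'
#' A collection of [LeafRecord-class] objects together with the
#' generator configuration and master seed that produced them, so any
#' dataset is exactly reproducible from its metadata.
#'
#' @slot records list of [LeafRecord-class].
#' @slot config generator configuration (list).
#' @slot seed integer seed used by the generator.
#' @export
setClass("RusDataset",
  representation(records = "list", config = "list", seed = "integer")
)

setValidity("RusDataset", function(object) {
  ids <- vapply(object@records, function(r) r@leafId, character(1))
  if (anyDuplicated(ids)) "duplicate leaf ids" else TRUE
})

#' RusSpectra: resampled two-channel spectra on the common grid
#'
#' A [SummarizedExperiment-class] holding the fixed-size model inputs:
#' two assays, `magnitude` (dB) and `phase` (rad), each 601 grid
#' frequencies (100 kHz to 1.6 MHz in 2.5 kHz steps, `rowData`) by
#' N samples. `colData` carries `leaf_id`, `measurement_idx`,
#' `method` (the interpolation method that produced the sample),
#' `rwc` and the mass annotations.
#'
#' @export
setClass("RusSpectra", contains = "SummarizedExperiment")

setValidity("RusSpectra", function(object) {
  msg <- character()
  if (!all(c("magnitude", "phase") %in% names(assays(object))))
    msg <- c(msg, "assays 'magnitude' and 'phase' required")
  if (nrow(object) != 601L)
    msg <- c(msg, "grid must have exactly 601 rows")
  if (!"frequency_hz" %in% names(rowData(object)))
    msg <- c(msg, "rowData must carry frequency_hz")
  need <- c("leaf_id", "measurement_idx", "method", "rwc")
  if (!all(need %in% names(colData(object))))
    msg <- c(msg, "colData must carry leaf_id, measurement_idx, method, rwc")
  if (length(msg)) msg else TRUE
})

#' RusCnn: compiled 1D convolutional RWC regressor
#'
#' Weights, batch-normalization running statistics, input
#' standardization statistics and configuration of the 18-layer 1D CNN.
#' Built untrained by [buildCnn()] and fitted by [trainCnn()].
#'
#' @slot config hyperparameter list, see [cnnConfig()].
#' @slot params named list of weight matrices/vectors.
#' @slot bnStats running mean/variance per batch-norm layer.
#' @slot normStats per-channel input standardization (means, sds).
#' @slot trained logical.
#' @slot lossTrace per-epoch training MSE.
#' @export
setClass("RusCnn",
  representation(
    config = "list", params = "list", bnStats = "list",
    normStats = "list", trained = "logical", lossTrace = "numeric"
  )
)

#' RusEval: evaluation report for one model family
#'
#' Per-sample and per-measurement predictions with the summary metrics:
#' global RMSE, Pearson R, the least-squares line of predictions on
#' true RWC, and the per-leaf RMSE used for paired model comparison.
#'
#' @slot perSample DataFrame: sample_id, leaf_id, measurement_idx,
#'   method, true_rwc, predicted_rwc.
#' @slot perMeasurement DataFrame: one row per measurement (mean over
#'   the interpolated versions).
#' @slot metricsSample,metricsMeasurement lists with rmse, pearson_r,
#'   slope, intercept, n.
#' @slot perLeafRmse named numeric, RMSE per test leaf
#'   (per-measurement predictions).
#' @slot modelTag `"cnn"` or `"rf"`.
#' @export
setClass("RusEval",
  representation(
    perSample = "DataFrame", perMeasurement = "DataFrame",
    metricsSample = "list", metricsMeasurement = "list",
    perLeafRmse = "numeric", modelTag = "character"
  )
)
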