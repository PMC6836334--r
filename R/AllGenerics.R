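#' @rdname BandSpectrum-class
#' @param object,x a rusleaf object
#' @export
setGeneric("bandId", function(object) standardGeneric("bandId"))

#' @rdname BandSpectrum-class
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))

#' @rdname BandSpectrum-class
#' @export
setGeneric("magnitudeDb", function(object) standardGeneric("magnitudeDb"))

#' @rdname BandSpectrum-class
#' @export
setGeneric("phaseRad", function(object) standardGeneric("phaseRad"))

#' @rdname LeafRecord-class
#' @export
setGeneric("leafId", function(object) standardGeneric("leafId"))

#' @rdname LeafRecord-class
#' @export
setGeneric("rwcValues", function(object) standardGeneric("rwcValues"))

#' @rdname RusDataset-class
#' @export
setGeneric("leafRecords", function(object) standardGeneric("leafRecords"))

setMethod("bandId", "BandSpectrum", function(object) object@bandId)
setMethod("frequencies", "BandSpectrum", function(object) object@frequency)
setMethod("magnitudeDb", "BandSpectrum", function(object) object@magnitudeDb)
setMethod("phaseRad", "BandSpectrum", function(object) object@phaseRad)

setMethod("leafId", "LeafRecord", function(object) object@leafId)
setMethod("leafId", "LeafTraits", function(object) object@leafId)
setMethod("rwcValues", "LeafRecord", function(object)
  vapply(object@measurements, `[[`, numeric(1), "rwc"))

setMethod("leafRecords", "RusDataset", function(object) object@records)

#' @describeIn RusDataset-class number of leaves
#' @export
setMethod("length", "RusDataset", function(x) length(x@records))

#' @describeIn RusDataset-class extract one LeafRecord
#' @param i index or leaf id
#' @export
setMethod("[[", "RusDataset", function(x, i) {
  if (is.character(i)) {
    ids <- vapply(x@records, leafId, character(1))
    i <- match(i, ids)
  }
  x@records[[i]]
})

setMethod("show", "BandSpectrum", function(object) {
  cat(sprintf("BandSpectrum '%s': %d points, %.0f-%.0f kHz\n",
              object@bandId, length(object@frequency),
              min(object@frequency) / 1e3, max(object@frequency) / 1e3))
})

setMethod("show", "LeafRecord", function(object) {
  cat(sprintf("LeafRecord '%s': %d measurements, RWC %.3f-%.3f, TM %.3f g, DM %.3f g\n",
              object@leafId, length(object@measurements),
              min(rwcValues(object)), max(rwcValues(object)),
              object@turgidMass, object@dryMass))
})

setMethod("show", "RusDataset", function(object) {
  nmeas <- sum(vapply(object@records, function(r)
    length(r@measurements), integer(1)))
  cat(sprintf("RusDataset: %d leaves, %d measurements (seed %d)\n",
              length(object@records), nmeas, object@seed))
})

setMethod("show", "RusCnn", function(object) {
  cat(sprintf("RusCnn: %s, %d parameters\n",
              if (object@trained) "trained" else "untrained",
              cnnParameterCount(object)))
  if (object@trained && length(object@lossTrace))
    cat(sprintf("  final training MSE %.3g after %d epochs\n",
                utils::tail(object@lossTrace, 1), length(object@lossTrace)))
})

setMethod("show", "RusEval", function(object) {
  cat(sprintf("RusEval [%s]: %d samples / %d measurements\n",
              object@modelTag, nrow(object@perSample),
              nrow(object@perMeasurement)))
  ms <- object@metricsMeasurement
  cat(sprintf("  per-measurement RMSE %.4f, Pearson R %.4f (pred = %.4f*RWC + %.4f)\n",
              ms$rmse, ms$pearson_r, ms$slope, ms$intercept))
})
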