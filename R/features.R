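#' Locate the dominant resonance peak
#'
#' Finds the global maximum of the magnitude channel: for
#' sub-wavelength leaves the first thickness resonance dominates the
#' analyzed window, so the global maximum operationalizes "the first
#' resonance peak". Ties are broken toward the lowest frequency. Set
#' `firstLocalMax = TRUE` to take the lowest-frequency local maximum
#' instead.
#'
#' @param spec a [resampleSpectrum()] result (list with `frequency`,
#'   `magnitudeDb`, `phaseRad`).
#' @param firstLocalMax use the first strict local maximum rather
#'   than the global one.
#' @return list with `index`, `peakFrequency` (Hz), `peakMagnitude`
#'   (dB), `peakPhase` (rad).
#' @export
locatePeak <- function(spec, firstLocalMax = FALSE) {
  m <- spec$magnitudeDb
  if (!length(m)) stop("empty magnitude channel")
  if (length(unique(m)) == 1L)
    stop("degenerate spectrum: magnitude channel is flat")
  idx <- if (firstLocalMax) {
    n <- length(m)
    cand <- which(m > c(-Inf, m[-n]) & m >= c(m[-1], -Inf))
    if (!length(cand)) which.max(m) else cand[1]
  } else {
    which.max(m)  # returns the first (lowest-frequency) maximum on ties
  }
  list(index = idx,
       peakFrequency = spec$frequency[idx],
       peakMagnitude = m[idx],
       peakPhase = spec$phaseRad[idx])
}

#' Normalized -6 dB bandwidth of the resonance peak
#'
#' Scans left and right from the peak for the first samples more than
#' 6 dB below the peak magnitude, interpolates the exact crossing
#' frequencies linearly between the bracketing samples, and returns
#' the separation normalized by the peak frequency:
#' `(f_hi - f_lo) / f_peak`, a damping (inverse-Q) proxy. If no
#' crossing exists on one side within the grid the bandwidth is
#' undefined and `NA` is returned with attribute `side` naming the
#' missing side.
#'
#' @param spec a [resampleSpectrum()] result.
#' @param peakIndex index of the peak, e.g. from [locatePeak()].
#' @return dimensionless bandwidth, or `NA` when one-sided-undefined.
#' @export
bandwidthMinus6db <- function(spec, peakIndex) {
  m <- spec$magnitudeDb
  f <- spec$frequency
  stopifnot(peakIndex >= 1, peakIndex <= length(m))
  thr <- m[peakIndex] - 6
  cross <- function(iOut, iIn) {
    ## linear interpolation between the bracketing samples
    f[iIn] + (f[iOut] - f[iIn]) * (m[iIn] - thr) / (m[iIn] - m[iOut])
  }
  lo <- NA_real_
  for (i in seq(peakIndex - 1, 1)) {
    if (peakIndex == 1L) break
    if (m[i] < thr) { lo <- cross(i, i + 1); break }
  }
  hi <- NA_real_
  for (i in seq(peakIndex + 1, length(m))) {
    if (peakIndex == length(m)) break
    if (m[i] < thr) { hi <- cross(i, i - 1); break }
  }
  if (is.na(lo) || is.na(hi)) {
    side <- c("left", "right")[c(is.na(lo), is.na(hi))]
    out <- NA_real_
    attr(out, "side") <- side
    return(out)
  }
  (hi - lo) / f[peakIndex]
}

#' Extract the four resonance-derived parameters of one spectrum
#'
#' The four NC-RUS-derived parameters: maximum magnitude of the
#' transmission coefficient, the frequency and phase at which that
#' maximum is located, and the normalized -6 dB bandwidth of the
#' resonance peak.
#'
#' @param spec a [resampleSpectrum()] result.
#' @param firstLocalMax see [locatePeak()].
#' @return list with `peakMagnitude`, `peakFrequency`, `peakPhase`,
#'   `normBandwidth` and `defined` (FALSE when the bandwidth is
#'   one-sided-undefined).
#' @export
extractFeatures <- function(spec, firstLocalMax = FALSE) {
  pk <- locatePeak(spec, firstLocalMax)
  bw <- bandwidthMinus6db(spec, pk$index)
  list(
    peakMagnitude = pk$peakMagnitude,
    peakFrequency = pk$peakFrequency,
    peakPhase = pk$peakPhase,
    normBandwidth = as.numeric(bw),
    defined = !is.na(bw)
  )
}

#' Feature table for every sample of a RusSpectra container
#'
#' Applies [extractFeatures()] to each column and returns the feature
#' matrix together with the sample annotations. Samples whose -6 dB
#' bandwidth is one-sided-undefined are flagged (`defined = FALSE`)
#' and are excluded from random-forest training downstream.
#'
#' @param spectra a [RusSpectra-class].
#' @param firstLocalMax see [locatePeak()].
#' @return `DataFrame` with columns sample_id, leaf_id,
#'   measurement_idx, method, rwc, peak_magnitude_db,
#'   peak_frequency_hz, peak_phase_rad, norm_bandwidth, defined.
#' @export
featureTable <- function(spectra, firstLocalMax = FALSE) {
  stopifnot(is(spectra, "RusSpectra"))
  f <- rowData(spectra)$frequency_hz
  mag <- assay(spectra, "magnitude")
  ph <- assay(spectra, "phase")
  feats <- lapply(seq_len(ncol(spectra)), function(j) {
    extractFeatures(list(frequency = f, magnitudeDb = mag[, j],
                         phaseRad = ph[, j]), firstLocalMax)
  })
  cd <- colData(spectra)
  out <- DataFrame(
    sample_id = cd$sample_id,
    leaf_id = cd$leaf_id,
    measurement_idx = cd$measurement_idx,
    method = cd$method,
    rwc = cd$rwc,
    peak_magnitude_db = vapply(feats, `[[`, numeric(1), "peakMagnitude"),
    peak_frequency_hz = vapply(feats, `[[`, numeric(1), "peakFrequency"),
    peak_phase_rad = vapply(feats, `[[`, numeric(1), "peakPhase"),
    norm_bandwidth = vapply(feats, `[[`, numeric(1), "normBandwidth"),
    defined = vapply(feats, `[[`, logical(1), "defined")
  )
  rownames(out) <- out$sample_id
  nUndef <- sum(!out$defined)
  if (nUndef > 0)
    message(sprintf("%d sample(s) with one-sided-undefined bandwidth", nUndef))
  out
}
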