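## the common frequency reference system: 100 kHz .. 1.6 MHz in 2.5 kHz
## steps, 601 points
.RESAMPLE_GRID <- seq(100e3, 1.6e6, by = 2.5e3)

#' The seven interpolation methods used for augmentation
#'
#' Fixed order: linear, cubic, splines, nearest, next, previous,
#' akima. `cubic` is the shape-preserving piecewise-cubic Hermite
#' (PCHIP); `splines` is the classical cubic spline with
#' endpoint-fitted (Forsythe--Malcolm--Moler) boundary conditions —
#' the two distinct cubic families common numerical toolkits offer.
#'
#' @return character vector of method names.
#' @export
interpolationMethods <- function() {
  c("linear", "cubic", "splines", "nearest", "next", "previous", "akima")
}

#' The common 601-point frequency grid
#'
#' @return frequencies in Hz, 100 kHz to 1.6 MHz in 2.5 kHz steps.
#' @export
resampleGrid <- function() .RESAMPLE_GRID

#' Subtract a calibration spectrum from a raw band measurement
#'
#' Converts a raw through-leaf band spectrum into the transmission
#' coefficient by subtracting the no-sample (through-air) calibration,
#' element-wise in both dB magnitude and phase. The synthetic
#' generator emits already-calibrated coefficients; this step exists
#' for real-data ingestion.
#'
#' @param raw,calibration [BandSpectrum-class] objects on identical
#'   frequency grids.
#' @return calibrated [BandSpectrum-class].
#' @export
applyCalibration <- function(raw, calibration) {
  stopifnot(is(raw, "BandSpectrum"), is(calibration, "BandSpectrum"))
  if (length(raw@frequency) != length(calibration@frequency) ||
      any(raw@frequency != calibration@frequency))
    stop("alignment error: calibration grid does not match measurement grid")
  new("BandSpectrum",
    bandId = raw@bandId,
    frequency = raw@frequency,
    magnitudeDb = raw@magnitudeDb - calibration@magnitudeDb,
    phaseRad = raw@phaseRad - calibration@phaseRad
  )
}

#' Concatenate the three band spectra sorted by frequency
#'
#' Pools the points of the three transducer bands into one ascending
#' sequence. Phase is unwrapped per band and then across the pooled
#' sequence, so inter-band 2*pi offsets are removed before
#' interpolation. Points with exactly equal frequencies (the shared
#' 0.35 MHz edge of the low and mid bands) are merged by averaging
#' both channels; the output frequencies are strictly increasing.
#' The result is independent of the order the bands are supplied in.
#'
#' @param bands list of three [BandSpectrum-class] objects with
#'   distinct band ids.
#' @return list with `frequency`, `magnitudeDb`, `phaseRad`.
#' @export
concatenateBands <- function(bands) {
  if (length(bands) != 3L)
    stop("incomplete measurement: exactly 3 band spectra required")
  ids <- vapply(bands, bandId, character(1))
  if (anyDuplicated(ids))
    stop("incomplete measurement: band ids must be distinct")
  bands <- bands[order(vapply(bands, function(b) min(b@frequency), numeric(1)))]
  f <- unlist(lapply(bands, frequencies))
  m <- unlist(lapply(bands, magnitudeDb))
  p <- unlist(lapply(bands, function(b)
    as.numeric(signal::unwrap(phaseRad(b)))))
  o <- order(f)
  f <- f[o]; m <- m[o]; p <- p[o]
  p <- as.numeric(signal::unwrap(p))
  ## merge exact duplicates by channel averaging
  grp <- cumsum(c(TRUE, diff(f) > 0))
  if (max(grp) < length(f)) {
    f <- as.numeric(tapply(f, grp, `[`, 1))
    m <- as.numeric(tapply(m, grp, mean))
    p <- as.numeric(tapply(p, grp, mean))
  }
  list(frequency = f, magnitudeDb = m, phaseRad = p)
}

## Classical Akima (1970) univariate interpolation: local slopes from
## the weighted average of adjacent secants (quadratically extended at
## the ends), evaluated as a cubic Hermite spline.
.akimaChannel <- function(x, y, xq) {
  n <- length(x)
  m <- diff(y) / diff(x)
  mm <- 2 * m[1] - m[2]; mmm <- 2 * mm - m[1]
  mp <- 2 * m[n - 1] - m[n - 2]; mpp <- 2 * mp - m[n - 1]
  me <- c(mmm, mm, m, mp, mpp)               # segment slopes, extended
  i <- seq_len(n)
  w1 <- abs(me[i + 3] - me[i + 2])           # |m_{i+1} - m_i|
  w2 <- abs(me[i + 1] - me[i])               # |m_{i-1} - m_{i-2}|
  t <- (me[i + 1] + me[i + 2]) / 2           # tie fallback
  ok <- (w1 + w2) > 1e-9 * max(w1 + w2, 1e-300)
  t[ok] <- (w1[ok] * me[i + 1][ok] + w2[ok] * me[i + 2][ok]) /
    (w1[ok] + w2[ok])
  stats::splinefunH(x, y, t)(xq)
}

## one-channel interpolation onto `xout`; `x` strictly increasing.
## queries are clamped to the measured support, i.e. values outside it
## (notably the 100-150 kHz stretch below the lowest transducer) are
## held at the nearest measured value for every method
.interpChannel <- function(x, y, xout, method) {
  xq <- pmin(pmax(xout, x[1]), x[length(x)])
  switch(method,
    linear = approx(x, y, xout = xq, method = "linear")$y,
    cubic = pracma::pchip(x, y, xq),
    splines = spline(x, y, xout = xq, method = "fmm")$y,
    nearest = {
      ## nearest knot; exact midpoints resolve to the left knot
      i <- findInterval(xq, x, all.inside = TRUE)
      left <- xq - x[i] <= x[i + 1] - xq
      y[ifelse(left, i, i + 1)]
    },
    ## queries are clamped to [x[1], x[n]], so the +1 / plain interval
    ## index is always a valid knot and exact knots return themselves
    `next` = y[findInterval(xq, x, left.open = TRUE) + 1L],
    previous = y[findInterval(xq, x)],
    akima = .akimaChannel(x, y, xq),
    stop(sprintf("configuration error: unknown interpolation method '%s'",
                 method))
  )
}

#' Resample a concatenated spectrum onto the common grid
#'
#' Channel-wise interpolation of magnitude and phase onto the fixed
#' 601-point grid (100 kHz--1.6 MHz, 2.5 kHz step). Below the lowest
#' measured frequency the nearest measured value is held for all
#' methods; interpolating methods reproduce the source values exactly
#' at their knots.
#'
#' @param spec output of [concatenateBands()] (list with `frequency`,
#'   `magnitudeDb`, `phaseRad`).
#' @param method one of [interpolationMethods()].
#' @return list with `frequency` (the grid), `magnitudeDb`,
#'   `phaseRad` (601 values each) and `method`.
#' @export
resampleSpectrum <- function(spec, method = "linear") {
  if (!method %in% interpolationMethods())
    stop(sprintf("configuration error: unknown interpolation method '%s'",
                 method))
  x <- spec$frequency
  if (length(x) < 4L)
    stop("need at least 4 points to resample")
  if (x[1] > 0.35e6 || x[length(x)] < 1.2e6)
    stop("data-quality error: measured support narrower than [0.35, 1.2] MHz")
  list(
    frequency = .RESAMPLE_GRID,
    magnitudeDb = .interpChannel(x, spec$magnitudeDb, .RESAMPLE_GRID, method),
    phaseRad = .interpChannel(x, spec$phaseRad, .RESAMPLE_GRID, method),
    method = method
  )
}

#' Interpolation augmentation of one measurement
#'
#' Resamples one concatenated spectrum with each of the seven
#' interpolation methods, producing seven slightly different versions
#' of the same measurement (the x7 augmentation: 280 measurements
#' yield 1960 samples).
#'
#' @param spec output of [concatenateBands()].
#' @param methods methods to use, default all seven in fixed order.
#' @return named list of [resampleSpectrum()] results.
#' @export
augmentSpectrum <- function(spec, methods = interpolationMethods()) {
  out <- lapply(methods, function(m) resampleSpectrum(spec, m))
  names(out) <- methods
  out
}

#' Assemble a dataset into the fixed-size model-input container
#'
#' Concatenates each measurement's three bands, applies the
#' interpolation augmentation, and collects everything into a
#' [RusSpectra-class] (a `SummarizedExperiment` with `magnitude` and
#' `phase` assays of dimension 601 x N and the annotations in
#' `colData`).
#'
#' @param dataset a [RusDataset-class].
#' @param methods interpolation methods, default all seven.
#' @return a [RusSpectra-class] with one column per
#'   (measurement, method).
#' @export
prepareSpectra <- function(dataset, methods = interpolationMethods()) {
  stopifnot(is(dataset, "RusDataset"))
  cols <- list(); mag <- list(); ph <- list()
  k <- 0L
  for (rec in leafRecords(dataset)) {
    for (j in seq_along(rec@measurements)) {
      meas <- rec@measurements[[j]]
      cc <- concatenateBands(meas$bands)
      aug <- augmentSpectrum(cc, methods)
      for (m in names(aug)) {
        k <- k + 1L
        mag[[k]] <- aug[[m]]$magnitudeDb
        ph[[k]] <- aug[[m]]$phaseRad
        cols[[k]] <- data.frame(
          leaf_id = rec@leafId, measurement_idx = j, method = m,
          rwc = meas$rwc, fm_g = meas$freshMass,
          tm_g = rec@turgidMass, dm_g = rec@dryMass,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  cd <- do.call(rbind, cols)
  rownames(cd) <- cd$sample_id <- sprintf("%s_m%02d_%s", cd$leaf_id,
                                          cd$measurement_idx, cd$method)
  se <- SummarizedExperiment(
    assays = list(
      magnitude = matrix(unlist(mag), nrow = 601L,
                         dimnames = list(NULL, rownames(cd))),
      phase = matrix(unlist(ph), nrow = 601L,
                     dimnames = list(NULL, rownames(cd)))
    ),
    rowData = DataFrame(frequency_hz = .RESAMPLE_GRID),
    colData = DataFrame(cd)
  )
  metadata(se) <- list(methods = methods, seed = dataset@seed)
  as(se, "RusSpectra")
}
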