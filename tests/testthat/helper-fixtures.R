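## fixtures are generated in code and cached for the session

suppressPackageStartupMessages(library(SummarizedExperiment))

.fixtures <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

smallDataset <- function(nLeaves = 4L, seed = 101L) {
  .cached(sprintf("ds_%d_%d", nLeaves, seed),
          simulateDataset(nLeaves, seed = seed))
}

smallSpectra <- function(nLeaves = 4L, seed = 101L) {
  .cached(sprintf("sp_%d_%d", nLeaves, seed),
          prepareSpectra(smallDataset(nLeaves, seed)))
}

## the default-size drying experiment shared by the heavier checks
defaultDataset <- function() .cached("ds_default", simulateDataset(seed = 1L))
defaultSpectra <- function() .cached("sp_default",
                                     prepareSpectra(defaultDataset()))
defaultFeatures <- function() .cached("ft_default", suppressMessages(
  featureTable(defaultSpectra())))

## a smooth synthetic resampled spectrum: damped resonance on a sloped
## baseline plus a smooth random component (spline through few knots)
randomSmoothSpectrum <- function() {
  f <- resampleGrid()
  f0 <- runif(1, 2.5e5, 1.2e6)
  width <- runif(1, 2e4, 2e5)
  depth <- runif(1, 5, 25)
  base <- -30 - runif(1, 0, 10) * (f - f[1]) / diff(range(f))
  knots <- seq(f[1], f[601], length.out = 8)
  rough <- spline(knots, rnorm(8, 0, runif(1, 0, 3)), xout = f)$y
  mag <- base + depth * exp(-((f - f0) / width)^2) + rough
  list(frequency = f, magnitudeDb = mag,
       phaseRad = cumsum(rnorm(601, 0, 0.01)))
}

## ---- independent brute-force oracles ----

## global maximum with lowest-frequency tie break, by full scan
oraclePeakIndex <- function(mag) which(mag == max(mag))[1]

## -6 dB crossings by exhaustive scan over every grid interval,
## keeping the crossings nearest the peak on each side
oracleBandwidth <- function(f, mag, peak) {
  thr <- mag[peak] - 6
  below <- mag < thr
  lo <- NA_real_; hi <- NA_real_
  left <- which(below & seq_along(mag) < peak)
  if (length(left)) {
    i <- max(left)  # nearest below-threshold sample left of the peak
    lo <- f[i] + (f[i + 1] - f[i]) * (thr - mag[i]) / (mag[i + 1] - mag[i])
  }
  right <- which(below & seq_along(mag) > peak)
  if (length(right)) {
    i <- min(right)
    hi <- f[i] + (f[i - 1] - f[i]) * (thr - mag[i]) / (mag[i - 1] - mag[i])
  }
  if (is.na(lo) || is.na(hi)) return(NA_real_)
  (hi - lo) / f[peak]
}

## textbook-formula metrics, written independently of the package
oracleMetrics <- function(true, pred) {
  n <- length(true)
  rmse <- sqrt(sum((pred - true)^2) / n)
  mx <- sum(true) / n; my <- sum(pred) / n
  sxy <- sum((true - mx) * (pred - my))
  sxx <- sum((true - mx)^2); syy <- sum((pred - my)^2)
  r <- sxy / sqrt(sxx * syy)
  slope <- sxy / sxx
  list(rmse = rmse, pearson_r = r, slope = slope,
       intercept = my - slope * mx)
}

oraclePairedT <- function(a, b) {
  d <- a - b; n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1))
}
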