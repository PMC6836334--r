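#' Leaf-one-out cross-validation split plan
#'
#' Grouped leave-one-out splits at the leaf level (leafOO-CV): one
#' fold per leaf, every measurement — and every interpolated version
#' of it — travels with its leaf, so a fold's test leaf never
#' contributes anything to its training set. Deterministic: folds
#' follow the leaf order of the input.
#'
#' @param leafIds character vector of the dataset's leaf ids (one
#'   entry per leaf), or a [RusDataset-class].
#' @return list of folds, each a list with `test` (one leaf id) and
#'   `train` (the remaining leaf ids).
#' @export
leafooSplits <- function(leafIds) {
  if (is(leafIds, "RusDataset"))
    leafIds <- vapply(leafRecords(leafIds), leafId, character(1))
  if (anyDuplicated(leafIds))
    stop("integrity error: duplicate leaf ids")
  if (length(leafIds) < 2)
    stop("need at least 2 leaves for cross-validation")
  lapply(seq_along(leafIds), function(i)
    list(test = leafIds[i], train = leafIds[-i]))
}

#' Density-dependent downsampling of training RWC values
#'
#' Equalizes the RWC histogram of a training set: the RWC range of
#' the supplied samples is cut into `nBins` equal-width bins, the
#' target count is the size of the smallest nonempty bin, and each
#' bin is randomly subsampled without replacement down to that
#' target. This counters the dominance of near-turgid samples so the
#' regressors do not disregard low RWC values. The discarded samples
#' form the pseudo-validation pool. Re-drawn independently per
#' cross-validation round.
#'
#' @param sampleIds identifiers of the training samples.
#' @param rwc RWC value of each sample (same length).
#' @param nBins number of equal-width bins, default 10.
#' @param seed integer seed making the draw reproducible.
#' @return list with `kept` (sample ids, in input order),
#'   `pseudoValidation` (the rest), `binEdges`, `targetCount`,
#'   `seed`.
#' @export
balanceTrainingSet <- function(sampleIds, rwc, nBins = 10L, seed = 1L) {
  stopifnot(length(sampleIds) == length(rwc), length(rwc) > 0)
  nBins <- as.integer(nBins)
  if (nBins < 2L)
    stop("configuration error: need at least 2 bins")
  if (nBins > length(rwc))
    stop("configuration error: more bins than samples")
  edges <- seq(min(rwc), max(rwc), length.out = nBins + 1L)
  bin <- findInterval(rwc, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nBins)
  target <- min(counts[counts > 0L])
  keptIdx <- .withSeed(as.integer(seed), {
    unlist(lapply(which(counts > 0L), function(b) {
      members <- which(bin == b)
      if (length(members) > target)
        sort(sample(members, target)) else members
    }))
  })
  keptIdx <- sort(keptIdx)
  list(
    kept = sampleIds[keptIdx],
    pseudoValidation = sampleIds[-keptIdx],
    binEdges = edges,
    targetCount = target,
    seed = as.integer(seed)
  )
}

#' Write a split/balance manifest as JSON
#'
#' Serializes a split plan with the per-fold kept sample ids and
#' seeds so any cross-validation run is exactly reproducible.
#'
#' @param splits output of [leafooSplits()].
#' @param balances optional list (parallel to `splits`) of
#'   [balanceTrainingSet()] results.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSplitManifest <- function(splits, balances = NULL, path) {
  manifest <- lapply(seq_along(splits), function(i) {
    entry <- list(fold = i, test_leaf = splits[[i]]$test,
                  train_leaves = splits[[i]]$train)
    if (!is.null(balances)) {
      entry$kept_samples <- balances[[i]]$kept
      entry$balance_seed <- balances[[i]]$seed
    }
    entry
  })
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
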