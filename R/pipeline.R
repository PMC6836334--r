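#' Pipeline run configuration
#'
#' A single serializable list driving [runPipeline()]: generator
#' settings, interpolation methods, model configurations, balancing
#' bins, the master seed, and an optional output directory. All
#' stage-level seeds are derived from the master seed by hashing the
#' stage name, so one knob reproduces the whole run.
#'
#' @param nLeaves number of simulated leaves.
#' @param seed master seed.
#' @param methods interpolation methods for the augmentation.
#' @param nBins RWC-equalization bins for training-set balancing.
#' @param noise generator noise, see [noiseConfig()].
#' @param cnn CNN hyperparameters, see [cnnConfig()]; the per-fold
#'   seed is derived and overrides `cnn$seed`.
#' @param rf random-forest hyperparameters, see [rfConfig()].
#' @param runCnn,runRf which model families to run.
#' @param cnnFolds optional integer vector restricting which
#'   cross-validation folds train a CNN (the RF always runs all
#'   folds); `NULL` means all.
#' @param outDir optional directory for manifests and reports.
#' @return configuration list.
#' @export
runConfig <- function(nLeaves = 31L, seed = 1L,
                      methods = interpolationMethods(),
                      nBins = 10L, noise = noiseConfig(),
                      cnn = cnnConfig(), rf = rfConfig(),
                      runCnn = TRUE, runRf = TRUE,
                      cnnFolds = NULL, outDir = NULL) {
  list(nLeaves = as.integer(nLeaves), seed = as.integer(seed),
       methods = methods, nBins = as.integer(nBins), noise = noise,
       cnn = cnn, rf = rf, runCnn = runCnn, runRf = runRf,
       cnnFolds = if (is.null(cnnFolds)) NULL else as.integer(cnnFolds),
       outDir = outDir)
}

.predFrame <- function(cd, idx, predicted) {
  data.frame(
    sample_id = cd$sample_id[idx], leaf_id = cd$leaf_id[idx],
    measurement_idx = cd$measurement_idx[idx], method = cd$method[idx],
    true_rwc = cd$rwc[idx], predicted_rwc = predicted,
    stringsAsFactors = FALSE
  )
}

#' Run the full simulation-to-evaluation pipeline
#'
#' Executes the stages in order — simulate, preprocess (concatenate +
#' resample + augment), feature extraction, leaf-one-out
#' cross-validation with per-round RWC balancing, model training and
#' prediction, evaluation — and returns every intermediate product.
#' Rerunning with an identical configuration reproduces all
#' deterministic artifacts (the RF and the split/balance manifests
#' exactly; the CNN exactly as well, since its training is seeded).
#'
#' @param cfg a [runConfig()] list.
#' @param verbose print per-stage progress.
#' @return list with `dataset`, `spectra`, `features`, `splits`,
#'   `balances`, `rfPredictions`, `cnnPredictions`, `rfEval`,
#'   `cnnEval`, `comparison` (paired t on per-leaf RMSE over the
#'   folds both families share), `anovaRf`/`anovaCnn`
#'   (interpolation-method checks) and `config`.
#' @export
runPipeline <- function(cfg = runConfig(), verbose = interactive()) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  say("simulate: %d leaves", cfg$nLeaves)
  dataset <- stage("simulate",
    simulateDataset(cfg$nLeaves, seed = deriveSeed(cfg$seed, "simulate"),
                    noise = cfg$noise))
  say("preprocess: %d interpolation methods", length(cfg$methods))
  spectra <- stage("preprocess", prepareSpectra(dataset, cfg$methods))
  say("features: %d samples", ncol(spectra))
  features <- stage("features", featureTable(spectra))
  splits <- stage("splits", leafooSplits(dataset))
  cd <- colData(spectra)

  cnnFolds <- if (is.null(cfg$cnnFolds)) seq_along(splits) else cfg$cnnFolds
  balances <- vector("list", length(splits))
  rfPred <- list(); cnnPred <- list()
  for (k in seq_along(splits)) {
    fold <- splits[[k]]
    trainIdx <- which(cd$leaf_id %in% fold$train)
    testIdx <- which(cd$leaf_id == fold$test)
    bal <- stage("balance",
      balanceTrainingSet(cd$sample_id[trainIdx], cd$rwc[trainIdx],
                         nBins = cfg$nBins,
                         seed = deriveSeed(cfg$seed, paste0("balance", k))))
    balances[[k]] <- bal
    keptIdx <- match(bal$kept, cd$sample_id)
    if (cfg$runRf) {
      rfCfg <- cfg$rf
      rfCfg$seed <- deriveSeed(cfg$seed, paste0("rf", k))
      fit <- stage("train-rf", trainRf(features[keptIdx, ], rfCfg))
      rfPred[[k]] <- .predFrame(cd, testIdx,
                                predictRf(fit, features[testIdx, ]))
    }
    if (cfg$runCnn && k %in% cnnFolds) {
      say("fold %d/%d: training CNN (%d samples)", k, length(splits),
          length(keptIdx))
      cnnCfg <- cfg$cnn
      cnnCfg$seed <- deriveSeed(cfg$seed, paste0("cnn", k))
      model <- buildCnn(cnnCfg)
      model <- stage("train-cnn",
        trainCnn(model, spectra[, keptIdx], cd$rwc[keptIdx]))
      cnnPred[[k]] <- .predFrame(cd, testIdx,
                                 predict(model, spectra[, testIdx]))
    }
  }

  out <- list(dataset = dataset, spectra = spectra, features = features,
              splits = splits, balances = balances, config = cfg)
  if (cfg$runRf) {
    out$rfPredictions <- do.call(rbind, rfPred)
    out$rfEval <- buildEvalReport(out$rfPredictions, "rf")
    out$anovaRf <- .methodAnova(out$rfPredictions)
  }
  if (cfg$runCnn && length(cnnPred)) {
    out$cnnPredictions <- do.call(rbind, cnnPred)
    out$cnnEval <- buildEvalReport(out$cnnPredictions, "cnn")
    out$anovaCnn <- .methodAnova(out$cnnPredictions)
  }
  if (!is.null(out$rfEval) && !is.null(out$cnnEval)) {
    shared <- intersect(names(out$cnnEval@perLeafRmse),
                        names(out$rfEval@perLeafRmse))
    if (length(shared) >= 3)
      out$comparison <- compareModels(out$cnnEval@perLeafRmse[shared],
                                      out$rfEval@perLeafRmse[shared])
  }
  if (!is.null(cfg$outDir)) .writeRunArtifacts(out, cfg$outDir)
  out
}

## per-method absolute-error matrix (measurements x methods) -> ANOVA
.methodAnova <- function(predictions) {
  df <- predictions[!is.na(predictions$predicted_rwc), , drop = FALSE]
  df$err <- abs(df$predicted_rwc - df$true_rwc)
  key <- interaction(df$leaf_id, df$measurement_idx, drop = TRUE)
  methods <- sort(unique(df$method))
  wide <- vapply(methods, function(m) {
    v <- rep(NA_real_, nlevels(key))
    sel <- df$method == m
    v[as.integer(key[sel])] <- df$err[sel]
    v
  }, numeric(nlevels(key)))
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  colnames(wide) <- methods
  if (nrow(wide) < 3) return(NULL)
  interpolationAnova(wide)
}

.writeRunArtifacts <- function(run, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeRusDataset(run$dataset, file.path(outDir, "dataset"))
  writeFeaturesCsv(run$features, file.path(outDir, "features.csv"))
  writeSplitManifest(run$splits, run$balances,
                     file.path(outDir, "splits.json"))
  jsonlite::write_json(
    run$config[setdiff(names(run$config), "outDir")],
    file.path(outDir, "run_config.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  for (tag in c("rf", "cnn")) {
    ev <- run[[paste0(tag, "Eval")]]
    if (is.null(ev)) next
    utils::write.csv(as.data.frame(ev@perSample),
                     file.path(outDir, paste0(tag, "_predictions.csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(per_sample = ev@metricsSample,
           per_measurement = ev@metricsMeasurement,
           per_leaf_rmse = as.list(ev@perLeafRmse)),
      file.path(outDir, paste0(tag, "_metrics.json")),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(outDir)
}
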