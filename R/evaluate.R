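#' Mean prediction over the interpolated versions of a measurement
#'
#' The seven interpolation-augmented versions of one NC-RUS
#' measurement are grouped by (leaf, measurement index) and their
#' predictions averaged, giving a unique value per acquired
#' measurement.
#'
#' @param predictions data.frame-like with columns `leaf_id`,
#'   `measurement_idx`, `true_rwc`, `predicted_rwc` (one row per
#'   interpolated version; `NA` predictions are dropped before
#'   averaging).
#' @return data.frame with one row per measurement.
#' @export
aggregateVersions <- function(predictions) {
  df <- as.data.frame(predictions)
  ok <- !is.na(df$predicted_rwc)
  if (!any(ok)) stop("no defined predictions to aggregate")
  df <- df[ok, , drop = FALSE]
  key <- interaction(df$leaf_id, df$measurement_idx, drop = TRUE)
  out <- data.frame(
    leaf_id = tapply(df$leaf_id, key, `[`, 1),
    measurement_idx = as.integer(tapply(df$measurement_idx, key, `[`, 1)),
    true_rwc = as.numeric(tapply(df$true_rwc, key, `[`, 1)),
    predicted_rwc = as.numeric(tapply(df$predicted_rwc, key, mean)),
    stringsAsFactors = FALSE
  )
  out[order(out$leaf_id, out$measurement_idx), , drop = FALSE]
}

#' RMSE, Pearson correlation and regression line
#'
#' Standard definitions: root mean square error of the predictions,
#' Pearson's linear correlation coefficient R, and the least-squares
#' line of predictions on true RWC
#' (`prediction = slope * RWC + intercept`).
#'
#' @param true,predicted equal-length numeric vectors (n >= 3).
#' @return list with `rmse`, `pearson_r`, `slope`, `intercept`, `n`.
#'   With constant truth, `pearson_r`, `slope` and `intercept` are
#'   `NA` and the result carries `degenerate = TRUE`.
#' @export
computeMetrics <- function(true, predicted) {
  stopifnot(length(true) == length(predicted), length(true) >= 3)
  ok <- !is.na(true) & !is.na(predicted)
  true <- true[ok]; predicted <- predicted[ok]
  rmse <- sqrt(mean((predicted - true)^2))
  if (sd(true) == 0) {
    return(list(rmse = rmse, pearson_r = NA_real_, slope = NA_real_,
                intercept = NA_real_, n = length(true), degenerate = TRUE))
  }
  fit <- lm(predicted ~ true)
  list(rmse = rmse,
       pearson_r = as.numeric(cor(true, predicted)),
       slope = as.numeric(coef(fit)[2]),
       intercept = as.numeric(coef(fit)[1]),
       n = length(true), degenerate = FALSE)
}

#' Assemble the evaluation report for one model family
#'
#' Computes per-sample and per-measurement (version-averaged)
#' metrics and the per-leaf RMSE sequence used for paired model
#' comparison.
#'
#' @param predictions data.frame with columns `sample_id`, `leaf_id`,
#'   `measurement_idx`, `method`, `true_rwc`, `predicted_rwc`.
#' @param modelTag `"cnn"` or `"rf"`.
#' @return a [RusEval-class].
#' @export
buildEvalReport <- function(predictions, modelTag) {
  df <- as.data.frame(predictions)
  perMeas <- aggregateVersions(df)
  okS <- !is.na(df$predicted_rwc)
  metricsS <- computeMetrics(df$true_rwc[okS], df$predicted_rwc[okS])
  metricsM <- computeMetrics(perMeas$true_rwc, perMeas$predicted_rwc)
  perLeaf <- vapply(split(perMeas, perMeas$leaf_id), function(d)
    sqrt(mean((d$predicted_rwc - d$true_rwc)^2)), numeric(1))
  new("RusEval",
      perSample = DataFrame(df[okS, , drop = FALSE]),
      perMeasurement = DataFrame(perMeas),
      metricsSample = metricsS, metricsMeasurement = metricsM,
      perLeafRmse = perLeaf, modelTag = as.character(modelTag))
}

#' Paired comparison of two model families by per-leaf RMSE
#'
#' Two-sided paired t-test on the per-leaf RMSE differences of two
#' models evaluated on the same leaves.
#'
#' @param perLeafRmseA,perLeafRmseB equal-length paired numeric
#'   vectors (n >= 3); if named, names are matched.
#' @return list with `t`, `p_value`, `df`, `mean_difference`,
#'   `degenerate` (TRUE when the differences have zero variance,
#'   where the t statistic is undefined for nonzero shift and the
#'   test is not meaningful).
#' @export
compareModels <- function(perLeafRmseA, perLeafRmseB) {
  stopifnot(length(perLeafRmseA) == length(perLeafRmseB),
            length(perLeafRmseA) >= 3)
  if (!is.null(names(perLeafRmseA)) && !is.null(names(perLeafRmseB)))
    perLeafRmseB <- perLeafRmseB[names(perLeafRmseA)]
  d <- perLeafRmseA - perLeafRmseB
  if (sd(d) < 1e-10 * max(abs(mean(d)), 1e-10)) {
    return(list(t = if (mean(d) == 0) 0 else NA_real_,
                p_value = if (mean(d) == 0) 1 else NA_real_,
                df = length(d) - 1L, mean_difference = mean(d),
                degenerate = mean(d) != 0))
  }
  ht <- t.test(perLeafRmseA, perLeafRmseB, paired = TRUE)
  list(t = as.numeric(ht$statistic), p_value = ht$p.value,
       df = as.numeric(ht$parameter), mean_difference = mean(d),
       degenerate = FALSE)
}

#' Do the interpolation methods differ? Repeated-measures check
#'
#' Repeated-measures ANOVA of per-sample prediction errors across the
#' seven interpolation methods (measurements as subjects), followed
#' by all pairwise comparisons with both Bonferroni-adjusted paired
#' t-tests and the Tukey--Kramer procedure.
#'
#' @param errors numeric matrix, one row per measurement and one
#'   column per interpolation method (complete cases).
#' @param alpha significance level for the summary flags.
#' @return list with `F`, `p_value`, `bonferroni` and `tukey`
#'   pairwise tables, and `any_significant`.
#' @export
interpolationAnova <- function(errors, alpha = 0.05) {
  errors <- as.matrix(errors)
  stopifnot(nrow(errors) >= 3, ncol(errors) >= 2,
            all(is.finite(errors)))
  nm <- colnames(errors)
  if (is.null(nm)) nm <- paste0("m", seq_len(ncol(errors)))
  long <- data.frame(
    err = as.vector(errors),
    method = factor(rep(nm, each = nrow(errors)), levels = nm),
    subject = factor(rep(seq_len(nrow(errors)), times = ncol(errors)))
  )
  if (all(abs(errors - errors[, 1]) < 1e-15)) {
    ## identical columns: no method effect by construction
    return(list(F = 0, p_value = 1, bonferroni = NULL, tukey = NULL,
                any_significant = FALSE))
  }
  fit <- aov(err ~ method + Error(subject), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  Fval <- tab["method", "F value"]
  pval <- tab["method", "Pr(>F)"]
  bf <- pairwise.t.test(long$err, long$method, paired = TRUE,
                        p.adjust.method = "bonferroni")
  tk <- TukeyHSD(aov(err ~ method + subject, data = long), "method")$method
  anySig <- (pval < alpha) &&
    (any(bf$p.value < alpha, na.rm = TRUE) ||
     any(tk[, "p adj"] < alpha, na.rm = TRUE))
  list(F = as.numeric(Fval), p_value = as.numeric(pval),
       bonferroni = bf$p.value, tukey = tk,
       any_significant = isTRUE(anySig))
}
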