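#' Random-forest configuration
#'
#' Defaults mirror the bagged regression-tree ensemble used on the
#' four resonance-derived parameters: 400 trees grown on bootstrap
#' samples drawn with replacement, half of the variables (2 of 4)
#' considered at each decision split, and a minimum of 3 observations
#' per tree leaf.
#'
#' @param n_trees,features_per_split,min_samples_leaf,replace,seed
#'   see description.
#' @return configuration list.
#' @export
rfConfig <- function(n_trees = 400L, features_per_split = 2L,
                     min_samples_leaf = 3L, replace = TRUE, seed = 1L) {
  list(n_trees = as.integer(n_trees),
       features_per_split = as.integer(features_per_split),
       min_samples_leaf = as.integer(min_samples_leaf),
       replace = replace, seed = as.integer(seed))
}

.RF_FEATURES <- c("peak_magnitude_db", "peak_frequency_hz",
                  "peak_phase_rad", "norm_bandwidth")

#' Train the random forest on the four derived parameters
#'
#' Fits a [randomForest::randomForest] regression ensemble of RWC on
#' peak magnitude, peak frequency, peak phase and normalized -6 dB
#' bandwidth. Rows whose bandwidth is one-sided-undefined
#' (`defined == FALSE`) are excluded (and counted in the result).
#' Seeded, so identical inputs give identical forests.
#'
#' @param features a [featureTable()] `DataFrame` (or data.frame with
#'   the four feature columns, `rwc` and `defined`).
#' @param cfg an [rfConfig()] list.
#' @return list with `forest` (the fitted randomForest), `cfg` and
#'   `nExcluded`.
#' @export
trainRf <- function(features, cfg = rfConfig()) {
  df <- as.data.frame(features)
  keep <- if ("defined" %in% names(df)) df$defined else rep(TRUE, nrow(df))
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 2 * cfg$min_samples_leaf)
    stop("need at least 2 * min_samples_leaf training rows")
  if (length(unique(df$rwc)) == 1L)
    warning("degenerate fit: all-constant target")
  x <- df[, .RF_FEATURES, drop = FALSE]
  fit <- .withSeed(cfg$seed,
    randomForest::randomForest(
      x = x, y = df$rwc,
      ntree = cfg$n_trees, mtry = cfg$features_per_split,
      nodesize = cfg$min_samples_leaf, replace = cfg$replace
    )
  )
  list(forest = fit, cfg = cfg, nExcluded = sum(!keep))
}

#' Predict RWC from a trained random forest
#'
#' @param model a [trainRf()] result.
#' @param features feature rows to predict; undefined-bandwidth rows
#'   yield `NA`.
#' @return numeric predictions (unclamped), named by `sample_id` when
#'   present.
#' @export
predictRf <- function(model, features) {
  if (is.null(model$forest))
    stop("state error: model has not been trained")
  df <- as.data.frame(features)
  out <- rep(NA_real_, nrow(df))
  ok <- if ("defined" %in% names(df)) df$defined else rep(TRUE, nrow(df))
  if (any(ok))
    out[ok] <- as.numeric(predict(model$forest,
                                  df[ok, .RF_FEATURES, drop = FALSE]))
  if ("sample_id" %in% names(df)) names(out) <- df$sample_id
  out
}
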