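test_that("version aggregation averages per measurement", {
  df <- data.frame(
    leaf_id = "a", measurement_idx = 1L, true_rwc = 0.9,
    predicted_rwc = c(0.8, 0.9, 1.0, 0.7, 0.9, 0.8, 0.9)
  )
  agg <- aggregateVersions(df)
  expect_identical(nrow(agg), 1L)
  expect_equal(agg$predicted_rwc, 6 / 7)
  same <- df; same$predicted_rwc <- 0.83
  expect_equal(aggregateVersions(same)$predicted_rwc, 0.83)
  ## NA versions are dropped before averaging
  withNa <- df; withNa$predicted_rwc[1] <- NA
  expect_equal(aggregateVersions(withNa)$predicted_rwc,
               mean(df$predicted_rwc[-1]))
})

test_that("metrics have their textbook identities", {
  x <- seq(0.5, 1, length.out = 10)
  perfect <- computeMetrics(x, x)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$pearson_r, 1)
  expect_equal(perfect$slope, 1)
  expect_equal(perfect$intercept, 0)
  anti <- computeMetrics(x, 1 - x)
  expect_equal(anti$pearson_r, -1)
  const <- computeMetrics(rep(0.8, 5), runif(5))
  expect_true(const$degenerate)
  expect_true(is.na(const$pearson_r))
})

test_that("metrics match an independent formula evaluation", {
  set.seed(3)
  for (i in 1:25) {
    true <- runif(10); pred <- runif(10)
    got <- computeMetrics(true, pred)
    ref <- oracleMetrics(true, pred)
    expect_equal(got$rmse, ref$rmse, tolerance = 1e-12)
    expect_equal(got$pearson_r, ref$pearson_r, tolerance = 1e-12)
    expect_equal(got$slope, ref$slope, tolerance = 1e-12)
    expect_equal(got$intercept, ref$intercept, tolerance = 1e-12)
  }
})

test_that("paired model comparison matches the t-distribution oracle", {
  a <- c(0.05, 0.06, 0.055, 0.07, 0.04, 0.06)
  same <- compareModels(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  constShift <- compareModels(a, a + 0.01)
  expect_true(constShift$degenerate)
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(12, 0.05, 0.01)
    y <- x + rnorm(12, 0.005, 0.004)
    got <- compareModels(x, y)
    ref <- oraclePairedT(x, y)
    expect_equal(got$t, ref$t, tolerance = 1e-9)
    expect_equal(got$p_value, ref$p, tolerance = 1e-9)
  }
})

test_that("named per-leaf vectors are matched before pairing", {
  a <- c(l1 = 0.05, l2 = 0.06, l3 = 0.04)
  b <- c(l3 = 0.05, l1 = 0.065, l2 = 0.07)
  got <- compareModels(a, b)
  ref <- oraclePairedT(a, b[names(a)])
  expect_equal(got$t, ref$t, tolerance = 1e-12)
})

test_that("identical method columns yield no interpolation effect", {
  e <- matrix(rep(runif(20, 0, 0.1), 7), ncol = 7,
              dimnames = list(NULL, interpolationMethods()))
  res <- interpolationAnova(e)
  expect_equal(res$F, 0)
  expect_false(res$any_significant)
})

test_that("a strongly shifted method is flagged by both procedures", {
  set.seed(17)
  e <- matrix(rnorm(30 * 7, 0.05, 0.005), ncol = 7,
              dimnames = list(NULL, interpolationMethods()))
  e[, "splines"] <- e[, "splines"] + 0.05  # 10 sigma shift
  res <- interpolationAnova(e)
  expect_true(res$any_significant)
  expect_lt(res$p_value, 0.05)
  bf <- res$bonferroni
  hit <- c(bf["splines", ], bf[, "splines"])
  expect_true(any(hit < 0.05, na.rm = TRUE))
  tk <- res$tukey
  rows <- grepl("splines", rownames(tk))
  expect_true(all(tk[rows, "p adj"] < 0.05))
})

test_that("evaluation reports aggregate cleanly from predictions", {
  set.seed(23)
  grid <- expand.grid(method = interpolationMethods(),
                      measurement_idx = 1:5,
                      leaf_id = c("a", "b", "c"),
                      stringsAsFactors = FALSE)
  grid$true_rwc <- rep(runif(15, 0.5, 1), each = 7)
  grid$predicted_rwc <- grid$true_rwc + rnorm(nrow(grid), 0, 0.03)
  grid$sample_id <- paste0("s", seq_len(nrow(grid)))
  ev <- buildEvalReport(grid, "rf")
  expect_s4_class(ev, "RusEval")
  expect_identical(nrow(ev@perMeasurement), 15L)
  expect_identical(nrow(ev@perSample), 105L)
  expect_length(ev@perLeafRmse, 3L)
  ## averaging the 7 versions cannot hurt the global RMSE noticeably
  expect_lte(ev@metricsMeasurement$rmse, ev@metricsSample$rmse + 1e-9)
})
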