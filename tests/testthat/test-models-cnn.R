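tinyCfg <- function(seed = 11L)
  cnnConfig(conv_kernel_counts = c(3L, 4L, 5L), conv_kernel_sizes = c(3L, 3L, 3L),
            fc_sizes = c(6L, 4L, 1L), input_length = 24L, n_channels = 2L,
            epochs = 30L, seed = seed)

test_that("the built network enumerates its 18 layers in order", {
  layers <- cnnLayers(buildCnn())
  expect_identical(nrow(layers), 18L)
  expect_identical(layers$type, c(
    "input",
    "conv1d", "batchnorm", "relu",
    "conv1d", "batchnorm", "relu", "maxpool1d",
    "conv1d", "batchnorm", "relu", "maxpool1d",
    "fc", "dropout", "fc", "dropout", "fc",
    "regression"))
  convs <- layers$spec[layers$type == "conv1d"]
  expect_identical(convs, c("17 kernels, size 11", "55 kernels, size 7",
                            "70 kernels, size 11"))
  expect_identical(layers$spec[layers$type == "fc"],
                   c("25 nodes", "25 nodes", "1 node"))
})

test_that("the parameter count matches layer arithmetic", {
  ## independent layer-by-layer count under same-padding stride-1
  ## convolutions and window-2 stride-2 pooling
  cfg <- cnnConfig()
  kc <- cfg$conv_kernel_counts; ks <- cfg$conv_kernel_sizes
  fc <- cfg$fc_sizes
  conv <- function(cin, cout, k) cin * k * cout + cout
  bn <- function(ch) 2 * ch
  flat <- kc[3] * (cfg$input_length %/% 2 %/% 2)
  expected <- conv(2, kc[1], ks[1]) + bn(kc[1]) +
    conv(kc[1], kc[2], ks[2]) + bn(kc[2]) +
    conv(kc[2], kc[3], ks[3]) + bn(kc[3]) +
    (flat * fc[1] + fc[1]) + (fc[1] * fc[2] + fc[2]) + (fc[2] * fc[3] + fc[3])
  expect_equal(cnnParameterCount(buildCnn(cfg)), expected)
})

test_that("an untrained forward pass maps any input to a finite scalar", {
  m <- buildCnn(tinyCfg())
  zeros <- matrix(0, 48, 3)
  out <- rusleaf:::cnn_predict_cpp(m@params, m@bnStats, zeros, m@config)
  expect_length(out, 3L)
  expect_true(all(is.finite(out)))
  expect_error(predict(m, zeros), "state error")  # predict needs training
})

test_that("analytic gradients match finite differences", {
  cfg <- tinyCfg()
  m <- buildCnn(cfg)
  set.seed(2)
  X <- matrix(rnorm(48 * 6), 48, 6)
  y <- runif(6)
  g <- rusleaf:::cnn_grad_cpp(m@params, m@bnStats, X, y, cfg)
  rel <- c()
  for (nm in c("Wc1", "Wc2", "Wc3", "Wf1", "Wf2", "Wf3")) {
    P <- m@params[[nm]]
    for (i in unique(round(seq(1, length(P), length.out = 6)))) {
      h <- 1e-2
      up <- m@params; up[[nm]][i] <- P[i] + h
      dn <- m@params; dn[[nm]][i] <- P[i] - h
      fd <- (rusleaf:::cnn_loss_cpp(up, m@bnStats, X, y, cfg) -
             rusleaf:::cnn_loss_cpp(dn, m@bnStats, X, y, cfg)) / (2 * h)
      rel <- c(rel, abs(fd - g$grads[[nm]][i]) /
                      max(abs(fd), abs(g$grads[[nm]][i]), 1e-3))
    }
  }
  ## single-precision finite differences occasionally straddle a
  ## ReLU/pool kink; the bulk of the gradient field must agree tightly
  expect_lt(median(rel), 1e-3)
  expect_gt(mean(rel < 2e-2), 0.9)
})

test_that("training reduces the loss on a small sample", {
  set.seed(5)
  X <- matrix(rnorm(48 * 20), 48, 20)
  y <- 0.5 + 0.4 * tanh(colMeans(X[1:10, ]))
  cfg <- tinyCfg(); cfg$epochs <- 350L
  m <- trainCnn(buildCnn(cfg), X, y)
  expect_lt(utils::tail(m@lossTrace, 1), m@lossTrace[1])
  expect_true(all(is.finite(m@lossTrace)))
})

test_that("training and prediction are seed-deterministic", {
  set.seed(6)
  X <- matrix(rnorm(48 * 24), 48, 24)
  y <- runif(24)
  cfg <- tinyCfg(seed = 77L); cfg$epochs <- 15L
  m1 <- trainCnn(buildCnn(cfg), X, y)
  m2 <- trainCnn(buildCnn(cfg), X, y)
  expect_identical(m1@params, m2@params)  # bit-identical weights
  p1 <- predict(m1, X); p2 <- predict(m1, X)
  expect_identical(p1, p2)  # dropout disabled at inference
  cfg2 <- tinyCfg(seed = 78L); cfg2$epochs <- 15L
  m3 <- trainCnn(buildCnn(cfg2), X, y)
  expect_false(identical(m1@params, m3@params))
})

test_that("input shape violations are rejected", {
  m <- buildCnn(tinyCfg())
  expect_error(trainCnn(m, matrix(0, 47, 5), runif(5)), "shape")
  expect_error(trainCnn(m, matrix(0, 48, 5), runif(4)), "shape")
})

test_that("a trained network beats the constant-mean predictor", {
  sp <- smallSpectra()
  cd <- colData(sp)
  testLeaf <- leafId(leafRecords(smallDataset())[[1]])
  trainIdx <- which(cd$leaf_id != testLeaf)
  testIdx <- which(cd$leaf_id == testLeaf)
  cfg <- cnnConfig(epochs = 12L, seed = 3L)
  m <- trainCnn(buildCnn(cfg), sp[, trainIdx], cd$rwc[trainIdx])
  pred <- predict(m, sp[, testIdx])
  rmseCnn <- sqrt(mean((pred - cd$rwc[testIdx])^2))
  rmseMean <- sqrt(mean((mean(cd$rwc[trainIdx]) - cd$rwc[testIdx])^2))
  expect_lt(rmseCnn, rmseMean)
})
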