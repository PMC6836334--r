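#' CNN hyperparameter configuration
#'
#' Defaults are the fixed training constants of the 18-layer
#' architecture: three 1D convolutional layers with (17, 55, 70)
#' kernels of sizes (11, 7, 11), three fully connected layers with
#' (25, 25, 1) nodes, dropout probability 0.30 after the first two,
#' max-pooling window 2 after the last two convolutional blocks,
#' 350 epochs, minibatch 32, SGDM with initial learning rate 0.0875,
#' three drops of factor 10 (evenly spaced at epochs
#' `ceiling(epochs * k/4)`), L2 regularization 1.25e-7 on the weight
#' matrices and momentum 0.8247, mean-squared-error loss.
#' Convolutions use same-padding with stride 1.
#'
#' @param conv_kernel_counts,conv_kernel_sizes,fc_sizes,dropout_prob
#'   architecture constants.
#' @param pool_window max-pooling window (and stride).
#' @param epochs,minibatch,initial_lr,lr_drops,l2,momentum training
#'   constants.
#' @param seed integer seed driving initialization, shuffling and
#'   dropout.
#' @param input_length,n_channels input geometry (601 x 2).
#' @return configuration list.
#' @export
cnnConfig <- function(conv_kernel_counts = c(17L, 55L, 70L),
                      conv_kernel_sizes = c(11L, 7L, 11L),
                      fc_sizes = c(25L, 25L, 1L),
                      dropout_prob = 0.30,
                      pool_window = 2L,
                      epochs = 350L, minibatch = 32L,
                      initial_lr = 0.0875, lr_drops = 3L,
                      l2 = 1.25e-7, momentum = 0.8247,
                      seed = 1L,
                      input_length = 601L, n_channels = 2L) {
  stopifnot(length(conv_kernel_counts) == 3, length(conv_kernel_sizes) == 3,
            length(fc_sizes) == 3, fc_sizes[3] == 1,
            all(conv_kernel_sizes %% 2 == 1), pool_window == 2)
  list(
    conv_kernel_counts = as.integer(conv_kernel_counts),
    conv_kernel_sizes = as.integer(conv_kernel_sizes),
    fc_sizes = as.integer(fc_sizes),
    dropout_prob = dropout_prob, pool_window = as.integer(pool_window),
    epochs = as.integer(epochs), minibatch = as.integer(minibatch),
    initial_lr = initial_lr, lr_drops = as.integer(lr_drops),
    l2 = l2, momentum = momentum, seed = as.integer(seed),
    input_length = as.integer(input_length),
    n_channels = as.integer(n_channels)
  )
}

#' Build the untrained CNN
#'
#' Initializes the convolutional stack with a uniform fan-in scheme
#' under the configured seed; the fully connected head — which is
#' linear, having no activations between its layers — uses a 10x
#' smaller scale so its initial end-to-end gain stays well below 1
#' (required for stability at the large configured initial learning
#' rate). Batch-norm scales start at 1, shifts and biases at 0; the
#' output bias is moved to the training-target mean when training
#' starts.
#'
#' @param cfg a [cnnConfig()] list.
#' @return an untrained [RusCnn-class].
#' @export
buildCnn <- function(cfg = cnnConfig()) {
  init <- cnn_init_cpp(cfg, cfg$seed)
  new("RusCnn", config = cfg, params = init$params, bnStats = init$bn,
      normStats = list(), trained = FALSE, lossTrace = numeric())
}

#' Layer enumeration of the CNN
#'
#' Walks the architecture and returns its 18 layers in order:
#' input, 3 x (conv + batch-norm + ReLU) with max-pooling after the
#' last two blocks, 3 fully connected layers with dropout after the
#' first two, and the mean-squared-error regression output.
#'
#' @param model a [RusCnn-class] (or a [cnnConfig()] list).
#' @return data.frame with `layer`, `type` and `spec` columns.
#' @export
cnnLayers <- function(model) {
  cfg <- if (is(model, "RusCnn")) model@config else model
  kc <- cfg$conv_kernel_counts; ks <- cfg$conv_kernel_sizes
  fc <- cfg$fc_sizes
  tab <- rbind(
    c("input", sprintf("%d x %d", cfg$input_length, cfg$n_channels)),
    c("conv1d", sprintf("%d kernels, size %d", kc[1], ks[1])),
    c("batchnorm", sprintf("%d channels", kc[1])),
    c("relu", ""),
    c("conv1d", sprintf("%d kernels, size %d", kc[2], ks[2])),
    c("batchnorm", sprintf("%d channels", kc[2])),
    c("relu", ""),
    c("maxpool1d", sprintf("window %d", cfg$pool_window)),
    c("conv1d", sprintf("%d kernels, size %d", kc[3], ks[3])),
    c("batchnorm", sprintf("%d channels", kc[3])),
    c("relu", ""),
    c("maxpool1d", sprintf("window %d", cfg$pool_window)),
    c("fc", sprintf("%d nodes", fc[1])),
    c("dropout", sprintf("p = %.2f", cfg$dropout_prob)),
    c("fc", sprintf("%d nodes", fc[2])),
    c("dropout", sprintf("p = %.2f", cfg$dropout_prob)),
    c("fc", sprintf("%d node", fc[3])),
    c("regression", "mean squared error")
  )
  data.frame(layer = seq_len(nrow(tab)), type = tab[, 1], spec = tab[, 2],
             stringsAsFactors = FALSE)
}

#' Number of learnable parameters of the CNN
#'
#' @param model a [RusCnn-class].
#' @return integer count over all weights, biases and batch-norm
#'   scale/shift parameters.
#' @export
cnnParameterCount <- function(model) {
  stopifnot(is(model, "RusCnn"))
  sum(vapply(model@params, length, integer(1)))
}

#' Two-channel input matrix for the CNN
#'
#' Stacks the magnitude assay above the phase assay, giving the
#' 1202 x N matrix (rows 1..601 magnitude, 602..1202 phase) the
#' compiled network consumes.
#'
#' @param spectra a [RusSpectra-class].
#' @return numeric matrix with one column per sample.
#' @export
cnnInputMatrix <- function(spectra) {
  stopifnot(is(spectra, "RusSpectra"))
  rbind(assay(spectra, "magnitude"), assay(spectra, "phase"))
}

.standardizeInput <- function(x, stats) {
  L <- nrow(x) / 2
  x[seq_len(L), ] <- (x[seq_len(L), ] - stats$magMean) / stats$magSd
  x[L + seq_len(L), ] <- (x[L + seq_len(L), ] - stats$phaseMean) / stats$phaseSd
  x
}

#' Train the CNN with stochastic gradient descent with momentum
#'
#' Standardizes each input channel (magnitude, phase) to zero mean
#' and unit variance using statistics of the training set only, then
#' runs seeded minibatch SGDM with the piecewise-constant learning
#' rate schedule (factor-10 drops at epochs `ceiling(epochs * k/4)`,
#' k = 1, 2, 3) and mean-squared-error loss. Identical seeds and data
#' give bit-identical trained weights.
#'
#' @param model an untrained (or previously trained) [RusCnn-class].
#' @param x input matrix from [cnnInputMatrix()] (1202 x N) or a
#'   [RusSpectra-class].
#' @param y numeric RWC targets, length N.
#' @return the trained [RusCnn-class] with its loss trace.
#' @export
trainCnn <- function(model, x, y) {
  stopifnot(is(model, "RusCnn"))
  if (is(x, "RusSpectra")) x <- cnnInputMatrix(x)
  cfg <- model@config
  if (nrow(x) != cfg$n_channels * cfg$input_length)
    stop("shape error: input must be (n_channels * input_length) x N")
  if (ncol(x) != length(y) || length(y) == 0)
    stop("shape error: targets must match the number of samples")
  L <- cfg$input_length
  stats <- list(
    magMean = mean(x[seq_len(L), ]), magSd = max(sd(x[seq_len(L), ]), 1e-8),
    phaseMean = mean(x[L + seq_len(L), ]),
    phaseSd = max(sd(x[L + seq_len(L), ]), 1e-8)
  )
  xs <- .standardizeInput(x, stats)
  if (!model@trained) {
    ## start the (linear) regression head at the training-target mean,
    ## so early gradients reflect structure rather than a gross offset
    model@params$bf3[1] <- mean(y)
  }
  drops <- ceiling(cfg$epochs * seq_len(cfg$lr_drops) / (cfg$lr_drops + 1))
  fit <- cnn_train_cpp(model@params, model@bnStats, xs, as.numeric(y),
                       cfg, cfg$epochs, cfg$minibatch, cfg$initial_lr,
                       cfg$momentum, cfg$l2, as.integer(drops), cfg$seed)
  initialize(model, params = fit$params, bnStats = fit$bn,
             normStats = stats, trained = TRUE,
             lossTrace = as.numeric(fit$lossTrace))
}

#' @describeIn trainCnn predict RWC for new spectra (dropout
#'   disabled, batch-norm running statistics); values are reported
#'   unclamped.
#' @param object a trained [RusCnn-class].
#' @param newdata input matrix or [RusSpectra-class].
#' @export
setMethod("predict", "RusCnn", function(object, newdata) {
  if (!object@trained)
    stop("state error: model has not been trained")
  if (is(newdata, "RusSpectra")) newdata <- cnnInputMatrix(newdata)
  cfg <- object@config
  if (nrow(newdata) != cfg$n_channels * cfg$input_length)
    stop("shape error: input must be (n_channels * input_length) x N")
  xs <- .standardizeInput(newdata, object@normStats)
  as.numeric(cnn_predict_cpp(object@params, object@bnStats, xs, cfg))
})
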