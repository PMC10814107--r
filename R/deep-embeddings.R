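# Deep-learned feature backends. The five CNN architectures contribute
# fixed-length embeddings from their designated layers; any backend obeying
# the protocol (embed / predict_probabilities / layer_activations_and_gradients)
# plugs in, including the deterministic mock. Fine-tuning is transfer
# learning: the classification head is replaced to match the dataset's
# classes and trained with SGD + momentum under a stepped learning-rate
# schedule, selecting the best fold model by held-out accuracy.

ARCHITECTURES <- data.frame(
  name = c("densenet121", "efficientnet_b2", "inception_v3", "resnet50",
           "vgg19"),
  embedding_layer = c("final_norm", "global_avg_pool", "global_avg_pool",
                      "global_avg_pool", "fc_penultimate"),
  embedding_dim = c(1024L, 1408L, 2048L, 2048L, 4096L),
  stringsAsFactors = FALSE)

#' Architecture specification for deep feature extraction
#'
#' Names the extraction point and embedding length of each supported CNN:
#' DenseNet-121 reads the normalization layer after the last dense block
#' (1024 values); EfficientNet-b2, Inception-V3 and ResNet-50 read their
#' final average-pooling layers (1408, 2048 and 2048 values); VGG-19 reads
#' the last fully connected layer before the output (4096 values).
#'
#' @param name One of `"densenet121"`, `"efficientnet_b2"`, `"inception_v3"`,
#'   `"resnet50"`, `"vgg19"`.
#' @return An `architecture_spec` with `name`, `embedding_layer`,
#'   `embedding_dim`.
#' @export
architecture_spec <- function(name) {
  i <- match(name, ARCHITECTURES$name)
  if (is.na(i)) stop("unknown architecture: ", name, call. = FALSE)
  structure(as.list(ARCHITECTURES[i, ]), class = "architecture_spec")
}

#' Fine-tuning configuration
#'
#' Defaults mirror the transfer-learning protocol used throughout the
#' package: 10 epochs of SGD with momentum 0.9 under cross-entropy loss,
#' initial learning rate 0.01 decayed by 0.75 every 2 epochs, and 10-fold
#' cross-validated model selection.
#'
#' @param epochs Training epochs per fold.
#' @param initial_lr Initial learning rate.
#' @param lr_decay_factor Multiplicative decay applied every
#'   `lr_decay_every` epochs.
#' @param lr_decay_every Epoch period of the decay (0-based epochs; the rate
#'   drops at epochs 2, 4, ...).
#' @param momentum SGD momentum coefficient.
#' @param folds Cross-validation folds used to select the returned model.
#' @param seed Integer seed for fold assignment and head initialization.
#' @return A `fine_tune_config` object.
#' @export
fine_tune_config <- function(epochs = 10L, initial_lr = 0.01,
                             lr_decay_factor = 0.75, lr_decay_every = 2L,
                             momentum = 0.9, folds = 10L, seed = 1L) {
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  structure(list(epochs = as.integer(epochs), initial_lr = initial_lr,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every = as.integer(lr_decay_every),
                 momentum = momentum, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "fine_tune_config")
}

#' Learning rate at a given epoch
#'
#' Stepped schedule lr(e) = initial_lr * factor^floor(e / every) with 0-based
#' epoch index, so e.g. epoch 4 under the defaults gives 0.01 * 0.75^2.
#'
#' @param epoch 0-based epoch index (vectorized).
#' @param config A [fine_tune_config()].
#' @return Numeric learning rate(s).
#' @export
learning_rate_schedule <- function(epoch, config = fine_tune_config()) {
  config$initial_lr *
    config$lr_decay_factor^(epoch %/% config$lr_decay_every)
}

# Softmax-head training by full-batch SGD with momentum under cross-entropy.
# z = X W' / sqrt(d); returns the trained n_classes x d weight matrix.
train_softmax_head <- function(X, y, config, init_seed) {
  n_classes <- nlevels(y)
  d <- ncol(X)
  Y <- diag(n_classes)[as.integer(y), , drop = FALSE]
  W <- withr::with_seed(init_seed,
                        matrix(stats::rnorm(n_classes * d, sd = 0.01),
                               n_classes))
  V <- matrix(0, n_classes, d)
  for (e in seq_len(config$epochs) - 1L) {
    lr <- learning_rate_schedule(e, config)
    z <- X %*% t(W) / sqrt(d)
    z <- z - apply(z, 1, max)
    P <- exp(z); P <- P / rowSums(P)
    grad <- t(P - Y) %*% X / (nrow(X) * sqrt(d))
    V <- config$momentum * V - lr * grad
    W <- W + V
  }
  W
}

#' Fine-tune a backend's classification head on a labeled dataset
#'
#' Replaces the output head with one matching the dataset's class count and
#' trains it per fold on the backend's embeddings (transfer learning; the
#' embedding extractor is frozen). The fold model with the highest held-out
#' accuracy is returned, ties broken by earliest fold.
#'
#' @param backend A `classification_backend` with `pretrained = TRUE` (the
#'   deterministic [mock_backend()] satisfies this; a weightless real backend
#'   raises "backend unavailable").
#' @param dataset List with `images` (named list) and `labels` (factor).
#' @param config A [fine_tune_config()].
#' @return The fitted backend, whose `predict_probabilities` uses the trained
#'   head, with a `fit_report` (per-fold accuracy, chosen fold, learning-rate
#'   schedule).
#' @export
fine_tune_model <- function(backend, dataset, config = fine_tune_config()) {
  if (!isTRUE(backend$pretrained))
    stop("backend unavailable: no pretrained weights", call. = FALSE)
  y <- droplevels(as.factor(dataset$labels))
  if (nlevels(y) < 2L) stop("dataset must have at least 2 classes",
                            call. = FALSE)
  emb <- backend$embed(dataset$images)
  plan <- fold_plan(y, k = config$folds, seed = config$seed)

  fold_acc <- numeric(config$folds)
  heads <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    tr <- plan$assignment != f
    W <- train_softmax_head(emb[tr, , drop = FALSE], droplevels(y[tr]),
                            config, init_seed = config$seed + f)
    z <- emb[!tr, , drop = FALSE] %*% t(W)
    pred <- levels(y)[max.col(z, ties.method = "first")]
    fold_acc[f] <- mean(pred == as.character(y[!tr]))
    heads[[f]] <- W
  }
  best <- which.max(fold_acc) # which.max takes the earliest maximum

  fitted <- backend
  fitted$head <- heads[[best]]
  fitted$classes <- levels(y)
  fitted$predict_probabilities <- function(images) {
    backend$predict_probabilities(images, head = heads[[best]])
  }
  fitted$fit_report <- list(
    fold_accuracy = fold_acc, chosen_fold = best,
    lr_schedule = learning_rate_schedule(seq_len(config$epochs) - 1L, config))
  fitted
}

#' Extract a deep-embedding table from a backend
#'
#' @param backend A `classification_backend` matching `spec`.
#' @param images Named list of RGB rasters.
#' @param spec An [architecture_spec()].
#' @return Data frame with `image_id` plus `spec$embedding_dim` feature
#'   columns named `<arch>_<i>`, rows in input order.
#' @export
extract_embeddings <- function(backend, images, spec = backend$arch) {
  if (!identical(backend$arch$name, spec$name))
    stop("backend architecture does not match spec", call. = FALSE)
  emb <- backend$embed(images)
  if (ncol(emb) != spec$embedding_dim)
    stop(sprintf("embedding dimension %d does not match spec (%d)",
                 ncol(emb), spec$embedding_dim), call. = FALSE)
  out <- data.frame(image_id = names(images), emb,
                    row.names = NULL, check.names = FALSE)
  names(out)[-1] <- paste0(spec$name, "_", seq_len(spec$embedding_dim))
  out
}
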