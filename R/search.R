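# Classifier-agnostic two-round random hyperparameter search.
#
# The network itself is pluggable: a trainer is any function
# (config, train) -> predictor, where train = list(x, y) and the
# predictor maps a list of images to labels.  The harness samples
# configurations from a random space, trains and ranks them by overall
# accuracy on a held-out test set, and re-runs the top performers with
# image augmentations (random horizontal flip and brightness shift).
# A compact multinomial-logistic trainer is provided so the protocol can
# be exercised end-to-end on synthetic images.

#' Define a random hyperparameter space
#'
#' @param lr_range positive length-2 vector: log-uniform learning-rate
#'   bounds (default `c(1e-4, 1e-2)`).
#' @param batch_sizes integer choices (default 256/512/1024).
#' @param momentum numeric choices (default 0 and 0.9).
#' @param optimizers subset of `"gd"`, `"momentum"`, `"adam"`.
#' @return object of class `hyperParamSpace`.
#' @export
hyperParamSpace <- function(lr_range = c(1e-4, 1e-2),
                            batch_sizes = c(256L, 512L, 1024L),
                            momentum = c(0, 0.9),
                            optimizers = c("gd", "momentum", "adam")) {
  stopifnot(length(lr_range) == 2L, all(lr_range > 0),
            lr_range[1] <= lr_range[2],
            length(batch_sizes) > 0L, length(momentum) > 0L,
            length(optimizers) > 0L)
  out <- list(lr_range = lr_range, batch_sizes = batch_sizes,
              momentum = momentum, optimizers = optimizers)
  class(out) <- "hyperParamSpace"
  out
}

#' Sample one trial configuration from the space
#'
#' Learning rate is log-uniform within its bounds; categorical fields are
#' uniform over their choices.  Uses (and advances) the current RNG
#' state, so a fixed seed upstream yields an identical config sequence.
#'
#' @param space a `hyperParamSpace`.
#' @param trial_id identifier for the trial.
#' @return one-row data frame: `trial_id`, `lr`, `batch_size`,
#'   `momentum`, `optimizer`.
#' @export
sampleConfig <- function(space, trial_id = 1L) {
  stopifnot(inherits(space, "hyperParamSpace"))
  data.frame(
    trial_id = trial_id,
    lr = exp(runif(1, log(space$lr_range[1]), log(space$lr_range[2]))),
    batch_size = resample(space$batch_sizes, 1L),
    momentum = resample(space$momentum, 1L),
    optimizer = resample(space$optimizers, 1L),
    stringsAsFactors = FALSE
  )
}

#' Augment an image: random horizontal flip and brightness shift
#'
#' @param img numeric matrix with values in `[0, 1]`.
#' @param flip_prob probability of mirroring the image left-right.
#' @param brightness_delta half-width of the uniform brightness shift;
#'   output pixels are clipped back to `[0, 1]`.
#' @return augmented image matrix.
#' @export
augmentImage <- function(img, flip_prob = 0.5, brightness_delta = 0.1) {
  stopifnot(is.matrix(img))
  if (runif(1) < flip_prob) img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
  if (brightness_delta > 0)
    img <- img + runif(1, -brightness_delta, brightness_delta)
  pmin(pmax(img, 0), 1)
}

flatten <- function(x) do.call(rbind, lapply(x, as.vector))

predictorAccuracy <- function(predictor, set) {
  mean(predictor(set$x) == set$y)
}

#' Multinomial-logistic (softmax regression) trainer on raw pixels
#'
#' Returns a trainer honouring the harness contract: it reads the
#' config's learning rate, batch size, momentum and optimizer and fits a
#' linear softmax classifier on flattened pixels by mini-batch gradient
#' descent (plain, with momentum, or adaptive-moment).  Deliberately
#' small -- it stands in for the CNN so the search protocol itself can be
#' tested.
#'
#' @param epochs training epochs (default 60).
#' @return function `(config, train)` returning a predictor
#'   `function(x) labels`.
#' @export
softmaxTrainer <- function(epochs = 60L) {
  function(config, train) {
    F0 <- flatten(train$x)
    ctr <- colMeans(F0)  # centring conditions the gradient
    X <- cbind(1, sweep(F0, 2, ctr))
    labels <- sort(unique(train$y))
    Y <- outer(train$y, labels, "==") * 1
    n <- nrow(X); d <- ncol(X); k <- length(labels)
    W <- matrix(0, d, k)
    V <- M2 <- matrix(0, d, k)
    lr <- config$lr; bs <- min(config$batch_size, n)
    t <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (b in seq(1, n, by = bs)) {
        idx <- ord[b:min(b + bs - 1, n)]
        S <- X[idx, , drop = FALSE] %*% W
        S <- exp(S - apply(S, 1, max))
        P <- S / rowSums(S)
        G <- crossprod(X[idx, , drop = FALSE], P - Y[idx, , drop = FALSE]) /
          length(idx)
        t <- t + 1
        if (config$optimizer == "gd") {
          W <- W - lr * G
        } else if (config$optimizer == "momentum") {
          V <- config$momentum * V + G
          W <- W - lr * V
        } else {  # adam
          V <- 0.9 * V + 0.1 * G
          M2 <- 0.999 * M2 + 0.001 * G^2
          vhat <- V / (1 - 0.9^t)
          mhat <- M2 / (1 - 0.999^t)
          W <- W - lr * vhat / (sqrt(mhat) + 1e-8)
        }
      }
    }
    function(x) {
      S <- cbind(1, sweep(flatten(x), 2, ctr)) %*% W
      labels[max.col(S, ties.method = "first")]
    }
  }
}

#' Train and rank one round of trial configurations
#'
#' Trains each configuration with the supplied trainer (optionally on
#' augmented copies of the training images), scores training, validation
#' and test overall accuracy plus test macro-F1, and ranks trials by test
#' OA (ties broken by validation accuracy, then trial id).  A failing
#' trainer marks its trial failed and excludes it from the ranking.
#' Only training data ever reach the trainer.
#'
#' @param trainer function `(config, train)` -> predictor.
#' @param configs data frame of trial configurations (see
#'   [sampleConfig()]).
#' @param data list with `train`, `validation`, `test`, each a
#'   `list(x, y)` of disjoint image sets.
#' @param augmented apply [augmentImage()] to the training images first?
#' @return data frame of class `trialResults`, ranked: `trial_id`, the
#'   config fields, `augmented`, `train_acc`, `validation_acc`,
#'   `test_oa`, `macro_f1`, `failed`.
#' @export
runRound <- function(trainer, configs, data, augmented = FALSE) {
  stopifnot(is.function(trainer), is.data.frame(configs),
            all(c("train", "validation", "test") %in% names(data)))
  rows <- lapply(seq_len(nrow(configs)), function(i) {
    cfg <- configs[i, , drop = FALSE]
    train <- data$train
    if (augmented) train <- list(x = lapply(train$x, augmentImage),
                                 y = train$y)
    res <- try(trainer(cfg, train), silent = TRUE)
    if (inherits(res, "try-error")) {
      cbind(cfg, augmented = augmented, train_acc = NA_real_,
            validation_acc = NA_real_, test_oa = NA_real_,
            macro_f1 = NA_real_, failed = TRUE)
    } else {
      pred_test <- res(data$test$x)
      mf1 <- evaluate(confusion(data.frame(true_label = data$test$y,
                                           pred_label = pred_test)))$macro_f1
      cbind(cfg, augmented = augmented,
            train_acc = predictorAccuracy(res, data$train),
            validation_acc = predictorAccuracy(res, data$validation),
            test_oa = mean(pred_test == data$test$y),
            macro_f1 = mf1, failed = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  ok <- out[!out$failed, , drop = FALSE]
  ok <- ok[order(-ok$test_oa, -ok$validation_acc, ok$trial_id), ,
           drop = FALSE]
  out <- rbind(ok, out[out$failed, , drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("trialResults", "data.frame")
  out
}

#' Two-round random hyperparameter-search protocol
#'
#' Round 1 samples `n_round1` configurations and trains them without
#' augmentation; the top `top_k` by test overall accuracy are re-run with
#' image augmentations, and the round-2 leader is the overall best.
#' Fully deterministic given `seed`, the trainer and the data.
#'
#' @param trainer function `(config, train)` -> predictor.
#' @param space a `hyperParamSpace`.
#' @param data list with disjoint `train`, `validation`, `test` sets.
#' @param n_round1 number of round-1 trials (must be >= `top_k`).
#' @param top_k finalists re-run with augmentation (default 5).
#' @param seed integer RNG seed.
#' @return list with `best` (one-row data frame), `round1`, `round2`
#'   (ranked `trialResults`) and `report` (all `n_round1 + top_k` trial
#'   rows).
#' @export
twoRoundProtocol <- function(trainer, space, data, n_round1, top_k = 5L,
                             seed = 1L) {
  stopifnot(n_round1 >= top_k, top_k >= 1L)
  withSeed(seed, {
    configs <- do.call(rbind, lapply(seq_len(n_round1),
                                     function(i) sampleConfig(space, i)))
    round1 <- runRound(trainer, configs, data, augmented = FALSE)
    finalists <- head(round1[!round1$failed, , drop = FALSE], top_k)
    cfg_cols <- c("trial_id", "lr", "batch_size", "momentum", "optimizer")
    round2 <- runRound(trainer, finalists[cfg_cols], data, augmented = TRUE)
    best <- round2[!round2$failed, , drop = FALSE][1, , drop = FALSE]
    list(best = best, round1 = round1, round2 = round2,
         report = rbind(round1, round2))
  })
}
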