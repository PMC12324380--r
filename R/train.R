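#' Training configuration
#'
#' Defaults are the full-scale training recipe: Adam with
#' learning rate 1e-4, L2 weight penalty 1e-4 applied inside the gradient
#' (the optimizer's classic weight-decay flavor, recorded in the manifest),
#' mini-batches of 32, 200 epochs, mean-squared-error loss on the 1-5 score
#' scale, and a 10% held-out validation fraction. No learning-rate schedule.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty coefficient.
#' @param batch_size Mini-batch size.
#' @param epochs Number of passes over the training set.
#' @param validation_fraction Fraction held out by [split_dataset()].
#' @param seed Integer seed controlling weight init and data order.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 1e-4, weight_decay = 1e-4,
                            batch_size = 32L, epochs = 200L,
                            validation_fraction = 0.10, seed = 1L) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1,
            epochs >= 1, validation_fraction > 0, validation_fraction <= 0.5)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 validation_fraction = validation_fraction, seed = as.integer(seed)),
            class = "training_config")
}

#' Bundle images, features and labels into a scorer dataset
#'
#' @param images List of square numeric matrices, all the same size.
#' @param features 6 x n matrix in [feature_names()] order (e.g. from
#'   [records_to_features()]).
#' @param labels Numeric scores on the 1-5 scale (or `NA` for unlabeled).
#' @return A `scorer_dataset` list.
#' @export
scorer_dataset <- function(images, features, labels = rep(NA_real_, length(images))) {
  n <- length(images)
  stopifnot(n >= 1L, ncol(features) == n, length(labels) == n)
  d <- dim(images[[1]])
  if (d[1] != d[2]) stop("dataset images must be square")
  if (!all(vapply(images, function(m) identical(dim(m), d), TRUE)))
    stop("all dataset images must share one size")
  structure(list(images = images, features = features, labels = as.numeric(labels),
                 side = d[1]), class = "scorer_dataset")
}

subset_dataset <- function(ds, idx) {
  scorer_dataset(ds$images[idx], ds$features[, idx, drop = FALSE], ds$labels[idx])
}

#' Split a labeled dataset into training and validation subsets
#'
#' Draws a seeded random validation subset of size `round(fraction * n)`;
#' train and validation are disjoint and exhaustive, and the same seed always
#' yields the same split.
#'
#' @param dataset A `scorer_dataset` with at least 10 records.
#' @param fraction Validation fraction in (0, 0.5].
#' @param seed Integer seed.
#' @return List with `train` and `validation` datasets plus the index
#'   vectors `train_idx`, `validation_idx`.
#' @export
split_dataset <- function(dataset, fraction = 0.10, seed = 1L) {
  stopifnot(inherits(dataset, "scorer_dataset"), fraction > 0, fraction <= 0.5)
  n <- length(dataset$images)
  if (n < 10L) stop("need at least 10 labeled records to split; got ", n)
  n_val <- max(1L, round(fraction * n))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  val_idx <- sort(sample.int(n, n_val))
  train_idx <- setdiff(seq_len(n), val_idx)
  list(train = subset_dataset(dataset, train_idx),
       validation = subset_dataset(dataset, val_idx),
       train_idx = train_idx, validation_idx = val_idx)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zero <- lapply(params, function(p) { p[] <- 0; p })
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# ---- training ---------------------------------------------------------------

#' Train the scorer on a labeled dataset
#'
#' Minimizes the mean squared error between the predicted score and the
#' numeric label with Adam, in shuffled mini-batches with batch normalization
#' active. Fully seeded: weight initialization and the per-epoch data order
#' both derive from `config$seed`, so identical configs reproduce identical
#' loss traces on CPU. A trailing mini-batch of size 1 is merged into the
#' previous batch (batch statistics need at least 2 images). Feature
#' standardization statistics (per-feature mean and sd over the training set)
#' are computed here and frozen into the returned manifest, along with the
#' canonical image side (the training image size).
#'
#' @param model A `scorer_model` (weights are re-initialized from the seed).
#' @param dataset A labeled `scorer_dataset` (no `NA` labels, finite features).
#' @param config A [training_config()].
#' @return List: `model` (trained), `manifest` ([scorer_manifest()]), `loss`
#'   (per-epoch mean training MSE), `n_batches` (batches per epoch).
#' @export
train_scorer <- function(model, dataset, config = training_config()) {
  stopifnot(inherits(model, "scorer_model"), inherits(dataset, "scorer_dataset"),
            inherits(config, "training_config"))
  n <- length(dataset$images)
  if (n < 2L) stop("training needs at least 2 records")
  if (anyNA(dataset$labels)) {
    bad <- which(is.na(dataset$labels))[1]
    stop("record ", bad, " has no label; every training record must be labeled")
  }
  if (any(!is.finite(dataset$features))) {
    bad <- which(colSums(!is.finite(dataset$features)) > 0)[1]
    stop("record ", bad, " has a non-finite feature vector")
  }

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  model <- model_init(model)

  f_mean <- rowMeans(dataset$features)
  f_sd <- apply(dataset$features, 1, stats::sd)
  f_sd[f_sd < 1e-12] <- 1
  names(f_mean) <- names(f_sd) <- feature_names()
  feats <- (dataset$features - f_mean) / f_sd
  imgs <- lapply(dataset$images, normalize_image)
  y <- dataset$labels

  params <- model_params(model)
  opt <- adam_init(params)
  batches <- .make_batches(n, config$batch_size)
  loss_trace <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (b in batches) {
      idx <- ord[b]
      x <- images_to_batch(imgs[idx])
      fw <- model_forward(model, x, feats[, idx, drop = FALSE], training = TRUE)
      model <- fw$model
      err <- fw$scores - y[idx]
      ep_loss <- ep_loss + sum(err^2)
      grads <- model_backward(model, fw$caches, 2 * err / length(idx))
      upd <- adam_step(params, grads, opt, config$learning_rate, config$weight_decay)
      params <- upd$params; opt <- upd$state
      model <- model_set_params(model, params)
    }
    loss_trace[epoch] <- ep_loss / n
  }

  manifest <- scorer_manifest(model, f_mean, f_sd,
                              canonical_side = dataset$side, seed = config$seed)
  list(model = model, manifest = manifest, loss = loss_trace,
       n_batches = length(batches))
}

.make_batches <- function(n, batch_size) {
  starts <- seq(1L, n, by = batch_size)
  batches <- lapply(starts, function(s) s:min(s + batch_size - 1L, n))
  k <- length(batches)
  if (k > 1L && length(batches[[k]]) == 1L) {
    batches[[k - 1L]] <- c(batches[[k - 1L]], batches[[k]])
    batches[[k]] <- NULL
  }
  batches
}

#' Predict scores for a dataset
#'
#' Inference-mode forward passes through [score_batch()], i.e. with the
#' manifest's canonicalization and normalization conventions.
#'
#' @param model A trained `scorer_model`.
#' @param manifest Its manifest.
#' @param dataset A `scorer_dataset`.
#' @return Numeric scores.
#' @export
predict_scores <- function(model, manifest, dataset) {
  score_batch(model, dataset$images, dataset$features, manifest)
}

#' Evaluate a trained scorer on a labeled dataset
#'
#' Reports the MSE on the native 1-5 score scale, the MSE after converting
#' both predictions and labels to the 0-1 bin scale with [score_to_bin()]
#' (when every value lies inside [1, 5] the two differ exactly by the factor
#' 16 of the affine map), and a 10 x 10 confusion summary of counts over
#' binned deciles of (true, predicted).
#'
#' @param model A trained `scorer_model`.
#' @param manifest Its manifest.
#' @param dataset A labeled `scorer_dataset`.
#' @return List: `mse`, `binned_mse`, `confusion` (10 x 10 count matrix,
#'   rows = true decile, columns = predicted decile), `n`, `predictions`.
#' @export
evaluate_scorer <- function(model, manifest, dataset) {
  stopifnot(length(dataset$images) >= 1L, !anyNA(dataset$labels))
  pred <- predict_scores(model, manifest, dataset)
  y <- dataset$labels
  mse <- mean((pred - y)^2)
  bp <- score_to_bin(pred); by <- score_to_bin(y)
  binned_mse <- mean((bp - by)^2)
  decile <- function(v) pmin(pmax(ceiling(v * 10), 1L), 10L)
  confusion <- matrix(0L, 10, 10,
                      dimnames = list(true = 1:10, predicted = 1:10))
  for (i in seq_along(y))
    confusion[decile(by[i]), decile(bp[i])] <- confusion[decile(by[i]), decile(bp[i])] + 1L
  list(mse = mse, binned_mse = binned_mse, confusion = confusion,
       n = length(y), predictions = pred)
}
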