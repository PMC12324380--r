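#' Architecture configuration for the 2D class-average scorer
#'
#' The scorer is a residual CNN over a single-channel class-average image,
#' fused with six physical metadata features. The convolutional trunk opens
#' with a 3x3 stem convolution, then a sequence of stages. Each stage is
#' entered through a pair of 2x2 stride-2 convolutions (learned downsampling
#' in place of pooling) followed by `blocks_per_stage` residual blocks at the
#' stage width. Batch normalization follows every convolution. The trunk ends
#' in adaptive average pooling to a fixed `pool_side` x `pool_side` grid, so
#' any square input with side >= `min_side` yields the same flattened length.
#' Pooled activations are concatenated with the standardized feature vector
#' and passed through a two-layer regression head emitting one unbounded
#' score (1 = best, 5 = worst on the training scale, open at both ends).
#'
#' @param stem Channels produced by the stem convolution.
#' @param stages Integer vector of channel widths, one per stage.
#' @param blocks_per_stage Residual blocks per stage (>= 1).
#' @param hidden Width of the hidden layer in the regression head.
#' @param pool_side Side of the adaptive-average-pooling output grid.
#' @param min_side Minimum accepted input image side, in pixels.
#' @param n_features Number of metadata features fused into the head.
#' @return A `scorer_config` list.
#' @examples
#' cfg <- scorer_config(stem = 8, stages = c(16, 32), blocks_per_stage = 1)
#' @export
scorer_config <- function(stem = 32L, stages = c(32L, 64L, 128L, 256L),
                          blocks_per_stage = 2L, hidden = 128L,
                          pool_side = 6L, min_side = 31L, n_features = 6L) {
  stopifnot(stem >= 1, all(stages >= 1), blocks_per_stage >= 1,
            hidden >= 1, pool_side >= 1, min_side >= 1)
  structure(list(stem = as.integer(stem), stages = as.integer(stages),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 hidden = as.integer(hidden), pool_side = as.integer(pool_side),
                 min_side = as.integer(min_side), n_features = as.integer(n_features)),
            class = "scorer_config")
}

#' Reduced configuration for CPU-scale experiments
#'
#' A small scorer (8-channel stem, two stages of 16 and 32 channels, one
#' residual block each, 32-unit head) suitable for training on synthetic
#' corpora on a single CPU core in minutes.
#'
#' @return A `scorer_config` list.
#' @export
scorer_config_small <- function() {
  scorer_config(stem = 8L, stages = c(16L, 32L), blocks_per_stage = 1L, hidden = 32L)
}

#' Build the residual scorer network
#'
#' Constructs all layers and initializes weights (He-normal) from the current
#' RNG stream; call `set.seed()` first for reproducible initialization.
#'
#' @param config A [scorer_config()].
#' @return A `scorer_model` list with the trunk, head, and config.
#' @export
build_model <- function(config = scorer_config()) {
  stopifnot(inherits(config, "scorer_config"))
  trunk <- list(stem_conv = nn_conv(1L, config$stem, 3L),
                stem_bn = nn_bn(config$stem), stem_relu = nn_relu())
  prev <- config$stem
  for (s in seq_along(config$stages)) {
    ch <- config$stages[s]
    trunk[[sprintf("s%d_down1", s)]] <- nn_conv(prev, ch, 2L, stride = 2L, pad_mode = "down")
    trunk[[sprintf("s%d_down1_bn", s)]] <- nn_bn(ch)
    trunk[[sprintf("s%d_down1_relu", s)]] <- nn_relu()
    trunk[[sprintf("s%d_down2", s)]] <- nn_conv(ch, ch, 2L, stride = 2L, pad_mode = "down")
    trunk[[sprintf("s%d_down2_bn", s)]] <- nn_bn(ch)
    trunk[[sprintf("s%d_down2_relu", s)]] <- nn_relu()
    for (b in seq_len(config$blocks_per_stage))
      trunk[[sprintf("s%d_block%d", s, b)]] <- nn_resblock(ch)
    prev <- ch
  }
  trunk$pool <- nn_pool_adapt(config$pool_side)
  n_flat <- prev * config$pool_side^2
  head <- list(fc1 = nn_dense(n_flat + config$n_features, config$hidden),
               fc1_relu = nn_relu(), fc2 = nn_dense(config$hidden, 1L))
  model <- structure(list(config = config, trunk = trunk, head = head,
                          n_flat = n_flat), class = "scorer_model")
  model_init(model)
}

# Re-initialize every weight from the current RNG stream.
model_init <- function(model) {
  model$trunk <- lapply(model$trunk, layer_init)
  model$head <- lapply(model$head, layer_init)
  model
}

#' @export
print.scorer_model <- function(x, ...) {
  p <- model_params(x)
  cat(sprintf("<scorer_model> stem %d | stages %s | %d block(s)/stage | %s parameters\n",
              x$config$stem, paste(x$config$stages, collapse = "-"),
              x$config$blocks_per_stage,
              format(sum(vapply(p, length, 1L)), big.mark = ",")))
  invisible(x)
}

# ---- forward / backward -----------------------------------------------------

# Stack a list of equally sized image matrices into an (H, W, 1, N) array.
images_to_batch <- function(images) {
  if (is.matrix(images)) images <- list(images)
  d <- dim(images[[1]])
  if (!all(vapply(images, function(m) identical(dim(m), d), TRUE)))
    stop("all images in one batch must share the same dimensions")
  array(unlist(images, use.names = FALSE), dim = c(d[1], d[2], 1L, length(images)))
}

# Forward pass. x: (H, W, 1, N) array; feats: n_features x N matrix of
# already-standardized features. Returns scores plus caches for backward and
# the model with refreshed batch-norm running statistics.
model_forward <- function(model, x, feats, training = FALSE) {
  d <- dim(x)
  if (d[1] != d[2]) stop("scorer input images must be square")
  if (d[1] < model$config$min_side)
    stop(sprintf("input side %d is below the %d-pixel minimum", d[1], model$config$min_side))
  if (!is.matrix(feats) || nrow(feats) != model$config$n_features || ncol(feats) != d[4])
    stop(sprintf("feature matrix must be %d x %d", model$config$n_features, d[4]))

  caches <- vector("list", length(model$trunk)); names(caches) <- names(model$trunk)
  for (nm in names(model$trunk)) {
    f <- layer_forward(model$trunk[[nm]], x, training)
    model$trunk[[nm]] <- f$layer; caches[[nm]] <- f$cache; x <- f$out
  }
  pooled_dim <- dim(x)[1:2]
  flat <- matrix(x, model$n_flat, d[4])
  inp <- rbind(flat, feats)
  hcaches <- vector("list", length(model$head)); names(hcaches) <- names(model$head)
  h <- inp
  for (nm in names(model$head)) {
    f <- layer_forward(model$head[[nm]], h, training)
    model$head[[nm]] <- f$layer; hcaches[[nm]] <- f$cache; h <- f$out
  }
  list(scores = as.numeric(h), model = model, pooled_dim = pooled_dim,
       caches = list(trunk = caches, head = hcaches,
                     pooled_shape = c(pooled_dim, dim(flat))))
}

# Backward pass from dL/dscore (length-N vector); returns grads named
# "<layer>/<param>" matching model_params().
model_backward <- function(model, caches, gscores) {
  g <- matrix(gscores, 1L)
  grads <- list()
  for (nm in rev(names(model$head))) {
    b <- layer_backward(model$head[[nm]], caches$head[[nm]], g)
    for (pn in names(b$grads)) grads[[paste0(nm, "/", pn)]] <- b$grads[[pn]]
    g <- b$gin
  }
  g <- g[seq_len(model$n_flat), , drop = FALSE]  # drop feature rows
  S <- model$config$pool_side
  dim(g) <- c(S, S, model$n_flat %/% S^2, ncol(g))
  trunk_names <- names(model$trunk)
  for (nm in rev(trunk_names)) {
    b <- layer_backward(model$trunk[[nm]], caches$trunk[[nm]], g,
                        need_gin = !identical(nm, trunk_names[1]))
    for (pn in names(b$grads)) grads[[paste0(nm, "/", pn)]] <- b$grads[[pn]]
    g <- b$gin
  }
  grads
}

# ---- flat parameter access --------------------------------------------------

model_params <- function(model) {
  out <- list()
  for (part in c("trunk", "head"))
    for (nm in names(model[[part]])) {
      p <- layer_params(model[[part]][[nm]])
      if (length(p)) {
        names(p) <- paste0(nm, "/", names(p))
        out <- c(out, p)
      }
    }
  out
}

model_set_params <- function(model, params) {
  for (part in c("trunk", "head"))
    for (nm in names(model[[part]])) {
      idx <- startsWith(names(params), paste0(nm, "/"))
      if (!any(idx)) next
      sub <- params[idx]
      names(sub) <- sub("^[^/]+/", "", names(sub))
      model[[part]][[nm]] <- layer_set_params(model[[part]][[nm]], sub)
    }
  model
}

# ---- manifest, scoring, persistence -----------------------------------------

#' Feature names in their fixed fusion order
#' @return Character vector of length 6.
#' @export
feature_names <- function() {
  c("pixel_size", "frc_resolution", "class_distribution",
    "dev_mean", "dev_median", "dev_mode")
}

#' Build a model manifest
#'
#' The manifest records everything inference needs to reproduce training-time
#' conventions: per-feature standardization statistics, the canonical image
#' side used at scoring time, the intensity-normalization convention, the
#' grade-letter mapping, the training seed and a weight checksum.
#'
#' @param model A `scorer_model`.
#' @param feature_mean,feature_sd Named numeric vectors over [feature_names()].
#' @param canonical_side Image side every scored image is brought to.
#' @param seed Training seed recorded for provenance.
#' @return A `scorer_manifest` list.
#' @export
scorer_manifest <- function(model, feature_mean, feature_sd,
                            canonical_side = 210L, seed = NA_integer_) {
  fn <- feature_names()
  if (!all(fn %in% names(feature_mean)) || !all(fn %in% names(feature_sd)))
    stop("feature_mean and feature_sd must be named over all of: ",
         paste(fn, collapse = ", "))
  structure(list(
    feature_names = fn,
    feature_mean = feature_mean[fn], feature_sd = feature_sd[fn],
    canonical_side = as.integer(canonical_side),
    normalization = "zscore-after-canonicalization",
    frc_unit = "angstrom",
    grade_map = c(A = 1, B = 2, C = 3, D = 4, F = 5),
    score_scale = c(best = 1, worst = 5),
    seed = as.integer(seed),
    checksum = model_checksum(model)), class = "scorer_manifest")
}

model_checksum <- function(model) {
  v <- unlist(model_params(model), use.names = FALSE)
  c(n = length(v), sum = sum(v), sumsq = sum(v^2))
}

standardize_features <- function(feats, manifest) {
  if (is.null(manifest$feature_mean) || is.null(manifest$feature_sd) ||
      anyNA(manifest$feature_mean) || anyNA(manifest$feature_sd))
    stop("manifest is missing feature standardization statistics; ",
         "refusing to score unstandardized features")
  (feats - manifest$feature_mean[feature_names()]) /
    pmax(manifest$feature_sd[feature_names()], 1e-12)
}

#' Score one class average
#'
#' Canonicalizes the image to the manifest's frame (zero-pad or Fourier-crop),
#' z-score normalizes it, standardizes the feature vector with the manifest's
#' training statistics, and runs the network in inference mode (fixed
#' batch-norm statistics), so repeated calls are bitwise identical. The
#' returned score is an unbounded real: 1 is the best training anchor, 5 the
#' worst, and inputs outside the training range may score outside [1, 5].
#'
#' @param model A trained `scorer_model`.
#' @param image Square numeric matrix (side >= 31).
#' @param features Numeric vector of the six features, in [feature_names()]
#'   order (names, if present, are checked).
#' @param manifest The [scorer_manifest()] saved with the model.
#' @return A single numeric score.
#' @export
score_class <- function(model, image, features, manifest) {
  score_batch(model, list(image), matrix(features, ncol = 1), manifest)
}

#' Score a batch of class averages
#'
#' @param model A trained `scorer_model`.
#' @param images List of square numeric matrices.
#' @param features 6 x n matrix, columns in the same order as `images`.
#' @param manifest The model's [scorer_manifest()].
#' @param chunk Number of images scored per forward pass.
#' @return Numeric vector of scores, one per image.
#' @export
score_batch <- function(model, images, features, manifest, chunk = 16L) {
  stopifnot(inherits(manifest, "scorer_manifest"))
  if (!is.matrix(features)) features <- matrix(features, ncol = length(images))
  if (!is.null(rownames(features)) &&
      !identical(rownames(features), feature_names()))
    stop("feature rows must follow feature_names() order")
  n <- length(images)
  stopifnot(ncol(features) == n)
  canon <- lapply(images, function(im)
    normalize_image(canonicalize(im, side = manifest$canonical_side)$pixels))
  feats <- apply(features, 2, standardize_features, manifest = manifest)
  feats <- matrix(feats, nrow = length(feature_names()))
  out <- numeric(n)
  for (i0 in seq(1L, n, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, n)
    fw <- model_forward(model, images_to_batch(canon[idx]),
                        feats[, idx, drop = FALSE], training = FALSE)
    out[idx] <- fw$scores
  }
  out
}

#' Convert a quality score to the 0-1 bin scale
#'
#' Affine reversal onto the higher-is-better ranking scale used by other 2D
#' class rankers: 1.0 (best) maps to 1.0 and 5.0 (worst) to 0.0, i.e.
#' `(5 - score) / 4`, clamped to [0, 1] so out-of-range scores saturate.
#'
#' @param score Numeric vector of scores on the 1-5 scale (open-ended).
#' @return Numeric vector in [0, 1].
#' @examples
#' score_to_bin(c(1, 3, 5, 6.2))
#' @export
score_to_bin <- function(score) pmin(1, pmax(0, (5 - score) / 4))

#' Map grade letters to numeric scores
#'
#' The five-letter expert rubric (A best ... F unusable) maps onto the five
#' integer anchors of the 1-5 score scale: A=1, B=2, C=3, D=4, F=5.
#'
#' @param grades Character vector of grades in A, B, C, D, F.
#' @return Numeric scores.
#' @export
grade_to_score <- function(grades) {
  map <- c(A = 1, B = 2, C = 3, D = 4, F = 5)
  bad <- !(grades %in% names(map))
  if (any(bad)) stop("unknown grade letter(s): ", paste(unique(grades[bad]), collapse = ", "))
  unname(map[grades])
}

#' Save a trained scorer and its manifest to one JSON file
#'
#' Weights are written at full double precision; the manifest checksum is
#' re-verified on load.
#'
#' @param model A `scorer_model`.
#' @param manifest Its [scorer_manifest()].
#' @param path Output file path (.json).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, manifest, path) {
  params <- model_params(model)
  ser <- lapply(params, function(p) list(dim = dim(p) %||% length(p), data = as.numeric(p)))
  bn <- list()
  for (part in c("trunk", "head"))
    for (nm in names(model[[part]]))
      bn <- c(bn, .bn_buffers(model[[part]][[nm]], nm))
  payload <- list(format = "cryograder-model-v1",
                  config = unclass(model$config),
                  manifest = unclass(manifest),
                  params = ser, bn_buffers = bn)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

.bn_buffers <- function(layer, prefix) {
  if (layer$type == "bn")
    return(stats::setNames(list(list(mean = layer$running_mean, var = layer$running_var)),
                           prefix))
  if (layer$type == "block") {
    out <- list()
    for (nm in c("bn1", "bn2"))
      out <- c(out, .bn_buffers(layer[[nm]], paste0(prefix, ".", nm)))
    return(out)
  }
  list()
}

.bn_restore <- function(layer, prefix, buffers) {
  if (layer$type == "bn" && prefix %in% names(buffers)) {
    layer$running_mean <- as.numeric(buffers[[prefix]]$mean)
    layer$running_var <- as.numeric(buffers[[prefix]]$var)
  } else if (layer$type == "block") {
    for (nm in c("bn1", "bn2"))
      layer[[nm]] <- .bn_restore(layer[[nm]], paste0(prefix, ".", nm), buffers)
  }
  layer
}

#' Load a scorer saved by [save_model()]
#'
#' @param path Path to the JSON file.
#' @return List with elements `model` and `manifest`.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (!identical(payload$format, "cryograder-model-v1"))
    stop("not a cryograder model file: ", path)
  cfg <- do.call(scorer_config, payload$config[
    c("stem", "stages", "blocks_per_stage", "hidden", "pool_side", "min_side", "n_features")])
  model <- build_model(cfg)
  params <- lapply(payload$params, function(p) {
    v <- as.numeric(p$data)
    if (length(p$dim) > 1L) dim(v) <- as.integer(p$dim)
    v
  })
  model <- model_set_params(model, params)
  for (part in c("trunk", "head"))
    for (nm in names(model[[part]]))
      model[[part]][[nm]] <- .bn_restore(model[[part]][[nm]], nm, payload$bn_buffers)
  man <- payload$manifest
  fn <- as.character(man$feature_names)
  manifest <- structure(list(
    feature_names = fn,
    feature_mean = stats::setNames(as.numeric(unlist(man$feature_mean)), fn),
    feature_sd = stats::setNames(as.numeric(unlist(man$feature_sd)), fn),
    canonical_side = as.integer(man$canonical_side),
    normalization = man$normalization, frc_unit = man$frc_unit,
    grade_map = stats::setNames(as.numeric(unlist(man$grade_map)),
                                c("A", "B", "C", "D", "F")),
    score_scale = stats::setNames(as.numeric(unlist(man$score_scale)),
                                  c("best", "worst")),
    seed = suppressWarnings(as.integer(man$seed)),
    checksum = stats::setNames(as.numeric(unlist(man$checksum)),
                               c("n", "sum", "sumsq"))),
    class = "scorer_manifest")
  got <- model_checksum(model)
  if (got["n"] != manifest$checksum["n"] ||
      abs(got["sum"] - manifest$checksum["sum"]) > 1e-6 * (1 + abs(manifest$checksum["sum"])) ||
      abs(got["sumsq"] - manifest$checksum["sumsq"]) > 1e-6 * (1 + manifest$checksum["sumsq"]))
    stop("model checksum mismatch: weights in ", path, " are corrupt")
  list(model = model, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
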