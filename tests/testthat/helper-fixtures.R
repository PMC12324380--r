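# Shared fixtures: everything is generated in code at test time.

# A tiny network that exercises every layer type but runs in milliseconds.
tiny_model <- function(seed = 42, min_side = 8L) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  build_model(scorer_config(stem = 2L, stages = c(3L, 4L), blocks_per_stage = 1L,
                            hidden = 4L, min_side = min_side))
}

tiny_manifest <- function(model, side = 64L) {
  mu <- stats::setNames(rep(0, 6), feature_names())
  sd1 <- stats::setNames(rep(1, 6), feature_names())
  scorer_manifest(model, mu, sd1, canonical_side = side)
}

# Sparse-signal image: n_sig pixels at `hi` on a `lo` background.
sparse_image <- function(side = 100L, n_sig = 10L, hi = 100, lo = 0) {
  img <- matrix(lo, side, side)
  img[seq_len(n_sig)] <- hi
  img
}

# Small labeled synthetic dataset for fast training tests.
quick_dataset <- function(n = 60, side = 32L, seed = 7) {
  gen <- generate_stack(synthetic_spec(n, image_side = side, seed = seed))
  synthetic_dataset(gen)
}
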