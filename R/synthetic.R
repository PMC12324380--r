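# Synthetic graded class averages.
#
# Each class is a Gaussian-blob phantom (a stand-in for a projected particle)
# degraded according to its quality grade: worse grades get a stronger
# low-pass (blurrier detail) and more additive Gaussian noise. Grades 1-5
# mirror the five-letter expert rubric (1 = best ... 5 = unusable). Two
# half-set noise realizations per class support an FRC-based resolution
# estimate exactly as half-set refinement would provide; class-distribution
# fractions come from a flat Dirichlet draw; per-class "true" masses make the
# intensity-to-mass calibration testable end to end.

#' Specification for a synthetic graded class-average dataset
#'
#' Defaults emulate a desk-scale 2D classification job: 64-px boxes at
#' 1 Angstrom/px, unit-amplitude phantoms of 3-7 blobs, a geometric
#' per-grade noise ladder (sd 0.02, 0.08, 0.25, 0.70, 2.0 -- real class
#' quality spans orders of magnitude in SNR, and a grade-5 class is noise
#' dominated) and Gaussian low-pass cutoffs (0.95, 0.75, 0.55, 0.35, 0.18)
#' of Nyquist, both monotone in grade. Regeneration with the same spec is
#' bit-identical.
#'
#' @param n_classes Number of classes.
#' @param grades Integer vector in 1..5, recycled to `n_classes`; default
#'   cycles through all five grades.
#' @param image_side Image side in pixels.
#' @param pixel_size Pixel size in Angstrom/pixel.
#' @param noise_sd_by_grade Additive noise sd for grades 1..5 (increasing).
#' @param blur_by_grade Low-pass cutoff, as a fraction of Nyquist, for
#'   grades 1..5 (decreasing).
#' @param n_blobs_range Range of blobs per phantom.
#' @param mass_slope True kDa per (intensity * Angstrom^2) used to assign
#'   known masses.
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_classes, grades = NULL, image_side = 64L,
                           pixel_size = 1.0,
                           noise_sd_by_grade = c(0.02, 0.08, 0.25, 0.70, 2.00),
                           blur_by_grade = c(0.95, 0.75, 0.55, 0.35, 0.18),
                           n_blobs_range = c(3L, 7L), mass_slope = 0.005,
                           seed = 1L) {
  if (is.null(grades)) grades <- rep_len(1:5, n_classes)
  grades <- as.integer(rep_len(grades, n_classes))
  stopifnot(all(grades %in% 1:5), image_side >= 8, pixel_size > 0,
            length(noise_sd_by_grade) == 5, length(blur_by_grade) == 5,
            mass_slope > 0)
  if (is.unsorted(noise_sd_by_grade) || is.unsorted(rev(blur_by_grade)))
    stop("noise must increase and the low-pass cutoff decrease with grade")
  structure(list(n_classes = as.integer(n_classes), grades = grades,
                 image_side = as.integer(image_side), pixel_size = pixel_size,
                 noise_sd_by_grade = noise_sd_by_grade,
                 blur_by_grade = blur_by_grade,
                 n_blobs_range = as.integer(n_blobs_range),
                 mass_slope = mass_slope, seed = as.integer(seed)),
            class = "synthetic_spec")
}

.blob_phantom <- function(side, n_blobs) {
  # blob centers inside the central half, widths 4-12% of the side
  cx <- stats::runif(n_blobs, 0.3 * side, 0.7 * side)
  cy <- stats::runif(n_blobs, 0.3 * side, 0.7 * side)
  w <- stats::runif(n_blobs, 0.04 * side, 0.12 * side)
  a <- stats::runif(n_blobs, 0.5, 1)
  xs <- matrix(seq_len(side), side, side)
  ys <- t(xs)
  img <- matrix(0, side, side)
  for (b in seq_len(n_blobs))
    img <- img + a[b] * exp(-((xs - cx[b])^2 + (ys - cy[b])^2) / (2 * w[b]^2))
  img
}

# Gaussian low-pass: attenuate |f| with sd = cutoff_frac * Nyquist.
.lowpass <- function(img, cutoff_frac) {
  n <- nrow(img)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n    # cycles/px
  r2 <- outer(f^2, f^2, "+")
  H <- exp(-r2 / (2 * (cutoff_frac * 0.5)^2))
  Re(stats::fft(stats::fft(img) * H, inverse = TRUE)) / n^2
}

#' Fourier ring correlation between two images
#'
#' Correlation of the two Fourier transforms over rings of integer radius.
#'
#' @param img1,img2 Equally sized square numeric matrices.
#' @return Data frame with `radius` (pixels in Fourier space, 1..Nyquist)
#'   and `frc`.
#' @export
frc_curve <- function(img1, img2) {
  n <- nrow(img1)
  stopifnot(identical(dim(img1), dim(img2)), n == ncol(img1))
  F1 <- stats::fft(img1); F2 <- stats::fft(img2)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  r <- round(sqrt(outer(f^2, f^2, "+")))
  rmax <- n %/% 2
  num <- Re(F1 * Conj(F2)); p1 <- Mod(F1)^2; p2 <- Mod(F2)^2
  out <- vapply(seq_len(rmax), function(k) {
    ring <- r == k
    s <- sum(num[ring]); d <- sqrt(sum(p1[ring]) * sum(p2[ring]))
    if (d == 0) 0 else s / d
  }, numeric(1))
  data.frame(radius = seq_len(rmax), frc = out)
}

#' Resolution estimate from the FRC 0.143 crossing
#'
#' Returns the resolution in Angstrom at the first ring where the FRC drops
#' below the 0.143 threshold (half-set convention), with linear interpolation
#' between rings. If the curve never crosses, the Nyquist resolution
#' (2 * pixel_size) is returned.
#'
#' @param img1,img2 Half-set images.
#' @param pixel_size Pixel size in Angstrom/pixel.
#' @param threshold FRC threshold (default 0.143).
#' @return Resolution in Angstrom.
#' @export
frc_resolution <- function(img1, img2, pixel_size, threshold = 0.143) {
  curve <- frc_curve(img1, img2)
  n <- nrow(img1)
  below <- which(curve$frc < threshold)
  if (!length(below)) return(2 * pixel_size)
  k <- below[1]
  r_cross <- if (k == 1L) curve$radius[1] else {
    f0 <- curve$frc[k - 1L]; f1 <- curve$frc[k]
    curve$radius[k - 1L] + (f0 - threshold) / (f0 - f1)
  }
  n * pixel_size / r_cross
}

#' Generate a synthetic graded class-average dataset
#'
#' Produces one image per class (low-pass filtered phantom plus seeded
#' Gaussian noise, averaged from two half-set realizations), a metadata
#' record per class (pixel size, FRC resolution from the half-sets' 0.143
#' crossing, Dirichlet class distribution summing to 1, mass features from
#' the clean phantom), the ground-truth grade as the label, and the known
#' true mass for calibration tests.
#'
#' @param spec A [synthetic_spec()].
#' @return List: `stack` (`class_average_stack`), `records` (`class_records`
#'   data frame with mass-deviation columns, `label` = grade, `true_mass_kda`
#'   and `grade` columns), `phantoms` (clean images).
#' @export
generate_stack <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  n <- spec$n_classes; side <- spec$image_side
  images <- phantoms <- vector("list", n)
  res <- numeric(n)
  for (i in seq_len(n)) {
    g <- spec$grades[i]
    n_blobs <- sample(spec$n_blobs_range[1]:spec$n_blobs_range[2], 1L)
    clean <- .blob_phantom(side, n_blobs)
    blurred <- .lowpass(clean, spec$blur_by_grade[g])
    sd_half <- spec$noise_sd_by_grade[g] * sqrt(2)
    half1 <- blurred + matrix(stats::rnorm(side^2, sd = sd_half), side)
    half2 <- blurred + matrix(stats::rnorm(side^2, sd = sd_half), side)
    images[[i]] <- (half1 + half2) / 2
    phantoms[[i]] <- clean
    res[i] <- frc_resolution(half1, half2, spec$pixel_size)
  }
  distr <- stats::rgamma(n, shape = 1)
  distr <- distr / sum(distr)

  intensities <- vapply(phantoms, summed_intensity, numeric(1),
                        pixel_size = spec$pixel_size)
  true_mass <- spec$mass_slope * intensities
  ft <- mass_feature_table(true_mass)

  records <- data.frame(class_index = seq_len(n) - 1L,
                        pixel_size = spec$pixel_size,
                        frc_resolution = res,
                        class_distribution = distr,
                        mass_kda = ft$mass_kda,
                        dev_mean = ft$dev_mean, dev_median = ft$dev_median,
                        dev_mode = ft$dev_mode,
                        label = as.numeric(spec$grades),
                        true_mass_kda = true_mass,
                        grade = spec$grades,
                        stringsAsFactors = FALSE)
  class(records) <- c("class_records", "data.frame")
  list(stack = class_average_stack(images, spec$pixel_size,
                                   source_path = "synthetic"),
       records = records, phantoms = phantoms)
}

#' Build a scorer dataset from a synthetic generation
#'
#' @param gen Output of [generate_stack()].
#' @return A labeled `scorer_dataset`.
#' @export
synthetic_dataset <- function(gen) {
  scorer_dataset(gen$stack$images, records_to_features(gen$records),
                 labels = gen$records$label)
}

#' Generate a synthetic intensity-to-mass calibration set
#'
#' Emulates reference class averages of particles with known masses:
#' intensities are log-uniform over two decades and masses follow
#' `mass = slope * intensity * (1 + e)` with seeded Gaussian relative
#' error `e`.
#'
#' @param n Number of points (>= 2).
#' @param slope True kDa per (intensity * Angstrom^2).
#' @param noise_rel Relative Gaussian noise sd (0 for exact).
#' @param seed Integer seed.
#' @return Data frame with `intensity` and `mass_kda`.
#' @export
generate_calibration_set <- function(n, slope = 0.005, noise_rel = 0.01, seed = 1L) {
  stopifnot(n >= 2, slope > 0, noise_rel >= 0)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  intensity <- 10^stats::runif(n, 2, 4)
  mass <- slope * intensity * (1 + stats::rnorm(n, sd = noise_rel))
  data.frame(intensity = intensity, mass_kda = mass)
}

#' Build a deterministic mock classification backend
#'
#' Test double for the workflow's backend contract: partitions its input
#' particles into `n_classes` classes with a draw seeded by
#' (seed, iteration, particle id), so the class of a particle never depends
#' on which other particles are present -- reruns, resumed runs, and runs
#' with different cutoffs see consistent assignments. Optionally attaches
#' synthetic class images and metadata so a real scorer can score the
#' classes.
#'
#' @param n_classes Number of classes per round.
#' @param image_provider Optional `function(class_id, iteration)` returning
#'   a class-average matrix.
#' @param record_provider Optional `function(class_id, iteration, n_members,
#'   n_total)` returning a metadata record list.
#' @return A backend `function(particle_ids, iteration, seed)`.
#' @export
mock_backend <- function(n_classes, image_provider = NULL, record_provider = NULL) {
  stopifnot(n_classes >= 1)
  n_classes <- as.integer(n_classes)
  function(particle_ids, iteration, seed) {
    assign_one <- function(id)
      1L + .class_seed(seed, iteration, as.integer(id)) %% n_classes
    cls <- vapply(particle_ids, assign_one, integer(1))
    used <- sort(unique(cls))
    lapply(used, function(k) {
      members <- particle_ids[cls == k]
      list(class_id = k,
           members = members,
           image = if (is.null(image_provider)) NULL else image_provider(k, iteration),
           record = if (is.null(record_provider)) NULL
                    else record_provider(k, iteration, length(members),
                                         length(particle_ids)))
    })
  }
}

#' Build a scripted class scorer
#'
#' Returns a scorer function that replays fixed per-round score sequences:
#' `scripts[[iteration]]` is recycled over the classes of that round. Rounds
#' beyond the script reuse the last entry.
#'
#' @param scripts List of numeric vectors, one per round.
#' @return A scorer `function(classes, iteration)`.
#' @export
scripted_scorer <- function(scripts) {
  stopifnot(length(scripts) >= 1)
  function(classes, iteration) {
    s <- scripts[[min(iteration, length(scripts))]]
    rep_len(s, length(classes))
  }
}

#' Wrap a trained model as a workflow class scorer
#'
#' The returned function scores each class of a classification result from
#' its attached image and metadata record (fields `pixel_size`,
#' `frc_resolution`, `class_distribution`, `mass_kda`); mass-deviation
#' features are computed across the classes of the round.
#'
#' @param model A trained `scorer_model`.
#' @param manifest Its manifest.
#' @return A scorer `function(classes, iteration)`.
#' @export
model_scorer <- function(model, manifest) {
  function(classes, iteration) {
    images <- lapply(classes, `[[`, "image")
    if (any(vapply(images, is.null, TRUE)))
      stop("model_scorer needs backends that attach class images")
    recs <- lapply(classes, `[[`, "record")
    masses <- vapply(recs, function(r) r$mass_kda, numeric(1))
    ft <- mass_feature_table(masses)
    feats <- rbind(vapply(recs, function(r) r$pixel_size, numeric(1)),
                   vapply(recs, function(r) r$frc_resolution, numeric(1)),
                   vapply(recs, function(r) r$class_distribution, numeric(1)),
                   ft$dev_mean, ft$dev_median, ft$dev_mode)
    rownames(feats) <- feature_names()
    score_batch(model, images, feats, manifest)
  }
}
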