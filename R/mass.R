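#' Segment particle signal from background by 3-sigma thresholding
#'
#' All pixels more than three standard deviations above the image mean are
#' taken as particle signal; the rest is background. Mean and sd are computed
#' over the whole image. The masks always partition the image, and a constant
#' image (sd 0) yields an empty particle mask, which downstream operations
#' treat as "no detectable particle". Thresholding is invariant to additive
#' intensity offsets.
#'
#' @param image Numeric matrix with finite values, at least 2 pixels.
#' @return List with logical matrices `particle` and `background`.
#' @examples
#' img <- matrix(0, 10, 10); img[5, 5] <- 100
#' seg <- segment_particle(img)
#' sum(seg$particle)  # 1
#' @export
segment_particle <- function(image) {
  if (!is.matrix(image) || length(image) < 2L) stop("image must be a matrix with >= 2 pixels")
  if (!all(is.finite(image))) stop("image contains non-finite values")
  thr <- mean(image) + 3 * stats::sd(image)
  particle <- image > thr
  list(particle = particle, background = !particle)
}

#' Background-subtracted summed particle intensity
#'
#' Sums the background-mean-subtracted intensity over the particle pixels and
#' multiplies by the pixel size squared, giving an area-weighted intensity in
#' intensity * Angstrom^2 that is proportional to the projected particle mass.
#' The background subtraction cancels any additive intensity offset; the
#' result scales linearly with multiplicative gain and with pixel_size^2.
#' Returns 0 when the particle mask is empty.
#'
#' @param image Numeric matrix.
#' @param pixel_size Pixel size in Angstrom/pixel (> 0).
#' @return Non-negative scalar (values below 0 are possible only if particle
#'   pixels fall below the background mean, which the 3-sigma threshold
#'   precludes).
#' @examples
#' img <- matrix(0, 100, 100); img[1:10] <- 100
#' summed_intensity(img, 1.0)  # 1000
#' @export
summed_intensity <- function(image, pixel_size) {
  stopifnot(is.numeric(pixel_size), pixel_size > 0)
  seg <- segment_particle(image)
  if (!any(seg$particle)) return(0)
  bg_mean <- mean(image[seg$background])
  sum(image[seg$particle] - bg_mean) * pixel_size^2
}

#' Fit the intensity-to-mass calibration
#'
#' Least-squares fit of `mass = slope * intensity` through the origin (zero
#' intensity implies zero mass), from reference class averages of particles
#' with known molecular masses. The slope is the calibration factor that
#' converts summed intensities to kDa. R^2 is reported against the
#' through-origin model with the uncentered total sum of squares (as
#' `lm(y ~ 0 + x)` reports), so it lies in [0, 1].
#'
#' @param intensity Summed intensities (intensity * Angstrom^2), all > 0.
#' @param mass_kda Known masses in kDa, all > 0, same length.
#' @return A `mass_calibration` list: `slope` (kDa per intensity * A^2),
#'   `fit_r2`, `n_points`.
#' @examples
#' fit_calibration(c(10, 20), c(5, 10))$slope  # 0.5
#' @export
fit_calibration <- function(intensity, mass_kda) {
  if (length(intensity) < 2L || length(mass_kda) < 2L)
    stop("calibration needs at least 2 points")
  if (length(intensity) != length(mass_kda))
    stop("intensity and mass_kda must have equal length")
  if (any(!is.finite(intensity)) || any(!is.finite(mass_kda)) ||
      any(intensity <= 0) || any(mass_kda <= 0))
    stop("calibration intensities and masses must all be positive and finite")
  # closed-form through-origin least squares: slope = sum(xy) / sum(x^2);
  # R^2 against the uncentered total SS, exactly what lm(y ~ 0 + x) reports
  slope <- sum(intensity * mass_kda) / sum(intensity^2)
  r2 <- 1 - sum((mass_kda - slope * intensity)^2) / sum(mass_kda^2)
  structure(list(slope = slope, fit_r2 = max(0, min(1, r2)),
                 n_points = length(intensity)),
            class = "mass_calibration")
}

#' @export
print.mass_calibration <- function(x, ...) {
  cat(sprintf("<mass_calibration> slope %.6g kDa per intensity*A^2 (R^2 %.4f, n = %d)\n",
              x$slope, x$fit_r2, x$n_points))
  invisible(x)
}

#' Estimate particle mass from a class average
#'
#' @param image Numeric matrix.
#' @param pixel_size Pixel size in Angstrom/pixel.
#' @param calibration A [fit_calibration()] result.
#' @return Estimated mass in kDa.
#' @export
estimate_mass <- function(image, pixel_size, calibration) {
  stopifnot(inherits(calibration, "mass_calibration"))
  calibration$slope * summed_intensity(image, pixel_size)
}

#' Half-sample mode of a continuous sample
#'
#' Robust, parameter-free mode estimator: repeatedly keeps the half of the
#' sorted sample with the smallest range. Falls back to the median for fewer
#' than 3 observations.
#'
#' @param x Numeric vector.
#' @return Scalar mode estimate.
#' @export
half_sample_mode <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0L) stop("empty sample")
  if (n < 3L) return(stats::median(x))
  while (n >= 4L) {
    h <- ceiling(n / 2)
    widths <- x[h:n] - x[seq_len(n - h + 1L)]
    j <- which.min(widths)
    x <- x[j:(j + h - 1L)]
    n <- h
  }
  if (n == 3L) {
    d1 <- x[2] - x[1]; d2 <- x[3] - x[2]
    if (d1 < d2) return(mean(x[1:2]))
    if (d2 < d1) return(mean(x[2:3]))
    return(x[2])
  }
  mean(x)
}

#' Mass-deviation features for one class
#'
#' Deviations of a class's mass from the mean, median, and mode of all class
#' masses in the same classification job. Summed over all classes the
#' mean-deviations cancel exactly (centering identity). The mode is the
#' half-sample mode ([half_sample_mode()]).
#'
#' @param masses Numeric vector of per-class masses in kDa (non-empty).
#' @param target_index 1-based index of the class of interest.
#' @return List: `mass_kda`, `dev_mean`, `dev_median`, `dev_mode` (all kDa).
#' @examples
#' mass_features(c(10, 20, 20, 50), 4)$dev_mean   # 25
#' @export
mass_features <- function(masses, target_index) {
  if (!length(masses)) stop("masses must be non-empty")
  if (target_index < 1L || target_index > length(masses))
    stop("target_index out of range")
  if (any(!is.finite(masses))) stop("masses must be finite")
  m <- masses[target_index]
  list(mass_kda = m,
       dev_mean = m - mean(masses),
       dev_median = m - stats::median(masses),
       dev_mode = m - half_sample_mode(masses))
}

#' Mass-deviation feature table for a whole job
#'
#' Vectorized [mass_features()] over every class of a job.
#'
#' @param masses Numeric vector of per-class masses in kDa.
#' @return Data frame with columns `mass_kda`, `dev_mean`, `dev_median`,
#'   `dev_mode`, one row per class.
#' @export
mass_feature_table <- function(masses) {
  if (!length(masses)) stop("masses must be non-empty")
  mu <- mean(masses); md <- stats::median(masses); mo <- half_sample_mode(masses)
  data.frame(mass_kda = masses, dev_mean = masses - mu,
             dev_median = masses - md, dev_mode = masses - mo)
}

#' Attach mass estimates and deviation features to class records
#'
#' Runs the pixel-intensity mass estimator over every image of a stack,
#' converts to kDa with the calibration, and adds `mass_kda`, `dev_mean`,
#' `dev_median`, `dev_mode` columns to the records.
#'
#' @param stack A `class_average_stack`.
#' @param records A `class_records` data frame aligned with the stack.
#' @param calibration A [fit_calibration()] result.
#' @return The records with mass columns filled.
#' @export
add_mass_features <- function(stack, records, calibration) {
  stopifnot(length(stack$images) == nrow(records))
  masses <- vapply(stack$images, function(im)
    estimate_mass(im, stack$pixel_size, calibration), numeric(1))
  ft <- mass_feature_table(masses)
  records$mass_kda <- ft$mass_kda
  records$dev_mean <- ft$dev_mean
  records$dev_median <- ft$dev_median
  records$dev_mode <- ft$dev_mode
  records
}
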