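# Pixel-intensity mass estimator: segmentation, summed intensity,
# calibration, deviation features.

test_that("3-sigma segmentation selects exactly the signal pixels", {
  # 100x100, 10 pixels at 100, rest 0: mean 0.1, sd 3.162, threshold 9.59
  img <- sparse_image()
  seg <- segment_particle(img)
  expect_identical(sum(seg$particle), 10L)
  expect_true(all(img[seg$particle] == 100))
  expect_true(all(seg$particle | seg$background))      # masks partition
  expect_false(any(seg$particle & seg$background))
})

test_that("segmentation handles constant images and additive offsets", {
  const <- matrix(5, 20, 20)
  seg <- segment_particle(const)
  expect_false(any(seg$particle))
  expect_true(all(seg$background))

  set.seed(5)
  img <- matrix(rnorm(50 * 50), 50); img[1:5] <- 50
  for (offset in c(-100, 3.7, 1e4))
    expect_identical(segment_particle(img + offset)$particle,
                     segment_particle(img)$particle)
})

test_that("summed intensity matches closed-form arithmetic and its scaling laws", {
  img <- sparse_image()
  expect_equal(summed_intensity(img, 1.0), 1000.0, tolerance = 1e-12)
  expect_equal(summed_intensity(img, 2.0), 4000.0, tolerance = 1e-12)
  expect_equal(summed_intensity(matrix(5, 10, 10), 1.0), 0.0)

  # invariant to additive offsets, linear in gain and pixel_size^2
  set.seed(6)
  base <- matrix(rnorm(64 * 64), 64); base[1:12] <- 40
  s0 <- summed_intensity(base, 1.3)
  for (offset in rnorm(5, sd = 20))
    expect_equal(summed_intensity(base + offset, 1.3), s0, tolerance = 1e-9 * abs(s0))
  expect_equal(summed_intensity(3 * base, 1.3), 3 * s0, tolerance = 1e-9 * abs(s0))
  expect_equal(summed_intensity(base, 2.6), 4 * s0, tolerance = 1e-9 * abs(s0))
})

test_that("through-origin calibration recovers exact and noisy slopes", {
  expect_equal(fit_calibration(c(10, 20), c(5, 10))$slope, 0.5, tolerance = 1e-12)

  x <- seq(100, 2000, length.out = 30)
  cal <- fit_calibration(x, 0.5 * x)
  expect_equal(cal$slope, 0.5, tolerance = 1e-12)
  expect_equal(cal$fit_r2, 1.0, tolerance = 1e-12)

  set.seed(21)
  y <- 0.5 * x * (1 + rnorm(30, sd = 0.01))
  noisy <- fit_calibration(x, y)
  expect_lt(abs(noisy$slope - 0.5) / 0.5, 0.02)
  expect_gt(noisy$fit_r2, 0.99)

  # cross-check the closed form against the standard linear-model fit
  fit_lm <- stats::lm(y ~ 0 + x)
  expect_equal(noisy$slope, unname(stats::coef(fit_lm)), tolerance = 1e-12)
  expect_equal(noisy$fit_r2, summary(fit_lm)$r.squared, tolerance = 1e-9)

  expect_error(fit_calibration(10, 5), "at least 2")
  expect_error(fit_calibration(c(10, -1), c(5, 5)), "positive")
})

test_that("synthetic calibration sets drive slope recovery end to end", {
  exact <- generate_calibration_set(20, slope = 0.004, noise_rel = 0, seed = 2)
  expect_equal(fit_calibration(exact$intensity, exact$mass_kda)$slope, 0.004,
               tolerance = 1e-12)
  expect_identical(nrow(generate_calibration_set(2, seed = 1)), 2L)

  noisy <- generate_calibration_set(50, slope = 0.004, noise_rel = 0.01, seed = 9)
  slope <- fit_calibration(noisy$intensity, noisy$mass_kda)$slope
  expect_lt(abs(slope - 0.004) / 0.004, 0.01)
})

test_that("mass deviation features match brute-force arithmetic", {
  f <- mass_features(c(100, 100, 100), 1)
  expect_equal(unlist(f[c("dev_mean", "dev_median", "dev_mode")]),
               c(dev_mean = 0, dev_median = 0, dev_mode = 0))

  f2 <- mass_features(c(10, 20, 20, 50), 4)
  expect_equal(f2$dev_mean, 25.0)    # mean 25
  expect_equal(f2$dev_median, 30.0)  # median 20

  set.seed(8)
  masses <- rlnorm(25, log(200), 0.5)
  tab <- mass_feature_table(masses)
  expect_equal(sum(tab$dev_mean), 0, tolerance = 1e-9 * mean(masses))
  expect_equal(tab$dev_mean, vapply(seq_along(masses), function(i)
    mass_features(masses, i)$dev_mean, numeric(1)))

  expect_error(mass_features(numeric(0), 1), "non-empty")
})

test_that("half-sample mode finds the dense region and degrades to the median", {
  set.seed(13)
  x <- c(rnorm(200, 10, 0.5), rnorm(20, 50, 5))  # mode near 10 despite outliers
  expect_lt(abs(half_sample_mode(x) - 10), 1)
  expect_equal(half_sample_mode(c(3)), 3)
  expect_equal(half_sample_mode(c(3, 7)), 5)     # median fallback below n = 3
})

test_that("mass estimates on synthetic phantoms are recovered through the calibration", {
  gen <- generate_stack(synthetic_spec(30, seed = 4))
  ints <- vapply(gen$phantoms, summed_intensity, numeric(1),
                 pixel_size = gen$stack$pixel_size)
  cal <- fit_calibration(ints, gen$records$true_mass_kda)
  expect_equal(cal$slope, 0.005, tolerance = 1e-9)   # generator's true slope
  est <- vapply(gen$phantoms, estimate_mass, numeric(1),
                pixel_size = gen$stack$pixel_size, calibration = cal)
  expect_equal(est, gen$records$true_mass_kda, tolerance = 1e-9)
})
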