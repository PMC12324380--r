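# MRC and STAR I/O: round trips, conventions, validation.

test_that("MRC stack round trip preserves dimensions, pixel size and float32 values", {
  set.seed(11)
  imgs <- lapply(1:10, function(i) matrix(rnorm(100 * 100), 100))
  stack <- class_average_stack(imgs, pixel_size = 1.5)
  path <- withr::local_tempfile(fileext = ".mrcs")
  write_class_stack(stack, path)
  rd <- read_class_stack(path)
  expect_length(rd$images, 10)
  expect_identical(dim(rd$images[[1]]), c(100L, 100L))
  expect_equal(rd$pixel_size, 1.5, tolerance = 1e-6)
  # doubles quantize to float32 on write; a second round trip is exact
  write_class_stack(rd, path)
  rd2 <- read_class_stack(path)
  expect_identical(rd2$images, rd$images)
})

test_that("a single 2D MRC (nz = 1) loads as a one-image stack", {
  stack <- class_average_stack(list(matrix(runif(32 * 32), 32)), pixel_size = 0.9)
  path <- withr::local_tempfile(fileext = ".mrc")
  write_class_stack(stack, path)
  rd <- read_class_stack(path)
  expect_length(rd$images, 1)
})

test_that("package reader agrees with an independent raw-byte decode", {
  # three fixture files of different sizes/content, decoded with plain readBin
  set.seed(3)
  for (side in c(16L, 33L, 64L)) {
    imgs <- lapply(1:3, function(i) matrix(rnorm(side^2, sd = 10), side))
    path <- withr::local_tempfile(fileext = ".mrcs")
    write_class_stack(class_average_stack(imgs, 1.2), path)
    rd <- read_class_stack(path)
    con <- file(path, "rb"); seek(con, 1024L)
    raw_vals <- readBin(con, "numeric", n = 3 * side^2, size = 4L, endian = "little")
    close(con)
    expect_equal(sum(unlist(rd$images)), sum(raw_vals), tolerance = 0)
  }
})

test_that("anisotropic pixel sizes and malformed headers are rejected with detail", {
  path <- withr::local_tempfile(fileext = ".mrc")
  write_class_stack(class_average_stack(list(matrix(0.5, 8, 8)), 1.0), path)
  # corrupt CELLA y so apix_y = 2.0 while apix_x = 1.0
  con <- file(path, "r+b"); seek(con, 44L, rw = "write")
  writeBin(16, con, size = 4L, endian = "little"); close(con)
  expect_error(read_class_stack(path), "anisotropic.*1\\b.*2\\b|anisotropic")
  con <- file(path, "r+b"); seek(con, 0L, rw = "write")
  writeBin(-5L, con, size = 4L, endian = "little"); close(con)
  expect_error(read_class_stack(path), "malformed")
  expect_error(read_class_stack(tempfile()), "no such file")
})

test_that("score STAR output follows the 1-based @ reference convention and round-trips", {
  tab <- score_table(class_index = 0:2, stack_name = "cls.mrcs",
                     score = c(1.234567, 3.0, 5.654321))
  expect_identical(tab$image_name[1], "000001@cls.mrcs")
  expect_identical(tab$image_name[3], "000003@cls.mrcs")
  path <- withr::local_tempfile(fileext = ".star")
  write_score_star(tab, path)
  txt <- readLines(path)
  expect_length(grep("@cls.mrcs", txt), 3)   # one data line per row
  rd <- read_score_star(path)
  expect_identical(rd$class_index, tab$class_index)
  expect_equal(rd$score, tab$score, tolerance = 1e-7)  # >= 6 significant digits
  expect_equal(rd$bin_score, tab$bin_score, tolerance = 1e-7)
})

test_that("metadata tables load identically from CSV and STAR encodings", {
  records <- data.frame(class_index = 0:19, pixel_size = 1.1,
                        frc_resolution = seq(4, 23),
                        class_distribution = rep(0.05, 20),
                        mass_kda = seq(100, 290, by = 10),
                        label = rep(c(1, 2, 3, 4, 5), 4))
  csv <- withr::local_tempfile(fileext = ".csv")
  star <- withr::local_tempfile(fileext = ".star")
  utils::write.csv(records, csv, row.names = FALSE)
  write_metadata_table(structure(records, class = c("class_records", "data.frame")), star)
  a <- read_metadata_table(csv)
  b <- read_metadata_table(star)
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-12)
  expect_identical(nrow(a), 20L)
})

test_that("metadata validation names the offending column, row and range", {
  df <- data.frame(pixel_size = c(1, 1), frc_resolution = c(5, 6),
                   class_distribution = c(0.5, 0.5))
  path <- withr::local_tempfile(fileext = ".csv")

  utils::write.csv(df[c("pixel_size", "frc_resolution")], path, row.names = FALSE)
  expect_error(read_metadata_table(path), "class_distribution")

  bad <- df; bad$class_distribution <- c(1.2, -0.2)
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_metadata_table(path), "out of \\[0, 1\\]")

  bad2 <- df; bad2$frc_resolution <- c("5", "oops")
  utils::write.csv(bad2, path, row.names = FALSE)
  expect_error(read_metadata_table(path), "non-numeric.*row 2")

  # grade letters convert to the 1-5 numeric anchors
  df$label <- c("A", "F")
  utils::write.csv(df, path, row.names = FALSE)
  expect_identical(read_metadata_table(path)$label, c(1, 5))
})

test_that("class distributions are renormalized inside the tolerant window, rejected outside", {
  df <- data.frame(pixel_size = 1, frc_resolution = 5,
                   class_distribution = c(0.50, 0.45))   # sums to 0.95
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  expect_warning(rec <- read_metadata_table(path), "renormalizing")
  expect_equal(sum(rec$class_distribution), 1, tolerance = 1e-12)

  df$class_distribution <- c(0.2, 0.2)                   # sums to 0.4
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_metadata_table(path), "outside the tolerated")
})
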