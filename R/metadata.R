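# Per-class metadata tables: pixel size, FRC resolution estimate, relative
# class distribution, plus optional mass and label columns. Accepted as CSV,
# TSV, or a STAR loop with the same fields as cg-prefixed tags.

.metadata_required <- c("pixel_size", "frc_resolution", "class_distribution")
.metadata_optional <- c("class_index", "mass_kda", "label")

.star_tag_map <- c(cgPixelSize = "pixel_size", cgFrcResolution = "frc_resolution",
                   cgClassDistribution = "class_distribution",
                   cgClassIndex = "class_index", cgMassKda = "mass_kda",
                   cgLabel = "label")

#' Read a per-class metadata table
#'
#' Reads CSV/TSV (columns `pixel_size`, `frc_resolution`,
#' `class_distribution`; optional `class_index`, `mass_kda`, `label`) or a
#' STAR loop with the equivalent tags (`_cgPixelSize`, `_cgFrcResolution`,
#' `_cgClassDistribution`, `_cgClassIndex`, `_cgMassKda`, `_cgLabel`). The two
#' encodings of the same data load to identical record tables. Missing
#' optional columns are left as `NA`, never silently defaulted. Labels may be
#' numeric scores or grade letters A-F (converted via [grade_to_score()]).
#'
#' Validation: `pixel_size` and `frc_resolution` must be positive;
#' `class_distribution` must lie in [0, 1] and the distributions of one table
#' (one classification job) must sum to 1. If the sum is off by up to 10% the
#' table is renormalized with a warning; a larger discrepancy is an error.
#'
#' @param path Path to a `.csv`, `.tsv`/`.txt`, or `.star` file.
#' @return A `class_records` data frame, one row per class, with columns
#'   `class_index` (0-based), `pixel_size`, `frc_resolution`,
#'   `class_distribution`, `mass_kda`, `label`.
#' @export
read_metadata_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "star") {
    df <- star_read(path)[[1]]
    known <- intersect(names(df), names(.star_tag_map))
    df <- df[known]
    names(df) <- .star_tag_map[known]
  } else {
    sep <- if (ext %in% c("tsv", "txt")) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, strip.white = TRUE)
  }
  miss <- setdiff(.metadata_required, names(df))
  if (length(miss))
    stop("metadata table is missing required column(s): ", paste(miss, collapse = ", "))
  for (cn in .metadata_required) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at row %d: '%s'",
                   cn, bad[1], df[[cn]][bad[1]]))
    if (anyNA(v))
      stop(sprintf("missing value in required column '%s' at row %d", cn, which(is.na(v))[1]))
    df[[cn]] <- v
  }
  n <- nrow(df)
  if (!("class_index" %in% names(df))) df$class_index <- seq_len(n) - 1L
  df$class_index <- as.integer(df$class_index)
  if (!("mass_kda" %in% names(df))) df$mass_kda <- NA_real_
  if ("label" %in% names(df)) {
    if (is.character(df$label) && any(df$label %in% c("A", "B", "C", "D", "F")))
      df$label <- grade_to_score(df$label)
    df$label <- as.numeric(df$label)
  } else df$label <- NA_real_

  if (any(df$pixel_size <= 0)) stop("pixel_size must be positive")
  if (any(df$frc_resolution <= 0)) stop("frc_resolution must be positive")
  if (any(df$class_distribution < 0 | df$class_distribution > 1))
    stop(sprintf("class_distribution out of [0, 1] at row %d (value %.6g)",
                 which(df$class_distribution < 0 | df$class_distribution > 1)[1],
                 df$class_distribution[df$class_distribution < 0 | df$class_distribution > 1][1]))
  s <- sum(df$class_distribution)
  if (abs(s - 1) > 1e-6) {
    if (s >= 0.9 && s <= 1.1) {
      warning(sprintf("class distributions sum to %.6g; renormalizing to 1", s))
      df$class_distribution <- df$class_distribution / s
    } else {
      stop(sprintf("class distributions sum to %.6g, outside the tolerated [0.9, 1.1] window", s))
    }
  }
  out <- df[c("class_index", "pixel_size", "frc_resolution", "class_distribution",
              "mass_kda", "label")]
  structure(out, class = c("class_records", "data.frame"))
}

#' Write a metadata table
#'
#' @param records A `class_records` data frame (or compatible).
#' @param path Output path; format chosen by extension (.csv, .tsv, .star).
#' @return `path`, invisibly.
#' @export
write_metadata_table <- function(records, path) {
  ext <- tolower(tools::file_ext(path))
  cols <- intersect(c("class_index", "pixel_size", "frc_resolution",
                      "class_distribution", "mass_kda", "label"), names(records))
  df <- as.data.frame(records)[cols]
  if (ext == "star") {
    keep <- !vapply(df, function(v) all(is.na(v)), TRUE)
    df <- df[keep]
    inv_map <- stats::setNames(names(.star_tag_map), .star_tag_map)
    names(df) <- inv_map[names(df)]
    star_write(df, path, block_name = "class_metadata")
  } else {
    utils::write.table(df, path, sep = if (ext == "tsv") "\t" else ",",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Assemble the model feature matrix from class records
#'
#' Returns the 6 x n feature matrix in [feature_names()] order. Mass
#' deviation features are computed from the `mass_kda` column if deviation
#' columns are absent.
#'
#' @param records A `class_records` data frame.
#' @return Numeric matrix with rownames [feature_names()].
#' @export
records_to_features <- function(records) {
  n <- nrow(records)
  if (all(c("dev_mean", "dev_median", "dev_mode") %in% names(records))) {
    devs <- rbind(records$dev_mean, records$dev_median, records$dev_mode)
  } else {
    if (anyNA(records$mass_kda))
      stop("records carry no mass deviations and mass_kda is incomplete; ",
           "run the mass estimator first")
    ft <- mass_feature_table(records$mass_kda)
    devs <- rbind(ft$dev_mean, ft$dev_median, ft$dev_mode)
  }
  m <- rbind(records$pixel_size, records$frc_resolution,
             records$class_distribution, devs)
  rownames(m) <- feature_names()
  m
}
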