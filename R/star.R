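# STAR file handling (RELION-style dialect): one or more data_ blocks, each
# either a loop_ table (underscore-prefixed tags, whitespace-delimited rows)
# or simple tag-value pairs. Column-number comments after tags ("#1") and
# full-line comments are ignored.

#' Read a STAR file
#'
#' @param path Path to a STAR file.
#' @return Named list of data blocks; loop blocks become data frames (numeric
#'   columns auto-converted), tag-value blocks become one-row data frames.
#' @export
star_read <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("^\\s+|\\s+$", "", lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  blocks <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "data_")) { i <- i + 1L; next }
    block_name <- sub("^data_", "", lines[i])
    if (!nzchar(block_name)) block_name <- "data"
    i <- i + 1L
    tags <- character(); rows <- list(); kv <- list()
    in_loop <- FALSE
    while (i <= length(lines) && !startsWith(lines[i], "data_")) {
      ln <- lines[i]
      if (identical(ln, "loop_")) {
        in_loop <- TRUE; tags <- character()
      } else if (startsWith(ln, "_")) {
        parts <- strsplit(ln, "\\s+")[[1]]
        tag <- sub("^_", "", parts[1])
        if (in_loop && (length(parts) == 1L || grepl("^#", parts[2]))) {
          tags <- c(tags, tag)
        } else {
          kv[[tag]] <- parts[2]
          in_loop <- FALSE
        }
      } else {
        vals <- strsplit(ln, "\\s+")[[1]]
        if (in_loop) {
          if (length(vals) != length(tags))
            stop(sprintf("STAR row %d has %d fields but the loop declares %d columns",
                         i, length(vals), length(tags)))
          rows[[length(rows) + 1L]] <- vals
        }
      }
      i <- i + 1L
    }
    df <- if (length(rows)) {
      m <- do.call(rbind, rows)
      colnames(m) <- tags
      as.data.frame(m, stringsAsFactors = FALSE)
    } else if (length(kv)) {
      as.data.frame(kv, stringsAsFactors = FALSE)
    } else data.frame()
    for (cn in names(df)) {
      v <- suppressWarnings(as.numeric(df[[cn]]))
      if (!anyNA(v)) df[[cn]] <- v
    }
    blocks[[block_name]] <- df
  }
  if (!length(blocks)) stop("no data_ block found in ", path)
  blocks
}

#' Write a single-loop STAR file
#'
#' @param df Data frame; column names become tags (underscore added).
#' @param path Output path.
#' @param block_name Name after `data_`.
#' @return `path`, invisibly.
#' @export
star_write <- function(df, path, block_name = "") {
  stopifnot(is.data.frame(df), nrow(df) >= 1L)
  fmt_col <- function(v) {
    if (is.numeric(v)) {
      out <- sprintf("%.8g", v)
      out[v == round(v) & abs(v) < 1e15] <- sprintf("%d", as.integer(round(v[v == round(v) & abs(v) < 1e15])))
      out
    } else as.character(v)
  }
  cols <- lapply(df, fmt_col)
  body <- do.call(paste, c(cols, sep = "\t"))
  lines <- c(paste0("data_", block_name), "", "loop_",
             sprintf("_%s #%d", names(df), seq_along(df)), body, "")
  writeLines(lines, path)
  invisible(path)
}

# RELION image-reference convention: 1-based slice index "@" stack name.
format_image_ref <- function(class_index, stack_name)
  sprintf("%06d@%s", as.integer(class_index) + 1L, stack_name)

parse_image_ref <- function(ref) {
  parts <- strsplit(ref, "@", fixed = TRUE)
  idx <- as.integer(vapply(parts, `[`, "", 1L)) - 1L
  stack <- vapply(parts, `[`, "", 2L)
  data.frame(class_index = idx, stack_name = stack, stringsAsFactors = FALSE)
}

#' Build a score table
#'
#' One row per scored class, in input-stack order. Scores live on the
#' open-ended 1 (best) to 5 (worst) scale and are never clamped; `bin_score`
#' is the clamped 0-1 reversal from [score_to_bin()].
#'
#' @param class_index 0-based integer class indices.
#' @param stack_name Stack file name for the image references.
#' @param score Numeric scores.
#' @return A `score_table` data frame with columns `class_index`,
#'   `image_name`, `score`, `bin_score`.
#' @export
score_table <- function(class_index, stack_name, score) {
  stopifnot(length(class_index) == length(score), all(is.finite(score)))
  structure(data.frame(class_index = as.integer(class_index),
                       image_name = format_image_ref(class_index, stack_name),
                       score = as.numeric(score),
                       bin_score = score_to_bin(score),
                       stringsAsFactors = FALSE),
            class = c("score_table", "data.frame"))
}

#' Write a score table as a STAR file
#'
#' Emits a single `data_` loop with tags `_cgImageName` (RELION-style
#' `NNNNNN@stack.mrcs` references, 1-based slice index), `_cgClassIndex`
#' (0-based), `_cgClassScore` (1-5 open-ended scale, best first) and
#' `_cgBinScore` (0-1, higher is better). Scores round-trip through
#' [read_score_star()] to at least 6 significant digits.
#'
#' @param table A [score_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_star <- function(table, path) {
  stopifnot(nrow(table) >= 1L)
  df <- data.frame(cgImageName = table$image_name,
                   cgClassIndex = table$class_index,
                   cgClassScore = table$score,
                   cgBinScore = table$bin_score,
                   stringsAsFactors = FALSE)
  star_write(df, path, block_name = "class_scores")
}

#' Read a score table written by [write_score_star()]
#'
#' @param path Path to the STAR file.
#' @return A `score_table` data frame.
#' @export
read_score_star <- function(path) {
  blocks <- star_read(path)
  df <- blocks[[1]]
  need <- c("cgImageName", "cgClassIndex", "cgClassScore")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("score STAR is missing column(s): ", paste(miss, collapse = ", "))
  structure(data.frame(class_index = as.integer(df$cgClassIndex),
                       image_name = as.character(df$cgImageName),
                       score = as.numeric(df$cgClassScore),
                       bin_score = if ("cgBinScore" %in% names(df))
                         as.numeric(df$cgBinScore) else score_to_bin(df$cgClassScore),
                       stringsAsFactors = FALSE),
            class = c("score_table", "data.frame"))
}
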