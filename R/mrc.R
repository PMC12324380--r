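# MRC2014 image-stack I/O.
#
# 1024-byte header of 4-byte words, little-endian; a stack of 2D class
# averages is nx x ny x nz with one class per z-section. Only the words this
# package needs are interpreted; writing emits mode 2 (float32) with
# NVERSION 20140, MAP "MAP " and little-endian MACHST.

.mrc_mode_info <- function(mode) {
  switch(as.character(mode),
    "0" = list(what = "integer", size = 1L, signed = TRUE),
    "1" = list(what = "integer", size = 2L, signed = TRUE),
    "2" = list(what = "numeric", size = 4L, signed = TRUE),
    "6" = list(what = "integer", size = 2L, signed = FALSE),
    stop(sprintf("unsupported MRC mode %s (modes 0, 1, 2 and 6 are accepted)", mode)))
}

#' Read an MRC2014 stack of 2D class averages
#'
#' Accepts a single 2D image (nz = 1) or a stack of 2D sections. Data modes
#' 0 (int8), 1 (int16), 2 (float32) and 6 (uint16) are converted to double.
#' The pixel size is taken from the header cell dimensions (CELLA / MX); the
#' x and y pixel sizes must agree to within 1e-3 relative, since 2D class
#' averages are isotropically sampled.
#'
#' @param path Path to an `.mrc`/`.mrcs` file.
#' @return A `class_average_stack`: list with `images` (list of matrices),
#'   `pixel_size` (Angstrom/pixel) and `source_path`.
#' @export
read_class_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256L, size = 4L, endian = "little")
  if (length(hdr_int) < 256L) stop("malformed MRC header (file shorter than 1024 bytes): ", path)
  seek(con, 0L)
  hdr_num <- readBin(con, "numeric", n = 256L, size = 4L, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  mx <- hdr_int[8]; my <- hdr_int[9]
  cella <- hdr_num[11:13]
  nsymbt <- hdr_int[24]
  if (nx <= 0 || ny <= 0 || nz <= 0 || mx <= 0 || my <= 0)
    stop(sprintf("malformed MRC header in %s: dimensions %d x %d x %d (MX %d, MY %d)",
                 path, nx, ny, nz, mx, my))
  info <- .mrc_mode_info(mode)
  apix_x <- cella[1] / mx
  apix_y <- cella[2] / my
  if (apix_x <= 0) stop("malformed MRC header: non-positive pixel size in ", path)
  if (abs(apix_x - apix_y) > 1e-3 * max(apix_x, apix_y))
    stop(sprintf("anisotropic pixel size in %s: x = %.6g, y = %.6g Angstrom/px",
                 path, apix_x, apix_y))
  seek(con, 1024L + max(nsymbt, 0L))
  n_vox <- as.double(nx) * ny * nz
  data <- readBin(con, info$what, n = n_vox, size = info$size,
                  signed = info$signed, endian = "little")
  if (length(data) < n_vox)
    stop(sprintf("truncated MRC data in %s: expected %.0f voxels, read %d",
                 path, n_vox, length(data)))
  data <- as.double(data)
  if (!all(is.finite(data)))
    stop("non-finite pixel values in ", path)
  arr <- array(data, dim = c(nx, ny, nz))
  images <- lapply(seq_len(nz), function(k) arr[, , k])
  class_average_stack(images, pixel_size = apix_x, source_path = path)
}

#' Construct a class-average stack
#'
#' @param images List of equally sized 2D numeric matrices (one per class).
#' @param pixel_size Pixel size in Angstrom/pixel (> 0).
#' @param source_path Provenance string.
#' @return A `class_average_stack` object.
#' @export
class_average_stack <- function(images, pixel_size, source_path = NA_character_) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1L, is.numeric(pixel_size), pixel_size > 0)
  d <- dim(images[[1]])
  for (im in images) {
    if (!is.matrix(im) || !identical(dim(im), d))
      stop("all images in a stack must be matrices of identical dimensions")
    if (!all(is.finite(im))) stop("stack images must be finite")
  }
  structure(list(images = images, pixel_size = as.numeric(pixel_size),
                 source_path = source_path),
            class = "class_average_stack")
}

#' @export
print.class_average_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<class_average_stack> %d classes of %d x %d px at %.4g Angstrom/px\n",
              length(x$images), d[1], d[2], x$pixel_size))
  invisible(x)
}

#' Write a class-average stack as an MRC2014 file
#'
#' Data are written as mode 2 (float32), little-endian, one 2D section per
#' class. Note float32 quantizes doubles; a written-then-reread stack is
#' bit-identical at float32 precision.
#'
#' @param stack A `class_average_stack`.
#' @param path Output path (`.mrc`/`.mrcs`).
#' @return `path`, invisibly.
#' @export
write_class_stack <- function(stack, path) {
  stopifnot(inherits(stack, "class_average_stack"))
  d <- dim(stack$images[[1]])
  nz <- length(stack$images)
  data <- unlist(stack$images, use.names = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  wf <- function(v) writeBin(as.double(v), con, size = 4L, endian = "little")
  wi(c(d[1], d[2], nz, 2L))                       # NX NY NZ MODE
  wi(c(0L, 0L, 0L))                               # N*START
  wi(c(d[1], d[2], nz))                           # MX MY MZ
  wf(stack$pixel_size * c(d[1], d[2], nz))        # CELLA
  wf(c(90, 90, 90))                               # CELLB
  wi(c(1L, 2L, 3L))                               # MAPC MAPR MAPS
  wf(c(min(data), max(data), mean(data)))         # DMIN DMAX DMEAN
  wi(c(0L, 0L))                                   # ISPG NSYMBT
  wi(rep(0L, 2L))                                 # EXTRA words 25-26
  writeChar("MRCO", con, nchars = 4L, eos = NULL) # EXTTYP (word 27)
  wi(20140L)                                      # NVERSION (word 28)
  wi(rep(0L, 21L))                                # EXTRA words 29-49
  wf(c(0, 0, 0))                                  # ORIGIN
  writeChar("MAP ", con, nchars = 4L, eos = NULL) # MAP
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(data))                             # RMS
  wi(0L)                                          # NLABL
  writeBin(raw(800L), con)                        # labels
  wf(data)
  invisible(path)
}
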