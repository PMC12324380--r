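#' Bring a class-average image to the canonical square frame
#'
#' Class averages arrive at whatever box size the extraction used; the scorer
#' wants one fixed frame (210 x 210 by default). Images smaller than the frame
#' are zero-padded around a centered window (odd differences put the extra
#' row/column at the bottom/right); images larger than the frame are
#' Fourier-cropped: high spatial frequencies are truncated symmetrically
#' around DC, which downsamples while preserving the low-frequency content
#' and, with the scaling used here, the mean intensity. Inputs must be square
#' and at least 31 pixels on a side.
#'
#' @param image Square numeric matrix with finite values.
#' @param side Target frame side in pixels (default 210).
#' @param min_side Smallest accepted input side (default 31).
#' @return A `canonical_image` list: `pixels` (`side` x `side` matrix),
#'   `original_shape`, and `scale_action` (one of `"identity"`, `"padded"`,
#'   `"fourier_downsampled"`).
#' @examples
#' img <- matrix(rnorm(100 * 100), 100)
#' c1 <- canonicalize(img)
#' dim(c1$pixels)          # 210 210
#' c1$scale_action         # "padded"
#' @export
canonicalize <- function(image, side = 210L, min_side = 31L) {
  if (!is.matrix(image)) stop("image must be a matrix")
  d <- dim(image)
  if (d[1] != d[2])
    stop(sprintf("non-square image (%d x %d): 2D class averages must be square", d[1], d[2]))
  if (!all(is.finite(image))) stop("image contains non-finite values")
  n <- d[1]
  if (n < min_side)
    stop(sprintf("input side %d is below the %d-pixel minimum input size", n, min_side))
  if (n == side) {
    act <- "identity"; px <- image
  } else if (n < side) {
    act <- "padded"
    top <- (side - n) %/% 2L
    left <- (side - n) %/% 2L
    px <- matrix(0, side, side)
    px[top + seq_len(n), left + seq_len(n)] <- image
  } else {
    act <- "fourier_downsampled"
    px <- fourier_crop(image, side)
  }
  structure(list(pixels = px, original_shape = d, scale_action = act),
            class = "canonical_image")
}

#' Fourier-crop a square image to a smaller side
#'
#' Truncates spatial frequencies above the new Nyquist limit symmetrically
#' around DC and rescales so the mean intensity (DC term) is preserved. This
#' is the standard downsampling used on particle images: low-frequency
#' content passes through unchanged (a pure cosine below the new Nyquist
#' keeps its amplitude), and the per-pixel mean power can only decrease.
#'
#' @param image Square numeric matrix.
#' @param m Target side, `m < nrow(image)`.
#' @return m x m numeric matrix.
#' @export
fourier_crop <- function(image, m) {
  n <- nrow(image)
  stopifnot(ncol(image) == n, m < n, m >= 1)
  Fm <- stats::fft(image)
  shift_n <- ((seq_len(n) - 1L + (n + 1L) %/% 2L) %% n) + 1L
  Fs <- Fm[shift_n, shift_n]                       # DC at floor(n/2)+1
  cn <- n %/% 2L + 1L
  win <- (cn - m %/% 2L):(cn + (m - m %/% 2L) - 1L)
  Fc <- Fs[win, win]
  unshift_m <- ((seq_len(m) - 1L + m %/% 2L) %% m) + 1L
  Fc <- Fc[unshift_m, unshift_m]
  Re(stats::fft(Fc, inverse = TRUE)) / (m * m) * (m / n)^2
}

#' Z-score normalize an image
#'
#' Subtracts the mean and divides by the standard deviation over all pixels
#' (sample sd, denominator n-1). A constant image maps to all zeros. Applied
#' after canonicalization, so padded zeros participate in the statistics; the
#' convention is recorded in the model manifest so training and inference
#' always match.
#'
#' @param image Numeric matrix with finite values.
#' @return Matrix of the same shape with mean 0 and sd 1 (or all zeros).
#' @export
normalize_image <- function(image) {
  if (!all(is.finite(image))) stop("image contains non-finite values")
  s <- stats::sd(image)
  if (!is.finite(s) || s == 0) return(array(0, dim(image)))
  (image - mean(image)) / s
}
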