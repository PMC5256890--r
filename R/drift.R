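# Lateral drift estimation by Fourier cross-correlation.
#
# The algorithm is raw circular cross-correlation: multiply the Fourier
# transform of the reference image by the complex conjugate of the new
# image's transform, inverse-transform, move the zero-frequency corners to
# the array center, and read off the peak position relative to the center
# pixel at 0-based (floor(H/2), floor(W/2)). The peak offset of that product
# is the shift that needs to be *corrected*; `estimate_shift()` returns its
# negation, i.e. the displacement of the new image relative to the
# reference, so that `corrective_shift()` is a plain negation.

#' Estimate lateral drift between two images
#'
#' @param reference,new numeric matrices of identical dimensions.
#' @param mean_subtract subtract each image's mean before correlating
#'   (off by default; the raw algorithm needs no whitening, but mean
#'   subtraction helps on bright uniform backgrounds).
#' @return Object of class `shift_estimate`: list with integer `d_row`,
#'   `d_col` (circular displacement of `new` relative to `reference`, in
#'   pixels, bounded by half the image size) and `peak` (correlation
#'   maximum). Ties at the peak resolve to the smallest row, then column.
#' @examples
#' img <- matrix(runif(64 * 64), 64)
#' moved <- img[c(62:64, 1:61), ]  # circular shift down by 3 rows
#' estimate_shift(img, moved)
#' @export
estimate_shift <- function(reference, new, mean_subtract = FALSE) {
  check_image(reference, "reference"); check_image(new, "new")
  if (!all(dim(reference) == dim(new)))
    stop("reference and new image dimensions differ", call. = FALSE)
  if (stats::sd(reference) == 0 || stats::sd(new) == 0)
    stop("drift estimation undefined for a constant image", call. = FALSE)
  H <- nrow(reference); W <- ncol(reference)
  a <- reference; b <- new
  if (isTRUE(mean_subtract)) { a <- a - mean(a); b <- b - mean(b) }
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) / (H * W)
  cc <- fftshift2(cc)
  pk <- which(cc == max(cc), arr.ind = TRUE)
  pk <- pk[order(pk[, 1], pk[, 2]), , drop = FALSE][1, ]  # deterministic ties
  # peak offset from center = shift to correct; displacement is its negation
  structure(list(d_row = -(as.integer(pk[1]) - 1L - H %/% 2L),
                 d_col = -(as.integer(pk[2]) - 1L - W %/% 2L),
                 peak = max(cc)),
            class = "shift_estimate")
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf("<shift_estimate> d_row = %+d, d_col = %+d px (peak %.4g)\n",
              x$d_row, x$d_col, x$peak))
  invisible(x)
}

#' Compensating scan shift for an estimated drift
#'
#' @param est a [estimate_shift()] result, or a length-2 integer vector
#'   `(d_row, d_col)`.
#' @return Integer vector `(d_row, d_col)` to apply to the acquisition
#'   window: the negation of the estimated drift.
#' @export
corrective_shift <- function(est) {
  if (inherits(est, "shift_estimate")) est <- c(est$d_row, est$d_col)
  stopifnot(length(est) == 2)
  -as.integer(est)
}

#' Circularly translate an image by an integer pixel shift
#'
#' `apply_shift(img, d)[i, j] == img[i - d_row, j - d_col]` with wrap-around;
#' the closed-loop counterpart of [estimate_shift()] used by the virtual
#' session runner and in round-trip tests.
#'
#' @param img numeric matrix.
#' @param d_row,d_col integer shift in pixels.
#' @return Shifted matrix of the same dimensions.
#' @export
apply_shift <- function(img, d_row, d_col) {
  circular_shift(img, as.integer(d_row), as.integer(d_col))
}
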