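#' @keywords internal
"_PACKAGE"

# Images are plain numeric matrices: rows = image rows (y), cols = x.
# Intensities are arbitrary non-negative units; operators work in double.

check_image <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("%s must be a numeric matrix", arg), call. = FALSE)
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop(sprintf("%s must have at least one row and column", arg), call. = FALSE)
  if (!all(is.finite(img)))
    stop(sprintf("%s contains non-finite values", arg), call. = FALSE)
  if (any(img < 0))
    stop(sprintf("%s contains negative intensities", arg), call. = FALSE)
  invisible(img)
}

#' Rectangular region of interest
#'
#' Defines an axis-aligned rectangle by its 0-based top-left corner and a
#' half-open extent, the convention used in session configuration files.
#'
#' @param row0,col0 0-based row/column of the top-left pixel.
#' @param height,width extent in pixels; the ROI covers rows
#'   `row0 .. row0+height-1` (0-based).
#' @return An object of class `rect_roi`.
#' @export
rect_roi <- function(row0, col0, height, width) {
  stopifnot(row0 >= 0, col0 >= 0, height >= 1, width >= 1)
  if (height * width < 4)
    stop("ROI area must be at least 4 pixels", call. = FALSE)
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "rect_roi")
}

#' @export
print.rect_roi <- function(x, ...) {
  cat(sprintf("<rect_roi> top-left (%d,%d), %d x %d px (0-based, half-open)\n",
              x$row0, x$col0, x$height, x$width))
  invisible(x)
}

crop_roi <- function(img, roi) {
  if (is.null(roi)) return(img)
  if (!inherits(roi, "rect_roi")) stop("roi must be a rect_roi", call. = FALSE)
  if (roi$row0 + roi$height > nrow(img) || roi$col0 + roi$width > ncol(img))
    stop("ROI extends outside the image", call. = FALSE)
  img[(roi$row0 + 1L):(roi$row0 + roi$height),
      (roi$col0 + 1L):(roi$col0 + roi$width), drop = FALSE]
}

# Replicate-padded shift: translate image content by (dr, dc), edge rows/cols
# repeated. Used to build finite-difference stencils without wrap-around.
shift_replicate <- function(x, dr, dc) {
  H <- nrow(x); W <- ncol(x)
  ri <- pmin(pmax(seq_len(H) - dr, 1L), H)
  ci <- pmin(pmax(seq_len(W) - dc, 1L), W)
  x[ri, ci, drop = FALSE]
}

# 2D convolution with replicate padding for small kernels, via shifted sums.
conv2_replicate <- function(x, k) {
  kh <- nrow(k); kw <- ncol(k)
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  cr <- (kh + 1L) %/% 2L; cc <- (kw + 1L) %/% 2L
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(kh)) for (j in seq_len(kw)) {
    w <- k[i, j]
    if (w != 0) out <- out + w * shift_replicate(x, cr - i, cc - j)
  }
  out
}

# Separable Gaussian blur with a normalized kernel and replicate boundary,
# computed as banded-matrix products (fast for the 128 px frames used here).
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  blur_matrix(nrow(x), sigma) %*% x %*% t(blur_matrix(ncol(x), sigma))
}

blur_matrix_cache <- new.env(parent = emptyenv())

blur_matrix <- function(n, sigma) {
  key <- sprintf("%d|%.8g", n, sigma)
  got <- blur_matrix_cache[[key]]
  if (!is.null(got)) return(got)
  # under continuous defocus the sigmas rarely repeat: keep the cache bounded
  if (length(ls(blur_matrix_cache)) >= 64L)
    rm(list = ls(blur_matrix_cache), envir = blur_matrix_cache)
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  g <- g / sum(g)
  B <- matrix(0, n, n)
  for (o in (-r):r) {
    idx <- pmin(pmax(seq_len(n) + o, 1L), n)  # replicate edges
    B[cbind(seq_len(n), idx)] <- B[cbind(seq_len(n), idx)] + g[o + r + 1L]
  }
  blur_matrix_cache[[key]] <- B
  B
}

# Circular (wrap-around) shift by integer (dr, dc): out[i,j] = x[i-dr, j-dc].
circular_shift <- function(x, dr, dc) {
  H <- nrow(x); W <- ncol(x)
  x[((seq_len(H) - 1L - dr) %% H) + 1L,
    ((seq_len(W) - 1L - dc) %% W) + 1L, drop = FALSE]
}

# Move zero-frequency corners to the array center (fftshift); the center
# lands at 0-based (floor(H/2), floor(W/2)) for even and odd sizes alike.
fftshift2 <- function(x) circular_shift(x, nrow(x) %/% 2L, ncol(x) %/% 2L)
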