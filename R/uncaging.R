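# Uncaging-target relocation and depth-dependent stimulation parameters.
#
# Immediately before each photostimulation the target is re-aligned to the
# spine surface: the image is thresholded, the perimeter of the resulting
# foreground objects is extracted, and the target jumps to the nearest
# perimeter pixel. Pulse duration and laser power scale linearly with the
# depth of the spine in tissue to compensate scattering losses.

#' Threshold an image to a binary mask
#'
#' @param img numeric matrix.
#' @param threshold intensity cutoff; pixels `>= threshold` become foreground.
#' @param relative if `TRUE`, `threshold` is a fraction of the image maximum
#'   rather than an absolute intensity.
#' @return Integer 0/1 matrix of the same dimensions.
#' @export
binarize <- function(img, threshold, relative = FALSE) {
  check_image(img)
  stopifnot(is.finite(threshold))
  if (isTRUE(relative)) threshold <- threshold * max(img)
  (img >= threshold) + 0L
}

#' Perimeter pixels of a binary mask
#'
#' A foreground pixel belongs to the perimeter when at least one of its
#' 4-neighbors is background or lies outside the frame; this yields a closed
#' 8-connected boundary curve for the uncaging target to land on.
#'
#' @param mask 0/1 (or logical) matrix with at least one foreground pixel.
#' @return Two-column integer matrix of 1-based `(row, col)` perimeter
#'   coordinates, ordered by row then column.
#' @export
mask_perimeter <- function(mask) {
  m <- (mask != 0)
  if (!any(m)) stop("mask has no foreground pixels", call. = FALSE)
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  core <- pad[2:(H + 1L), 2:(W + 1L)]
  interior <- core &
    pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  per <- which(core & !interior, arr.ind = TRUE)
  per <- per[order(per[, 1], per[, 2]), , drop = FALSE]
  colnames(per) <- c("row", "col")
  per
}

#' Relocate an uncaging target to the nearest object perimeter
#'
#' Binarizes the image, extracts the perimeter of all foreground objects and
#' moves the target to the perimeter pixel at minimal Euclidean distance
#' (ties: smallest row, then smallest column).
#'
#' @param img numeric matrix (the current best-focus frame).
#' @param threshold intensity cutoff passed to [binarize()].
#' @param target length-2 numeric `(row, col)` of the current target (1-based).
#' @param relative see [binarize()].
#' @return Integer `(row, col)` of the relocated target. If no pixel clears
#'   the threshold a condition of class `spine_lost` is signalled, which the
#'   session runner uses to drop the position from rotation.
#' @export
relocate_target <- function(img, threshold, target, relative = FALSE) {
  stopifnot(length(target) == 2)
  mask <- binarize(img, threshold, relative)
  if (!any(mask != 0))
    stop(structure(class = c("spine_lost", "error", "condition"),
                   list(message = "no foreground above threshold: spine lost",
                        call = sys.call())))
  per <- mask_perimeter(mask)
  d2 <- (per[, 1] - target[1])^2 + (per[, 2] - target[2])^2
  best <- which(d2 == min(d2))[1L]  # rows pre-sorted by (row, col)
  c(row = unname(per[best, 1]), col = unname(per[best, 2]))
}

#' Depth-dependent uncaging parameters
#'
#' Laser power and pulse duration are interpolated linearly over the tissue
#' depth range: (4 ms, 3.5 mW) at the shallow end to (8 ms, 4.0 mW) at the
#' deep end, compensating scattering in slice tissue. The pulse train is
#' fixed at 30 pulses delivered at 1 Hz.
#'
#' @param depth_um spine depth in tissue (clamped into the range).
#' @param depth_min_um,depth_max_um depth range covered by the experiment.
#' @return List with `power_mW`, `pulse_ms`, `n_pulses`, `rate_Hz`.
#' @export
uncaging_params_for_depth <- function(depth_um, depth_min_um = 0,
                                      depth_max_um = 50) {
  if (!(depth_min_um < depth_max_um))
    stop("degenerate depth range", call. = FALSE)
  f <- (min(max(depth_um, depth_min_um), depth_max_um) - depth_min_um) /
    (depth_max_um - depth_min_um)
  list(power_mW = 3.5 + 0.5 * f, pulse_ms = 4 + 4 * f,
       n_pulses = 30L, rate_Hz = 1)
}
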