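# Spine structural-plasticity quantification: sum-project each time point's
# Z-stack, integrate fluorescence in spine (oval) and dendrite (polygon)
# ROIs as a volume proxy, normalize each object to its pre-uncaging mean,
# and compute transient (1-3 min) and sustained (26-30 min) phase statistics
# with unpaired t-tests against the dendrite control.

#' Quantification regions of interest
#'
#' Ovals select spines, polygons select dendrite segments. A pixel belongs
#' to an ROI when its center falls inside the shape (deterministic and
#' resolution-independent).
#'
#' @param center_row,center_col oval center in pixel coordinates (1-based).
#' @param semi_row,semi_col oval semi-axes in pixels.
#' @param vertices two-column matrix of polygon vertices `(row, col)`.
#' @param label object label: `"stimulated"`, `"adjacent"`, or `"dendrite"`.
#' @return Object of class `quant_roi`.
#' @export
oval_roi <- function(center_row, center_col, semi_row, semi_col,
                     label = c("stimulated", "adjacent", "dendrite")) {
  stopifnot(semi_row > 0, semi_col > 0)
  structure(list(kind = "oval", center = c(center_row, center_col),
                 semi = c(semi_row, semi_col), label = match.arg(label)),
            class = "quant_roi")
}

#' @rdname oval_roi
#' @export
polygon_roi <- function(vertices, label = c("stimulated", "adjacent", "dendrite")) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 3)
  structure(list(kind = "polygon", vertices = vertices, label = match.arg(label)),
            class = "quant_roi")
}

#' Logical pixel mask of a quantification ROI
#'
#' @param roi a [oval_roi()] or [polygon_roi()].
#' @param dim image dimensions `c(rows, cols)`.
#' @return Logical matrix; `TRUE` where the pixel center lies inside.
#' @export
roi_mask <- function(roi, dim) {
  stopifnot(inherits(roi, "quant_roi"), length(dim) == 2)
  H <- dim[1]; W <- dim[2]
  if (roi$kind == "oval") {
    r <- matrix(seq_len(H), H, W)
    c <- matrix(seq_len(W), H, W, byrow = TRUE)
    m <- ((r - roi$center[1]) / roi$semi[1])^2 +
      ((c - roi$center[2]) / roi$semi[2])^2 <= 1
  } else {
    pts <- cbind(rep(seq_len(H), W), rep(seq_len(W), each = H))
    inside <- mgcv::in.out(rbind(roi$vertices, roi$vertices[1, ]),
                           pts)
    m <- matrix(inside, H, W)
  }
  if (!any(m)) stop("ROI covers no pixel centers", call. = FALSE)
  m
}

#' Sum projection of a Z-stack
#'
#' @param stack a [zstack()] (or list of matrices).
#' @return Pixelwise sum of all slices.
#' @export
sum_project <- function(stack) {
  slices <- if (inherits(stack, "zstack")) stack$slices else stack
  stopifnot(is.list(slices), length(slices) >= 1)
  Reduce(`+`, slices)
}

#' Integrated ROI fluorescence (volume proxy)
#'
#' Sums the pixels whose centers fall inside the ROI. With a background ROI,
#' the mean background intensity times the ROI pixel count is subtracted
#' first.
#'
#' @param img image (typically a [sum_project()]ion).
#' @param roi a [oval_roi()]/[polygon_roi()].
#' @param background_roi optional ROI sampling background.
#' @return Scalar intensity sum.
#' @export
integrate_roi <- function(img, roi, background_roi = NULL) {
  m <- roi_mask(roi, dim(img))
  total <- sum(img[m])
  if (!is.null(background_roi)) {
    bm <- roi_mask(background_roi, dim(img))
    total <- total - mean(img[bm]) * sum(m)
  }
  total
}

#' Normalize volume traces to their pre-uncaging baseline
#'
#' Each object's trace is divided by its own mean over the pre-uncaging
#' window, so every normalized trace averages 1 before stimulation.
#'
#' @param traces data.frame with columns `time_min` (relative to uncaging at
#'   t = 0), `object_id`, `label`, `value` (integrated intensity).
#' @param pre_window length-2 numeric; times in `[pre_window[1],
#'   pre_window[2]]` form the baseline (default: everything before 0).
#' @return data.frame of class `volume_series` with added columns
#'   `normalized_volume` (V/V0) and `delta_volume` (V/V0 - 1).
#' @export
normalize_series <- function(traces, pre_window = c(-Inf, 0)) {
  stopifnot(all(c("time_min", "object_id", "label", "value") %in% names(traces)))
  out <- traces
  out$normalized_volume <- NA_real_
  for (id in unique(out$object_id)) {
    sel <- out$object_id == id
    pre <- sel & out$time_min >= pre_window[1] & out$time_min < pre_window[2]
    if (!any(pre))
      stop(sprintf("object '%s' has no pre-uncaging time points", id),
           call. = FALSE)
    v0 <- mean(out$value[pre])
    if (!is.finite(v0) || v0 <= 0)
      stop(sprintf("object '%s' has non-positive pre-uncaging mean", id),
           call. = FALSE)
    out$normalized_volume[sel] <- out$value[sel] / v0
  }
  out$delta_volume <- out$normalized_volume - 1
  class(out) <- c("volume_series", "data.frame")
  out
}

#' Transient and sustained phase statistics
#'
#' For each object, the phase value is the mean volume change (V/V0 - 1)
#' over the window's samples; group means of stimulated and adjacent spines
#' are each compared to the dendrite control with a two-tailed unpaired
#' (pooled-variance) t-test.
#'
#' @param series a [normalize_series()] result.
#' @param transient_window,sustained_window closed time windows in minutes
#'   relative to uncaging onset (defaults 1-3 and 26-30 min).
#' @return data.frame of class `phase_stats`: one row per phase x comparison
#'   with the group mean change, dendrite mean change, `t`, `df`, `p`, and
#'   group sizes.
#' @export
phase_stats <- function(series, transient_window = c(1, 3),
                        sustained_window = c(26, 30)) {
  stopifnot(inherits(series, "data.frame"),
            all(c("time_min", "object_id", "label", "delta_volume") %in%
                  names(series)))
  phase_values <- function(win, label) {
    sel <- series$label == label & series$time_min >= win[1] &
      series$time_min <= win[2]
    if (!any(sel))
      stop(sprintf("no '%s' samples in window [%g, %g] min", label,
                   win[1], win[2]), call. = FALSE)
    tapply(series$delta_volume[sel], series$object_id[sel], mean)
  }
  one <- function(phase, win, label) {
    g <- phase_values(win, label)
    d <- phase_values(win, "dendrite")
    tt <- stats::t.test(g, d, var.equal = TRUE)
    data.frame(phase = phase, comparison = paste0(label, " vs dendrite"),
               mean_change = mean(g), dendrite_change = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, n = length(g), n_dendrite = length(d))
  }
  labels <- intersect(c("stimulated", "adjacent"), unique(series$label))
  rows <- list()
  for (lab in labels) {
    rows[[length(rows) + 1L]] <- one("transient", transient_window, lab)
    rows[[length(rows) + 1L]] <- one("sustained", sustained_window, lab)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("phase_stats", "data.frame")
  out
}

#' @export
print.phase_stats <- function(x, ...) {
  cat("Spine volume change by phase (unpaired t vs dendrite control)\n")
  y <- x
  y$mean_change <- sprintf("%+.3f", y$mean_change)
  y$dendrite_change <- sprintf("%+.3f", y$dendrite_change)
  y$t <- sprintf("%.2f", y$t)
  y$p <- format.pval(y$p, digits = 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
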