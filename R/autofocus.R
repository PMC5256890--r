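# Autofocus engine: pick the best focal slice of a Z-stack with a chosen
# focus operator, and benchmark all operators against annotated stacks using
# the relative-accuracy metric (100% = exact slice, 0% = farthest slice,
# 50% = expectation of a uniformly random pick with a centered target).

#' Z-stack of equally spaced image slices
#'
#' @param slices list of numeric matrices, all the same dimensions, ordered
#'   by increasing depth.
#' @param z_um numeric vector of slice depths in micrometres (strictly
#'   increasing, uniform step), or a single start value used with `step_um`.
#' @param step_um slice spacing in micrometres when `z_um` is a scalar start.
#' @return Object of class `zstack`.
#' @export
zstack <- function(slices, z_um = 0, step_um = NULL) {
  if (!is.list(slices) || length(slices) < 2L)
    stop("a zstack needs at least 2 slices", call. = FALSE)
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all slices must have identical dimensions", call. = FALSE)
  n <- length(slices)
  if (length(z_um) == 1L && !is.null(step_um))
    z_um <- z_um + step_um * (seq_len(n) - 1L)
  if (length(z_um) != n)
    stop("z_um must match the number of slices", call. = FALSE)
  dz <- diff(z_um)
  if (any(dz <= 0)) stop("z positions must be strictly increasing", call. = FALSE)
  if (max(dz) - min(dz) > 1e-9)
    stop("z spacing must be uniform (within 1e-9 um)", call. = FALSE)
  structure(list(slices = slices, z_um = as.numeric(z_um)), class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<zstack> %d slices of %d x %d px, z = %.3g..%.3g um (step %.3g)\n",
              length(x$slices), d[1], d[2], x$z_um[1],
              x$z_um[length(x$z_um)], x$z_um[2] - x$z_um[1]))
  invisible(x)
}

#' @export
length.zstack <- function(x) length(x$slices)

#' Autofocus routine configuration
#'
#' Bundles the user-facing autofocus parameters: the half-range and step of
#' the Z search, how often the routine runs, which operator scores the
#' slices, and how the correction is applied.
#'
#' @param range_um half-range of the Z search (stack spans `center +/- range_um`).
#' @param step_um slice spacing of the search stack.
#' @param frequency run autofocus every `frequency`-th imaging cycle.
#' @param operator focus operator id (see [focus_operators()]).
#' @param roi optional [rect_roi()] restricting focus evaluation to the spine.
#' @param correction_mode `"scan-shift"` (galvanometer offset) or `"motor"`.
#' @param use_etl logical; whether axial moves are made with the tunable lens.
#' @return Object of class `autofocus_config`.
#' @export
autofocus_config <- function(range_um = 1.5, step_um = 0.5, frequency = 1L,
                             operator = "BREN", roi = NULL,
                             correction_mode = c("scan-shift", "motor"),
                             use_etl = TRUE) {
  stopifnot(range_um > 0, step_um > 0, frequency >= 1)
  structure(list(range_um = range_um, step_um = step_um,
                 frequency = as.integer(frequency), operator = operator,
                 roi = roi, correction_mode = match.arg(correction_mode),
                 use_etl = isTRUE(use_etl)),
            class = "autofocus_config")
}

#' Focus value per slice of a Z-stack
#'
#' @param stack a [zstack()].
#' @param op focus operator id.
#' @param roi optional [rect_roi()].
#' @param params operator parameter overrides, see [compute_focus()].
#' @return data.frame with columns `z_um` and `focus` (slice order preserved).
#' @export
focus_curve <- function(stack, op, roi = NULL, params = list()) {
  stopifnot(inherits(stack, "zstack"))
  vals <- vapply(stack$slices, compute_focus, numeric(1),
                 op = op, roi = roi, params = params)
  data.frame(z_um = stack$z_um, focus = vals)
}

# Argmax with ties broken toward a preferred index (stack center), then
# toward the lower index.
argmax_toward <- function(vals, prefer) {
  m <- max(vals)
  cand <- which(vals >= m - 0)  # exact ties
  cand[order(abs(cand - prefer), cand)][1L]
}

#' Best-focus slice of a Z-stack
#'
#' Scores every slice with the chosen operator and returns the index of the
#' maximal focus value. Ties are broken toward the stack center (the previous
#' best-focus estimate in a tracking loop), then toward the lower index.
#'
#' @inheritParams focus_curve
#' @return 1-based slice index.
#' @export
best_focus <- function(stack, op, roi = NULL, params = list()) {
  fc <- focus_curve(stack, op, roi, params)
  argmax_toward(fc$focus, (length(stack) + 1) / 2)
}

#' Relative accuracy of a focal-slice selection
#'
#' Standardized distance between the selected and target slice, expressed as
#' a percentage: 100 for an exact hit, 0 for the slice farthest from the
#' target, and linear in between. A selector that picks uniformly at random
#' over the Z range of a stack with a centered target scores 50 on average.
#'
#' @param z_selected,z_target 1-based slice indices (may be fractional for a
#'   continuous selection along the Z range).
#' @param n_slices number of slices in the stack.
#' @return Accuracy in percent, in `[0, 100]`.
#' @export
relative_accuracy <- function(z_selected, z_target, n_slices) {
  stopifnot(n_slices >= 1)
  if (any(z_selected < 1 | z_selected > n_slices) ||
      any(z_target < 1 | z_target > n_slices))
    stop("slice indices must lie in [1, n_slices]", call. = FALSE)
  d_max <- pmax(z_target - 1, n_slices - z_target)
  acc <- 100 * (1 - abs(z_selected - z_target) / d_max)
  # d_max = 0 only in a single-slice stack, where the selection is exact
  acc[!is.finite(acc)] <- 100
  acc
}

#' Benchmark focus operators against annotated Z-stacks
#'
#' Runs each operator over a dataset of stacks with known target slices and
#' reports the mean relative accuracy and mean per-slice compute time, the
#' two axes of the algorithm-selection tool.
#'
#' @param dataset list of entries, each a list with elements `stack`
#'   ([zstack()]), `target` (1-based annotated focal index) and optionally
#'   `roi` ([rect_roi()]).
#' @param ops operator ids to evaluate; default all 27.
#' @return data.frame (class `focus_benchmark`) with columns `operator`,
#'   `accuracy_pct`, `mean_time_s`, sorted by decreasing accuracy. Timings
#'   are informational only (they depend on the machine).
#' @export
benchmark_operators <- function(dataset, ops = focus_operators()) {
  if (length(dataset) == 0) stop("dataset is empty", call. = FALSE)
  for (e in dataset) {
    stopifnot(inherits(e$stack, "zstack"))
    if (e$target < 1 || e$target > length(e$stack))
      stop("target index outside stack", call. = FALSE)
  }
  n_slices_total <- sum(vapply(dataset, function(e) length(e$stack), numeric(1)))
  res <- lapply(ops, function(op) {
    t0 <- proc.time()[["elapsed"]]
    acc <- vapply(dataset, function(e) {
      sel <- best_focus(e$stack, op, e$roi)
      relative_accuracy(sel, e$target, length(e$stack))
    }, numeric(1))
    t1 <- proc.time()[["elapsed"]]
    data.frame(operator = op, accuracy_pct = mean(acc),
               mean_time_s = (t1 - t0) / n_slices_total)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$accuracy_pct, out$operator), ]
  rownames(out) <- NULL
  class(out) <- c("focus_benchmark", "data.frame")
  out
}

#' @export
print.focus_benchmark <- function(x, ...) {
  cat(sprintf("Focus-operator benchmark (%d operators)\n", nrow(x)))
  y <- x
  y$accuracy_pct <- sprintf("%6.1f", y$accuracy_pct)
  y$mean_time_s <- sprintf("%.2e", y$mean_time_s)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
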