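# File formats: multi-page TIFF Z-stacks (16-bit grayscale), benchmark
# manifests (CSV), session plans (JSON/YAML), quantification tables (CSV).

# Intensities are stored in 16-bit TIFF as round(value / scale) with the
# scale recorded by the caller; the default scale 1 suits the phantom's
# 0..~400 intensity range.

#' Read or write a Z-stack as a multi-page TIFF
#'
#' @param stack a [zstack()].
#' @param path TIFF file path.
#' @param scale intensity units per 16-bit count (write: values are divided
#'   by `scale` and rounded; read: counts are multiplied back).
#' @param z_um,step_um depth axis for the slices read back (the TIFF itself
#'   carries no Z metadata).
#' @return `read_zstack_tiff()` returns a [zstack()];
#'   `write_zstack_tiff()` returns `path` invisibly.
#' @export
write_zstack_tiff <- function(stack, path, scale = 1) {
  stopifnot(inherits(stack, "zstack"))
  pages <- lapply(stack$slices, function(s) {
    m <- round(s / scale)
    if (any(m > 65535)) stop("intensity overflows 16-bit range; raise scale",
                             call. = FALSE)
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_zstack_tiff
#' @export
read_zstack_tiff <- function(path, z_um = 0, step_um = 0.5, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  slices <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p * 65535 * scale
  })
  zstack(slices, z_um = z_um, step_um = step_um)
}

#' Read a focus-benchmark manifest and its stacks
#'
#' The manifest is a CSV with columns `filename`, `target_slice_index`
#' (1-based), and ROI columns `roi_row0`, `roi_col0`, `roi_h`, `roi_w`
#' (0-based top-left; all-NA rows mean full frame). Stack TIFFs are resolved
#' relative to the manifest's directory.
#'
#' @param manifest_csv path to the manifest CSV.
#' @return Dataset list suitable for [benchmark_operators()].
#' @export
read_benchmark_manifest <- function(manifest_csv) {
  man <- utils::read.csv(manifest_csv, stringsAsFactors = FALSE)
  stopifnot(all(c("filename", "target_slice_index") %in% names(man)))
  dir <- dirname(manifest_csv)
  lapply(seq_len(nrow(man)), function(i) {
    roi <- NULL
    if (all(c("roi_row0", "roi_col0", "roi_h", "roi_w") %in% names(man)) &&
        !is.na(man$roi_row0[i]))
      roi <- rect_roi(man$roi_row0[i], man$roi_col0[i], man$roi_h[i],
                      man$roi_w[i])
    list(stack = read_zstack_tiff(file.path(dir, man$filename[i])),
         target = man$target_slice_index[i], roi = roi)
  })
}

#' Write a benchmark report CSV
#'
#' @param result a [benchmark_operators()] result.
#' @param path output CSV path.
#' @export
write_benchmark_report <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}

#' Serialize or load a session plan (JSON or YAML by extension)
#'
#' @param plan a [session_plan()].
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return `read_session_plan()` returns a [session_plan()].
#' @export
write_session_plan <- function(plan, path) {
  stopifnot(inherits(plan, "session_plan"))
  obj <- list(capacity = if (is.finite(plan$capacity)) plan$capacity else "unlimited",
              tick_s = plan$tick_s,
              steps = lapply(plan$steps, function(s)
                s[!vapply(s, function(v) is.na(v)[1], logical(1))]))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_session_plan
#' @export
read_session_plan <- function(path) {
  obj <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  steps <- lapply(obj$steps, function(s)
    timeline_step(s$position_id, s$kind, s$start_s %||% 0,
                  s$duration_s %||% 0, s$period_s))
  cap <- obj$capacity
  if (identical(cap, "unlimited")) cap <- Inf
  session_plan(steps, capacity = cap, tick_s = obj$tick_s %||% 0.1)
}

#' Write a synthetic benchmark dataset to disk
#'
#' Renders seeded phantom stacks with randomized focal planes as 16-bit
#' multi-page TIFFs plus a [read_benchmark_manifest()]-compatible CSV and a
#' ground-truth JSON — the virtual counterpart of a directory of annotated
#' Z-stacks for the algorithm-selection tool.
#'
#' @param dir output directory (created if missing).
#' @param n_stacks number of stacks.
#' @param scope a [microscope()].
#' @param af an [autofocus_config()] (stack geometry).
#' @param seed RNG seed.
#' @return The manifest path, invisibly.
#' @export
simulate_benchmark_dataset <- function(dir, n_stacks = 30, scope = microscope(),
                                       af = autofocus_config(), seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  ph <- default_phantom()
  n_slices <- length(seq(-af$range_um, af$range_um, by = af$step_um))
  rows <- list(); truth <- list()
  for (i in seq_len(n_stacks)) {
    # random axial offset of the specimen inside the stack
    dz <- stats::runif(1, -af$range_um + af$step_um, af$range_um - af$step_um)
    acq <- acquire_stack(ph, af, scope, drift_um = c(0, 0, dz))
    fn <- sprintf("stack_%03d.tif", i)
    write_zstack_tiff(acq$stack, file.path(dir, fn))
    rows[[i]] <- data.frame(filename = fn,
                            target_slice_index = acq$truth$focal_index,
                            roi_row0 = NA, roi_col0 = NA, roi_h = NA, roi_w = NA)
    truth[[i]] <- list(filename = fn, z_true_um = acq$truth$z_true_um,
                       focal_index = acq$truth$focal_index)
  }
  man <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), man, row.names = FALSE)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(man)
}

#' Write session outputs as tidy CSV files
#'
#' @param session a [run_session()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_session_outputs <- function(session, dir) {
  stopifnot(inherits(session, "spine_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(session$log, file.path(dir, "session_log.csv"),
                   row.names = FALSE)
  if (!is.null(session$volumes))
    utils::write.csv(as.data.frame(session$volumes),
                     file.path(dir, "volume_series.csv"), row.names = FALSE)
  invisible(dir)
}
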