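# Closed-loop session runner against the virtual microscope: schedule
# imaging/uncaging events, and per imaging event acquire a stack, refocus,
# estimate lateral drift against the position's reference image, shift the
# acquisition window, and quantify ROIs; per uncaging event re-align the
# target to the spine perimeter and log the depth-modulated pulse
# parameters. Ground-truth tracking errors are logged alongside.

#' Map a motor position to a galvanometer scan offset
#'
#' All positions within one field of view are addressed purely by scan
#' (galvo) offsets relative to the single motor coordinate that defines the
#' FOV center; the map is linear and invertible.
#'
#' @param motor_xyz_um position `(x, y, z)` in motor micrometres.
#' @param fov_center_um the FOV-defining motor coordinate `(x, y, z)`.
#' @param fov_size_um lateral extent of the scannable field.
#' @param scan_range full scan-coordinate span corresponding to
#'   `fov_size_um` (arbitrary galvo units; default normalized to 1).
#' @return `motor_to_scan()`: scan offset `(x, y)` with the motor Z passed
#'   through unchanged; `scan_to_motor()` inverts it.
#' @export
motor_to_scan <- function(motor_xyz_um, fov_center_um, fov_size_um,
                          scan_range = 1) {
  stopifnot(length(motor_xyz_um) == 3, length(fov_center_um) == 3,
            fov_size_um > 0, scan_range > 0)
  d <- motor_xyz_um[1:2] - fov_center_um[1:2]
  if (any(abs(d) > fov_size_um / 2))
    stop("position lies outside the field of view", call. = FALSE)
  c(scan_x = d[[1]] / fov_size_um * scan_range,
    scan_y = d[[2]] / fov_size_um * scan_range,
    z_um = motor_xyz_um[[3]])
}

#' @rdname motor_to_scan
#' @param scan_xyz scan offset as returned by `motor_to_scan()`.
#' @export
scan_to_motor <- function(scan_xyz, fov_center_um, fov_size_um,
                          scan_range = 1) {
  stopifnot(length(scan_xyz) == 3)
  c(scan_xyz[[1]] / scan_range * fov_size_um + fov_center_um[[1]],
    scan_xyz[[2]] / scan_range * fov_size_um + fov_center_um[[2]],
    scan_xyz[[3]])
}

#' Imaging position for a virtual session
#'
#' @param id position label (must match the plan's `position_id`s).
#' @param ph a [phantom()] imaged at this position.
#' @param z_depth_um depth of the spine in tissue (drives the uncaging
#'   power/pulse modulation, see [uncaging_params_for_depth()]).
#' @param threshold binarization threshold for uncaging-target relocation.
#' @param rois optional list of [oval_roi()]/[polygon_roi()]; by default
#'   ROIs are placed from the phantom's own geometry (ovals over each spine
#'   head, a polygon over a clear dendrite segment).
#' @return Object of class `session_position`.
#' @export
session_position <- function(id, ph = default_phantom(), z_depth_um = 25,
                             threshold = 20, rois = NULL) {
  stopifnot(inherits(ph, "phantom"))
  structure(list(id = as.character(id), phantom = ph,
                 z_depth_um = z_depth_um, threshold = threshold,
                 rois = rois),
            class = "session_position")
}

# Default quantification ROIs from phantom geometry.
default_rois <- function(ph, scope) {
  px <- scope$px_um
  rois <- list()
  for (s in ph$spines) {
    ctr <- spine_head_center(ph, s) / px
    rois[[length(rois) + 1L]] <-
      oval_roi(ctr[1], ctr[2], 8, 8, label = s$label)
  }
  # dendrite segment away from the spines
  sx <- vapply(ph$spines, function(s) s$x_um, numeric(1))
  seg <- c(0.5, 2.5)
  if (length(sx) && min(sx) < 3) seg <- c(ph$frame_um - 2.9, ph$frame_um - 0.9)
  r0 <- (ph$dendrite_row_um - ph$dendrite_radius_um - 0.4) / px
  r1 <- (ph$dendrite_row_um + ph$dendrite_radius_um + 0.4) / px
  rois[[length(rois) + 1L]] <-
    polygon_roi(rbind(c(r0, seg[1] / px), c(r0, seg[2] / px),
                      c(r1, seg[2] / px), c(r1, seg[1] / px)),
                label = "dendrite")
  rois
}

#' Run a closed-loop virtual imaging/uncaging session
#'
#' Executes a [session_plan()] against the virtual microscope. Every imaging
#' event acquires a Z-stack at the current Z estimate, refocuses with the
#' configured operator, estimates lateral drift of the best-focus frame
#' against the reference captured at position definition, applies the
#' corrective scan shift (falling back to a zoomed-out reference when the
#' estimate hits the half-frame aliasing bound), and quantifies the ROIs on
#' the sum projection. Every uncaging event relocates the target to the
#' nearest point on the thresholded object perimeter and starts the
#' position's plasticity clock. Three consecutive relocation failures mark
#' the spine lost and drop the position.
#'
#' @param plan a [session_plan()].
#' @param positions list of [session_position()]s (one per plan position).
#' @param scope a [microscope()] (its [noise_model()] applies to every
#'   acquisition; references are captured with the same noise).
#' @param af an [autofocus_config()].
#' @param drift a [drift_model()] (advanced once per imaging frame).
#' @param plasticity a [plasticity_model()]; its onset is re-anchored to the
#'   actual uncaging execution time of each position.
#' @param correction enable lateral drift correction (on by default;
#'   disabling it lets the tracking error grow with the raw random walk).
#' @param imaging_s,uncaging_s durations charged to the event queue for an
#'   imaging cycle and an uncaging train (default 30 pulses at 1 Hz).
#' @param seed optional seed for the session's randomness.
#' @return Object of class `spine_session`: list with `log` (one row per
#'   executed event: times, drift estimate, applied correction, focus index,
#'   relocated target, true drift and tracking errors), `volumes` (a
#'   [normalize_series()] data.frame when uncaging occurred, else raw
#'   traces), and `lost` (ids of positions dropped as spine-lost).
#' @export
run_session <- function(plan, positions, scope = microscope(),
                        af = autofocus_config(), drift = drift_model(),
                        plasticity = plasticity_model(), correction = TRUE,
                        imaging_s = 1, uncaging_s = 30, seed = NULL) {
  stopifnot(inherits(plan, "session_plan"))
  if (!is.null(seed)) set.seed(seed)
  if (inherits(positions, "session_position")) positions <- list(positions)
  names(positions) <- vapply(positions, `[[`, character(1), "id")
  half <- scope$frame_px %/% 2L
  zoomed_out <- microscope(scope$frame_px, scope$px_um * 2, scope$sigma0_px,
                           scope$z_half_um, scope$noise)

  st <- new.env(parent = emptyenv())
  for (p in positions) {
    rois <- p$rois %||% default_rois(p$phantom, scope)
    st[[p$id]] <- list2env(list(
      drift = drift_state(), corr_um = c(x = 0, y = 0),
      z_est = p$phantom$z_um, uncaged_at_s = NA_real_,
      target = {
        s1 <- Filter(function(s) s$label == "stimulated", p$phantom$spines)
        if (length(s1)) round(spine_head_center(p$phantom, s1[[1]]) / scope$px_um)
        else c(row = scope$frame_px / 2, col = scope$frame_px / 2)
      },
      reference = render_slice(p$phantom, p$phantom$z_um, scope),
      reference_out = render_slice(p$phantom, p$phantom$z_um, zoomed_out),
      last_img = NULL, frame_count = 0L, rois = rois,
      roi_masks = lapply(rois, roi_mask,
                         dim = c(scope$frame_px, scope$frame_px)),
      fail_count = 0L, lost = FALSE,
      last_fire_s = 0), parent = emptyenv())
  }

  log_rows <- list(); vol_rows <- list()

  executor <- function(action) {
    ps <- st[[action$position_id]]
    p <- positions[[action$position_id]]
    if (ps$lost) return(0)
    if (action$kind == "imaging") {
      dt_min <- (action$fire_s - ps$last_fire_s) / 60
      ps$last_fire_s <- action$fire_s
      ps$drift <- step_drift(ps$drift, drift, dt_min)
      vf <- NULL
      if (!is.na(ps$uncaged_at_s)) {
        pm <- plasticity_model(ps$uncaged_at_s / 60, plasticity$A_trans,
                               plasticity$tau_trans_min, plasticity$A_sust)
        vf <- c(stimulated = spine_volume_factor(pm, action$fire_s / 60))
      }
      eff <- ps$drift$offset_um - c(ps$corr_um[["x"]], ps$corr_um[["y"]], 0)
      acq <- acquire_stack(p$phantom, af, scope, center_z_um = ps$z_est,
                           drift_um = eff, volume_factors = vf)
      ps$frame_count <- ps$frame_count + 1L
      if ((ps$frame_count - 1L) %% af$frequency == 0L) {
        idx <- best_focus(acq$stack, af$operator, af$roi)
        ps$z_est <- acq$stack$z_um[idx]
      } else {
        idx <- (length(acq$stack) + 1L) %/% 2L  # keep the current Z estimate
      }
      img <- acq$stack$slices[[idx]]
      ps$last_img <- img
      est <- list(d_row = 0L, d_col = 0L)
      fell_back <- FALSE
      if (correction) {
        est <- estimate_shift(ps$reference, img)
        if (max(abs(c(est$d_row, est$d_col))) >= half - 1) {
          # aliasing bound: realign once against the zoomed-out reference
          fell_back <- TRUE
          out_img <- render_slice(p$phantom, ps$z_est, zoomed_out,
                                  drift_um = eff, volume_factors = vf)
          est_out <- estimate_shift(ps$reference_out, out_img)
          est <- list(d_row = 2L * est_out$d_row, d_col = 2L * est_out$d_col)
        }
        ps$corr_um <- ps$corr_um + c(x = est$d_col * scope$px_um,
                                     y = est$d_row * scope$px_um)
      }
      resid_px <- (ps$drift$offset_um[1:2] -
                     c(ps$corr_um[["x"]], ps$corr_um[["y"]])) / scope$px_um
      proj <- sum_project(acq$stack)
      for (k in seq_along(ps$rois)) {
        roi <- ps$rois[[k]]
        vol_rows[[length(vol_rows) + 1L]] <<- data.frame(
          time_min = NA_real_, time_s = action$fire_s,
          object_id = paste(p$id, roi$label, k, sep = ":"),
          label = roi$label, value = sum(proj[ps$roi_masks[[k]]]),
          position_id = p$id)
      }
      log_rows[[length(log_rows) + 1L]] <<- data.frame(
        fire_s = action$fire_s, start_s = action$start_s,
        end_s = action$start_s + imaging_s,
        position_id = p$id, action = "imaging",
        d_row = est$d_row, d_col = est$d_col, fell_back = fell_back,
        focus_index = idx,
        true_focal_index = acq$truth$focal_index,
        focal_error_um = abs(ps$z_est - acq$truth$z_true_um),
        lateral_error_px = sqrt(sum(resid_px^2)),
        target_row = NA_integer_, target_col = NA_integer_,
        pulse_ms = NA_real_, power_mW = NA_real_)
      return(imaging_s)
    }
    # uncaging: re-align the target to the spine surface, then "fire"
    img <- ps$last_img %||% render_slice(
      p$phantom, ps$z_est, scope,
      drift_um = ps$drift$offset_um - c(ps$corr_um[["x"]], ps$corr_um[["y"]], 0))
    tgt <- tryCatch(relocate_target(img, p$threshold, ps$target),
                    spine_lost = function(e) NULL)
    if (is.null(tgt)) {
      ps$fail_count <- ps$fail_count + 1L
      if (ps$fail_count >= 3L) ps$lost <- TRUE
      log_rows[[length(log_rows) + 1L]] <<- data.frame(
        fire_s = action$fire_s, start_s = action$start_s,
        end_s = action$start_s,
        position_id = p$id, action = "uncaging-failed",
        d_row = NA_integer_, d_col = NA_integer_, fell_back = FALSE,
        focus_index = NA_integer_, true_focal_index = NA_integer_,
        focal_error_um = NA_real_, lateral_error_px = NA_real_,
        target_row = NA_integer_, target_col = NA_integer_,
        pulse_ms = NA_real_, power_mW = NA_real_)
      return(0)
    }
    ps$fail_count <- 0L
    ps$uncaged_at_s <- action$fire_s
    up <- uncaging_params_for_depth(p$z_depth_um)
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      fire_s = action$fire_s, start_s = action$start_s,
      end_s = action$start_s + uncaging_s,
      position_id = p$id, action = "uncaging",
      d_row = NA_integer_, d_col = NA_integer_, fell_back = FALSE,
      focus_index = NA_integer_, true_focal_index = NA_integer_,
      focal_error_um = NA_real_, lateral_error_px = NA_real_,
      target_row = tgt[["row"]], target_col = tgt[["col"]],
      pulse_ms = up$pulse_ms, power_mW = up$power_mW)
    uncaging_s
  }

  qlog <- run_queue(plan, executor)
  ev <- do.call(rbind, log_rows)
  vols <- do.call(rbind, vol_rows)
  if (!is.null(vols)) {
    # anchor each position's time axis to its actual uncaging execution
    for (id in names(positions)) {
      t0 <- st[[id]]$uncaged_at_s
      if (!is.na(t0)) {
        sel <- vols$position_id == id
        vols$time_min[sel] <- (vols$time_s[sel] - t0) / 60
      }
    }
    complete <- !anyNA(vols$time_min) &&
      all(tapply(vols$time_min < 0, vols$object_id, any)) &&
      any(vols$time_min >= 0)
    if (complete) vols <- normalize_series(vols)
  }
  lost <- names(which(vapply(names(positions),
                             function(id) st[[id]]$lost, logical(1))))
  structure(list(log = ev, volumes = vols, lost = lost, queue_log = qlog),
            class = "spine_session")
}

#' @export
print.spine_session <- function(x, ...) {
  n_img <- sum(x$log$action == "imaging")
  n_unc <- sum(x$log$action == "uncaging")
  cat(sprintf("<spine_session> %d imaging events, %d uncaging events, %d position(s) lost\n",
              n_img, n_unc, length(x$lost)))
  if (n_img) {
    err <- x$log$lateral_error_px[x$log$action == "imaging"]
    cat(sprintf("  final lateral tracking error %.2f px; mean %.2f px\n",
                err[length(err)], mean(err)))
  }
  invisible(x)
}
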