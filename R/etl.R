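# Electrically tunable lens (ETL) calibration: fit the control-value <-> Z
# mapping from autofocus-at-stepped-motor-Z data, invert it, and synthesize
# per-scanline control waveforms for tilted-plane imaging. Pure math; no
# device I/O. The control axis is the lens drive current in mA (0-300 for
# the reference device), a single abstract axis covering what GUIs variously
# label "voltage".

etl_control_range <- c(0, 300)

#' Collect ETL calibration points from stepped motor moves
#'
#' Calibration steps the Z motor through known displacements and autofocuses
#' using only the tunable lens at each step; the control value the autofocus
#' settles on, paired with the motor Z, forms one calibration point. Steps
#' where the autofocus fails are skipped with a warning.
#'
#' @param z_steps_um numeric vector of motor Z positions (>= 2 distinct).
#' @param etl_autofocus `function(z_um)` returning the control value (mA)
#'   that focuses the lens at that plane — in simulation, the virtual
#'   microscope's ETL response.
#' @return data.frame with `control_mA` and `z_um`, one row per successful
#'   step.
#' @export
run_calibration <- function(z_steps_um, etl_autofocus) {
  z_steps_um <- unique(as.numeric(z_steps_um))
  if (length(z_steps_um) < 2)
    stop("calibration needs at least 2 distinct z steps", call. = FALSE)
  rows <- lapply(z_steps_um, function(z) {
    ctrl <- tryCatch(etl_autofocus(z), error = function(e) {
      warning(sprintf("autofocus failed at z = %g um (%s); point skipped",
                      z, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(ctrl)) NULL else data.frame(control_mA = ctrl, z_um = z)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) < 2)
    stop("calibration failed: fewer than 2 usable points", call. = FALSE)
  out
}

#' Fit an ETL control-to-Z calibration curve
#'
#' Least-squares fit of focal displacement Z as a linear or polynomial
#' function of the control value. The fitted curve must be strictly
#' monotonic over the control range of the data, so that it can be inverted
#' to command a target Z.
#'
#' @param points data.frame with `control_mA` and `z_um`
#'   (from [run_calibration()]).
#' @param kind `"linear"` or `"polynomial"`.
#' @param degree polynomial degree (default 3; ignored for linear).
#' @return Object of class `etl_calibration`: coefficients (ascending
#'   powers of control), valid control/Z ranges, and fit residuals.
#' @export
fit_calibration <- function(points, kind = c("linear", "polynomial"),
                            degree = 3L) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(points), all(c("control_mA", "z_um") %in% names(points)))
  d <- if (kind == "linear") 1L else as.integer(degree)
  stopifnot(d >= 1)
  if (nrow(points) < d + 1L)
    stop(sprintf("need at least %d points for degree %d", d + 1L, d),
         call. = FALSE)
  fit <- stats::lm(z_um ~ stats::poly(control_mA, d, raw = TRUE), data = points)
  coefs <- unname(stats::coef(fit))
  ctrl_range <- range(points$control_mA)
  model <- structure(list(kind = kind, degree = d, coefficients = coefs,
                          control_range = ctrl_range,
                          z_range = sort(eval_poly(coefs, ctrl_range)),
                          residuals = unname(stats::residuals(fit))),
                     class = "etl_calibration")
  # strict monotonicity over the valid range, checked on a dense grid
  grid <- seq(ctrl_range[1], ctrl_range[2], length.out = 512L)
  dz <- diff(eval_poly(coefs, grid))
  if (!(all(dz > 0) || all(dz < 0)))
    stop("fitted curve is not strictly monotonic over the control range",
         call. = FALSE)
  model
}

eval_poly <- function(coefs, x) {
  out <- 0
  for (k in rev(seq_along(coefs))) out <- out * x + coefs[k]
  out
}

#' @export
print.etl_calibration <- function(x, ...) {
  cat(sprintf("<etl_calibration> %s (degree %d)\n", x$kind, x$degree))
  cat("  z(control) coefficients:", signif(x$coefficients, 6), "\n")
  cat(sprintf("  control range %g..%g mA -> z %g..%g um; max |residual| %.3g um\n",
              x$control_range[1], x$control_range[2],
              x$z_range[1], x$z_range[2],
              if (length(x$residuals)) max(abs(x$residuals)) else 0))
  invisible(x)
}

#' @rdname control_for_z
#' @export
z_for_control <- function(model, control_mA) {
  stopifnot(inherits(model, "etl_calibration"))
  if (any(control_mA < model$control_range[1] - 1e-9 |
          control_mA > model$control_range[2] + 1e-9))
    stop("control value outside calibrated range", call. = FALSE)
  eval_poly(model$coefficients, control_mA)
}

#' Convert between target Z and ETL control value
#'
#' `z_for_control()` evaluates the fitted curve; `control_for_z()` inverts
#' it (analytically for a linear fit, by bisection for polynomials — the fit
#' is guaranteed monotonic). Round trips agree to well under 1e-6 um.
#'
#' @param model an [fit_calibration()] result.
#' @param z_um,control_mA values to convert (vectorized).
#' @return Numeric vector of control values (mA) or Z positions (um).
#' @export
control_for_z <- function(model, z_um) {
  stopifnot(inherits(model, "etl_calibration"))
  if (any(z_um < model$z_range[1] - 1e-9 | z_um > model$z_range[2] + 1e-9))
    stop("z outside calibrated range", call. = FALSE)
  if (model$degree == 1L) {
    b <- model$coefficients
    return((z_um - b[1]) / b[2])
  }
  vapply(z_um, function(z) {
    stats::uniroot(function(c) eval_poly(model$coefficients, c) - z,
                   interval = model$control_range, tol = 1e-12,
                   extendInt = "no")$root
  }, numeric(1))
}

#' Per-scanline control waveform for tilted-plane imaging
#'
#' Tilting the imaging plane is achieved by updating the ETL control value
#' in phase with the slow-scanning galvanometer: scanline `i` of `n` images
#' the plane `z_center + (i - (n-1)/2) * dz_per_line`. The tilt is
#' parameterized as a Z increment per line (well-posed up to steep tilts,
#' unlike an angle).
#'
#' @param model an [fit_calibration()] result.
#' @param z_center_um Z of the frame center.
#' @param dz_per_line_um Z increment per scanline (0 = flat plane).
#' @param n_lines scanlines per frame.
#' @return Object of class `tilt_waveform`: list with `control_mA` (length
#'   `n_lines`), `z_um` per line, `z_center_um`, `dz_per_line_um`.
#' @export
tilt_waveform <- function(model, z_center_um, dz_per_line_um, n_lines) {
  stopifnot(inherits(model, "etl_calibration"), n_lines >= 1)
  z <- z_center_um + (seq_len(n_lines) - 1 - (n_lines - 1) / 2) * dz_per_line_um
  ctrl <- control_for_z(model, z)  # errors if any line leaves the range
  structure(list(control_mA = ctrl, z_um = z, z_center_um = z_center_um,
                 dz_per_line_um = dz_per_line_um),
            class = "tilt_waveform")
}

#' @export
print.tilt_waveform <- function(x, ...) {
  cat(sprintf("<tilt_waveform> %d lines, z %g..%g um (%+g um/line), control %g..%g mA\n",
              length(x$control_mA), min(x$z_um), max(x$z_um),
              x$dz_per_line_um, min(x$control_mA), max(x$control_mA)))
  invisible(x)
}

#' Save or load an ETL calibration as JSON
#'
#' @param model an [fit_calibration()] result.
#' @param path file path.
#' @return `read_calibration()` returns the `etl_calibration`;
#'   `write_calibration()` returns `path` invisibly.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "etl_calibration"))
  jsonlite::write_json(
    list(kind = model$kind, degree = model$degree,
         coefficients = model$coefficients,
         control_range = model$control_range, z_range = model$z_range),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(kind = j$kind, degree = as.integer(j$degree),
                 coefficients = as.numeric(j$coefficients),
                 control_range = as.numeric(j$control_range),
                 z_range = as.numeric(j$z_range), residuals = numeric(0)),
            class = "etl_calibration")
}
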