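# Virtual two-photon microscope: ground-truthed dendrite/spine phantoms
# imaged under defocus blur, shot + read noise, lateral/axial drift, and an
# uncaging-evoked volume transient, so the whole tracking loop is testable
# without hardware or downloads.
#
# Image formation model (thin-specimen optical sectioning): each structure
# contributes its projected column-density footprint (analytic, so
# sub-pixel lateral drift is exact), weighted by a normalized Gaussian
# axial response in (z_slice - z_structure) and blurred laterally with a
# normalized Gaussian kernel of width
#     sigma(dz) = sigma0 * sqrt(1 + (dz / z_half)^2).
# Blur conserves integrated intensity, and summing a stack over slices
# integrates the axial response, so the sum projection of a spine scales
# linearly with its simulated volume factor.

#' Virtual microscope parameters
#'
#' @param frame_px square frame size in pixels.
#' @param px_um pixel size in micrometres.
#' @param sigma0_px in-focus lateral PSF width (Gaussian sigma, pixels).
#' @param z_half_um axial half-width: defocus at which the lateral blur has
#'   grown by sqrt(2), and the sigma of the axial response.
#' @param noise a [noise_model()]; `noise_model()` (all zeros) is noise-free.
#' @return Object of class `microscope`.
#' @export
microscope <- function(frame_px = 128L, px_um = 0.1, sigma0_px = 1.3,
                       z_half_um = 0.8, noise = noise_model()) {
  stopifnot(frame_px >= 8, px_um > 0, sigma0_px > 0, z_half_um > 0)
  structure(list(frame_px = as.integer(frame_px), px_um = px_um,
                 sigma0_px = sigma0_px, z_half_um = z_half_um, noise = noise),
            class = "microscope")
}

#' Detection noise model
#'
#' Shot noise is Poisson on photon counts (`photons_per_unit` photons per
#' intensity unit; 0 disables it), read noise is additive Gaussian, and
#' `background` is a uniform offset added before the shot-noise draw.
#' Negative readouts are clipped at zero.
#'
#' @param photons_per_unit photon gain; the SNR at a pixel of intensity I is
#'   `sqrt(I * photons_per_unit)` when read noise is negligible.
#' @param read_sd Gaussian read-noise standard deviation (intensity units).
#' @param background uniform background level (intensity units).
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(photons_per_unit = 0, read_sd = 0, background = 0) {
  stopifnot(photons_per_unit >= 0, read_sd >= 0, background >= 0)
  structure(list(photons_per_unit = photons_per_unit, read_sd = read_sd,
                 background = background),
            class = "noise_model")
}

#' Noise model achieving a target peak signal-to-noise ratio
#'
#' @param snr target SNR at the brightest structure pixel.
#' @param peak_intensity nominal peak intensity of the phantom (the default
#'   matches [default_phantom()]'s dendrite).
#' @param read_sd,background passed through to [noise_model()].
#' @return A [noise_model()] with `photons_per_unit = snr^2 / peak_intensity`.
#' @export
noise_for_snr <- function(snr, peak_intensity = 100, read_sd = 0,
                          background = 0) {
  stopifnot(snr > 0, peak_intensity > 0)
  noise_model(snr^2 / peak_intensity, read_sd, background)
}

#' Dendrite/spine phantom
#'
#' A horizontal dendrite (cylinder along x) carrying spherical-headed spines
#' attached by thin necks, all lying in one specimen plane at `z_um`.
#' Intensities are emitter densities per micrometre of optical path, so a
#' rendered pixel value is density x projected thickness.
#'
#' @param frame_um field size in micrometres (square).
#' @param dendrite_row_um y (row) position of the dendrite axis.
#' @param dendrite_radius_um dendrite radius.
#' @param dendrite_intensity emitter density of the dendrite.
#' @param dendrite_modulation relative amplitude of the fixed smooth
#'   intensity variation along the dendrite axis (caliber variation /
#'   varicosities). It gives the image structure in both lateral directions,
#'   which real dendrites have and registration needs; 0 yields a perfectly
#'   uniform (x-invariant) cylinder.
#' @param spines list of [spine()]s.
#' @param z_um specimen plane depth.
#' @return Object of class `phantom`.
#' @export
phantom <- function(frame_um = 12.8, dendrite_row_um = 6.4,
                    dendrite_radius_um = 0.5, dendrite_intensity = 100,
                    dendrite_modulation = 0.35, spines = list(), z_um = 0) {
  stopifnot(dendrite_radius_um > 0, dendrite_intensity >= 0,
            dendrite_modulation >= 0, dendrite_modulation < 1)
  for (s in spines) stopifnot(inherits(s, "spine"))
  structure(list(frame_um = frame_um, dendrite_row_um = dendrite_row_um,
                 dendrite_radius_um = dendrite_radius_um,
                 dendrite_intensity = dendrite_intensity,
                 dendrite_modulation = dendrite_modulation,
                 spines = spines, z_um = z_um),
            class = "phantom")
}

#' @rdname phantom
#' @param x_um position of the spine along the dendrite (column direction).
#' @param side `-1` (spine extends toward smaller rows) or `+1`.
#' @param neck_um neck length from dendrite surface to head center.
#' @param head_radius_um baseline spine-head radius.
#' @param neck_radius_um neck radius.
#' @param intensity emitter density of the spine.
#' @param label `"stimulated"` or `"adjacent"` (drives the plasticity model
#'   and the quantification grouping).
#' @export
spine <- function(x_um, side = -1, neck_um = 1.2, head_radius_um = 0.3,
                  neck_radius_um = 0.05, intensity = 100,
                  label = c("stimulated", "adjacent")) {
  stopifnot(head_radius_um > 0, neck_um >= 0, side %in% c(-1, 1))
  structure(list(x_um = x_um, side = side, neck_um = neck_um,
                 head_radius_um = head_radius_um,
                 neck_radius_um = neck_radius_um, intensity = intensity,
                 label = match.arg(label)),
            class = "spine")
}

#' @rdname phantom
#' @export
default_phantom <- function() {
  # a realistically spiny dendrite (~0.5 per um, varied geometry); the first
  # is the uncaging target, the one at 8.0 um the scored neighbor
  phantom(spines = list(
    spine(5.1, side = -1, label = "stimulated"),
    spine(8.0, side = +1, label = "adjacent"),
    spine(1.6, side = +1, neck_um = 0.9, head_radius_um = 0.26,
          label = "adjacent"),
    spine(3.2, side = -1, neck_um = 1.0, head_radius_um = 0.33,
          label = "adjacent"),
    spine(6.6, side = +1, neck_um = 1.4, head_radius_um = 0.24,
          label = "adjacent"),
    spine(9.7, side = -1, neck_um = 0.8, head_radius_um = 0.30,
          label = "adjacent"),
    spine(11.3, side = +1, neck_um = 1.1, head_radius_um = 0.27,
          label = "adjacent")
  ))
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %g um field, dendrite r=%g um at row %g um, %d spine(s)\n",
              x$frame_um, x$dendrite_radius_um, x$dendrite_row_um,
              length(x$spines)))
  invisible(x)
}

# Head center of spine s (row, col) in specimen micrometres.
spine_head_center <- function(ph, s) {
  c(row = ph$dendrite_row_um + s$side * (ph$dendrite_radius_um + s$neck_um),
    col = s$x_um)
}

# Projected column-density footprint of the phantom on the pixel grid,
# shifted laterally by drift (row, col) in um. volume_factors scales each
# spine's head volume (radius ~ factor^(1/3)). The footprint is evaluated on
# an `oversample`-times finer subpixel grid and block-averaged, so that the
# integral of a sharp-rimmed structure is grid-alignment independent (the
# residual discretization error is ~0.2% at the default 4x).
phantom_footprint <- function(ph, scope, drift_rc_um = c(0, 0),
                              volume_factors = NULL, oversample = 4L) {
  os <- as.integer(oversample)
  n <- scope$frame_px * os; px <- scope$px_um / os
  yy <- (seq_len(n) - 0.5) * px
  xx <- yy
  img <- matrix(0, n, n)
  # dendrite: thickness 2*sqrt(r^2 - dy^2), density modulated along x
  dy <- yy - (ph$dendrite_row_um + drift_rc_um[1])
  thick <- 2 * sqrt(pmax(ph$dendrite_radius_um^2 - dy^2, 0))
  a <- ph$dendrite_modulation %||% 0
  dxx <- xx - drift_rc_um[2]
  prof <- 1 + a * (0.6 * sin(2 * pi * dxx / 5.3) +
                     0.4 * sin(2 * pi * dxx / 1.9 + 0.8))
  img <- img + ph$dendrite_intensity * outer(thick, prof)
  for (k in seq_along(ph$spines)) {
    s <- ph$spines[[k]]
    f <- 1
    if (!is.null(volume_factors)) {
      if (s$label %in% names(volume_factors)) f <- volume_factors[[s$label]]
      else if (is.null(names(volume_factors)) && length(volume_factors) >= k)
        f <- volume_factors[[k]]
    }
    rh <- s$head_radius_um * f^(1 / 3)
    ctr <- spine_head_center(ph, s) + drift_rc_um
    # only the head's bounding box can contribute
    ri <- which(abs(yy - ctr[1]) <= rh)
    ci <- which(abs(xx - ctr[2]) <= rh)
    if (length(ri) && length(ci)) {
      d2 <- outer((yy[ri] - ctr[1])^2, (xx[ci] - ctr[2])^2, `+`)
      img[ri, ci] <- img[ri, ci] + s$intensity * 2 * sqrt(pmax(rh^2 - d2, 0))
    }
    # neck: cylinder along the row direction
    if (s$neck_um > 0 && s$neck_radius_um > 0) {
      y0 <- ph$dendrite_row_um + drift_rc_um[1]
      ys <- sort(c(y0 + s$side * ph$dendrite_radius_um, ctr[1]))
      rows <- which(yy >= ys[1] & yy <= ys[2])
      cols <- which(abs(xx - ctr[2]) <= s$neck_radius_um)
      if (length(rows) && length(cols)) {
        tn <- 2 * sqrt(pmax(s$neck_radius_um^2 - (xx[cols] - ctr[2])^2, 0))
        img[rows, cols] <- img[rows, cols] +
          s$intensity * matrix(tn, length(rows), length(cols), byrow = TRUE)
      }
    }
  }
  downsample_mean(img, os)
}

# Block-average an (os*n) x (os*n) matrix down to n x n.
downsample_mean <- function(big, os) {
  if (os == 1L) return(big)
  N <- nrow(big); n <- N %/% os
  b1 <- matrix(colSums(matrix(big, nrow = os)), nrow = n)       # rows
  b2 <- matrix(colSums(matrix(t(b1), nrow = os)), nrow = n)     # cols
  t(b2) / os^2
}

apply_noise <- function(img, nm) {
  out <- img + nm$background
  if (nm$photons_per_unit > 0)
    out <- stats::rpois(length(out), out * nm$photons_per_unit) /
      nm$photons_per_unit
  if (nm$read_sd > 0)
    out <- out + stats::rnorm(length(out), sd = nm$read_sd)
  matrix(pmax(out, 0), nrow(img), ncol(img))
}

#' Render one image plane of a phantom
#'
#' @param ph a [phantom()].
#' @param z_um depth of the imaged plane.
#' @param scope a [microscope()].
#' @param defocus_um additional defocus applied on top of the geometric
#'   `z_um - z(structure)` distance (useful for isolating the blur response).
#' @param drift_um current specimen drift `(x, y, z)` in micrometres
#'   (x = columns, y = rows).
#' @param volume_factors named scaling of spine head volumes, e.g.
#'   `c(stimulated = 2.4)`; see [spine_volume_factor()].
#' @param noise logical; apply the scope's [noise_model()].
#' @param footprint precomputed [phantom_footprint] (internal reuse across
#'   the slices of one stack; the footprint depends on drift and volume
#'   factors but not on z).
#' @return Numeric matrix `frame_px` x `frame_px`.
#' @export
render_slice <- function(ph, z_um, scope = microscope(), defocus_um = 0,
                         drift_um = c(0, 0, 0), volume_factors = NULL,
                         noise = TRUE, footprint = NULL) {
  stopifnot(inherits(ph, "phantom"), inherits(scope, "microscope"))
  z_struct <- ph$z_um + drift_um[3]
  dz <- z_um - z_struct + defocus_um
  axial <- exp(-(z_um - z_struct)^2 / (2 * scope$z_half_um^2))
  foot <- footprint %||% phantom_footprint(
    ph, scope, drift_rc_um = c(drift_um[2], drift_um[1]),
    volume_factors = volume_factors)
  sig <- scope$sigma0_px * sqrt(1 + (dz / scope$z_half_um)^2)
  img <- gaussian_blur(axial * foot, sig)
  if (isTRUE(noise)) img <- apply_noise(img, scope$noise)
  img
}

#' Uncaging-evoked spine volume factor
#'
#' Baseline 1 before uncaging onset; from onset, a sustained plateau plus an
#' exponentially decaying transient:
#' `1 + A_sust + A_trans * exp(-(t - t0) / tau)` for `t >= t0`.
#'
#' @param t0_min uncaging onset (minutes).
#' @param A_trans amplitude of the transient component.
#' @param tau_trans_min transient decay constant (minutes).
#' @param A_sust sustained (long-lasting) amplitude.
#' @return `plasticity_model()` returns the model object;
#'   `spine_volume_factor()` the (vectorized) factor at `t_min`.
#' @export
plasticity_model <- function(t0_min = 0, A_trans = 2.0, tau_trans_min = 1.5,
                             A_sust = 0.6) {
  stopifnot(A_trans >= 0, A_sust >= 0, tau_trans_min > 0)
  structure(list(t0_min = t0_min, A_trans = A_trans,
                 tau_trans_min = tau_trans_min, A_sust = A_sust),
            class = "plasticity_model")
}

#' @rdname plasticity_model
#' @param model a [plasticity_model()].
#' @param t_min time in minutes.
#' @export
spine_volume_factor <- function(model, t_min) {
  stopifnot(inherits(model, "plasticity_model"))
  ifelse(t_min < model$t0_min, 1,
         1 + model$A_sust +
           model$A_trans * exp(-(t_min - model$t0_min) / model$tau_trans_min))
}

#' Specimen drift model and state
#'
#' Per-axis Gaussian random walk plus optional linear creep. Randomness
#' comes from R's global RNG; seed the session with `set.seed()` for
#' reproducible drift histories.
#'
#' @param sigma_um random-walk step standard deviation per frame, scalar or
#'   per-axis `(x, y, z)`.
#' @param creep_um_per_min deterministic creep velocity `(x, y, z)`.
#' @return `drift_model()`/`drift_state()` return the respective objects;
#'   `step_drift()` the advanced state.
#' @export
drift_model <- function(sigma_um = 0.15, creep_um_per_min = c(0, 0, 0)) {
  if (length(sigma_um) == 1) sigma_um <- rep(sigma_um, 3)
  stopifnot(length(sigma_um) == 3, all(sigma_um >= 0),
            length(creep_um_per_min) == 3)
  structure(list(sigma_um = sigma_um, creep_um_per_min = creep_um_per_min),
            class = "drift_model")
}

#' @rdname drift_model
#' @param offset_um initial `(x, y, z)` offset.
#' @export
drift_state <- function(offset_um = c(0, 0, 0)) {
  stopifnot(length(offset_um) == 3)
  structure(list(offset_um = as.numeric(offset_um)), class = "drift_state")
}

#' @rdname drift_model
#' @param state a [drift_state()].
#' @param model a [drift_model()].
#' @param dt_min minutes elapsed since the previous frame (scales creep,
#'   not the per-frame random-walk step).
#' @export
step_drift <- function(state, model, dt_min = 1) {
  stopifnot(inherits(state, "drift_state"), inherits(model, "drift_model"))
  step <- if (any(model$sigma_um > 0))
    stats::rnorm(3, 0, model$sigma_um) else c(0, 0, 0)
  drift_state(state$offset_um + step + model$creep_um_per_min * dt_min)
}

#' Acquire a virtual Z-stack around a commanded center plane
#'
#' Renders `2 * range_um / step_um + 1` slices spanning
#' `center_z_um +/- range_um` with the current drift applied to the
#' specimen, and returns the stack together with its ground truth.
#'
#' @param ph a [phantom()].
#' @param af an [autofocus_config()] giving range and step.
#' @param scope a [microscope()].
#' @param center_z_um commanded stack center (the tracker's current Z
#'   estimate).
#' @param drift_um specimen drift `(x, y, z)` in micrometres.
#' @param volume_factors,noise passed to [render_slice()].
#' @return List with `stack` (a [zstack()]) and `truth`: the true focal
#'   plane `z_true_um`, the 1-based `focal_index` of the slice nearest it
#'   (NA when the true plane lies outside the stack), and the true lateral
#'   drift `drift_px` as `(row, col)` pixels.
#' @export
acquire_stack <- function(ph, af = autofocus_config(), scope = microscope(),
                          center_z_um = 0, drift_um = c(0, 0, 0),
                          volume_factors = NULL, noise = TRUE) {
  z <- seq(center_z_um - af$range_um, center_z_um + af$range_um,
           by = af$step_um)
  foot <- phantom_footprint(ph, scope,
                            drift_rc_um = c(drift_um[2], drift_um[1]),
                            volume_factors = volume_factors)
  slices <- lapply(z, render_slice, ph = ph, scope = scope,
                   drift_um = drift_um, volume_factors = volume_factors,
                   noise = noise, footprint = foot)
  z_true <- ph$z_um + drift_um[3]
  idx <- which.min(abs(z - z_true))
  if (abs(z[idx] - z_true) > af$step_um) idx <- NA_integer_
  list(stack = zstack(slices, z),
       truth = list(z_true_um = z_true, focal_index = idx,
                    drift_px = c(row = drift_um[2] / scope$px_um,
                                 col = drift_um[1] / scope$px_um)))
}
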