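---
title: "Methods: automated spine tracking, photostimulation targeting, and the virtual microscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated spine tracking, photostimulation targeting, and the virtual microscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinetrack)
```

## Why this package exists

Quantifying structural long-term potentiation (sLTP) of dendritic spines
means holding a micron-scale target in focus and in frame for an hour while
the tissue drifts, then photostimulating it with micron precision, and
finally reading out a fluorescence-based volume trace. `spinetrack`
implements the software side of that workflow — focus scoring, autofocus
algorithm selection, Fourier drift correction, uncaging-target relocation,
a timer/event-queue acquisition scheduler, tunable-lens calibration math,
and volume quantification — together with a fully synthetic two-photon
microscope, so every control loop can be exercised and validated at the
desk, with ground truth, and no hardware.

## Focus measures and autofocus

`compute_focus()` exposes 27 operators: 25 classical measures from the
autofocus literature (Brenner gradient, Tenengrad and its variance,
Laplacian energy/variants, gray-level variance family, DCT energy ratios,
histogram measures, Vollath's autocorrelation, and so on) plus two
purpose-built ones for sparse fluorescent structures: `BRGT`, the maximum
pixel intensity, and `MGRD`, the maximum gradient magnitude (central
differences in both axes, magnitude $\sqrt{g_x^2+g_y^2}$). Every operator is
evaluated in floating point, optionally inside a rectangular ROI, and is
oriented so that **higher always means sharper**; a per-operator flag in the
registry records the original literature convention so downstream argmax
logic never branches.

Defaults follow the common reference implementations: 15-pixel windows for
the windowed measures (GDER, GLLV, HELM, SFIL), threshold 0 for GRAT, and
8×8 blocks for the DCT measures. The DCT measures use non-overlapping
blocks rather than a sliding window — the sliding form is quadratically
more expensive and does not change the ranking behaviour the registry is
used for. All of these are overridable per call.

`best_focus()` scores each slice of a Z-stack and returns the argmax, with
ties broken toward the stack center — in a tracking loop the center is the
previous best estimate, so this is the conservative choice — and then
toward the lower index.

### The selection benchmark and its metric

`benchmark_operators()` scores every operator against a set of annotated
stacks by *relative accuracy*,

$$\mathrm{acc} = 100\left(1 - \frac{|z_\mathrm{sel} - z_\mathrm{tgt}|}{d_\mathrm{max}}\right),
\qquad d_\mathrm{max} = \max(z_\mathrm{tgt} - 1,\; n - z_\mathrm{tgt}),$$

i.e. the distance to the annotated slice, standardized per stack by the
worst achievable distance. The formula is reconstructed from its three
anchor values: an exact selection scores 100 %, the farthest slice scores
0 %, and a selector drawing uniformly over the continuous Z range of a
stack with a centered target scores 50 % in expectation. Per-stack
standardization happens before averaging across stacks (the alternative —
standardizing the averaged distance — was rejected because it lets one
eccentric target dominate). Timings are measured with a monotonic clock and
reported per slice; they are informational only.

## Drift correction

`estimate_shift()` is raw circular cross-correlation computed in the
Fourier domain: multiply the DFT of the reference by the complex conjugate
of the new frame's DFT, inverse-transform, move the zero-frequency corners
to the center, and take the peak position relative to the center pixel at
0-based $(\lfloor H/2\rfloor, \lfloor W/2\rfloor)$. No spectral whitening
and no windowing, matching the minimal algorithm that suffices at these
frame sizes; an optional mean-subtraction flag exists for bright uniform
backgrounds. The peak offset of that product is the shift that must be
*corrected*; `estimate_shift()` returns its negation — the displacement of
the new frame relative to the reference — so `corrective_shift()` is a
plain negation and a round trip is the identity. Shifts are integer pixels
(the correction is applied as a scan-angle offset, so there is nothing to
gain from subpixel output), peak ties resolve to the smallest row then
column, and estimates are valid up to half the frame; beyond that the
session runner falls back to a zoomed-out reference (below).

## Uncaging-target relocation and depth modulation

Immediately before each photostimulation the target is re-aligned to the
spine surface: `binarize()` thresholds the current best-focus frame
(absolute intensity by default, fraction-of-max optionally),
`mask_perimeter()` keeps foreground pixels with a background or
out-of-frame **4-neighbor** (which yields a closed 8-connected boundary for
the target to land on), and `relocate_target()` picks the perimeter pixel
at minimal **Euclidean** distance — "closest point on a membrane" is a
physical distance, not a city-block one — with ties to the smallest row
then column. All foreground objects compete; no object labelling is
attempted. An empty mask raises a `spine_lost` condition.

Pulse duration and power compensate scattering with depth:
`uncaging_params_for_depth()` interpolates linearly from (4 ms, 3.5 mW) at
the shallow end of the configured depth range to (8 ms, 4.0 mW) at the deep
end (the linear form is the simplest monotone choice; only the endpoints
are constrained by practice), with a fixed train of 30 pulses at 1 Hz.

## The timeline scheduler

Each position step owns a timer that fires once per imaging period for the
step's duration (inclusive end — a step "runs for" its duration), exactly
once for an uncaging step. Firings append actions to a FIFO queue; a
separate activation timer ticks every 0.1 s, starts the front action if one
waits, and pauses while it executes, so actions never overlap and a
delayed cycle is delayed, never dropped. Same-tick firings enqueue in
position-definition order. When more positions are defined than `capacity`
allows concurrently, `rotate_positions()` admits them in definition order,
each one tick after an active position's final firing. Everything runs on a
virtual clock, so runs are bit-identical across repeats; a wall-clock
driver would differ only in the time source.

## ETL calibration

`run_calibration()` emulates the tuning routine: step a Z motor, autofocus
using only the tunable lens, and record (control value, Z) pairs.
`fit_calibration()` least-squares fits Z as a linear or polynomial
(default degree 3) function of control current, verifies strict
monotonicity on a dense grid over the calibrated range (a non-invertible
calibration is refused), and `control_for_z()` inverts it analytically
(linear) or by bisection (polynomial) with round-trip error well below
1e-6 µm. Tilted-plane imaging is parameterized as **Δz per scanline**
rather than an angle — steep tilts have a tangent singularity in angle
form, while Δz/line maps directly to the per-line control update of
`tilt_waveform()`. The control axis is labelled mA (drive current 0–300 mA
for the reference device); GUI conventions that call the same axis
"voltage" are treated as the same single abstract control value.

## Volume quantification and phase statistics

Each time point's stack is sum-projected; `integrate_roi()` sums the pixels
whose **centers** fall inside an oval (spine) or polygon (dendrite) ROI —
center containment is deterministic and resolution-independent — with
optional background subtraction (off by default). `normalize_series()`
divides each object's trace by its own pre-uncaging mean, so every
normalized trace is 1 before stimulation by construction; both $V/V_0$ and
$\Delta V/V_0$ columns are emitted since either convention is in use.
`phase_stats()` averages $\Delta V/V_0$ per object over the closed windows
1–3 min (transient) and 26–30 min (sustained) after uncaging onset and
compares stimulated and adjacent spines to the dendrite control with
two-tailed unpaired **pooled-variance** t-tests (the plain reading of
"unpaired t-test"; Welch would also be defensible, but the pooled form is
the textbook default and is what the oracle test reproduces by hand).

## The virtual microscope

The phantom is a horizontal dendritic cylinder (radius 0.5 µm, emitter
density 100 per µm of optical path) carrying spherical-headed spines on
thin necks, all in one specimen plane. The default field is 128×128 px at
0.1 µm/px with 7-slice stacks at 0.5 µm steps — the small-stack regime the
autofocus benchmark targets. Two deliberate realism choices matter for the
control loops:

* the dendrite's density is modulated along its axis by a fixed smooth
  two-frequency profile (±35 %, emulating caliber variation and
  varicosities), and the default phantom carries seven spines of varied
  geometry (~0.5 µm⁻¹ density). Without such axial structure a cylinder is
  translation-invariant along x and the cross-correlation peak is
  degenerate in that direction — a failure of the *phantom*, not of the
  estimator;
* image formation uses the thin-specimen optical-sectioning limit: each
  structure contributes its projected column-density footprint, weighted by
  a normalized Gaussian axial response in $(z_\mathrm{slice} -
  z_\mathrm{structure})$ (σ = `z_half_um` = 0.8 µm) and blurred laterally
  with a normalized Gaussian kernel of width
  $\sigma(\Delta z) = \sigma_0\sqrt{1 + (\Delta z / z_\mathrm{half})^2}$,
  $\sigma_0$ = 1.3 px. A hard geometric cross-section model was rejected:
  at 0.5 µm slice steps, sub-half-micron structures intersect at most one
  slice, which degenerates focus curves and makes the volume readout
  discretization-dominated. With the sectioning model, blur conserves
  integrated intensity, summing a stack integrates the axial response, and
  the sum projection of a spine scales linearly with its simulated volume
  factor (verified to ±2 %).

Footprints are evaluated on a 4× supersampled subpixel grid and
block-averaged; without this, the integral of a sharp-rimmed sphere
wobbles ±6 % with grid alignment, swamping the volume signal. Noise is
Poisson shot noise on photon counts plus Gaussian read noise and a uniform
background, with negative readouts clipped at zero; `noise_for_snr()` sets
the photon gain so the brightest structure pixel reaches a target SNR.
Drift is a per-axis Gaussian random walk (default σ = 0.15 µm/frame) plus
optional linear creep. sLTP is modelled as
$f(t) = 1 + A_\mathrm{sust} + A_\mathrm{trans}e^{-(t-t_0)/\tau}$ for
$t \ge t_0$ (defaults $A_\mathrm{trans} = 2$, $\tau = 1.5$ min,
$A_\mathrm{sust} = 0.6$ — a large-response regime typical of single-spine
uncaging experiments), applied to the stimulated spine's head as a radius
scaling with radius ∝ volume$^{1/3}$.

One quantitative limitation worth knowing: the ROI-integrated volume
readout systematically underestimates the generative volume factor by
roughly 3–6 % — blur tails of an enlarged head escape a finite oval, and
the time-invariant neck/dendrite contribution inside the ROI dilutes the
relative change — exactly as it would for hand-drawn ROIs on real data.

What the phantom does **not** emulate: photobleaching, aberrations and a
physical PSF, dendrite morphology change, occlusions, or multi-dendrite
fields. Passing tests therefore show the control loops are correct under
calibrated defocus/noise/drift, not that they are robust to every failure
mode of real tissue (the two biological failure modes the workflow is known
for — cell death and very low fluorescence — are represented only abstractly
by the `spine_lost` path).

## The closed loop

`run_session()` executes a `session_plan()` against the virtual scope. Per
imaging event: advance drift; acquire a stack at the current Z estimate;
refocus (updating Z); estimate lateral drift of the best-focus frame
against the reference captured at position definition; apply the corrective
scan shift; quantify ROIs on the sum projection. References are **never**
re-baselined during a session by default — updating them lets the reference
itself drift — and the zoomed-out reference (same frame count, 2× pixel
size) is consulted only when the zoomed-in estimate hits the half-frame
aliasing bound. Per uncaging event: relocate the target, log the
depth-modulated parameters, and start that position's plasticity clock.
Three consecutive relocation failures mark the spine lost and drop the
position from rotation. Tracking error against ground truth is logged per
frame.

## Numerical choices and problem sizes

Tolerances and sizes used by the validation suite, chosen as comfortable
desk-scale settings: uniform-selector calibration of the accuracy metric at
100,000 draws (law-of-large-numbers noise ≈ ±0.25 %); exhaustive shift
recovery on 16×16 and 64×64 frames plus 200 random 8×8 instances against a
brute-force spatial oracle; 50 seeded stacks for the autofocus check
(noise-free: exact; peak SNR 5: within ±1 slice); 100 seeded 50-minute
closed-loop runs (success: final lateral error ≤ 2 px and focal error ≤ 1
slice); a 24-spine cohort at SNR 10 for quantification recovery (within
10 % of the generative transient/sustained means); 1,000 randomized
scheduler plans; calibration residuals ≤ 1e-9 on noise-free responses. All
simulation randomness flows through R's global RNG from a single seed.
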