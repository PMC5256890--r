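Package: spinetrack
Title: Automated Focus, Drift Correction and Photostimulation Targeting for
    Long-Term Dendritic Spine Imaging, with a Virtual Two-Photon Microscope
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hardware-free implementation of an automated dendritic spine
    tracking and photostimulation workflow: a registry of 27 focus-measure
    operators with an autofocus algorithm-selection benchmark, Fourier
    cross-correlation lateral drift estimation, perimeter-based relocation of
    glutamate-uncaging targets, a deterministic timer/event-queue scheduler
    for interleaved multi-position imaging and uncaging, electrically tunable
    lens (ETL) calibration and tilted-plane waveform synthesis, and
    normalized spine-volume quantification with transient/sustained phase
    statistics. A built-in virtual microscope renders ground-truthed
    dendrite/spine phantoms under defocus blur, shot and read noise, lateral
    and axial drift, and uncaging-evoked structural plasticity, so the whole
    closed loop is testable at the desk.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
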