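test_that("motor-to-scan mapping is linear, centered and invertible", {
  ctr <- c(100, 200, -30)
  expect_equal(motor_to_scan(ctr, ctr, 50),
               c(scan_x = 0, scan_y = 0, z_um = -30))
  p <- c(110, 190, -28)
  sc <- motor_to_scan(p, ctr, 50)
  expect_equal(unname(scan_to_motor(sc, ctr, 50)), p, tolerance = 1e-9)
  expect_error(motor_to_scan(c(100 + 37.5, 200, 0), ctr, 50), "outside")
})

test_that("zero drift, noise-free closed loop is exactly null", {
  pl <- simple_plan(duration_s = 240, period_s = 60, uncage_s = 130)
  ses <- run_session(pl, list(session_position("P1")),
                     drift = drift_model(sigma_um = 0), seed = 1)
  img <- ses$log[ses$log$action == "imaging", ]
  expect_true(all(img$d_row == 0 & img$d_col == 0))
  expect_true(all(img$focus_index == img$focus_index[1]))
  expect_true(all(img$lateral_error_px == 0))
  v <- as.data.frame(ses$volumes)
  pre <- v[v$time_min < 0, ]
  expect_equal(pre$normalized_volume, rep(1, nrow(pre)), tolerance = 1e-6)
  # uncaging happened, was relocated onto the perimeter, and params logged
  unc <- ses$log[ses$log$action == "uncaging", ]
  expect_equal(nrow(unc), 1)
  expect_true(is.finite(unc$pulse_ms) && unc$pulse_ms >= 4 && unc$pulse_ms <= 8)
})

test_that("the closed loop tracks a drifting specimen", {
  pl <- simple_plan(duration_s = 1500, period_s = 60, uncage_s = 130)
  ses <- run_session(pl, list(session_position("P1")),
                     scope = microscope(noise = noise_for_snr(10)),
                     drift = drift_model(sigma_um = 0.15), seed = 42)
  img <- ses$log[ses$log$action == "imaging", ]
  expect_lte(img$lateral_error_px[nrow(img)], 2)
  expect_lte(img$focal_error_um[nrow(img)], 0.5 + 1e-9)
  # without correction the error tracks the raw random walk instead
  ses0 <- run_session(pl, list(session_position("P1")),
                      scope = microscope(noise = noise_for_snr(10)),
                      drift = drift_model(sigma_um = 0.15),
                      correction = FALSE, seed = 42)
  img0 <- ses0$log[ses0$log$action == "imaging", ]
  expect_gt(mean(img0$lateral_error_px), mean(img$lateral_error_px))
})

test_that("staggered multi-position uncaging events never overlap", {
  steps <- list()
  for (i in 1:5) {
    id <- paste0("P", i)
    steps[[length(steps) + 1]] <- timeline_step(id, "imaging", 0, 360, 120)
    steps[[length(steps) + 1]] <- timeline_step(id, "uncaging", 100 + 37 * (i - 1))
  }
  pl <- session_plan(steps)
  positions <- lapply(paste0("P", 1:5), session_position)
  ses <- run_session(pl, positions, drift = drift_model(sigma_um = 0.02),
                     scope = microscope(noise = noise_for_snr(10)),
                     imaging_s = 0.5, uncaging_s = 30, seed = 5)
  unc <- ses$log[ses$log$action == "uncaging", ]
  expect_equal(nrow(unc), 5)
  expect_setequal(unc$position_id, paste0("P", 1:5))
  o <- order(unc$start_s)
  expect_true(all(unc$start_s[o][-1] >= unc$end_s[o][-5] - 1e-9))
})

test_that("autofocus frequency limits refocusing to every k-th cycle", {
  pl <- simple_plan(duration_s = 360, period_s = 60, uncage_s = 400)
  ses <- run_session(pl, list(session_position("P1")),
                     af = autofocus_config(frequency = 3),
                     drift = drift_model(sigma_um = 0), seed = 4)
  img <- ses$log[ses$log$action == "imaging", ]
  # zero drift: non-refocus frames report the stack-center slice; refocus
  # frames (1st, 4th, 7th) agree because the specimen never moves
  expect_equal(nrow(img), 7)
  expect_true(all(img$focus_index == 4))
  expect_true(all(img$lateral_error_px == 0))
})

test_that("a vanished spine is dropped after three failed relocations", {
  # threshold far above any achievable intensity: relocation always fails
  pos <- session_position("P1", threshold = 1e7)
  pl <- session_plan(list(
    timeline_step("P1", "imaging", 0, 600, 60),
    timeline_step("P1", "uncaging", 70),
    timeline_step("P1", "uncaging", 130),
    timeline_step("P1", "uncaging", 190),
    timeline_step("P1", "uncaging", 250)))
  ses <- run_session(pl, list(pos), drift = drift_model(sigma_um = 0), seed = 2)
  expect_equal(ses$lost, "P1")
  expect_equal(sum(ses$log$action == "uncaging-failed"), 3)
  # events after the third failure were skipped
  expect_lt(max(ses$log$fire_s), 600)
})
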