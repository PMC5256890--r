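test_that("calibration recovers exact linear and cubic responses", {
  # virtual ETL with true linear response z = 0.5 * control - 20
  af_linear <- function(z) (z + 20) / 0.5
  pts <- run_calibration(seq(-10, 10, by = 5), af_linear)
  expect_equal(nrow(pts), 5)
  fit <- fit_calibration(pts, "linear")
  expect_equal(fit$coefficients[2], 0.5, tolerance = 1e-9)
  expect_equal(fit$coefficients[1], -20, tolerance = 1e-9)
  expect_lt(max(abs(fit$residuals)), 1e-9)
  # cubic response (strictly increasing on [0, 300])
  b <- c(-15, 0.12, 2e-4, 1e-6)
  zc <- function(ctrl) b[1] + b[2] * ctrl + b[3] * ctrl^2 + b[4] * ctrl^3
  af_cubic <- function(z) uniroot(function(c) zc(c) - z, c(0, 300),
                                  tol = 1e-13)$root
  pts3 <- run_calibration(zc(seq(10, 290, length.out = 9)), af_cubic)
  fit3 <- fit_calibration(pts3, "polynomial", degree = 3)
  expect_equal(fit3$coefficients, b, tolerance = 1e-6)
  expect_lt(max(abs(fit3$residuals)), 1e-9)
})

test_that("degenerate calibrations are rejected", {
  expect_error(run_calibration(5, function(z) z), "at least 2")
  pts <- data.frame(control_mA = c(0, 10, 20), z_um = c(0, 5, 10))
  expect_error(fit_calibration(pts, "polynomial", degree = 5), "at least 6")
  # non-monotonic data fit with matching degree
  wob <- data.frame(control_mA = seq(0, 100, by = 10),
                    z_um = sin(seq(0, 100, by = 10) / 10))
  expect_error(fit_calibration(wob, "polynomial", degree = 5),
               "not strictly monotonic")
  # skipped autofocus failures still calibrate from the rest
  flaky <- function(z) if (z == 5) stop("no focus") else z * 2
  expect_warning(pts2 <- run_calibration(c(0, 5, 10, 15), flaky), "skipped")
  expect_equal(nrow(pts2), 3)
})

test_that("control<->z round trips to sub-nanometre accuracy", {
  b <- c(2, 0.08, -5e-5, 8e-7)
  pts <- data.frame(control_mA = seq(0, 300, length.out = 12))
  pts$z_um <- b[1] + b[2] * pts$control_mA + b[3] * pts$control_mA^2 +
    b[4] * pts$control_mA^3
  fit <- fit_calibration(pts, "polynomial", 3)
  set.seed(6)
  z <- runif(100, min(fit$z_range), max(fit$z_range))
  err <- abs(z_for_control(fit, control_for_z(fit, z)) - z)
  expect_lt(max(err), 1e-6)
  expect_error(control_for_z(fit, max(fit$z_range) + 1), "outside")
  expect_error(z_for_control(fit, 301), "outside")
  # linear model: z = 0 maps to the intercept's control value
  lin <- fit_calibration(data.frame(control_mA = c(0, 100, 200),
                                    z_um = c(-10, 0, 10)), "linear")
  expect_equal(control_for_z(lin, 0), 100, tolerance = 1e-9)
})

test_that("noisy calibrations tighten with more points", {
  slope <- 0.4; icept <- -30
  coef_err <- function(n, seed) {
    set.seed(seed)
    ctrl <- seq(10, 290, length.out = n)
    pts <- data.frame(control_mA = ctrl,
                      z_um = icept + slope * ctrl + rnorm(n, 0, 0.5))
    fit <- fit_calibration(pts, "linear")
    abs(fit$coefficients[2] - slope)
  }
  few <- mean(vapply(1:40, function(s) coef_err(5, s), numeric(1)))
  many <- mean(vapply(1:40, function(s) coef_err(50, s), numeric(1)))
  expect_lt(many, few)
})

test_that("tilt waveforms track the commanded plane", {
  lin <- fit_calibration(data.frame(control_mA = c(0, 300),
                                    z_um = c(-15, 15)), "linear")
  flat <- tilt_waveform(lin, 3, 0, 64)
  expect_equal(flat$control_mA, rep(control_for_z(lin, 3), 64))
  tw <- tilt_waveform(lin, 0, 0.05, 128)
  # linear model + constant dz per line -> arithmetic sequence
  expect_equal(diff(tw$control_mA), rep(diff(tw$control_mA)[1], 127))
  expect_equal(tw$z_um[1] + tw$z_um[128], 0)  # symmetric about the center
  expect_error(tilt_waveform(lin, 14, 0.5, 128), "outside")
})

test_that("calibration JSON round-trips", {
  lin <- fit_calibration(data.frame(control_mA = c(0, 150, 300),
                                    z_um = c(-15, 0, 15)), "linear")
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(lin, path)
  back <- read_calibration(path)
  expect_equal(back$coefficients, lin$coefficients)
  expect_equal(z_for_control(back, 77), z_for_control(lin, 77))
})
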