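test_that("binarize thresholds inclusively, absolute or relative", {
  img <- matrix(1:25, 5, 5) * 1.0
  expect_equal(sum(binarize(img, 26)), 0)
  expect_equal(sum(binarize(img, 1)), 25)  # threshold = min -> all foreground
  sq <- matrix(2, 5, 5); sq[2:4, 2:4] <- 50
  m <- binarize(sq, 25)
  expect_equal(which(m == 1, arr.ind = TRUE),
               which(sq == 50, arr.ind = TRUE))
  expect_equal(binarize(sq, 0.5, relative = TRUE), m)
})

test_that("perimeter = foreground pixels with a background/out-of-frame 4-neighbor", {
  one <- matrix(0, 5, 5); one[3, 3] <- 1
  expect_equal(mask_perimeter(one), cbind(row = 3, col = 3))
  sq <- matrix(0, 5, 5); sq[2:4, 2:4] <- 1
  per <- mask_perimeter(sq)
  expect_equal(nrow(per), 8)  # 3x3 square: all but the center
  expect_false(any(per[, 1] == 3 & per[, 2] == 3))
  full <- matrix(1, 4, 6)
  perf <- mask_perimeter(full)
  inner <- perf[, 1] > 1 & perf[, 1] < 4 & perf[, 2] > 1 & perf[, 2] < 6
  expect_false(any(inner))  # frame edge only
  expect_equal(nrow(perf), 2 * 4 + 2 * 6 - 4)
  expect_error(mask_perimeter(matrix(0, 3, 3)), "no foreground")
})

test_that("perimeter matches the exhaustive neighbor scan on random blobs", {
  set.seed(31)
  for (i in 1:10) {
    m <- matrix(0L, 12, 12)
    # random blob: a few overlapping rectangles
    for (k in 1:3) {
      r <- sort(sample(12, 2)); c <- sort(sample(12, 2))
      m[r[1]:r[2], c[1]:c[2]] <- 1L
    }
    expect_equal(unname(mask_perimeter(m)), unname(oracle_perimeter(m)))
  }
})

test_that("relocate_target finds the nearest perimeter point", {
  disk <- matrix(0, 21, 21)
  rr <- row(disk) - 11; cc <- col(disk) - 11
  disk[rr^2 + cc^2 <= 36] <- 60  # radius-6 disk at (11, 11)
  # target outside, straight above the center: boundary point in between
  tgt <- relocate_target(disk, 30, c(2, 11))
  expect_equal(tgt, c(row = 5, col = 11))
  # a target already on the perimeter stays put
  expect_equal(relocate_target(disk, 30, c(5, 11)), c(row = 5, col = 11))
  # equidistant tie resolves to the smaller row
  two <- matrix(0, 5, 5); two[1, 3] <- 9; two[5, 3] <- 9
  expect_equal(relocate_target(two, 5, c(3, 3)), c(row = 1, col = 3))
  expect_error(relocate_target(disk, 1000, c(2, 11)), class = "spine_lost")
})

test_that("relocation matches exhaustive scans and is translation-equivariant", {
  set.seed(13)
  for (i in 1:10) {
    m <- matrix(0, 16, 16)
    r <- sort(sample(3:14, 2)); c <- sort(sample(3:14, 2))
    m[r[1]:r[2], c[1]:c[2]] <- 40
    tgt <- c(sample(16, 1), sample(16, 1))
    got <- relocate_target(m, 20, tgt)
    expect_equal(unname(got), unname(oracle_nearest_perimeter(m, tgt)))
    # relocated point lies on the perimeter, at minimal distance
    per <- mask_perimeter(binarize(m, 20))
    expect_true(any(per[, 1] == got[1] & per[, 2] == got[2]))
    dmin <- min(sqrt((per[, 1] - tgt[1])^2 + (per[, 2] - tgt[2])^2))
    expect_equal(sqrt(sum((got - tgt)^2)), dmin)
    # translation equivariance while the object stays in frame
    m2 <- matrix(0, 16, 16)
    m2[r[1]:r[2] + 1, c[1]:c[2] + 1] <- 40
    if (max(r) < 14 && max(c) < 14 && all(tgt < 15)) {
      got2 <- relocate_target(m2, 20, tgt + 1)
      expect_equal(unname(got2), unname(got) + 1)
    }
  }
})

test_that("uncaging parameters interpolate linearly with depth", {
  lo <- uncaging_params_for_depth(0, 0, 50)
  expect_equal(lo$pulse_ms, 4); expect_equal(lo$power_mW, 3.5)
  hi <- uncaging_params_for_depth(50, 0, 50)
  expect_equal(hi$pulse_ms, 8); expect_equal(hi$power_mW, 4.0)
  mid <- uncaging_params_for_depth(25, 0, 50)
  expect_equal(mid$pulse_ms, 6); expect_equal(mid$power_mW, 3.75)
  expect_equal(mid$n_pulses, 30L); expect_equal(mid$rate_Hz, 1)
  # clamped outside the range
  expect_equal(uncaging_params_for_depth(-10, 0, 50)$pulse_ms, 4)
  expect_equal(uncaging_params_for_depth(90, 0, 50)$pulse_ms, 8)
  expect_error(uncaging_params_for_depth(5, 10, 10), "degenerate")
})
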