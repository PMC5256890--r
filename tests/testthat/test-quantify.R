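test_that("sum projection is the pixelwise slice sum", {
  a <- matrix(runif(36), 6)
  st <- zstack(list(a, a), 0, 1)
  expect_equal(sum_project(st), 2 * a)
  expect_equal(sum_project(list(a)), a)
  ph <- default_phantom()
  acq <- acquire_stack(ph, noise = FALSE)
  m <- roi_mask(oval_roi(47, 51, 8, 8, "stimulated"), c(128, 128))
  per_slice <- sum(vapply(acq$stack$slices, function(s) sum(s[m]), numeric(1)))
  expect_equal(sum(sum_project(acq$stack)[m]), per_slice)  # linearity
})

test_that("integrate_roi counts pixel centers, subtracts background, stays linear", {
  img <- matrix(5, 10, 10)
  roi <- oval_roi(5, 5, 2.2, 2.2, "stimulated")
  k <- sum(roi_mask(roi, dim(img)))
  expect_equal(integrate_roi(img, roi), 5 * k)
  bg <- polygon_roi(rbind(c(7.5, 7.5), c(7.5, 10.4), c(10.4, 10.4), c(10.4, 7.5)),
                    "dendrite")
  expect_equal(integrate_roi(img, roi, background_roi = bg), 0)
  # a bright square fully inside an oval is fully captured
  img2 <- matrix(0, 10, 10); img2[4:6, 4:6] <- 7
  big <- oval_roi(5, 5, 4.4, 4.4, "stimulated")
  expect_equal(integrate_roi(img2, big), 7 * 9)
  # additive over disjoint ROIs and linear in intensity
  left <- polygon_roi(rbind(c(0.6, 0.6), c(0.6, 5.4), c(10.4, 5.4), c(10.4, 0.6)),
                      "dendrite")
  right <- polygon_roi(rbind(c(0.6, 5.6), c(0.6, 10.4), c(10.4, 10.4), c(10.4, 5.6)),
                       "dendrite")
  set.seed(2)
  img3 <- matrix(runif(100), 10)
  expect_equal(integrate_roi(img3, left) + integrate_roi(img3, right), sum(img3))
  expect_equal(integrate_roi(3 * img3, left), 3 * integrate_roi(img3, left))
})

test_that("normalization divides by the pre-uncaging mean and is idempotent", {
  tr <- data.frame(time_min = rep(c(-2, -1, 1, 2), 2),
                   object_id = rep(c("a", "b"), each = 4),
                   label = rep(c("stimulated", "dendrite"), each = 4),
                   value = c(2, 2, 2, 2, 4, 4, 8, 8))
  ns <- normalize_series(tr)
  expect_equal(ns$normalized_volume, c(1, 1, 1, 1, 1, 1, 2, 2))
  expect_equal(ns$delta_volume, ns$normalized_volume - 1)
  # idempotent on an already-normalized series
  tr2 <- ns; tr2$value <- ns$normalized_volume
  expect_equal(normalize_series(tr2)$normalized_volume, ns$normalized_volume)
  bad <- tr; bad$value[1:4] <- 0
  expect_error(normalize_series(bad), "non-positive")
  expect_error(normalize_series(tr[tr$time_min > 0, ]), "no pre-uncaging")
})

test_that("phase statistics reproduce the pooled-variance t-test", {
  mk <- function(vals, label, prefix) {
    do.call(rbind, lapply(seq_along(vals), function(i)
      data.frame(time_min = c(-1, 2, 28), object_id = paste0(prefix, i),
                 label = label, value = c(1, vals[i], vals[i]))))
  }
  tr <- rbind(mk(c(4, 5, 6), "stimulated", "s"), mk(c(1, 2, 3), "dendrite", "d"))
  ns <- normalize_series(tr)
  st <- phase_stats(ns)
  tr_row <- st[st$phase == "transient" & st$comparison == "stimulated vs dendrite", ]
  expect_equal(tr_row$t, oracle_pooled_t(c(4, 5, 6) - 1, c(1, 2, 3) - 1))
  expect_equal(tr_row$t, 3 / sqrt(2 / 3))  # hand-evaluated textbook formula
  expect_equal(tr_row$n, 3)
  # identical groups: t = 0, p = 1
  tr_same <- rbind(mk(c(2, 3, 4), "stimulated", "s"), mk(c(2, 3, 4), "dendrite", "d"))
  st_same <- phase_stats(normalize_series(tr_same))
  expect_equal(st_same$t, c(0, 0))
  expect_equal(st_same$p, c(1, 1))
  expect_error(phase_stats(ns, transient_window = c(10, 11)), "no .* samples")
})

test_that("p-values are uniform under the null", {
  set.seed(100)
  n_rep <- 4000
  ps <- numeric(n_rep)
  base <- data.frame(time_min = rep(2, 12),
                     object_id = paste0("o", 1:12),
                     label = rep(c("stimulated", "dendrite"), each = 6),
                     value = NA_real_)
  for (r in seq_len(n_rep)) {
    d <- base
    d$delta_volume <- rnorm(12)
    ps[r] <- phase_stats(d, transient_window = c(1, 3),
                         sustained_window = c(1, 3))$p[1]
  }
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.03)
})
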