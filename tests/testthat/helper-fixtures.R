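# Shared in-code fixtures.

# single-threaded linear algebra: many small matrix products run faster
# without thread-pool spin on constrained CPUs
Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1")

# Deterministic textured test image (smoothed noise, strictly positive).
textured_image <- function(n = 32, seed = 42) {
  withr::with_seed(seed, {
    img <- matrix(runif(n * n, 1, 100), n, n)
    k <- matrix(1 / 9, 3, 3)
    # light smoothing so blur has texture to destroy at every scale
    pad <- rbind(img[1, ], img, img[n, ])
    pad <- cbind(pad[, 1], pad, pad[, n])
    sm <- img
    for (i in 1:n) for (j in 1:n)
      sm[i, j] <- sum(pad[i:(i + 2), j:(j + 2)] * k)
    sm
  })
}

# Gaussian-blurred copy via an independent FFT-free path (stats::filter on
# rows then columns with a normalized kernel, edges replicated).
blur_image <- function(img, sigma) {
  if (sigma == 0) return(img)
  r <- ceiling(3 * sigma)
  g <- exp(-((-r):r)^2 / (2 * sigma^2)); g <- g / sum(g)
  smooth1 <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    as.numeric(stats::filter(vp, g, sides = 2))[(r + 1):(r + length(v))]
  }
  t(apply(apply(img, 2, smooth1), 1, smooth1))
}

# A small session plan: one position imaged every minute with one uncaging.
simple_plan <- function(duration_s = 300, period_s = 60, uncage_s = 130,
                        id = "P1") {
  session_plan(list(
    timeline_step(id, "imaging", 0, duration_s, period_s),
    timeline_step(id, "uncaging", uncage_s)))
}
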