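# Independent brute-force oracles, deliberately written as plain per-pixel
# loops so they share no code path with the implementations they check.

# Brenner's squared-difference measure, direct evaluation: horizontal and
# vertical differences at lag 2 (zero where the lag leaves the image),
# elementwise max, squared, averaged.
oracle_brenner <- function(x) {
  H <- nrow(x); W <- ncol(x)
  acc <- 0
  for (i in seq_len(H)) for (j in seq_len(W)) {
    dh <- if (i + 2 <= H) x[i + 2, j] - x[i, j] else 0
    dv <- if (j + 2 <= W) x[i, j + 2] - x[i, j] else 0
    acc <- acc + max(dh, dv)^2
  }
  acc / (H * W)
}

# Spatial circular cross-correlation argmax: the lag (dr, dc) maximizing
# sum_ij ref[i, j] * new[i + dr, j + dc] (indices wrapped). Returns the lag
# wrapped into the same signed range estimate_shift uses, ties resolved to
# the smallest row then column.
oracle_xcorr_shift <- function(ref, new) {
  H <- nrow(ref); W <- ncol(ref)
  best <- -Inf; best_d <- c(0L, 0L)
  wrap <- function(d, n) {
    m <- as.integer(ceiling(n / 2) - 1)
    ((d + m) %% n) - m
  }
  for (dr in 0:(H - 1)) for (dc in 0:(W - 1)) {
    s <- 0
    for (i in seq_len(H)) for (j in seq_len(W)) {
      s <- s + ref[i, j] * new[(i - 1 + dr) %% H + 1, (j - 1 + dc) %% W + 1]
    }
    d <- c(wrap(dr, H), wrap(dc, W))
    if (s > best + 1e-9 ||
        (abs(s - best) <= 1e-9 &&
         (d[1] < best_d[1] || (d[1] == best_d[1] && d[2] < best_d[2])))) {
      best <- s; best_d <- d
    }
  }
  best_d
}

# Exhaustive central-difference gradient scan (replicate edges); returns the
# maximum magnitude.
oracle_max_gradient <- function(x) {
  H <- nrow(x); W <- ncol(x)
  cl <- function(v, n) min(max(v, 1), n)
  best <- -Inf
  for (i in seq_len(H)) for (j in seq_len(W)) {
    gx <- (x[i, cl(j + 1, W)] - x[i, cl(j - 1, W)]) / 2
    gy <- (x[cl(i + 1, H), j] - x[cl(i - 1, H), j]) / 2
    best <- max(best, sqrt(gx^2 + gy^2))
  }
  best
}

# Exhaustive perimeter membership + nearest-perimeter scan for small masks.
oracle_perimeter <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  out <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] == 0) next
    nb <- c(
      if (i > 1) mask[i - 1, j] else 0, if (i < H) mask[i + 1, j] else 0,
      if (j > 1) mask[i, j - 1] else 0, if (j < W) mask[i, j + 1] else 0)
    if (any(nb == 0) || i == 1 || i == H || j == 1 || j == W)
      out <- rbind(out, c(i, j))
  }
  out
}

oracle_nearest_perimeter <- function(mask, target) {
  per <- oracle_perimeter(mask)
  d <- sqrt((per[, 1] - target[1])^2 + (per[, 2] - target[2])^2)
  cand <- per[d <= min(d) + 1e-12, , drop = FALSE]
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  cand[1, ]
}

# Pooled-variance two-sample t statistic, textbook formula.
oracle_pooled_t <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}
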