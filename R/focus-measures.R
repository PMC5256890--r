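# Focus-measure operator registry.
#
# Each operator maps an image (optionally restricted to a rectangular ROI)
# to a single scalar, with the convention that HIGHER always means SHARPER:
# operators whose literature form is minimized at best focus are sign-flipped
# on the way out, so a downstream argmax over a Z-stack is uniform.
#
# The 25 literature operators follow the widely used MATLAB "fmeasure"
# reference implementations; BRGT (maximum brightness) and MGRD (maximum
# gradient magnitude) are the two purpose-built additions for sparse
# fluorescent structures such as dendrites, where the brightest, highest-
# contrast plane is the focal plane.

sobel_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
sobel_y <- t(sobel_x)
laplacian_k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3, byrow = TRUE)

# Orthonormal DCT-II matrix (for block DCT energy measures).
dct_matrix <- function(n) {
  k <- 0:(n - 1)
  D <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  D[1, ] <- sqrt(1 / n)
  D
}

# Mean of a per-block statistic over non-overlapping b x b blocks (whole
# image if smaller than one block).
block_mean <- function(x, b, stat) {
  H <- nrow(x); W <- ncol(x)
  if (H < b || W < b) return(stat(x))
  nr <- H %/% b; nc <- W %/% b
  vals <- numeric(nr * nc); k <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    k <- k + 1L
    vals[k] <- stat(x[((i - 1) * b + 1):(i * b), ((j - 1) * b + 1):(j * b)])
  }
  mean(vals)
}

# Histogram entropy (bits) over 256 bins spanning the observed range.
hist_entropy <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(0)
  p <- tabulate(pmin(255L, as.integer((x - r[1]) / (r[2] - r[1]) * 256)) + 1L,
                nbins = 256L)
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

# First-derivative-of-Gaussian filter pair, window w (odd), sigma = (w%/%2)/2.5.
gauss_deriv_filters <- function(w) {
  N <- w %/% 2L
  sig <- N / 2.5
  g <- outer(-N:N, -N:N, function(y, x) exp(-(x^2 + y^2) / (2 * sig^2)))
  gx <- outer(-N:N, -N:N, function(y, x) -x) * g / sig^2
  gx <- gx / sum(abs(gx))
  list(gx = gx, gy = t(gx))
}

local_mean <- function(x, w) {
  conv2_replicate(x, matrix(1 / (w * w), w, w))
}

local_var <- function(x, w) {
  m <- local_mean(x, w)
  v <- local_mean(x * x, w) - m * m
  pmax(v, 0)
}

pop_var <- function(x) mean((x - mean(x))^2)

fm_funs <- list(
  ACMO = function(x, p) mean(abs(x - mean(x))),
  BREN = function(x, p) {
    H <- nrow(x); W <- ncol(x)
    DH <- matrix(0, H, W); DV <- matrix(0, H, W)
    if (H > 2) DH[1:(H - 2), ] <- x[3:H, ] - x[1:(H - 2), ]
    if (W > 2) DV[, 1:(W - 2)] <- x[, 3:W] - x[, 1:(W - 2)]
    mean(pmax(DH, DV)^2)
  },
  CONT = function(x, p) {
    s <- matrix(0, nrow(x), ncol(x))
    for (dr in -1:1) for (dc in -1:1)
      if (dr != 0 || dc != 0) s <- s + abs(x - shift_replicate(x, dr, dc))
    mean(s)
  },
  CURV = function(x, p) {
    M1 <- matrix(c(-1, 0, 1), 3, 3, byrow = TRUE)
    M2 <- matrix(c(1, 0, 1), 3, 3, byrow = TRUE)
    P0 <- conv2_replicate(x, M1) / 6
    P1 <- conv2_replicate(x, t(M1)) / 6
    A <- conv2_replicate(x, M2); B <- conv2_replicate(x, t(M2))
    P2 <- 3 * A / 10 - B / 5
    P3 <- -A / 5 + 3 * B / 10
    mean(abs(P0) + abs(P1) + abs(P2) + abs(P3))
  },
  DCTE = function(x, p) {
    b <- p$block
    block_mean(x, b, function(m) {
      D <- dct_matrix(nrow(m)) %*% m %*% t(dct_matrix(ncol(m)))
      dc <- D[1, 1]^2
      if (dc == 0) return(0)
      (sum(D^2) - D[1, 1]^2) / dc
    })
  },
  DCTR = function(x, p) {
    b <- p$block
    block_mean(x, b, function(m) {
      D <- dct_matrix(nrow(m)) %*% m %*% t(dct_matrix(ncol(m)))
      dc <- D[1, 1]^2
      if (dc == 0) return(0)
      (D[1, 2]^2 + D[2, 1]^2 + D[2, 2]^2) / dc
    })
  },
  GDER = function(x, p) {
    f <- gauss_deriv_filters(p$window)
    rx <- conv2_replicate(x, f$gx); ry <- conv2_replicate(x, f$gy)
    mean(rx^2 + ry^2)
  },
  GLVA = function(x, p) pop_var(x),
  GLLV = function(x, p) pop_var(local_var(x, p$window)),
  GLVN = function(x, p) {
    m <- mean(x)
    if (m == 0) 0 else pop_var(x) / m
  },
  GRAE = function(x, p) {
    ix <- shift_replicate(x, 0, -1) - x
    iy <- shift_replicate(x, -1, 0) - x
    mean(ix^2 + iy^2)
  },
  GRAT = function(x, p) {
    ix <- abs(shift_replicate(x, 0, -1) - x)
    iy <- abs(shift_replicate(x, -1, 0) - x)
    fm <- pmax(ix, iy)
    fm[fm < p$threshold] <- 0
    n <- sum(fm != 0)
    if (n == 0) 0 else sum(fm) / n
  },
  GRAS = function(x, p) {
    ix <- shift_replicate(x, 0, -1) - x
    mean(ix^2)
  },
  HELM = function(x, p) {
    u <- local_mean(x, p$window)
    r <- ifelse(x == 0, 1, u / x)
    fm <- ifelse(u > x, r, ifelse(r == 0, 1, 1 / r))
    mean(fm)
  },
  HISE = function(x, p) hist_entropy(x),
  HISR = function(x, p) max(x) - min(x),
  LAPE = function(x, p) mean(conv2_replicate(x, laplacian_k)^2),
  LAPM = function(x, p) {
    m <- matrix(c(-1, 2, -1), 1, 3)
    mean(abs(conv2_replicate(x, m)) + abs(conv2_replicate(x, t(m))))
  },
  LAPV = function(x, p) pop_var(conv2_replicate(x, laplacian_k)),
  LAPD = function(x, p) {
    m1 <- matrix(c(-1, 2, -1), 1, 3)
    m2 <- matrix(c(0, 0, -1, 0, 2, 0, -1, 0, 0), 3, 3, byrow = TRUE) / sqrt(2)
    m3 <- matrix(c(-1, 0, 0, 0, 2, 0, 0, 0, -1), 3, 3, byrow = TRUE) / sqrt(2)
    mean(abs(conv2_replicate(x, m1)) + abs(conv2_replicate(x, t(m1))) +
           abs(conv2_replicate(x, m2)) + abs(conv2_replicate(x, m3)))
  },
  SFIL = function(x, p) {
    f <- gauss_deriv_filters(p$window)
    rx <- conv2_replicate(x, f$gx); ry <- conv2_replicate(x, f$gy)
    # steerable first derivative: response at angle t is cos(t)rx + sin(t)ry
    best <- abs(rx)
    for (t in c(45, 90, 135) * pi / 180)
      best <- pmax(best, abs(cos(t) * rx + sin(t) * ry))
    mean(best)
  },
  SFRQ = function(x, p) {
    ix <- shift_replicate(x, 0, -1) - x
    iy <- shift_replicate(x, -1, 0) - x
    mean(sqrt(ix^2 + iy^2))
  },
  TENG = function(x, p) {
    gx <- conv2_replicate(x, sobel_x); gy <- conv2_replicate(x, sobel_y)
    mean(gx^2 + gy^2)
  },
  TENV = function(x, p) {
    gx <- conv2_replicate(x, sobel_x); gy <- conv2_replicate(x, sobel_y)
    pop_var(gx^2 + gy^2)
  },
  VOLA = function(x, p) {
    H <- nrow(x)
    if (H < 3) return(0)
    i1 <- sum(x[1:(H - 1), ] * x[2:H, ])
    i2 <- sum(x[1:(H - 2), ] * x[3:H, ])
    (i1 - i2) / length(x)
  },
  BRGT = function(x, p) max(x),
  MGRD = function(x, p) {
    # central differences with replicate edges; max gradient magnitude
    gx <- (shift_replicate(x, 0, -1) - shift_replicate(x, 0, 1)) / 2
    gy <- (shift_replicate(x, -1, 0) - shift_replicate(x, 1, 0)) / 2
    max(sqrt(gx^2 + gy^2))
  }
)

fm_defaults <- list(
  DCTE = list(block = 8L), DCTR = list(block = 8L),
  GDER = list(window = 15L), GLLV = list(window = 15L),
  HELM = list(window = 15L), SFIL = list(window = 15L),
  GRAT = list(threshold = 0)
)

fm_names <- c(
  ACMO = "Absolute central moment", BREN = "Brenner's focus measure",
  CONT = "Image contrast", CURV = "Image curvature",
  DCTE = "DCT energy", DCTR = "DCT energy ratio",
  GDER = "Gaussian derivative", GLVA = "Gray-level variance",
  GLLV = "Gray-level local variance", GLVN = "Gray-level variance normalized",
  GRAE = "Energy of gradient", GRAT = "Thresholded gradient",
  GRAS = "Squared gradient", HELM = "Helmli's mean ratio",
  HISE = "Histogram entropy", HISR = "Histogram range",
  LAPE = "Energy of Laplacian", LAPM = "Modified Laplacian",
  LAPV = "Variance of Laplacian", LAPD = "Diagonal Laplacian",
  SFIL = "Steerable filters", SFRQ = "Spatial frequency",
  TENG = "Tenengrad", TENV = "Tenengrad variance",
  VOLA = "Vollath's autocorrelation", BRGT = "Maximum brightness",
  MGRD = "Maximum gradient magnitude"
)

# All registered operators are maximized at best focus in the form above, so
# no sign flip is currently active; the flag is kept per operator so that any
# future "lower = sharper" addition plugs into the same argmax convention.
fm_higher_is_sharper <- stats::setNames(rep(TRUE, length(fm_funs)), names(fm_funs))

#' List the registered focus-measure operators
#'
#' @return Character vector of the 27 operator identifiers (stable strings,
#'   used verbatim in configuration files and the CLI).
#' @export
focus_operators <- function() names(fm_funs)

#' Describe a focus-measure operator
#'
#' @param id operator identifier (see [focus_operators()]).
#' @return List with the operator's `id`, full `name`, default `params`, and
#'   its `higher_is_sharper` flag.
#' @export
focus_operator_info <- function(id) {
  id <- match.arg(id, names(fm_funs))
  list(id = id, name = unname(fm_names[id]),
       params = fm_defaults[[id]] %||% list(),
       higher_is_sharper = unname(fm_higher_is_sharper[id]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute a focus value for an image
#'
#' Evaluates one of the registered focus-measure operators over an image or a
#' rectangular sub-region. Higher values always mean sharper focus,
#' irrespective of the operator's original literature convention.
#'
#' @param img numeric matrix of non-negative intensities.
#' @param op operator identifier (see [focus_operators()]).
#' @param roi optional [rect_roi()]; when given, only those pixels enter the
#'   computation.
#' @param params named list overriding operator defaults (e.g.
#'   `list(window = 9)` for GDER/GLLV/HELM/SFIL, `list(threshold = 5)` for
#'   GRAT, `list(block = 16)` for DCTE/DCTR).
#' @return Finite scalar focus value.
#' @examples
#' img <- matrix(runif(64 * 64), 64)
#' compute_focus(img, "TENG")
#' compute_focus(img, "BREN", roi = rect_roi(10, 10, 20, 20))
#' @export
compute_focus <- function(img, op, roi = NULL, params = list()) {
  check_image(img)
  if (!is.character(op) || length(op) != 1L || !op %in% names(fm_funs))
    stop(sprintf("unknown focus operator '%s'", paste(op, collapse = ",")),
         call. = FALSE)
  x <- crop_roi(img, roi)
  p <- utils::modifyList(fm_defaults[[op]] %||% list(), params)
  w <- p$window
  if (!is.null(w) && (nrow(x) < w || ncol(x) < w))
    stop(sprintf("image (%dx%d) smaller than %s neighborhood (%d)",
                 nrow(x), ncol(x), op, w), call. = FALSE)
  val <- fm_funs[[op]](x, p)
  if (!fm_higher_is_sharper[[op]]) val <- -val
  if (!is.finite(val)) stop(sprintf("operator %s returned non-finite value", op),
                            call. = FALSE)
  val
}
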