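# Internal image helpers shared across modules.

# Bilinear sampling of img at fractional (x, y) coordinates (x = column,
# y = row, 1-based). Points outside the image return `fill`.
bilinear_sample <- function(img, x, y, fill = 0) {
  ny <- nrow(img); nx <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  # clamp corner indices, then invalidate out-of-support points
  inside <- x >= 1 & x <= nx & y >= 1 & y <= ny
  x0c <- pmin(pmax(x0, 1), nx); x1c <- pmin(x0c + 1, nx)
  y0c <- pmin(pmax(y0, 1), ny); y1c <- pmin(y0c + 1, ny)
  idx <- function(r, c) (c - 1) * ny + r
  v <- (1 - fx) * (1 - fy) * img[idx(y0c, x0c)] +
    fx * (1 - fy) * img[idx(y0c, x1c)] +
    (1 - fx) * fy * img[idx(y1c, x0c)] +
    fx * fy * img[idx(y1c, x1c)]
  v[!inside] <- fill
  v
}

# Resample img through an AffineTransform: out(p) = img(A p + b), bilinear,
# border fill 0. Also returns the validity mask as attribute "support".
warp_affine <- function(img, transform, fill = 0) {
  ny <- nrow(img); nx <- ncol(img)
  g <- expand_grid_xy(nx, ny)
  q <- cbind(g$x, g$y) %*% t(transform$matrix)
  qx <- q[, 1] + transform$offset[1]
  qy <- q[, 2] + transform$offset[2]
  out <- matrix(bilinear_sample(img, qx, qy, fill = fill), ny, nx)
  support <- matrix(qx >= 1 & qx <= nx & qy >= 1 & qy <= ny, ny, nx)
  attr(out, "support") <- support
  out
}

expand_grid_xy <- function(nx, ny) {
  list(x = rep(seq_len(nx), each = ny), y = rep(seq_len(ny), times = nx))
}

# Normalized cross-correlation of two images over an optional mask.
ncc <- function(a, b, mask = NULL) {
  if (!is.null(mask)) { a <- a[mask]; b <- b[mask] }
  a <- a - mean(a); b <- b - mean(b)
  d <- sqrt(sum(a^2) * sum(b^2))
  if (d == 0) return(0)
  sum(a * b) / d
}

# Integer-pixel translation of b relative to a by phase correlation.
# Returns c(dx, dy) such that b is (approximately) a shifted by (dx, dy).
phase_correlate <- function(a, b) {
  fa <- stats::fft(a); fb <- stats::fft(b)
  cp <- fa * Conj(fb)
  # regularized whitening: full normalization lets spectral tails with no
  # signal dominate on smooth images
  mag <- Mod(cp)
  r <- Re(stats::fft(cp / (mag + 1e-3 * max(mag)), inverse = TRUE))
  k <- which.max(r)
  ny <- nrow(a); nx <- ncol(a)
  iy <- (k - 1) %% ny; ix <- (k - 1) %/% ny
  # wrap to signed shifts
  if (iy > ny / 2) iy <- iy - ny
  if (ix > nx / 2) ix <- ix - nx
  c(dx = -ix, dy = -iy)
}

# Square mean (box) filter of odd width; edges use shrinking windows.
mean_filter <- function(img, window) {
  window <- as.integer(window)
  if (window <= 1) return(img)
  if (window %% 2 == 0) stop("smoothing window must be odd")
  k <- matrix(1, window, window)
  num <- img
  num[is.na(num)] <- 0
  cnt <- (!is.na(img)) * 1
  s <- conv2_same(num, k)
  n <- conv2_same(cnt, k)
  out <- s / pmax(n, 1)
  out[n == 0] <- NA_real_
  out
}

# 2-D "same" convolution with zero padding (small kernels only).
conv2_same <- function(img, k) {
  kr <- nrow(k); kc <- ncol(k)
  pr <- (kr - 1) %/% 2; pc <- (kc - 1) %/% 2
  ny <- nrow(img); nx <- ncol(img)
  pad <- matrix(0, ny + 2 * pr, nx + 2 * pc)
  pad[(pr + 1):(pr + ny), (pc + 1):(pc + nx)] <- img
  out <- matrix(0, ny, nx)
  for (i in seq_len(kr)) for (j in seq_len(kc)) {
    if (k[i, j] == 0) next
    out <- out + k[i, j] * pad[i:(i + ny - 1), j:(j + nx - 1)]
  }
  out
}

# Sample positions along a line region every `step` pixels, averaged over
# `line_width` parallel offsets. Returns sampling coordinate lists.
line_sampling_grid <- function(line, step = 1) {
  dx <- line$x1 - line$x0; dy <- line$y1 - line$y0
  len <- sqrt(dx^2 + dy^2)
  if (len == 0) stop("degenerate line region")
  ux <- dx / len; uy <- dy / len       # along-line unit vector
  nxv <- -uy; nyv <- ux                # normal unit vector
  s <- seq(0, len, by = step)
  w <- line$line_width
  offs <- seq(-(w - 1) / 2, (w - 1) / 2, by = 1)
  list(s = s,
       x = outer(line$x0 + s * ux, offs * nxv, `+`),
       y = outer(line$y0 + s * uy, offs * nyv, `+`))
}

# Mean of img over the width offsets of a line grid -> profile along s.
sample_line_mean <- function(img, grid) {
  v <- bilinear_sample(img, as.numeric(grid$x), as.numeric(grid$y), fill = NA)
  rowMeans(matrix(v, nrow = length(grid$s)), na.rm = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
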