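# Shared fixture builders (all generated in code; no stored images).

# Smooth random speckle image: Gaussian-filtered uniform noise, positive.
speckle_image <- function(n = 96, sigma = 3, seed = 42) {
  set.seed(seed)
  img <- matrix(stats::runif(n * n), n, n)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma)) + 0.1
  matrix(as.numeric(sm), n, n)
}

# Binary disk of given radius on a dark field.
disk_image <- function(n = 128, radius = 50, value = 1, cx = NULL, cy = NULL) {
  cx <- if (is.null(cx)) (n + 1) / 2 else cx
  cy <- if (is.null(cy)) (n + 1) / 2 else cy
  x <- matrix(rep(seq_len(n), each = n), n, n)
  y <- matrix(rep(seq_len(n), times = n), n, n)
  value * (((x - cx)^2 + (y - cy)^2) <= radius^2)
}

# Uniform polarized set with given anisotropy/intensity (no noise).
uniform_set <- function(r = 0.2, total = 300, n = 32, ...) {
  make_polarized_scene(r_field = r, intensity = total, dims = c(n, n), ...)
}
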