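#' Estimate the channel-alignment affine transform
#'
#' Intensity-based estimation of the affine transform mapping the
#' perpendicular-channel image onto the parallel-channel image. The
#' translation is seeded by phase correlation and the transform
#' (translation + rotation + isotropic scale about the image centre) is
#' refined by maximizing the normalized cross-correlation between the
#' warped `ipe` and `ipa` reference images. A precomputed transform can
#' always be supplied to [apply_registration()] instead.
#'
#' @param ref_ipa,ref_ipe reference images (same shape), e.g. the first
#'   un-bleached frame of each channel.
#' @param refine logical; refine rotation/scale/subpixel shift after the
#'   phase-correlation seed (default `TRUE`).
#' @param margin interior-window margin in pixels excluded from the
#'   similarity score (resampled border pixels carry fill values).
#' @return An [affine_transform()]; `warning_flag` is set (and identity
#'   returned) when the images are degenerate or alignment did not improve
#'   the similarity.
#' @export
estimate_registration <- function(ref_ipa, ref_ipe, refine = TRUE,
                                  margin = 8) {
  stopifnot(identical(dim(ref_ipa), dim(ref_ipe)))
  if (stats::sd(ref_ipa) == 0 || stats::sd(ref_ipe) == 0) {
    warning("constant reference image; returning identity transform")
    return(affine_transform(warning_flag = TRUE))
  }
  seed <- phase_correlate(ref_ipa, ref_ipe)
  cx <- (ncol(ref_ipa) + 1) / 2
  cy <- (nrow(ref_ipa) + 1) / 2
  # parameters: (tx px, ty px, theta deg, 100 log-scale) about the image
  # centre -- all on a ~1-unit natural scale so Nelder-Mead steps are
  # commensurate
  par_to_transform <- function(p) {
    s <- exp(p[4] / 100); th <- p[3] * pi / 180
    A <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    b <- c(cx, cy) - A %*% c(cx, cy) + p[1:2]
    affine_transform(A, b)
  }
  # score similarity over an interior window: border pixels carry fill
  # values after resampling and would otherwise dominate low-contrast
  # images
  ny <- nrow(ref_ipa); nx <- ncol(ref_ipa)
  core <- matrix(FALSE, ny, nx)
  my <- min(margin, floor((ny - 4) / 2)); mx <- min(margin, floor((nx - 4) / 2))
  core[(my + 1):(ny - my), (mx + 1):(nx - mx)] <- TRUE
  n_px <- length(ref_ipa)
  objective <- function(p) {
    tf <- par_to_transform(p)
    w <- warp_affine(ref_ipe, tf)
    m <- attr(w, "support") & core
    # small overlaps give spuriously high correlations on smooth images
    if (sum(m) < 0.25 * n_px) return(1)
    -ncc(ref_ipa, w, m)
  }
  best_par <- c(seed[1], seed[2], 0, 0)
  if (objective(c(0, 0, 0, 0)) < objective(best_par))
    best_par <- c(0, 0, 0, 0)      # seed worse than no shift: discard it
  if (refine) {
    for (pass in 1:2) {   # restart re-expands the collapsed simplex
      opt <- tryCatch(
        stats::optim(best_par, objective, method = "Nelder-Mead",
                     control = list(maxit = 800, reltol = 1e-12)),
        error = function(e) NULL)
      if (is.null(opt)) break
      best_par <- opt$par
    }
  }
  tf <- par_to_transform(best_par)
  score0 <- ncc(ref_ipa, ref_ipe, core)
  score1 <- -objective(best_par)
  if (score1 < score0 - 1e-9) {
    warning("alignment did not improve similarity; returning identity")
    return(affine_transform(warning_flag = TRUE))
  }
  tf
}

#' Apply a registration transform to the perpendicular channel
#'
#' Resamples every `ipe` frame through the same affine transform (bilinear
#' interpolation, zero border fill), leaving `ipa` untouched. For
#' photobleaching series the transform is estimated once on the first
#' (un-bleached) frame and applied to all subsequent frames; for spreading
#' movies it is estimated on the last frame.
#'
#' @param set a [polarized_image_set()].
#' @param transform an [affine_transform()].
#' @return The set with `ipe` resampled, `registration` recorded, and a
#'   `border_mask` attribute marking pixels that fell outside the source
#'   support in any frame (excluded from downstream masks).
#' @export
apply_registration <- function(set, transform) {
  stopifnot(inherits(set, "PolarizedImageSet"),
            inherits(transform, "AffineTransform"))
  if (is_identity_transform(transform)) {
    set$registration <- transform
    return(set)
  }
  border <- NULL
  for (k in seq_len(n_frames(set))) {
    w <- warp_affine(get_frame(set$ipe, k), transform)
    sup <- attr(w, "support")
    border <- if (is.null(border)) !sup else border | !sup
    set$ipe[, , k] <- w
  }
  set$registration <- transform
  attr(set, "border_mask") <- border
  attr(set, "interpolation") <- "bilinear"
  set
}

# Inverse of an affine transform (maps source coords back to reference).
invert_transform <- function(t) {
  Ai <- solve(t$matrix)
  affine_transform(Ai, -Ai %*% t$offset)
}
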