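#' Calibrate the Laurdan GP G-factor
#'
#' The generalized polarization of a reference solution (Laurdan in DMSO)
#' is conventionally 0.207; the channel G-factor that maps the measured
#' reference GP onto that value is
#' `G = (GPref + GPref GPmes - GPmes - 1) / (GPmes + GPref GPmes - GPref - 1)`,
#' and is applied uniformly to the disordered (Ch2) channel. By
#' construction, recomputing the reference GP with the calibrated G-factor
#' returns exactly `gp_ref` (closed-form inverse).
#'
#' @param gp_mes measured reference GP (at G = 1), in (-1, 1). May be a
#'   scalar or a pair of reference channel images, in which case the
#'   intensity-weighted mean GP of the reference image is used (summed
#'   channel intensities).
#' @param gp_ref reference GP, conventionally 0.207.
#' @param ch2 second reference channel image when `gp_mes` is an image.
#' @return A `GPCalibration`: list with `gp_ref`, `gp_mes`, `gfactor`.
#' @export
calibrate_gfactor <- function(gp_mes, gp_ref = 0.207, ch2 = NULL) {
  if (is.matrix(gp_mes)) {
    stopifnot(is.matrix(ch2), identical(dim(gp_mes), dim(ch2)))
    s1 <- sum(gp_mes); s2 <- sum(ch2)
    gp_mes <- (s1 - s2) / (s1 + s2)
  }
  stopifnot(gp_mes > -1, gp_mes < 1, gp_ref > -1, gp_ref < 1)
  den <- gp_mes + gp_ref * gp_mes - gp_ref - 1
  if (abs(den) < 1e-12) stop("degenerate calibration: denominator ~ 0")
  gfactor <- (gp_ref + gp_ref * gp_mes - gp_mes - 1) / den
  structure(list(gp_ref = gp_ref, gp_mes = gp_mes, gfactor = gfactor),
            class = "GPCalibration")
}

#' Per-pixel Laurdan generalized polarization map
#'
#' `GP = (ICh1 - G ICh2) / (ICh1 + G ICh2)` computed per pixel from the
#' ordered-phase (Ch1, 435/40 nm) and disordered-phase (Ch2, 504/37 nm)
#' emission channels of background-subtracted Laurdan images. Higher GP
#' reports higher membrane lipid order. Pixels whose corrected total
#' intensity does not exceed `threshold` are masked.
#'
#' @param ch1,ch2 channel images (same shape, background-subtracted).
#' @param cal a `GPCalibration` from [calibrate_gfactor()], or a scalar
#'   G-factor.
#' @param threshold total-intensity (`ICh1 + G ICh2`) mask threshold.
#' @return A `GPMap`: list with `gp` (NA where masked), `total_intensity`,
#'   `mask`, `gfactor`.
#' @export
compute_gp <- function(ch1, ch2, cal = calibrate_gfactor(0.207),
                       threshold = 0) {
  stopifnot(identical(dim(ch1), dim(ch2)))
  g <- if (inherits(cal, "GPCalibration")) cal$gfactor else cal
  stopifnot(is.finite(g), g > 0)
  total <- ch1 + g * ch2
  mask <- total > threshold
  if (!any(mask)) warning("GP threshold leaves an empty mask")
  gp <- matrix(NA_real_, nrow(ch1), ncol(ch1))
  gp[mask] <- (ch1[mask] - g * ch2[mask]) / total[mask]
  structure(list(gp = gp, total_intensity = total, mask = mask,
                 gfactor = g),
            class = "GPMap")
}

#' ROI-level GP statistics
#'
#' Per region, GP is computed from the region's summed channel
#' intensities (`(sum ICh1 - G sum ICh2) / (sum ICh1 + G sum ICh2)`), the
#' ~2x2 um ROI convention; the SD column is the per-pixel GP SD.
#'
#' @inheritParams compute_gp
#' @param regions list of [region_rect()] / [region_mask()] objects.
#' @param method `"photon"` (summed intensities) or `"pixelmean"`.
#' @return A `GPStats` data frame with columns `label`, `mean_gp`,
#'   `sd_gp`, `total_intensity`, `n_pixels`.
#' @export
roi_gp <- function(ch1, ch2, cal = calibrate_gfactor(0.207), regions,
                   method = c("photon", "pixelmean")) {
  method <- match.arg(method)
  g <- if (inherits(cal, "GPCalibration")) cal$gfactor else cal
  ratio_stats(ch1, g * ch2, regions, method,
              num = function(a, b) a - b, den = function(a, b) a + b,
              cls = "GPStats", value_name = "gp")
}
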