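#' Subtract the channel backgrounds
#'
#' Removes the buffer-image (or scalar) background from each polarized
#' channel pixelwise and clips negatives to zero, as camera-offset noise
#' would otherwise push the anisotropy out of its physical range. The
#' backgrounds of the returned set are reset to zero, so the operation is
#' idempotent.
#'
#' @param set a [polarized_image_set()].
#' @return The background-subtracted `PolarizedImageSet`.
#' @export
subtract_background <- function(set) {
  stopifnot(inherits(set, "PolarizedImageSet"))
  sub <- function(stack, bg) {
    if (is.matrix(bg)) {
      for (k in seq_len(dim(stack)[3])) stack[, , k] <- stack[, , k] - bg
    } else {
      stack <- stack - bg
    }
    stack[stack < 0] <- 0
    stack
  }
  set$ipa <- sub(set$ipa, set$background_ipa)
  set$ipe <- sub(set$ipe, set$background_ipe)
  set$background_ipa <- 0
  set$background_ipe <- 0
  set
}

#' Compute the polarimetric G-factor field
#'
#' The G-factor is the per-pixel detection-sensitivity ratio of the two
#' polarization channels, measured on an isotropic dye solution
#' (fluorescein in water): `g = Ipa / Ipe`. Pixels whose reference `Ipe`
#' falls below `floor_frac` of its median are imputed with the median
#' G-factor and flagged, to avoid division blow-ups at dark pixels.
#'
#' @param fluorescein_ipa,fluorescein_ipe background-subtracted reference
#'   images of the isotropic dye, one per channel.
#' @param floor_frac dark-pixel floor as a fraction of the median reference
#'   `Ipe` (default 0.01).
#' @return An object of class `GFactorField` with elements `g` (matrix or
#'   scalar) and `flagged` (logical matrix of imputed pixels).
#' @export
compute_gfactor <- function(fluorescein_ipa, fluorescein_ipe,
                            floor_frac = 0.01) {
  stopifnot(identical(dim(fluorescein_ipa), dim(fluorescein_ipe)))
  floor_val <- floor_frac * stats::median(fluorescein_ipe)
  valid <- fluorescein_ipe > floor_val
  if (!any(valid)) stop("entire reference Ipe image is below the dark floor")
  g <- matrix(NA_real_, nrow(fluorescein_ipa), ncol(fluorescein_ipa))
  g[valid] <- fluorescein_ipa[valid] / fluorescein_ipe[valid]
  med_g <- stats::median(g[valid])
  g[!valid] <- med_g
  structure(list(g = g, flagged = !valid), class = "GFactorField")
}

#' @rdname compute_gfactor
#' @param g scalar or matrix of positive G-factor values (for a known or
#'   externally calibrated field).
#' @export
gfactor_field <- function(g = 1) {
  if (!all(is.finite(g)) || !all(g > 0))
    stop("G-factor values must be finite and strictly positive")
  flagged <- if (is.matrix(g)) matrix(FALSE, nrow(g), ncol(g)) else FALSE
  structure(list(g = g, flagged = flagged), class = "GFactorField")
}

# g * ipe, broadcasting a scalar or per-pixel field over a frame.
gcorrect_ipe <- function(ipe_frame, g) {
  gv <- if (inherits(g, "GFactorField")) g$g else g
  if (is.matrix(gv) && !identical(dim(gv), dim(ipe_frame)))
    stop("G-factor field dimensions do not match the frames")
  ipe_frame * gv
}

#' Per-pixel emission anisotropy map
#'
#' Computes the steady-state fluorescence emission anisotropy
#' `r = (Ipa - Ipe') / (Ipa + 2 Ipe')` with the G-factor-corrected
#' perpendicular channel `Ipe' = g * Ipe`, masking pixels whose total
#' intensity `Ipa + 2 Ipe'` does not exceed `threshold`. HomoFRET between
#' clustered fluorophores depolarizes emission, so lower `r` reports more
#' nanoclustering.
#'
#' An optional 2-D averaging filter (window 3 or 5) may be applied to the
#' returned `r` field for map rendering; it is cosmetic only and all ROI
#' statistics are computed from the unsmoothed field.
#'
#' @param set a background-subtracted [polarized_image_set()].
#' @param g a `GFactorField` (or scalar via [gfactor_field()]).
#' @param threshold total-intensity threshold; pixels at or below it are
#'   masked (`NA`). Default 0 masks only empty pixels.
#' @param smoothing_window odd integer; 1 disables smoothing.
#' @param frame frame index to map (default 1).
#' @return An `AnisotropyMap` with elements `r`, `r_smooth`,
#'   `total_intensity`, `mask`, `smoothing_window`, `pixel_size`.
#' @export
compute_anisotropy <- function(set, g = gfactor_field(1), threshold = 0,
                               smoothing_window = 1, frame = 1) {
  stopifnot(inherits(set, "PolarizedImageSet"), threshold >= 0)
  ipa <- get_frame(set$ipa, frame)
  ipe_c <- gcorrect_ipe(get_frame(set$ipe, frame), g)
  total <- ipa + 2 * ipe_c
  mask <- total > threshold
  if (!any(mask))
    warning("intensity threshold leaves an empty mask")
  r <- matrix(NA_real_, nrow(ipa), ncol(ipa))
  r[mask] <- (ipa[mask] - ipe_c[mask]) / total[mask]
  r_smooth <- if (smoothing_window > 1) mean_filter(r, smoothing_window) else r
  structure(list(r = r, r_smooth = r_smooth, total_intensity = total,
                 mask = mask, smoothing_window = as.integer(smoothing_window),
                 pixel_size = set$pixel_size),
            class = "AnisotropyMap")
}

#' @export
print.AnisotropyMap <- function(x, ...) {
  cat(sprintf("AnisotropyMap: %d x %d px, %d masked-in, median r = %.4f\n",
              nrow(x$r), ncol(x$r), sum(x$mask),
              stats::median(x$r, na.rm = TRUE)))
  invisible(x)
}

# Summed-channel ("photon-weighted") anisotropy of a pixel subset.
mask_anisotropy <- function(ipa, ipe_c, mask) {
  spa <- sum(ipa[mask]); spe <- sum(ipe_c[mask])
  tot <- spa + 2 * spe
  list(r = if (tot > 0) (spa - spe) / tot else NA_real_, total_intensity = tot)
}

#' ROI-level anisotropy statistics
#'
#' For each region the anisotropy is computed from the region's summed
#' `Ipa` and summed G-factor-corrected `Ipe` (photon-weighted), exactly as
#' intensities extracted from a drawn ROI would be combined; the mean of
#' per-pixel `r` values is available via `method = "pixelmean"` for
#' sensitivity analysis. `sd_anisotropy` is always the SD of per-pixel `r`
#' inside the region.
#'
#' @param set background-subtracted [polarized_image_set()].
#' @param g a `GFactorField`.
#' @param regions list of [region_rect()] / [region_mask()] objects. A
#'   label-mask region contributes one record per label.
#' @param frame frame index (default 1).
#' @param method `"photon"` (summed intensities, default) or `"pixelmean"`.
#' @return A data frame of class `ROIStats` with columns `label`,
#'   `mean_anisotropy`, `sd_anisotropy`, `total_intensity` (summed
#'   `Ipa + 2 Ipe'`), `n_pixels`.
#' @export
roi_anisotropy <- function(set, g = gfactor_field(1), regions, frame = 1,
                           method = c("photon", "pixelmean")) {
  method <- match.arg(method)
  stopifnot(inherits(set, "PolarizedImageSet"))
  ipa <- get_frame(set$ipa, frame)
  ipe_c <- gcorrect_ipe(get_frame(set$ipe, frame), g)
  ratio_stats(ipa, ipe_c, regions, method,
              num = function(a, b) a - b, den = function(a, b) a + 2 * b,
              cls = "ROIStats", value_name = "anisotropy")
}

# Shared ROI machinery for anisotropy ((a-b)/(a+2b)) and GP ((a-b)/(a+b)).
ratio_stats <- function(cha, chb, regions, method, num, den, cls, value_name) {
  if (inherits(regions, "Region")) regions <- list(regions)
  if (!length(regions)) stop("at least one region is required")
  rows <- list()
  pixel_ratio <- function(a, b) {
    d <- den(a, b)
    ifelse(d > 0, num(a, b) / d, NA_real_)
  }
  for (i in seq_along(regions)) {
    reg <- regions[[i]]
    masks <- list()
    if (reg$kind == "label-mask" && !is.logical(reg$mask) &&
        max(reg$mask) > 1) {
      for (lv in setdiff(sort(unique(as.integer(reg$mask))), 0L))
        masks[[paste0(region_label(reg, "blob"), "_", lv)]] <- reg$mask == lv
    } else {
      m <- tryCatch(region_to_mask(reg, dim(cha)), error = function(e) {
        warning(conditionMessage(e)); NULL
      })
      if (!is.null(m)) masks[[region_label(reg, paste0("roi_", i))]] <- m
    }
    for (lab in names(masks)) {
      m <- masks[[lab]]
      if (!any(m)) next
      pr <- pixel_ratio(cha[m], chb[m])
      sa <- sum(cha[m]); sb <- sum(chb[m])
      tot <- den(sa, sb)
      val <- if (method == "photon") {
        if (tot > 0) num(sa, sb) / tot else NA_real_
      } else {
        mean(pr, na.rm = TRUE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        label = lab, value = val,
        sd = if (sum(m) > 1) stats::sd(pr, na.rm = TRUE) else 0,
        total_intensity = tot, n_pixels = sum(m),
        stringsAsFactors = FALSE)
    }
    if (!length(masks))
      message("region ", i, " is empty or out of bounds; skipped")
  }
  if (!length(rows)) stop("no usable region")
  out <- do.call(rbind, rows)
  names(out)[names(out) == "value"] <- paste0("mean_", value_name)
  names(out)[names(out) == "sd"] <- paste0("sd_", value_name)
  class(out) <- c(cls, "data.frame")
  out
}

#' Bin ROI anisotropy by total intensity
#'
#' Reproduces the intensity-binned anisotropy plot: ROI anisotropies are
#' grouped into total-intensity (`Ipa + 2 Ipe'`) bins and each bin's mean
#' and SD are reported. A ROI falling exactly on a bin's right edge is
#' assigned to that (lower) bin; the lowest edge is inclusive.
#'
#' @param stats an `ROIStats` data frame from [roi_anisotropy()].
#' @param n_bins number of equal-width bins spanning the observed intensity
#'   range (ignored when `edges` is given).
#' @param edges explicit ascending bin edges.
#' @return A `BinnedAnisotropy` data frame with columns `bin_lo`, `bin_hi`,
#'   `bin_center`, `mean_anisotropy`, `sd_anisotropy`, `count`.
#' @export
bin_by_intensity <- function(stats, n_bins = 10, edges = NULL) {
  stopifnot(nrow(stats) >= 1)
  x <- stats$total_intensity
  if (is.null(edges)) {
    rng <- range(x)
    if (diff(rng) == 0) {           # all ROIs identical -> single bin
      edges <- c(rng[1] - 0.5, rng[1] + 0.5)
    } else {
      edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    }
  }
  stopifnot(!is.unsorted(edges), length(edges) >= 2)
  idx <- cut(x, breaks = edges, right = TRUE, include.lowest = TRUE,
             labels = FALSE)
  nb <- length(edges) - 1
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1])
  out$bin_center <- (out$bin_lo + out$bin_hi) / 2
  out$mean_anisotropy <- out$sd_anisotropy <- rep(NA_real_, nb)
  out$count <- tabulate(idx, nbins = nb)
  for (b in seq_len(nb)) {
    v <- stats$mean_anisotropy[which(idx == b)]
    if (length(v)) {
      out$mean_anisotropy[b] <- mean(v)
      out$sd_anisotropy[b] <- if (length(v) > 1) stats::sd(v) else 0
    }
  }
  class(out) <- c("BinnedAnisotropy", "data.frame")
  out
}
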