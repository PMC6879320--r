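#' Nanopattern layout
#'
#' Geometry of a chromium line grid under a supported lipid bilayer:
#' axis-aligned line positions (here the column coordinates of vertical
#' lines), nominal spacing (~2 um) and line width (~100 nm).
#'
#' @param line_x pattern line positions in pixels (columns for vertical
#'   orientation).
#' @param orientation `"vertical"` (lines run along image rows) or
#'   `"horizontal"`.
#' @param spacing_um nominal line spacing in micrometres.
#' @param width_nm nominal line width in nanometres.
#' @return A `PatternLayout`.
#' @export
pattern_layout <- function(line_x, orientation = c("vertical", "horizontal"),
                           spacing_um = 2, width_nm = 100) {
  orientation <- match.arg(orientation)
  stopifnot(length(line_x) >= 1, spacing_um > 0)
  structure(list(line_x = sort(as.numeric(line_x)),
                 orientation = orientation,
                 spacing_um = spacing_um, width_nm = width_nm),
            class = "PatternLayout")
}

#' Segment punctate structures (blobs)
#'
#' General-purpose segmentation of bright puncta (vinculin microclusters,
#' paxillin focal adhesions): Gaussian smoothing, global threshold (Otsu
#' on the smoothed image, or a user value), optional intersection with a
#' gradient-magnitude mask to tighten boundaries, hole filling, connected
#' component labelling, and a minimum-size filter.
#'
#' @param image 2-D marker image.
#' @param sigma Gaussian smoothing sigma in pixels (default 1).
#' @param threshold `"otsu"` or a numeric threshold on the smoothed image.
#' @param min_size minimum blob size in pixels (default 4).
#' @param use_gradient intersect with a Sobel gradient-magnitude mask
#'   (Otsu-thresholded, dilated) to refine boundaries (default `FALSE`).
#' @param pixel_size um per pixel, for blob areas.
#' @return A `BlobSegmentation`: list with `labels` (integer matrix, 0 =
#'   background), `table` (data frame: `label`, `area_um2`, `n_pixels`,
#'   `centroid_x`, `centroid_y`, `mean_intensity`), and `params`. An
#'   image without blobs yields an empty table, not an error.
#' @export
segment_blobs <- function(image, sigma = 1, threshold = "otsu",
                          min_size = 4, use_gradient = FALSE,
                          pixel_size = 0.0977) {
  stopifnot(is.matrix(image))
  sm <- if (sigma > 0)
    as.matrix(EBImage::gblur(EBImage::Image(image), sigma = sigma))
  else image
  rng <- range(sm)
  empty <- function() {
    structure(list(
      labels = matrix(0L, nrow(image), ncol(image)),
      table = data.frame(label = integer(0), area_um2 = numeric(0),
                         n_pixels = integer(0), centroid_x = numeric(0),
                         centroid_y = numeric(0), mean_intensity = numeric(0)),
      params = list(sigma = sigma, threshold = threshold,
                    min_size = min_size, use_gradient = use_gradient)),
      class = "BlobSegmentation")
  }
  if (diff(rng) == 0) return(empty())
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image((sm - rng[1]) / diff(rng))) * diff(rng) +
      rng[1]
  } else as.numeric(threshold)
  bw <- sm > thr
  if (use_gradient) {
    gx <- conv2_same(sm, matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3))
    gy <- conv2_same(sm, t(matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)))
    gm <- sqrt(gx^2 + gy^2)
    grng <- range(gm)
    gthr <- EBImage::otsu(EBImage::Image((gm - grng[1]) / diff(grng))) *
      diff(grng) + grng[1]
    gmask <- as.matrix(EBImage::dilate(EBImage::Image((gm > gthr) * 1),
                                       EBImage::makeBrush(3, "box"))) > 0
    bw <- bw & gmask
  }
  if (!any(bw)) return(empty())
  bw <- as.matrix(EBImage::fillHull(EBImage::Image(bw * 1))) > 0
  lab <- matrix(as.integer(EBImage::bwlabel(EBImage::Image(bw * 1))),
                nrow(image))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  out <- matrix(0L, nrow(image), ncol(image))
  rows <- list()
  for (new_id in seq_along(keep)) {
    m <- lab == keep[new_id]
    out[m] <- new_id
    ij <- which(m, arr.ind = TRUE)
    rows[[new_id]] <- data.frame(
      label = new_id, area_um2 = sum(m) * pixel_size^2, n_pixels = sum(m),
      centroid_x = mean(ij[, 2]), centroid_y = mean(ij[, 1]),
      mean_intensity = mean(image[m]))
  }
  structure(list(labels = out,
                 table = if (length(rows)) do.call(rbind, rows)
                         else empty()$table,
                 params = list(sigma = sigma, threshold = threshold,
                               min_size = min_size,
                               use_gradient = use_gradient)),
            class = "BlobSegmentation")
}

#' @export
print.BlobSegmentation <- function(x, ...) {
  cat(sprintf("BlobSegmentation: %d blob(s)\n", nrow(x$table)))
  invisible(x)
}

#' Focal-adhesion areas from a paxillin image
#'
#' Segments adhesions from a background-subtracted paxillin image with
#' [segment_blobs()] (gradient filter on by default) and returns the
#' per-adhesion area table plus summary statistics.
#'
#' @param paxillin_image background-subtracted marker image.
#' @param ... passed to [segment_blobs()].
#' @param use_gradient see [segment_blobs()]; default `TRUE` here.
#' @return list with `areas` (the per-blob table), `summary` (n, mean,
#'   median, sd of area in um^2) and the `segmentation`.
#' @export
adhesion_areas <- function(paxillin_image, use_gradient = TRUE, ...) {
  seg <- segment_blobs(paxillin_image, use_gradient = use_gradient, ...)
  a <- seg$table$area_um2
  list(areas = seg$table,
       summary = data.frame(n = length(a),
                            mean_um2 = if (length(a)) mean(a) else NA_real_,
                            median_um2 = if (length(a)) stats::median(a)
                                         else NA_real_,
                            sd_um2 = if (length(a) > 1) stats::sd(a)
                                     else NA_real_),
       segmentation = seg)
}

#' Anisotropy inside and outside segmented blob masks
#'
#' Extracts photon-weighted anisotropy from the polarized channels within
#' each blob mask (one record per blob), and within user-supplied
#' regions; all pixels outside every blob (and outside `exclude`, e.g.
#' the pattern zone) form an `"outside"` record for the inside-vs-outside
#' comparison.
#'
#' @param seg a [segment_blobs()] result, co-registered with `set`.
#' @param set background-subtracted [polarized_image_set()].
#' @param g a `GFactorField`.
#' @param outside_regions optional list of regions outside the blobs.
#' @param exclude optional logical matrix of pixels (e.g. pattern lines)
#'   excluded from the `"outside"` pool.
#' @param frame frame index.
#' @return An `ROIStats` data frame (blob records, optional user-region
#'   records, and the pooled `"outside"` record).
#' @export
anisotropy_in_masks <- function(seg, set, g = gfactor_field(1),
                                outside_regions = NULL, exclude = NULL,
                                frame = 1) {
  stopifnot(inherits(seg, "BlobSegmentation"),
            inherits(set, "PolarizedImageSet"))
  dims <- dim(set$ipa)[1:2]
  if (!identical(dim(seg$labels), as.integer(dims)))
    stop("segmentation and polarized images are not co-registered")
  regions <- list(region_mask(seg$labels, label = "blob"))
  out_mask <- seg$labels == 0
  if (!is.null(exclude)) out_mask <- out_mask & !exclude
  regions <- c(regions, list(region_mask(out_mask, label = "outside")),
               outside_regions %||% list())
  roi_anisotropy(set, g, regions, frame = frame)
}

#' Detect on-pattern and inter-pattern ROIs
#'
#' The chromium lines exclude the bilayer, so the marker intensity dips
#' along them; dips are detected as columns (for vertical patterns) whose
#' mean intensity falls below `median - 2 MAD`, grouped into lines. A
#' 1 x 4 um rectangle (long axis along the line) is placed on each line
#' and 2 x 2 um squares at the inter-line midpoints. If no dip is
#' detectable the layout must be supplied explicitly.
#'
#' @param intensity total-intensity image.
#' @param layout optional [pattern_layout()]; when `NULL` it is detected
#'   from the intensity dips.
#' @param pixel_size um per pixel.
#' @param center_y row at which ROIs are centred (default: image centre).
#' @return list with `on_pattern` and `inter_pattern` lists of
#'   [region_rect()]s (clipped to the image and flagged via their labels
#'   when clipping occurred) and the `layout` used.
#' @export
pattern_rois <- function(intensity, layout = NULL, pixel_size = 0.0977,
                         center_y = NULL) {
  stopifnot(is.matrix(intensity))
  ny <- nrow(intensity); nx <- ncol(intensity)
  if (is.null(layout)) {
    cm <- colMeans(intensity)
    lo <- stats::median(cm) - 2 * stats::mad(cm)
    dip_cols <- which(cm < lo)
    if (!length(dip_cols))
      stop("no intensity dip detected; supply the pattern layout explicitly")
    splits <- split(dip_cols, cumsum(c(1, diff(dip_cols) > 1)))
    centers <- vapply(splits, function(cs) cs[which.min(cm[cs])], numeric(1))
    spacing <- if (length(centers) > 1) mean(diff(sort(centers))) * pixel_size
               else 2
    layout <- pattern_layout(centers, "vertical", spacing_um = spacing)
  }
  stopifnot(inherits(layout, "PatternLayout"))
  if (layout$orientation != "vertical")
    stop("only axis-aligned vertical patterns are supported; rotate first")
  center_y <- center_y %||% round(ny / 2)
  w_on <- max(1L, round(1 / pixel_size))   # 1 um across the line
  h_on <- max(1L, round(4 / pixel_size))   # 4 um along the line
  sq <- max(1L, round(2 / pixel_size))     # 2 x 2 um inter-pattern squares
  clip_rect <- function(x, y, w, h, label) {
    x2 <- min(x + w - 1L, nx); y2 <- min(y + h - 1L, ny)
    x1 <- max(x, 1L); y1 <- max(y, 1L)
    if (x2 < x1 || y2 < y1) return(NULL)
    clipped <- (x1 != x) || (y1 != y) || (x2 != x + w - 1L) ||
      (y2 != y + h - 1L)
    region_rect(x1, y1, x2 - x1 + 1L, y2 - y1 + 1L,
                label = if (clipped) paste0(label, "_clipped") else label)
  }
  on_pattern <- list()
  for (i in seq_along(layout$line_x)) {
    lx <- round(layout$line_x[i])
    rr <- clip_rect(lx - w_on %/% 2L, center_y - h_on %/% 2L, w_on, h_on,
                    sprintf("on_pattern_%d", i))
    if (!is.null(rr)) on_pattern[[length(on_pattern) + 1]] <- rr
  }
  inter_pattern <- list()
  mids <- if (length(layout$line_x) > 1)
    round((layout$line_x[-1] + layout$line_x[-length(layout$line_x)]) / 2)
  else integer(0)
  for (i in seq_along(mids)) {
    rr <- clip_rect(mids[i] - sq %/% 2L, center_y - sq %/% 2L, sq, sq,
                    sprintf("inter_pattern_%d", i))
    if (!is.null(rr)) inter_pattern[[length(inter_pattern) + 1]] <- rr
  }
  list(on_pattern = on_pattern, inter_pattern = inter_pattern,
       layout = layout)
}

#' Peak-aligned line profiles across marker clusters
#'
#' For each ~1 um line drawn through a marker cluster (perpendicular to
#' the pattern), the marker intensity profile is normalized to its own
#' maximum — clusters enrich to different levels — and profiles are
#' shifted so the marker peaks coincide at distance 0. The partner
#' channels are sampled along the same lines; partner intensity and
#' photon-weighted anisotropy are then averaged in bins of the signed
#' aligned distance. Lines whose marker maximum sits on an endpoint (no
#' interior peak) are excluded.
#'
#' @param marker marker-channel image (e.g. vinculin).
#' @param set partner [polarized_image_set()].
#' @param g a `GFactorField`.
#' @param lines list of [region_line()]s crossing marker clusters.
#' @param bin_width_um distance bin width (default 1 pixel).
#' @param frame frame index.
#' @return An `AlignedProfile` data frame: `distance_um`,
#'   `marker_norm` (mean normalized marker intensity, peak = 1),
#'   `partner_intensity`, `partner_r`, `sd_r`, `n`.
#' @export
aligned_line_profiles <- function(marker, set, g = gfactor_field(1), lines,
                                  bin_width_um = NULL, frame = 1) {
  stopifnot(is.matrix(marker), inherits(set, "PolarizedImageSet"))
  if (inherits(lines, "Region")) lines <- list(lines)
  px <- set$pixel_size
  bin_width_um <- bin_width_um %||% px
  ipa <- get_frame(set$ipa, frame)
  ipe_c <- gcorrect_ipe(get_frame(set$ipe, frame), g)
  samples <- list()
  for (i in seq_along(lines)) {
    grid <- line_sampling_grid(lines[[i]])
    mk <- sample_line_mean(marker, grid)
    if (all(!is.finite(mk)) || max(mk, na.rm = TRUE) <= 0) {
      message("line ", i, " has no marker signal; excluded"); next
    }
    pk <- which.max(mk)
    if (pk == 1 || pk == length(mk) ||
        stats::sd(mk, na.rm = TRUE) == 0) {
      message("line ", i, " has no interior marker peak; excluded"); next
    }
    samples[[length(samples) + 1]] <- data.frame(
      line = i,
      distance_um = (grid$s - grid$s[pk]) * px,
      marker_norm = mk / mk[pk],
      pa = sample_line_mean(ipa, grid),
      pe = sample_line_mean(ipe_c, grid))
  }
  if (!length(samples)) stop("no line with an interior marker peak")
  pooled <- do.call(rbind, samples)
  bin <- round(pooled$distance_um / bin_width_um)
  ub <- sort(unique(bin))
  out <- do.call(rbind, lapply(ub, function(b) {
    d <- pooled[bin == b & is.finite(pooled$pa), , drop = FALSE]
    spa <- sum(d$pa); spe <- sum(d$pe)
    r_pix <- ifelse(d$pa + 2 * d$pe > 0,
                    (d$pa - d$pe) / (d$pa + 2 * d$pe), NA_real_)
    data.frame(distance_um = b * bin_width_um,
               marker_norm = mean(d$marker_norm, na.rm = TRUE),
               partner_intensity = mean(d$pa + 2 * d$pe),
               partner_r = if (spa + 2 * spe > 0)
                 (spa - spe) / (spa + 2 * spe) else NA_real_,
               sd_r = if (nrow(d) > 1) stats::sd(r_pix, na.rm = TRUE) else 0,
               n = nrow(d))
  }))
  class(out) <- c("AlignedProfile", "data.frame")
  out
}

#' Cluster-centred average images
#'
#' Crops a window (default 1 x 1 um) around each segmented cluster
#' centroid; when a pattern layout is given, crops whose nearest pattern
#' line lies to the right are mirrored so the pattern always sits on the
#' left-hand side. Marker crops are normalized to their own maximum
#' before averaging; the partner channels are averaged as raw intensities
#' and the anisotropy of the *averaged* channels is computed
#' (photon-weighted convention) and then 3-pixel mean filtered.
#'
#' @param marker marker image.
#' @param set partner [polarized_image_set()].
#' @param seg a [segment_blobs()] result on `marker`.
#' @param g a `GFactorField`.
#' @param window_um crop window edge length (default 1 um).
#' @param layout optional [pattern_layout()] used for orientation.
#' @param frame frame index.
#' @return list with `marker_avg` (peak-normalized), `intensity_avg`,
#'   `anisotropy_avg` (3-pixel averaged), `n_clusters`. Clusters too
#'   close to the border are skipped (with a message); zero usable
#'   clusters is an error.
#' @export
cluster_average_image <- function(marker, set, seg, g = gfactor_field(1),
                                  window_um = 1, layout = NULL, frame = 1) {
  stopifnot(inherits(seg, "BlobSegmentation"),
            inherits(set, "PolarizedImageSet"))
  px <- set$pixel_size
  half <- max(1L, round(window_um / px / 2))
  w <- 2L * half + 1L
  ipa <- get_frame(set$ipa, frame)
  ipe_c <- gcorrect_ipe(get_frame(set$ipe, frame), g)
  ny <- nrow(marker); nx <- ncol(marker)
  acc_m <- acc_a <- acc_e <- matrix(0, w, w)
  n_used <- 0
  for (i in seq_len(nrow(seg$table))) {
    cx <- round(seg$table$centroid_x[i]); cy <- round(seg$table$centroid_y[i])
    if (cx - half < 1 || cx + half > nx || cy - half < 1 || cy + half > ny) {
      message("cluster ", i, " too close to the border; skipped"); next
    }
    rows <- (cy - half):(cy + half); cols <- (cx - half):(cx + half)
    cm <- marker[rows, cols]; ca <- ipa[rows, cols]; ce <- ipe_c[rows, cols]
    if (!is.null(layout)) {
      nearest <- layout$line_x[which.min(abs(layout$line_x - cx))]
      if (nearest > cx) {         # mirror so the pattern lies left
        cm <- cm[, w:1]; ca <- ca[, w:1]; ce <- ce[, w:1]
      }
    }
    acc_m <- acc_m + cm / max(cm)
    acc_a <- acc_a + ca
    acc_e <- acc_e + ce
    n_used <- n_used + 1
  }
  if (n_used == 0) stop("no cluster usable for averaging")
  avg_a <- acc_a / n_used; avg_e <- acc_e / n_used
  total <- avg_a + 2 * avg_e
  r <- ifelse(total > 0, (avg_a - avg_e) / total, NA_real_)
  list(marker_avg = acc_m / n_used,
       intensity_avg = total,
       anisotropy_avg = mean_filter(matrix(r, w, w), 3),
       n_clusters = n_used)
}
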