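#' Photobleaching nanocluster analysis
#'
#' In a homoFRET photobleaching experiment, bleaching removes acceptors
#' from nanoclusters, so anisotropy rises linearly as intensity falls; the
#' extrapolated anisotropy at complete bleaching (`I/I0 -> 0`) is the
#' limiting monomer anisotropy. Per ROI and frame the total intensity and
#' photon-weighted anisotropy are computed, intensities are normalized to
#' the ROI's first (un-bleached) frame to give `I/I0` ratios independent
#' of starting intensity, all `(I/I0, r)` pairs are pooled across ROIs,
#' binned in `I/I0`, and the line `r = a (1 - I/I0) + r_start` is fitted
#' by ordinary least squares to the bin means over `fit_range`. The
#' asymptote is `a + r_start`.
#'
#' @param series a registered, background-subtracted
#'   [polarized_image_set()] with >= 2 frames (alignment computed on the
#'   first, un-bleached frame).
#' @param g a `GFactorField`.
#' @param regions list of [region_rect()] ROIs on intensity-flat membrane.
#' @param n_bins number of equal-width `I/I0` bins over (0, 1] (default
#'   10).
#' @param fit_range `I/I0` interval whose bin means enter the linear fit
#'   (default `c(0.2, 1)`; the line is extrapolated to `I/I0 = 0`).
#' @return A `BleachCurve`: list with `bins` (data frame: `bin_center`,
#'   `mean_r`, `sd_r`, `n`), `slope`, `intercept` (`r` at `I/I0 = 1`),
#'   `asymptote` (`r` at `I/I0 = 0`), and the pooled `pairs` data frame.
#' @export
bleach_analysis <- function(series, g = gfactor_field(1), regions,
                            n_bins = 10, fit_range = c(0.2, 1)) {
  stopifnot(inherits(series, "PolarizedImageSet"), n_frames(series) >= 2)
  if (inherits(regions, "Region")) regions <- list(regions)
  dims <- dim(series$ipa)[1:2]
  pairs <- list()
  for (i in seq_along(regions)) {
    m <- region_to_mask(regions[[i]], dims)
    if (is.null(m)) { message("ROI ", i, " empty; skipped"); next }
    i0 <- NA_real_
    for (k in seq_len(n_frames(series))) {
      st <- mask_anisotropy(get_frame(series$ipa, k),
                            gcorrect_ipe(get_frame(series$ipe, k), g), m)
      if (k == 1) {
        i0 <- st$total_intensity
        if (!is.finite(i0) || i0 <= 0) {
          message("ROI ", i, " has non-positive frame-0 intensity; dropped")
          break
        }
      }
      pairs[[length(pairs) + 1]] <- data.frame(
        roi = i, frame = k, i_rel = st$total_intensity / i0, r = st$r)
    }
  }
  if (!length(pairs)) stop("no usable ROI in the bleach series")
  pairs <- do.call(rbind, pairs)
  edges <- seq(0, 1, length.out = n_bins + 1)
  idx <- cut(pmin(pairs$i_rel, 1), breaks = edges, right = TRUE,
             include.lowest = FALSE, labels = FALSE)
  bins <- data.frame(bin_center = (edges[-1] + edges[-length(edges)]) / 2)
  bins$mean_r <- bins$sd_r <- rep(NA_real_, n_bins)
  bins$n <- tabulate(idx, nbins = n_bins)
  for (b in seq_len(n_bins)) {
    v <- pairs$r[which(idx == b)]
    if (length(v)) {
      bins$mean_r[b] <- mean(v)
      bins$sd_r[b] <- if (length(v) > 1) stats::sd(v) else 0
    }
  }
  sel <- !is.na(bins$mean_r) & bins$bin_center >= fit_range[1] &
    bins$bin_center <= fit_range[2]
  if (sum(sel) < 2) stop("fewer than 2 populated bins in the fit range")
  fit <- stats::lm(mean_r ~ I(1 - bin_center), data = bins[sel, ])
  a <- unname(stats::coef(fit)[2]); r_start <- unname(stats::coef(fit)[1])
  structure(list(bins = bins, slope = a, intercept = r_start,
                 asymptote = a + r_start,
                 slope_se = summary(fit)$coefficients[2, 2],
                 pairs = pairs),
            class = "BleachCurve")
}

#' @export
print.BleachCurve <- function(x, ...) {
  cat(sprintf(
    "BleachCurve: slope %.4f, r(I/I0=1) = %.4f, asymptote r(I/I0->0) = %.4f\n",
    x$slope, x$intercept, x$asymptote))
  invisible(x)
}

#' Segment the cell from a total-intensity image
#'
#' Thresholds the total-intensity image, keeps the largest connected
#' component as the cell, optionally erodes the mask by
#' `edge_erosion_px` (edge pixels can carry spurious anisotropy from
#' scattered excitation outside the evanescent field; excluding up to 20
#' px does not change whole-cell estimates), and reports the area in um^2.
#'
#' @param total_intensity image matrix (`Ipa + 2 Ipe'`).
#' @param threshold intensity threshold; `NULL` uses Otsu's method.
#' @param edge_erosion_px radius of a disc structuring element for
#'   erosion (0 = none).
#' @param pixel_size um per pixel.
#' @return list with `mask` (logical), `area_um2`, `threshold`.
#' @export
segment_cell <- function(total_intensity, threshold = NULL,
                         edge_erosion_px = 0, pixel_size = 0.0977) {
  stopifnot(is.matrix(total_intensity), edge_erosion_px >= 0)
  if (is.null(threshold)) {
    rng <- range(total_intensity)
    threshold <- if (diff(rng) == 0) rng[1] else
      EBImage::otsu(EBImage::Image((total_intensity - rng[1]) / diff(rng))) *
        diff(rng) + rng[1]
  }
  bw <- total_intensity > threshold
  if (!any(bw))
    stop(sprintf("empty cell mask at threshold %.4g (image max %.4g)",
                 threshold, max(total_intensity)))
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  tab <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  mask <- matrix(as.integer(lab) == which.max(tab), nrow(bw), ncol(bw))
  if (edge_erosion_px > 0) {
    brush <- EBImage::makeBrush(2 * edge_erosion_px + 1, shape = "disc")
    mask <- as.matrix(EBImage::erode(EBImage::Image(mask * 1), brush)) > 0
  }
  list(mask = mask, area_um2 = sum(mask) * pixel_size^2,
       threshold = threshold)
}

#' Whole-cell spreading kinetics
#'
#' Per frame of a spreading movie (registration computed on the last
#' frame), segments the cell from the total-intensity image, computes the
#' cell area and the whole-cell photon-weighted anisotropy, and the
#' between-frame differences `d_area` and `d_r`. The anisotropy change is
#' additionally reported normalized by the trace's anisotropy range
#' (`d_r_norm`), so that traces from different cells can be compared.
#'
#' @param series a [polarized_image_set()] movie with `frame_interval > 0`.
#' @param g a `GFactorField`.
#' @param threshold segmentation threshold (`NULL` = per-frame Otsu).
#' @param edge_erosion_px erosion applied before whole-cell statistics.
#' @return A `SpreadingTrace` data frame: `t_s`, `area_um2`, `r`,
#'   `d_area`, `d_r`, `d_r_norm` (differences are `NA` on the first
#'   frame); segmentation failures yield `NA` rows and the trace
#'   continues.
#' @export
spreading_kinetics <- function(series, g = gfactor_field(1),
                               threshold = NULL, edge_erosion_px = 0) {
  stopifnot(inherits(series, "PolarizedImageSet"),
            series$frame_interval > 0)
  nf <- n_frames(series)
  out <- data.frame(t_s = (seq_len(nf) - 1) * series$frame_interval,
                    area_um2 = NA_real_, r = NA_real_)
  for (k in seq_len(nf)) {
    ipe_c <- gcorrect_ipe(get_frame(series$ipe, k), g)
    total <- get_frame(series$ipa, k) + 2 * ipe_c
    seg <- tryCatch(
      segment_cell(total, threshold, edge_erosion_px, series$pixel_size),
      error = function(e) NULL)
    if (is.null(seg)) next
    out$area_um2[k] <- seg$area_um2
    out$r[k] <- mask_anisotropy(get_frame(series$ipa, k), ipe_c, seg$mask)$r
  }
  out$d_area <- c(NA, diff(out$area_um2))
  out$d_r <- c(NA, diff(out$r))
  r_range <- diff(range(out$r, na.rm = TRUE))
  out$d_r_norm <- if (is.finite(r_range) && r_range > 0)
    out$d_r / r_range else out$d_r
  attr(out, "frame_interval") <- series$frame_interval
  class(out) <- c("SpreadingTrace", "data.frame")
  out
}

#' Characteristic times of a spreading trace
#'
#' `peak_d_area_time()` finds the time of maximal area change (the P1
#' marker) as the maximum of the 3-point-median-smoothed `d_area` series,
#' ties broken to the earliest frame. `anisotropy_drop_time()` locates
#' the centre of the anisotropy decrease as the weighted centroid of the
#' negative `d_r` deviations (each between-frame difference assigned to
#' its interval midpoint) — robust when the decrease is spread over
#' several frames. The difference between the two is the lead of
#' nanocluster formation over peak cell expansion.
#'
#' @param trace a `SpreadingTrace` from [spreading_kinetics()].
#' @return Time in seconds (`NA` if the series has no finite values).
#' @export
peak_d_area_time <- function(trace) {
  d <- trace$d_area
  ok <- which(is.finite(d))
  if (!length(ok)) return(NA_real_)
  sm <- stats::runmed(d[ok], k = min(3, 2 * floor(length(ok) / 2) + 1))
  trace$t_s[ok[which(sm == max(sm))[1]]]
}

#' @rdname peak_d_area_time
#' @param window half-width, in frames, of the centroid window around the
#'   smoothed `d_r` minimum (default 6).
#' @export
anisotropy_drop_time <- function(trace, window = 6) {
  d <- trace$d_r
  ok <- which(is.finite(d))
  if (!length(ok)) return(NA_real_)
  dt <- attr(trace, "frame_interval") %||% stats::median(diff(trace$t_s))
  k <- min(5, 2 * floor((length(ok) - 1) / 2) + 1)
  sm <- stats::runmed(d[ok], k = k)
  i0 <- which(sm == min(sm))[1]
  sel <- ok[max(1, i0 - window):min(length(ok), i0 + window)]
  w <- pmax(-d[sel], 0)
  if (sum(w) == 0) return(NA_real_)
  sum(w * (trace$t_s[sel] - dt / 2)) / sum(w)
}

#' Align spreading traces at their peak area change
#'
#' Shifts each trace in time so that its (median-smoothed) `d_area` peak
#' sits at `t = 0` — the P1-phase marker — then averages the traces on a
#' common binned time axis, reporting per-bin mean and SEM of area,
#' anisotropy and normalized anisotropy change.
#'
#' @param traces list of `SpreadingTrace` data frames.
#' @param bin_width time bin width in seconds (default: the first trace's
#'   frame interval).
#' @return data frame with `t_s` (bin centers, 0 at the aligned peak) and
#'   `mean`/`sem` columns for `area_um2`, `r` and `d_r_norm`; attribute
#'   `peak_times` records each trace's original peak time. Traces without
#'   a finite `d_area` are excluded with a message.
#' @export
align_traces <- function(traces, bin_width = NULL) {
  if (inherits(traces, "SpreadingTrace")) traces <- list(traces)
  stopifnot(length(traces) >= 1)
  peaks <- vapply(traces, peak_d_area_time, numeric(1))
  keep <- is.finite(peaks)
  if (!all(keep)) message(sum(!keep), " trace(s) without a d_area peak excluded")
  traces <- traces[keep]; peaks <- peaks[keep]
  if (!length(traces)) stop("no trace with a defined d_area peak")
  bin_width <- bin_width %||% attr(traces[[1]], "frame_interval") %||% 15
  pooled <- do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(t_al = tr$t_s - peaks[i], area_um2 = tr$area_um2,
               r = tr$r, d_r_norm = tr$d_r_norm)
  }))
  bin <- round(pooled$t_al / bin_width)
  ub <- sort(unique(bin))
  agg <- function(v)
    t(vapply(ub, function(b) {
      x <- v[bin == b & is.finite(v)]
      c(mean = if (length(x)) mean(x) else NA_real_,
        sem = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_)
    }, c(mean = 0, sem = 0)))
  out <- data.frame(t_s = ub * bin_width)
  for (v in c("area_um2", "r", "d_r_norm")) {
    a <- agg(pooled[[v]])
    out[[paste0("mean_", v)]] <- a[, "mean"]
    out[[paste0("sem_", v)]] <- a[, "sem"]
  }
  attr(out, "peak_times") <- peaks
  out
}

#' Intensity and anisotropy kymograph along a line
#'
#' Samples a line (default 3 pixels wide, drawn perpendicular to the cell
#' edge) on every frame and stacks the profiles in time: one matrix of
#' width-averaged total intensity and one of photon-weighted anisotropy,
#' rows = position along the line, columns = frames.
#'
#' @param series a [polarized_image_set()] time-lapse.
#' @param g a `GFactorField`.
#' @param line a [region_line()] (its `line_width` sets the averaging
#'   width).
#' @return A `Kymograph`: list with `intensity` and `anisotropy`
#'   matrices, `position_px`, `time_s`. Line points outside the image are
#'   truncated with a warning.
#' @export
kymograph <- function(series, g = gfactor_field(1), line) {
  stopifnot(inherits(series, "PolarizedImageSet"),
            inherits(line, "Region"), line$kind == "line")
  grid <- line_sampling_grid(line)
  dims <- dim(series$ipa)[1:2]
  inb <- grid$x >= 1 & grid$x <= dims[2] & grid$y >= 1 & grid$y <= dims[1]
  row_ok <- rowSums(matrix(inb, nrow = length(grid$s))) > 0
  if (!all(row_ok)) {
    warning("line extends outside the image; truncated")
    grid$x <- grid$x[row_ok, , drop = FALSE]
    grid$y <- grid$y[row_ok, , drop = FALSE]
    grid$s <- grid$s[row_ok]
  }
  nf <- n_frames(series)
  inten <- aniso <- matrix(NA_real_, length(grid$s), nf)
  for (k in seq_len(nf)) {
    pa <- sample_line_mean(get_frame(series$ipa, k), grid)
    pe <- sample_line_mean(gcorrect_ipe(get_frame(series$ipe, k), g), grid)
    inten[, k] <- pa + 2 * pe
    aniso[, k] <- ifelse(inten[, k] > 0, (pa - pe) / inten[, k], NA_real_)
  }
  structure(list(intensity = inten, anisotropy = aniso,
                 position_px = grid$s,
                 time_s = (seq_len(nf) - 1) * series$frame_interval),
            class = "Kymograph")
}
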