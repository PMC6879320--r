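#' Read a polarized channel pair from TIFF files
#'
#' Reads single- or multi-page TIFFs for the parallel and perpendicular
#' channels (the `<stem>_pa.tif` / `<stem>_pe.tif` convention) into a
#' [polarized_image_set()].
#'
#' @param pa_path,pe_path TIFF file paths for the two channels.
#' @param ... forwarded to [polarized_image_set()] (pixel size, frame
#'   interval, backgrounds).
#' @return A `PolarizedImageSet`.
#' @export
read_polarized_tiff <- function(pa_path, pe_path, ...) {
  polarized_image_set(read_tiff_stack(pa_path), read_tiff_stack(pe_path),
                      ...)
}

read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]   # first sample of RGB pages
    p
  })
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' Write and read float images (anisotropy, GP, kymograph) as TIFF
#'
#' TIFF samples are stored as 32-bit values in [0, 1]; the affine scaling
#' that maps the data range onto [0, 1] (and the NA sentinel) is recorded
#' in a JSON sidecar `<path>.json`, and `read_float_tiff()` inverts it.
#'
#' @param img numeric matrix.
#' @param path output path.
#' @export
write_float_tiff <- function(img, path) {
  na <- is.na(img)
  rng <- range(img[!na], finite = TRUE)
  if (!all(is.finite(rng))) rng <- c(0, 1)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  scaled <- (img - rng[1]) / scale
  scaled[na] <- 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32)
  jsonlite::write_json(list(offset = rng[1], scale = scale,
                            na_mask = which(na)),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_float_tiff
#' @export
read_float_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    img <- img * meta$scale + meta$offset
    img[meta$na_mask] <- NA_real_
  }
  img
}

#' Write ROI statistics or binned curves as CSV
#'
#' @param x a data frame (`ROIStats`, `BinnedAnisotropy`, `BleachCurve`
#'   bins, ...).
#' @param path output path.
#' @export
write_stats_csv <- function(x, path) {
  if (inherits(x, "BleachCurve")) x <- x$bins
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read an autocorrelation curve or intensity trace from CSV
#'
#' `read_acf_csv()` expects columns `lag_s` and `G` (extra columns such as
#' `G_sd` are honoured); `read_trace_csv()` expects `t_s` and `counts`
#' with a constant sampling interval.
#'
#' @param path CSV file path.
#' @return An [acf_curve()] or [intensity_trace()].
#' @export
read_acf_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("lag_s", "G") %in% names(d)))
  acf_curve(d$lag_s, d$G, g_sd = if ("G_sd" %in% names(d)) d$G_sd)
}

#' @rdname read_acf_csv
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("t_s", "counts") %in% names(d)), nrow(d) >= 2)
  dt <- diff(d$t_s)
  if (diff(range(dt)) > 1e-9 * mean(dt))
    stop("trace sampling interval is not constant")
  intensity_trace(d$counts, mean(dt))
}
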