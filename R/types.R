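#' Polarized image set
#'
#' Container for a registered pair of polarized detection channels: the
#' parallel (`Ipa`) and perpendicular (`Ipe`) emission images acquired
#' simultaneously on an emission-anisotropy TIRF microscope. Stacks are
#' stored as `[y, x, frame]` arrays; single frames are promoted to
#' one-frame stacks.
#'
#' @param ipa,ipe numeric matrix or 3-D array (`[y, x, frame]`), parallel and
#'   perpendicular channel intensities in photons/ADU. Must share dimensions.
#' @param pixel_size pixel size in micrometres per pixel (> 0). The default
#'   corresponds to a 512x512 EMCCD field of ~50x50 um at 100X
#'   magnification.
#' @param frame_interval time between frames in seconds (0 for a single
#'   frame).
#' @param background_ipa,background_ipe scalar or matrix background (buffer
#'   image acquired under identical conditions) for each channel.
#' @param registration an [affine_transform()] to be applied to the `ipe`
#'   channel, or `NULL` for identity.
#'
#' @return An object of class `PolarizedImageSet`.
#' @seealso [subtract_background()], [compute_anisotropy()]
#' @export
polarized_image_set <- function(ipa, ipe, pixel_size = 0.0977,
                                frame_interval = 0,
                                background_ipa = 0, background_ipe = 0,
                                registration = NULL) {
  ipa <- as_stack(ipa)
  ipe <- as_stack(ipe)
  if (!identical(dim(ipa), dim(ipe)))
    stop("ipa and ipe stacks must have identical dimensions")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a positive scalar (um/pixel)")
  if (frame_interval < 0) stop("frame_interval must be >= 0")
  check_background(background_ipa, dim(ipa)[1:2])
  check_background(background_ipe, dim(ipe)[1:2])
  if (!is.null(registration)) stopifnot(inherits(registration, "AffineTransform"))
  structure(list(ipa = ipa, ipe = ipe,
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 background_ipa = background_ipa,
                 background_ipe = background_ipe,
                 registration = registration),
            class = "PolarizedImageSet")
}

as_stack <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("image stacks must be matrices or [y, x, frame] arrays")
  storage.mode(x) <- "double"
  x
}

check_background <- function(bg, frame_dim) {
  if (is.matrix(bg)) {
    if (!identical(dim(bg), as.integer(frame_dim)))
      stop("background image dimensions do not match the frames")
  } else if (!(is.numeric(bg) && length(bg) == 1)) {
    stop("background must be a scalar or a matrix matching the frame shape")
  }
  invisible(TRUE)
}

#' @export
print.PolarizedImageSet <- function(x, ...) {
  d <- dim(x$ipa)
  cat(sprintf("PolarizedImageSet: %d x %d px, %d frame(s), %.4f um/px",
              d[1], d[2], d[3], x$pixel_size))
  if (x$frame_interval > 0) cat(sprintf(", dt = %g s", x$frame_interval))
  cat("\n")
  invisible(x)
}

n_frames <- function(set) dim(set$ipa)[3]

# Extract frame k as a plain matrix (no dimension dropping surprises).
get_frame <- function(stack, k)
  matrix(stack[, , k], dim(stack)[1], dim(stack)[2])

#' 2-D affine transform
#'
#' A transform mapping reference-channel pixel coordinates `p = (x, y)`
#' (x = column, y = row, 1-based) to source-channel coordinates
#' `q = matrix %*% p + offset`. Used to resample the perpendicular channel
#' onto the parallel channel's pixel grid.
#'
#' @param matrix 2x2 linear part (dimensionless); must be invertible.
#' @param offset length-2 translation in pixels `(dx, dy)`.
#' @param warning_flag logical; set when estimation fell back to identity.
#' @return An object of class `AffineTransform`.
#' @export
affine_transform <- function(matrix = diag(2), offset = c(0, 0),
                             warning_flag = FALSE) {
  matrix <- base::matrix(as.numeric(matrix), 2, 2)
  offset <- as.numeric(offset)
  if (length(offset) != 2 || !all(is.finite(matrix)) || !all(is.finite(offset)))
    stop("affine transform must be finite with a length-2 offset")
  if (abs(det(matrix)) <= 1e-12)
    stop("affine linear part is singular")
  structure(list(matrix = matrix, offset = offset,
                 warning_flag = isTRUE(warning_flag)),
            class = "AffineTransform")
}

#' @export
print.AffineTransform <- function(x, ...) {
  cat("AffineTransform\n  linear part:\n")
  print(signif(x$matrix, 6))
  cat(sprintf("  offset (px): (%.4g, %.4g)%s\n", x$offset[1], x$offset[2],
              if (x$warning_flag) "  [fallback/identity warning]" else ""))
  invisible(x)
}

is_identity_transform <- function(t, tol = 1e-12) {
  max(abs(t$matrix - diag(2))) < tol && max(abs(t$offset)) < tol
}

#' Regions of interest
#'
#' Regions name the pixel subsets over which anisotropy or GP statistics are
#' extracted: rectangles (the ~2x2 um ROIs drawn on intensity-flat
#' membrane), line scans, or arbitrary label masks. Pixel coordinates are
#' 1-based; rectangles are inclusive of both corners.
#'
#' @param x,y column and row of the rectangle's top-left pixel.
#' @param width,height extent in pixels (>= 1).
#' @param label free-text region label.
#' @return An object of class `Region`.
#' @export
region_rect <- function(x, y, width, height, label = "") {
  stopifnot(width >= 1, height >= 1)
  structure(list(kind = "rectangle",
                 x = as.integer(x), y = as.integer(y),
                 width = as.integer(width), height = as.integer(height),
                 label = label),
            class = "Region")
}

#' @param x0,y0,x1,y1 line endpoints in pixel coordinates (may be fractional).
#' @param line_width averaging width in pixels perpendicular to the line
#'   (default 3, the kymograph convention).
#' @rdname region_rect
#' @export
region_line <- function(x0, y0, x1, y1, line_width = 3, label = "") {
  stopifnot(line_width >= 1)
  structure(list(kind = "line", x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                 line_width = line_width, label = label),
            class = "Region")
}

#' @param mask integer label matrix (0 = background) or logical matrix.
#' @rdname region_rect
#' @export
region_mask <- function(mask, label = "") {
  stopifnot(is.matrix(mask))
  structure(list(kind = "label-mask", mask = mask, label = label),
            class = "Region")
}

#' @export
print.Region <- function(x, ...) {
  cat("Region [", x$kind, "]",
      if (nzchar(x$label)) paste0(" '", x$label, "'"), "\n", sep = "")
  invisible(x)
}

# Logical mask for a region on an image of dimension dim_yx; NULL when the
# region lies entirely outside the image.
region_to_mask <- function(region, dim_yx) {
  ny <- dim_yx[1]; nx <- dim_yx[2]
  m <- matrix(FALSE, ny, nx)
  if (region$kind == "rectangle") {
    cols <- intersect(seq.int(region$x, region$x + region$width - 1L), 1:nx)
    rows <- intersect(seq.int(region$y, region$y + region$height - 1L), 1:ny)
    if (!length(cols) || !length(rows)) return(NULL)
    m[rows, cols] <- TRUE
  } else if (region$kind == "label-mask") {
    mk <- region$mask
    if (!identical(dim(mk), as.integer(dim_yx)))
      stop("label-mask dimensions do not match the image")
    m <- mk > 0
  } else {
    stop("line regions are sampled, not rasterised; use sample_line()")
  }
  if (!any(m)) NULL else m
}

region_label <- function(region, fallback) {
  if (nzchar(region$label)) region$label else fallback
}
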