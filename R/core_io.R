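#' Lamina propria region labels
#'
#' Region labels used throughout the package. SHG sections resolve five
#' lamina propria segments; OCT B-scans resolve only three (the OCT set is a
#' subset of the SHG set).
#'
#' @format Character vectors.
#' @name regions
NULL

#' @rdname regions
#' @export
SHG_REGIONS <- c("SLP", "SVLT", "MID", "IVLT", "DEEP")

#' @rdname regions
#' @export
OCT_REGIONS <- c("SLP", "MID", "DEEP")

#' Construct an intensity image
#'
#' The universal raster container for the pipeline: a 2D matrix of
#' nonnegative intensities with a channel tag and pixel pitch. Rows increase
#' downward (with depth on OCT); columns increase laterally. Axial pitch on
#' OCT images is optical, i.e. not yet corrected for the tissue refractive
#' index (see [path_to_depth()]).
#'
#' @param pixels numeric matrix, all values finite and >= 0.
#' @param bit_depth 8 or 16.
#' @param channel one of "SHG", "TPEF", "OCT".
#' @param pixel_pitch_x_um,pixel_pitch_z_um micrometers per pixel along
#'   columns (lateral) and rows (axial/depth); must be positive.
#' @return An object of class `vf_image`.
#' @export
vf_image <- function(pixels, bit_depth = 16L,
                     channel = c("SHG", "TPEF", "OCT"),
                     pixel_pitch_x_um = 1, pixel_pitch_z_um = pixel_pitch_x_um) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("intensities must be finite and nonnegative")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (pixel_pitch_x_um <= 0 || pixel_pitch_z_um <= 0)
    stop("pixel pitch must be positive")
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth), channel = channel,
         pixel_pitch_x_um = pixel_pitch_x_um, pixel_pitch_z_um = pixel_pitch_z_um),
    class = "vf_image")
}

#' @export
print.vf_image <- function(x, ...) {
  cat(sprintf("<vf_image> %s %dx%d px, %d-bit, pitch %.3g x %.3g um/px\n",
              x$channel, nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              x$pixel_pitch_z_um, x$pixel_pitch_x_um))
  invisible(x)
}

#' @export
dim.vf_image <- function(x) dim(x$pixels)

# Accept either a vf_image or a bare matrix everywhere downstream.
as_pixels <- function(image) {
  if (inherits(image, "vf_image")) image$pixels
  else if (is.matrix(image)) image
  else stop("expected a vf_image or a numeric matrix")
}

#' Read a grayscale TIFF image or frame stack
#'
#' Reads single- or multi-page grayscale TIFF. Multi-page files (OCT frame
#' stacks) are returned as a `vf_stack`: a list of `vf_image` frames sharing
#' one geometry.
#'
#' @param path path to a TIFF file.
#' @param channel channel tag to record ("SHG", "TPEF" or "OCT").
#' @param pixel_pitch_x_um,pixel_pitch_z_um pixel pitch to record, um/px.
#' @return A `vf_image`, or a `vf_stack` for multi-page input.
#' @export
read_image <- function(path, channel = c("SHG", "TPEF", "OCT"),
                       pixel_pitch_x_um = 1, pixel_pitch_z_um = pixel_pitch_x_um) {
  channel <- match.arg(channel)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (length(pages) == 0) stop("empty TIFF: ", path)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3)
      stop("non-grayscale (multi-channel) TIFF not supported: ", path)
    bits <- attr(p, "bits.per.sample")
    if (is.null(bits)) bits <- 16L
    if (nrow(p) == 0 || ncol(p) == 0) stop("zero-sized image: ", path)
    vf_image(matrix(as.numeric(p), nrow(p), ncol(p)), bit_depth = bits,
             channel = channel, pixel_pitch_x_um = pixel_pitch_x_um,
             pixel_pitch_z_um = pixel_pitch_z_um)
  })
  if (length(frames) == 1) return(frames[[1]])
  structure(frames, class = "vf_stack")
}

#' Write an image (or frame stack) to grayscale TIFF
#'
#' Values are stored at the image's recorded bit depth; intensities are
#' clamped to the representable range and rounded, so round-trips are
#' bit-exact for integer-valued images.
#'
#' @param image a `vf_image` or `vf_stack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  frames <- if (inherits(image, "vf_stack")) image else list(image)
  maxv <- 2^frames[[1]]$bit_depth - 1
  dat <- lapply(frames, function(f) {
    pmin(pmax(round(f$pixels), 0), maxv) / maxv
  })
  if (length(dat) == 1) dat <- dat[[1]]
  tiff::writeTIFF(dat, path, bits.per.sample = frames[[1]]$bit_depth)
  invisible(path)
}

#' Tile an image into non-overlapping analysis windows
#'
#' Enumerates square windows of edge `window_px` separated by `gap_px`
#' pixels between adjacent window edges (stride `window_px + gap_px`),
#' row-major from the top-left corner. Windows that do not fit entirely
#' inside the image are discarded, not padded.
#'
#' @param image a `vf_image`, matrix, or integer vector `c(rows, cols)`.
#' @param window_px window edge length in pixels (>= 8); default 50.
#' @param gap_px gap between windows in pixels (>= 0); default 5, i.e. 10%
#'   of the default window edge.
#' @return A data.frame of 1-based top-left anchors with columns
#'   `origin_row`, `origin_col`, and attributes `window_px`, `gap_px`.
#' @export
tile_windows <- function(image, window_px = 50, gap_px = 5) {
  if (window_px < 8) stop("window_px must be >= 8")
  if (gap_px < 0) stop("gap_px must be >= 0")
  d <- if (is.numeric(image) && !is.matrix(image) && length(image) == 2) image
       else dim(as_pixels(image))
  stride <- window_px + gap_px
  rows <- seq(1, by = stride, length.out = max(0, (d[1] - window_px) %/% stride + 1))
  cols <- seq(1, by = stride, length.out = max(0, (d[2] - window_px) %/% stride + 1))
  if (length(rows) == 0 || length(cols) == 0) {
    warning("image smaller than one window; empty grid")
    grid <- data.frame(origin_row = integer(0), origin_col = integer(0))
  } else {
    grid <- expand.grid(origin_col = cols, origin_row = rows)[, c(2, 1)]
    rownames(grid) <- NULL
  }
  attr(grid, "window_px") <- window_px
  attr(grid, "gap_px") <- gap_px
  grid
}

#' Extract one window from an image
#'
#' @param image a `vf_image` or matrix.
#' @param origin_row,origin_col 1-based top-left anchor.
#' @param window_px window edge length.
#' @return The `window_px` x `window_px` submatrix.
#' @export
window_at <- function(image, origin_row, origin_col, window_px) {
  px <- as_pixels(image)
  px[origin_row:(origin_row + window_px - 1),
     origin_col:(origin_col + window_px - 1), drop = FALSE]
}

#' Quantize a window to discrete gray levels
#'
#' Linear per-window min-max mapping of intensities onto `{0, ...,
#' levels-1}`. A constant window maps to all zeros. The mapping is monotone
#' in intensity.
#'
#' @param window numeric matrix.
#' @param levels number of gray levels (>= 2); default 8.
#' @return Integer matrix with values in `[0, levels-1]`.
#' @export
quantize_gray <- function(window, levels = 8) {
  if (levels < 2) stop("levels must be >= 2")
  rng <- range(window)
  if (rng[2] == rng[1]) {
    q <- window
    q[] <- 0L
    storage.mode(q) <- "integer"
    return(q)
  }
  q <- floor((window - rng[1]) / (rng[2] - rng[1]) * levels)
  q[q > levels - 1] <- levels - 1
  storage.mode(q) <- "integer"
  q
}

#' Convert an image to 8-bit gray scale
#'
#' Global linear min-max rescale to integers 0..255 (0 = black, 255 =
#' white), the preprocessing applied before structure-tensor analysis of
#' 16-bit acquisitions.
#'
#' @param image a `vf_image` or matrix.
#' @return A matrix of integers in 0..255.
#' @export
convert_8bit <- function(image) {
  px <- as_pixels(image)
  rng <- range(px)
  if (rng[2] == rng[1]) {
    px[] <- 0
    return(px)
  }
  round((px - rng[1]) / (rng[2] - rng[1]) * 255)
}
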