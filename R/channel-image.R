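#' Single-channel micrograph raster with physical scale
#'
#' The unit every pipeline in wmquant consumes: a 2-D non-negative intensity
#' matrix (arbitrary units) plus the physical edge length of one pixel in
#' micrometres. Coordinates throughout the package are 1-based `(row, col)`
#' with the pixel-center convention: pixel `(i, j)` is the unit square centred
#' at `(i, j)`.
#'
#' @param pixels numeric matrix, all values finite and `>= 0`.
#' @param pixel_size_um physical edge length of one pixel, in micrometres.
#' @param channel_name free-text channel label (e.g. `"SMI94-red"`, `"DAPI"`).
#' @return An object of class `ChannelImage`.
#' @examples
#' img <- channel_image(matrix(0, 10, 10), pixel_size_um = 0.32)
#' dim(img$pixels)
#' @export
channel_image <- function(pixels, pixel_size_um, channel_name = "gray") {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("'pixels' must have at least one row and one column")
  if (!all(is.finite(pixels)))
    stop("'pixels' must be finite")
  if (any(pixels < 0))
    stop("'pixels' must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be a single positive number")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         channel_name = as.character(channel_name)[1L]),
    class = "ChannelImage")
}

#' @export
print.ChannelImage <- function(x, ...) {
  cat(sprintf("ChannelImage '%s': %d x %d px, %.4g um/px, range [%g, %g]\n",
              x$channel_name, nrow(x$pixels), ncol(x$pixels),
              x$pixel_size_um, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a grayscale TIFF as a ChannelImage
#'
#' Intensities are preserved bit-exactly for 8- and 16-bit grayscale files
#' (values are the raw integer sample values, not rescaled to \[0, 1\]).
#'
#' @param path path to an 8- or 16-bit grayscale TIFF.
#' @param pixel_size_um physical pixel size (not carried in plain TIFFs;
#'   must be supplied here or via the run configuration).
#' @param channel for multi-channel files, which plane to take (integer);
#'   reading a multi-channel file without `channel` is an error.
#' @param channel_name label for the returned image.
#' @return A [channel_image()].
#' @export
read_image <- function(path, pixel_size_um, channel = NULL,
                       channel_name = NULL) {
  if (!file.exists(path)) stop("image file not found: ", path)
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3L) {
    if (is.null(channel))
      stop("multi-channel TIFF; supply 'channel' to select a plane: ", path)
    px <- px[, , as.integer(channel)]
  }
  if (is.null(channel_name))
    channel_name <- sub("\\.tiff?$", "", basename(path), ignore.case = TRUE)
  channel_image(px, pixel_size_um, channel_name)
}

#' Write a ChannelImage to a grayscale TIFF
#'
#' Pixel values are rounded to the nearest integer and stored at the requested
#' bit depth, so integer-valued images round-trip bit-exactly through
#' [read_image()]. Values outside the representable range are an error.
#'
#' @param img a [channel_image()].
#' @param path output file path.
#' @param bits bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 16L) {
  stopifnot(inherits(img, "ChannelImage"))
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L)) stop("'bits' must be 8 or 16")
  top <- 2^bits - 1
  v <- round(img$pixels)
  if (any(v < 0) || any(v > top))
    stop(sprintf("pixel values outside the %d-bit range [0, %d]", bits, top))
  tiff::writeTIFF(v / top, path, bits.per.sample = bits)
  invisible(path)
}
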