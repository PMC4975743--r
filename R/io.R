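# PNG/TIFF image input and output on native intensity scales.

#' Read a grayscale image
#'
#' Reads PNG or TIFF and returns float intensities on the native scale of
#' the stored bit depth: 8-bit files map to `[0, 255]`, 16-bit to
#' `[0, 65535]`; 32-bit TIFFs (written by [write_image()] as
#' `img / max_value`) are returned multiplied by `max_value`.  RGB(A) input
#' is converted to a single channel by Rec.601 luminance with a warning.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param max_value Intensity scale applied to float TIFF data (default
#'   255).
#' @return Numeric matrix.
#' @export
read_image <- function(path, max_value = 255) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path)
    scale <- 255
  } else if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(x, "bits.per.sample")
    scale <- if (is.null(bits)) 255
             else if (bits == 16) 65535
             else if (bits == 32) max_value else 255
  } else stop("unsupported image format: .", ext)
  if (length(dim(x)) == 3) {
    warning("RGB input converted to grayscale by Rec.601 luminance")
    x <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  }
  matrix(as.numeric(x) * scale, nrow(x), ncol(x))
}

#' Write a grayscale image
#'
#' The format follows the file extension.  PNG stores 8 bits; TIFF stores
#' `bits` of 8, 16 or 32.  Every depth clips to `[0, max_value]` and
#' quantizes to the `2^bits - 1` grid.  The default `max_value` is the
#' native scale of the depth (255 for 8-bit, 65535 for 16-bit), making
#' writing the exact inverse of [read_image()]; 32-bit output keeps the
#' `max_value = 255` interpretation with quantization step
#' `max_value / (2^32 - 1)` (relative error about 2e-10, near-lossless).
#' Pass `max_value` explicitly to rescale instead.
#'
#' @param img Numeric matrix on the `[0, max_value]` scale.
#' @param path Output path (`.png`, `.tif`, `.tiff`).
#' @param bits Bit depth for TIFF output (8, 16 or 32).
#' @param max_value Intensity scale of `img`; defaults to the depth's
#'   native scale (255 for PNG/8-bit and 32-bit, 65535 for 16-bit).
#' @return The path, invisibly.
#' @export
write_image <- function(img, path, bits = 8, max_value = NULL) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  ext <- tolower(tools::file_ext(path))
  bits <- as.integer(bits)
  if (is.null(max_value))
    max_value <- if (ext == "png" || bits != 16L) 255 else 65535
  x01 <- pmin(pmax(img / max_value, 0), 1)
  if (ext == "png") {
    png::writePNG(round(x01 * 255) / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!bits %in% c(8L, 16L, 32L)) stop("bits must be 8, 16 or 32")
    lv <- 2^bits - 1
    tiff::writeTIFF(round(x01 * lv) / lv, path, bits.per.sample = bits)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}
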