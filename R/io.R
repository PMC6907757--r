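#' Read a single-channel image from PNG or TIFF
#'
#' Intensities are mapped to \eqn{[0, 1]} by the bit-depth maximum (the
#' underlying readers already do this for PNG/TIFF). Multi-channel
#' input is collapsed to luminance (weights 0.299, 0.587, 0.114) with a
#' warning; an alpha channel is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return An `npgtv_image` matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (supported: png, tif, tiff)",
                 ext), call. = FALSE)
  )
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc >= 3L) {
      warning("multi-channel image collapsed to luminance", call. = FALSE)
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  arr[arr < 0] <- 0
  arr[arr > 1] <- 1
  image_grid(arr)
}

#' Write an image as PNG or TIFF
#'
#' Quantizes unit-interval intensities to the requested bit depth with
#' round-half-up, then writes losslessly. The format follows the file
#' extension.
#'
#' @param image Image matrix with intensities in \eqn{[0, 1]}.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @param bit_depth 8 or 16; 16-bit output requires the TIFF format
#'   (the PNG writer stores 8 bits per sample).
#' @return The path, invisibly.
#' @export
write_image <- function(image, path, bit_depth = 8L) {
  px <- as_pixels(image_grid(as_pixels(image)))
  if (!bit_depth %in% c(8L, 16L)) {
    stop("`bit_depth` must be 8 or 16", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "tif", "tiff")) {
    stop(sprintf("unsupported image format '.%s' (supported: png, tif, tiff)",
                 ext), call. = FALSE)
  }
  if (bit_depth == 16L && ext == "png") {
    stop("16-bit output is only supported for TIFF", call. = FALSE)
  }
  maxv <- 2^bit_depth - 1
  q <- floor(px * maxv + 0.5) / maxv  # round-half-up quantization
  if (ext == "png") {
    png::writePNG(q, path)
  } else {
    tiff::writeTIFF(q, path, bits.per.sample = bit_depth)
  }
  invisible(path)
}
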