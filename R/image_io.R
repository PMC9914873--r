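#' Read an image file as an 8-bit grayscale intensity matrix
#'
#' Reads PNG, TIFF or JPEG. Colour images are converted to luminance with the
#' Rec. 601 weights (0.299 R + 0.587 G + 0.114 B); intensities are rescaled to
#' the integer range \[0, 255\].
#'
#' @param path Path to a PNG/TIFF/JPEG file.
#' @return A numeric matrix of intensities in \[0, 255\] (rows = image rows).
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format '.", ext, "' for ", path,
         " (supported: png, tiff, jpeg)")
  )
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    arr <- if (nch >= 3) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else arr[, , 1]
  }
  round(clip8(arr * 255))
}

#' Write an 8-bit grayscale matrix as a PNG file
#'
#' @param img Numeric matrix with intensities in \[0, 255\].
#' @param path Output path (".png").
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  assert_gray_image(img)
  png::writePNG(round(img) / 255, target = path)
  invisible(path)
}

#' Write a binary mask as a PNG file (values 0/255)
#'
#' @param mask Binary 0/1 matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_image <- function(mask, path) {
  assert_binary_mask(mask)
  png::writePNG(mask * 1.0, target = path)
  invisible(path)
}
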