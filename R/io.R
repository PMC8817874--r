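#' Grayscale image input/output
#'
#' Thin wrappers over the png and tiff readers. Images are represented in
#' the package as numeric matrices on the 0--255 scale regardless of the
#' file bit depth; RGB(A) input is reduced to luma (Rec. 601 weights).
#' Clipping to the valid range happens only here, at the I/O boundary.
#'
#' @name image-io
NULL

#' Read a grayscale image from PNG or TIFF
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric matrix on the 0--255 scale.
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(arr)) == 3L) {
    ch <- dim(arr)[3]
    arr <- if (ch >= 3) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr[, , 1]
    }
  }
  arr * 255
}

#' Write a grayscale image to PNG or TIFF
#'
#' @param img Numeric matrix on the 0--255 scale (clipped on write).
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @param bits Bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path, bits = 8) {
  assert_gray(img)
  if (!bits %in% c(8, 16)) stop("`bits` must be 8 or 16", call. = FALSE)
  x <- clip255(img) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path, dpi = NULL),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = bits),
    stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}
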