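#' Read a raster image (PNG or TIFF)
#'
#' Loads a lossless raster image for analysis.  Images are represented as
#' plain numeric arrays with intensities on the 0--255 scale: RGB images as
#' `height x width x 3` arrays, grayscale images as `height x width`
#' matrices, indexed `[row, col]` with row 1 at the top.  All reported
#' pixel coordinates elsewhere in the package (circle centres, ground
#' truth) are 0-based in this frame, i.e. the top-left pixel is
#' `(cy = 0, cx = 0)`.
#'
#' Grayscale files are promoted to RGB by channel triplication; an alpha
#' channel, if present, is dropped.  JPEG input is rejected: its lossy
#' compression blurs the vacuole edges the detector votes from.
#'
#' @param path Path to a PNG or TIFF file.
#' @return Numeric RGB array (`height x width x 3`, values 0--255).
#' @examples
#' f <- tempfile(fileext = ".png")
#' save_image(array(255, c(2, 2, 3)), f)
#' img <- load_image(f)
#' dim(img)
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 4L)
  img <- if (length(magic) >= 4L &&
             identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47)))) {
    png::readPNG(path)
  } else if (length(magic) >= 4L &&
             (identical(magic[1:3], as.raw(c(0x49, 0x49, 0x2a))) ||
              identical(magic[1:3], as.raw(c(0x4d, 0x4d, 0x00))))) {
    tiff::readTIFF(path)
  } else if (length(magic) >= 2L && identical(magic[1:2], as.raw(c(0xff, 0xd8)))) {
    stop("unsupported image format: JPEG input is rejected ",
         "(lossy compression distorts vacuole edges); use PNG or TIFF",
         call. = FALSE)
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  img <- img * 255
  if (is.matrix(img)) {
    img <- array(img, c(dim(img), 3L))
  } else if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 2L) img <- array(img[, , 1L], c(dim(img)[1:2], 3L))
    else if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  }
  check_image(img)
  img
}

#' Write a raster image (PNG or TIFF)
#'
#' Inverse of [load_image()]: writes an RGB array or grayscale matrix
#' (0--255 scale) losslessly; the format is chosen from the file
#' extension (`.png`, `.tif`, `.tiff`).
#'
#' @param img Numeric array `H x W x 3` or matrix `H x W`, values 0--255.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  check_image(img)
  x <- pmin(pmax(img / 255, 0), 1)
  ext <- tolower(tools::file_ext(path))
  write_atomic(path, function(tmp) {
    switch(ext,
      png  = png::writePNG(x, tmp),
      tif  = ,
      tiff = tiff::writeTIFF(x, tmp, bits.per.sample = 8L),
      stop("unsupported image format: .", ext, " (use .png or .tiff)",
           call. = FALSE)
    )
  })
}

#' Convert an RGB image to luminance
#'
#' Rec.601 luma: `L = 0.299 R + 0.587 G + 0.114 B`, kept at full floating
#' precision.  Lipid vacuoles are near-white in H&E sections, so any
#' monotone luminance works for segmentation; a fixed formula keeps
#' results bit-stable.  Scalar (already-gray) input is returned unchanged.
#'
#' @param img RGB array (`H x W x 3`) or grayscale matrix, values 0--255.
#' @return Grayscale matrix (`H x W`), values in `[0, 255]`.
#' @examples
#' to_luminance(array(c(255, 0, 0), c(1, 1, 3)))  # 76.245
#' @export
to_luminance <- function(img) {
  check_image(img)
  if (is_gray_image(img)) return(img)
  lum <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  matrix(lum, dim(img)[1], dim(img)[2])
}

#' Pixel-size calibration
#'
#' Histology scanners report a physical pixel size; the package never
#' infers it from the image (scale-bar OCR is out of scope), so it is a
#' required user input wherever micrometre measurements are produced.
#'
#' @param um_per_px Micrometres per pixel, strictly positive.
#'   Default 1, i.e. measurements stay in pixel units.
#' @return A validated scalar of class `calibration`.
#' @export
calibration <- function(um_per_px = 1) {
  if (!is.numeric(um_per_px) || length(um_per_px) != 1L ||
      !is.finite(um_per_px) || um_per_px <= 0)
    stop("invalid calibration: um_per_px must be a single positive number",
         call. = FALSE)
  structure(as.numeric(um_per_px), class = "calibration")
}
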