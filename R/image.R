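#' Gray images
#'
#' Images are plain numeric matrices: `H x W`, real-valued intensities on the
#' 8-bit scale `[0, 255]` (internally real-valued; quantized to 8 bit only on
#' export). Row = image row (y), column = image column (x).
#'
#' @param x object to validate/coerce
#' @return a numeric matrix
#' @export
as_gray_image <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("a gray image must be a numeric matrix")
  if (!all(is.finite(x))) stop("gray image contains non-finite values")
  if (nrow(x) < 16 || ncol(x) < 16) stop("gray image must be at least 16x16")
  x
}

#' Default rotation center of an image
#'
#' The geometric image center `((W-1)/2, (H-1)/2)` in 0-based `(x, y)` pixel
#' coordinates.
#'
#' @param img numeric matrix
#' @return numeric length-2 vector `(x, y)`
#' @export
image_center <- function(img) {
  c((ncol(img) - 1) / 2, (nrow(img) - 1) / 2)
}

#' Read an 8-bit grayscale image (PNG or TIFF)
#'
#' @param path file path; format chosen by extension
#' @return numeric matrix with values in `[0, 255]`
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # drop color/alpha channels
  round(img * 255)
}

#' Write a gray image as 8-bit PNG or TIFF
#'
#' Values are clamped to `[0, 255]` and rounded; the round trip
#' `write_gray()` then [read_gray()] is bit-exact for integer-valued input.
#'
#' @param img numeric matrix on the `[0, 255]` scale
#' @param path output path (`.png`, `.tif` or `.tiff`)
#' @export
write_gray <- function(img, path) {
  v <- round(pmin(pmax(img, 0), 255)) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(v, path),
    tif = ,
    tiff = tiff::writeTIFF(v, path, bits.per.sample = 8L),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

#' Rotate an image about a center with bilinear resampling
#'
#' Rotates the image content by `angle_deg` about `center`; positions sampled
#' from outside the frame read as 0. A rotation by `theta` shows the sample as
#' it appears at rotation-stage angle `theta` under the package's rotation
#' convention (`x' = cos*x - sin*y`, `y' = sin*x + cos*y` about the center).
#'
#' @param image numeric matrix
#' @param angle_deg rotation angle in degrees
#' @param center `(x, y)` rotation center, 0-based; default image center
#' @return numeric matrix, same dimensions
#' @export
rotate_image <- function(image, angle_deg, center = NULL) {
  image <- as_gray_image(image)
  if (is.null(center)) center <- image_center(image)
  cpp_rotate_image(image, angle_deg * pi / 180, center[1], center[2])
}

#' Bilinear image sampling at subpixel positions
#'
#' @param img numeric matrix
#' @param x,y 0-based coordinates (vectors); positions outside read 0
#' @return numeric vector of sampled intensities
#' @export
bilinear_sample <- function(img, x, y) {
  cpp_bilinear(img, as.numeric(x), as.numeric(y))
}

# rotate points (n x 2 or length-2) by angle_rad about center
rotate_points <- function(pts, angle_rad, center) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  co <- cos(angle_rad); si <- sin(angle_rad)
  dx <- pts[, 1] - center[1]; dy <- pts[, 2] - center[2]
  cbind(center[1] + co * dx - si * dy, center[2] + si * dx + co * dy)
}
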