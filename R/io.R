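#' Write / read a sinogram as float TIFF with a JSON sidecar
#'
#' The TIFF stores 32-bit float values scaled to `[0, 1]`; the sidecar
#' (`<path>.json`) records the scale factor and the optical configuration so
#' the round trip is lossless up to float precision.
#'
#' @param sino a [sinogram()]
#' @param path output path (`.tif`/`.tiff`)
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram"))
  mx <- max(sino$values)
  scale <- if (mx > 0) mx else 1
  tiff::writeTIFF(sino$values / scale, path, bits.per.sample = 32L)
  side <- unclass(sino$config)
  side$scale <- scale
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @return `read_sinogram`: a [sinogram()]
#' @export
read_sinogram <- function(path) {
  v <- tiff::readTIFF(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- optical_config(side$n_medium, side$n_sample, side$n_projections,
                        side$angular_range_deg, side$slope_order,
                        side$slope_neighbors, side$step_px)
  sinogram(v * side$scale, cfg)
}
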