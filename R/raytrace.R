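#' Optical and sampling configuration for a simulated SLOT acquisition
#'
#' @param n_medium refractive index of the immersion medium (n1)
#' @param n_sample refractive index of the sample (n2); both RIs must lie in
#'   `[1, 99]`
#' @param n_projections number of projections over the angular range (>= 4)
#' @param angular_range_deg angular range of the acquisition; a full
#'   rotation (360) is assumed by the correction
#' @param slope_order polynomial order for surface slope regression
#' @param slope_neighbors odd window size for slope regression
#' @param step_px ray-marching step in pixels
#' @return object of class `optical_config`
#' @export
optical_config <- function(n_medium = 1.4, n_sample = 1.4,
                           n_projections = 800, angular_range_deg = 360,
                           slope_order = 2, slope_neighbors = 7,
                           step_px = 1.0) {
  for (n in c(n_medium, n_sample))
    if (n < 1 || n > 99) stop("refractive indices must be between 1 and 99")
  if (n_projections < 4) stop("at least 4 projections are required")
  if (slope_neighbors %% 2 != 1 || slope_neighbors < 3)
    stop("slope_neighbors must be odd and >= 3")
  structure(list(n_medium = n_medium, n_sample = n_sample,
                 n_projections = as.integer(n_projections),
                 angular_range_deg = angular_range_deg,
                 slope_order = slope_order,
                 slope_neighbors = as.integer(slope_neighbors),
                 step_px = step_px),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(paste0("optical config: n_medium %.4g, n_sample %.4g, ",
                     "%d projections / %g deg\n"),
              x$n_medium, x$n_sample, x$n_projections, x$angular_range_deg))
  invisible(x)
}

#' Snell refraction at an interface
#'
#' `n1 sin(alpha) = n2 sin(beta)`. When `|n1/n2 * sin(alpha)| > 1` the ray
#' undergoes total internal reflection and does not enter the sample; this is
#' reported as a flag, not an error. Vectorized over `alpha`.
#'
#' @param n1 refractive index on the incident side
#' @param n2 refractive index on the transmitted side
#' @param alpha incident angle(s) vs the surface normal, radians (may be
#'   signed)
#' @return list with `beta` (radians, `NA` under TIR) and logical `tir`
#' @export
snell_refract <- function(n1, n2, alpha) {
  s <- (n1 / n2) * sin(alpha)
  tir <- abs(s) > 1
  beta <- ifelse(tir, NA_real_, asin(pmin(pmax(s, -1), 1)))
  list(beta = beta, tir = tir)
}

#' Sinogram container
#'
#' A `P x W` array: row `p` (1-based) holds the projection acquired at
#' `theta_p = (p-1) * angular_range / P` degrees; columns are lateral scan
#' positions (lab-frame image columns).
#'
#' @param values numeric `P x W` matrix
#' @param config the [optical_config()] used (angular metadata)
#' @return object of class `sinogram`
#' @export
sinogram <- function(values, config) {
  stopifnot(is.matrix(values), inherits(config, "optical_config"))
  if (nrow(values) != config$n_projections)
    stop("sinogram row count does not match n_projections")
  structure(list(values = values, n_projections = nrow(values),
                 width = ncol(values), config = config), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("sinogram: %d projections x %d positions (n1 %.4g, n2 %.4g)\n",
              x$n_projections, x$width, x$config$n_medium, x$config$n_sample))
  invisible(x)
}

#' @export
plot.sinogram <- function(x, ...) {
  v <- x$values
  image(t(v)[, nrow(v):1], col = gray(seq(0, 1, length.out = 256)),
        axes = FALSE, asp = nrow(v) / ncol(v), ...)
  invisible(x)
}

projection_angles <- function(config) {
  p <- seq_len(config$n_projections) - 1
  p * config$angular_range_deg / config$n_projections
}

# shared core: trace all rays for all projection angles
trace_all <- function(pair, contour, config, march) {
  thetas <- projection_angles(config) * pi / 180
  inside <- matrix(as.integer(contour$filled), nrow(contour$filled))
  cpp_trace_rays(pair$structure, inside, contour$points, contour$normals,
                 pair$rotation_center[1], pair$rotation_center[2],
                 thetas, ncol(pair$structure),
                 config$n_medium, config$n_sample, config$step_px, march)
}

#' Trace a single vertical scan ray through the phantom
#'
#' The lab-frame ray travels downward (+y) at column `scan_x` with the sample
#' at rotation angle `theta_deg`. The ray refracts at its first boundary
#' intersection (subpixel, by segment intersection; incident angle from the
#' slope fit at the nearer contour vertex) and then marches in steps of
#' `config$step_px` along the refracted direction, summing bilinear samples
#' of the structure image until it crosses the boundary on the backside or
#' leaves the frame. Exit-side refraction is not modeled (fluorescence is
#' collected omnidirectionally).
#'
#' @param pair a [phantom_pair()]
#' @param contour [trace_contour()] of the surface (computed if `NULL`)
#' @param scan_x 0-based lab column of the ray
#' @param config an [optical_config()]
#' @param theta_deg sample rotation angle in degrees
#' @return list: `entry_point` (x, y, sample frame; `NA` on miss),
#'   `incident_angle` (signed radians vs outward normal), `refracted_angle`,
#'   `exit_direction` (unit vector inside the sample), `tir`, `hit`,
#'   `integrated_intensity`
#' @export
trace_ray <- function(pair, contour = NULL, scan_x, config, theta_deg = 0) {
  stopifnot(inherits(pair, "phantom_pair"))
  if (is.null(contour))
    contour <- trace_contour(pair$surface, config$slope_order,
                             config$slope_neighbors)
  inside <- matrix(as.integer(contour$filled), nrow(contour$filled))
  res <- cpp_trace_rays(pair$structure, inside, contour$points,
                        contour$normals, pair$rotation_center[1],
                        pair$rotation_center[2], theta_deg * pi / 180,
                        ncol(pair$surface), config$n_medium, config$n_sample,
                        config$step_px, TRUE)
  j <- scan_x + 1
  list(entry_point = c(res$entry_x[1, j], res$entry_y[1, j]),
       incident_angle = res$alpha[1, j],
       refracted_angle = res$beta[1, j],
       exit_direction = c(res$dir_x[1, j], res$dir_y[1, j]),
       tir = res$tir[1, j] == 1L, hit = res$hit[1, j] == 1L,
       integrated_intensity = res$intensity[1, j])
}

#' Simulate a full SLOT acquisition
#'
#' For each projection angle the sample is (digitally) rotated and every
#' vertical scan ray is refracted at the boundary per Snell's law, then
#' integrated through the structure image along its real path; row `p` of the
#' sinogram is the projection at `theta_p`. Rays that miss the sample or
#' undergo total internal reflection write 0. Per-ray entry data (entry
#' point, incident angle, TIR flag) are returned as an [entry point
#' table][build_entry_table] for the rearrangement correction.
#'
#' @param pair a [phantom_pair()]
#' @param config an [optical_config()]
#' @param contour optional precomputed [trace_contour()] of the surface
#' @return list with `sinogram` (a [sinogram()]) and `entry_points`
#'   (an `entry_table`)
#' @export
simulate_sinogram <- function(pair, config = optical_config(), contour = NULL) {
  stopifnot(inherits(pair, "phantom_pair"), inherits(config, "optical_config"))
  if (is.null(contour))
    contour <- trace_contour(pair$surface, config$slope_order,
                             config$slope_neighbors)
  res <- trace_all(pair, contour, config, march = TRUE)
  list(sinogram = sinogram(res$intensity, config),
       entry_points = entry_table_from_trace(res, config, pair$rotation_center))
}
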