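#' Digital rotation angle that maps the expected beam path onto the real one
#'
#' A vertical scan ray that would enter the sample at incident angle `alpha1`
#' (vs the outward surface normal) without refraction actually travels that
#' in-sample path at a different rotation angle of the sample. The required
#' digital rotation follows from Snell's law at the entry point:
#' `n1 sin(alpha1 + dtheta) = n2 sin(alpha1)`, i.e. the refracted ray at the
#' rotated pose makes the same angle with the normal as the unrefracted
#' expected ray. Solving,
#' `dtheta = alpha1 - asin((n2/n1) sin(alpha1))` in the package's signed
#' convention (positive = counterclockwise under the package rotation
#' convention; the sign and ratio are pinned by a brute-force ray-traced
#' rotation-search oracle in the test suite). Where
#' `|(n2/n1) sin(alpha1)| > 1` the correspondence does not exist (information
#' about that entry point is never recorded) and `NA` is returned.
#'
#' `ratio = "inverted"` exposes the ratio `n1/n2` variant for debugging; it
#' does not satisfy the geometric oracle.
#'
#' @param n1 medium refractive index
#' @param n2 sample refractive index
#' @param alpha1 signed incident angle(s), radians
#' @param ratio `"snell"` (default) or `"inverted"` (debug)
#' @return digital rotation angle(s) in degrees; `NA` where no
#'   correspondence exists
#' @export
delta_theta <- function(n1, n2, alpha1, ratio = c("snell", "inverted")) {
  ratio <- match.arg(ratio)
  if (n1 == n2) return(0 * alpha1)     # exactly zero for matched media
  r <- if (ratio == "snell") n2 / n1 else n1 / n2
  s <- r * sin(alpha1)
  out <- ifelse(abs(s) > 1, NA_real_,
                alpha1 - asin(pmin(pmax(s, -1), 1)))
  out * 180 / pi
}

#' Vertical sinogram offset for a digital rotation
#'
#' With `P` projections over a full rotation, one sinogram row spans
#' `range/P` degrees; a digital rotation of `dtheta` degrees is
#' `dtheta * P / range` rows (with 800 projections over 360 deg, 1 degree is
#' 2.2 rows). The sinogram is periodic in angle over a full rotation, so the
#' offset is reported modulo `P`.
#'
#' @param delta_theta_deg digital rotation(s), degrees
#' @param n_projections number of sinogram rows `P`
#' @param angular_range_deg angular range (must cover a full rotation)
#' @return fractional row offset(s) in `[0, P)`
#' @export
vertical_offset <- function(delta_theta_deg, n_projections,
                            angular_range_deg = 360) {
  if (angular_range_deg != 360)
    stop("the rearrangement requires a full 360 degree acquisition")
  (delta_theta_deg * n_projections / angular_range_deg) %% n_projections
}

#' Horizontal sinogram offset for a rotated entry point
#'
#' The lab-frame entry position rotates with the sample: rotating the entry
#' point about the rotation center by `delta_theta` moves its lab column by
#' the horizontal offset.
#'
#' @param entry_point lab-frame entry point `(x, y)` (or an `n x 2` matrix)
#' @param delta_theta_deg digital rotation(s), degrees
#' @param center rotation center `(x, y)`
#' @return fractional column offset(s): rotated x minus original x
#' @export
horizontal_offset <- function(entry_point, delta_theta_deg, center) {
  if (is.null(dim(entry_point))) entry_point <- matrix(entry_point, ncol = 2)
  a <- delta_theta_deg * pi / 180
  dx <- entry_point[, 1] - center[1]
  dy <- entry_point[, 2] - center[2]
  (center[1] + cos(a) * dx - sin(a) * dy) - entry_point[, 1]
}

# assemble an entry_table from a cpp_trace_rays result
entry_table_from_trace <- function(res, config, center) {
  dt <- delta_theta(config$n_medium, config$n_sample, res$alpha)
  valid <- res$hit == 1L & res$tir != 1L & !is.na(dt)
  dt[!valid] <- NA_real_
  structure(list(entry_x = res$entry_x, entry_y = res$entry_y,
                 alpha = res$alpha, beta = res$beta, delta_theta = dt,
                 tir = res$tir == 1L, hit = res$hit == 1L, valid = valid,
                 config = config, center = center),
            class = "entry_table")
}

#' Per-(projection, column) entry-point table for sinogram rearrangement
#'
#' Rotates the sample surface to every projection angle and performs the ray
#' propagation of the simulator (without path integration) to record, for
#' each scan column: the subpixel entry point, the signed incident angle
#' `alpha1` of the vertical ray vs the local outward normal, the digital
#' rotation [delta_theta()], a TIR flag, and a validity flag (rays that miss
#' the sample, undergo TIR, or have no refraction-free correspondence are
#' invalid and contribute 0 to the corrected sinogram).
#'
#' @param surface boundary gray image
#' @param config an [optical_config()]; `n_sample` is the candidate sample RI
#' @param center rotation center; default image center
#' @param contour optional precomputed [trace_contour()]
#' @return object of class `entry_table`
#' @export
build_entry_table <- function(surface, config, center = NULL, contour = NULL) {
  if (is.null(center))
    center <- attr(surface, "center") %||% image_center(surface)
  if (is.null(contour))
    contour <- trace_contour(surface, config$slope_order, config$slope_neighbors)
  pair <- list(structure = matrix(0, nrow(surface), ncol(surface)),
               rotation_center = center)
  res <- trace_all(pair, contour, config, march = FALSE)
  entry_table_from_trace(res, config, center)
}

#' @export
print.entry_table <- function(x, ...) {
  cat(sprintf(paste0("entry table: %d x %d rays; %.1f%% hit, %.1f%% TIR, ",
                     "%.1f%% unrecoverable\n"),
              nrow(x$alpha), ncol(x$alpha), 100 * mean(x$hit),
              100 * mean(x$tir), 100 * invalid_fraction(x)))
  invisible(x)
}

#' Fraction of sample-hitting rays whose data are unrecoverable
#'
#' Rays that hit the sample but have no refraction-free correspondence
#' (arcsin domain exceeded, for `n2 > n1` at steep incidence) or are lost to
#' total internal reflection (`n1 > n2`). These grow with the RI mismatch and
#' concentrate in the outer columns; the rearrangement reports rather than
#' hides them.
#'
#' @param table an [build_entry_table()] result
#' @return fraction in `[0, 1]`
#' @export
invalid_fraction <- function(table) {
  hits <- sum(table$hit)
  if (hits == 0) return(0)
  sum(table$hit & !table$valid) / hits
}

#' Export an entry table as a data frame (CSV-ready)
#'
#' @param x an `entry_table`
#' @param ... unused
#' @return data frame with one row per (projection, column) ray that hit
#' @export
as.data.frame.entry_table <- function(x, ...) {
  P <- nrow(x$alpha); W <- ncol(x$alpha)
  keep <- which(x$hit)
  data.frame(projection = (keep - 1) %% P,
             column = (keep - 1) %/% P,
             entry_x = x$entry_x[keep], entry_y = x$entry_y[keep],
             alpha1_deg = x$alpha[keep] * 180 / pi,
             delta_theta_deg = x$delta_theta[keep],
             tir = x$tir[keep], valid = x$valid[keep])
}

#' Rearrange a refraction-distorted sinogram
#'
#' Each output sample `(p, w)` — the value an unrefracted ray would have
#' acquired — is pulled from the input sinogram at
#' `(p + vertical_offset, w + horizontal_offset)` by bilinear interpolation,
#' with rows wrapped modulo `P` (the 360-degree acquisition is periodic in
#' angle). Invalid entries (miss, TIR, no correspondence, or a source column
#' outside the sinogram) write 0: clamping would fabricate data.
#'
#' @param sino a [sinogram()]
#' @param table an [build_entry_table()] for the same geometry and config
#' @return corrected [sinogram()]
#' @export
rearrange_sinogram <- function(sino, table) {
  stopifnot(inherits(sino, "sinogram"), inherits(table, "entry_table"))
  P <- sino$n_projections; W <- sino$width
  if (!all(dim(table$alpha) == c(P, W)))
    stop("entry table shape does not match the sinogram")
  cfg <- table$config
  thetas <- projection_angles(cfg) * pi / 180
  cx <- table$center[1]; cy <- table$center[2]

  dt <- table$delta_theta                      # degrees, NA where invalid
  ok <- table$valid & !is.na(dt)
  dtr <- dt * pi / 180
  # lab-frame entry point at the original pose
  th <- matrix(thetas, P, W)
  dx <- table$entry_x - cx; dy <- table$entry_y - cy
  Lx <- cx + cos(th) * dx - sin(th) * dy
  Ly <- cy + sin(th) * dx + cos(th) * dy
  # rotate it by delta_theta about the rotation center -> horizontal offset
  hx <- cx + cos(dtr) * (Lx - cx) - sin(dtr) * (Ly - cy)
  hoff <- hx - Lx

  p0 <- matrix(0:(P - 1), P, W)
  w0 <- matrix(0:(W - 1), P, W, byrow = TRUE)
  src_r <- (p0 + dt * P / cfg$angular_range_deg) %% P
  src_c <- w0 + hoff
  ok <- ok & !is.na(src_c) & src_c >= 0 & src_c <= W - 1

  out <- matrix(0, P, W)
  if (any(ok)) {
    r <- src_r[ok]; cc <- src_c[ok]
    fr <- r - floor(r)
    r0 <- floor(r) %% P          # r may equal P exactly (fp modulo quirk)
    r1 <- (r0 + 1) %% P
    c0 <- pmin(floor(cc), W - 2); fc <- cc - c0
    S <- sino$values
    v <- (1 - fr) * (1 - fc) * S[cbind(r0 + 1, c0 + 1)] +
         (1 - fr) * fc       * S[cbind(r0 + 1, c0 + 2)] +
         fr * (1 - fc)       * S[cbind(r1 + 1, c0 + 1)] +
         fr * fc             * S[cbind(r1 + 1, c0 + 2)]
    out[ok] <- v
  }
  sinogram(out, cfg)
}

#' One-call correction pipeline
#'
#' Builds the entry table for `surface` at the candidate sample RI and
#' rearranges the sinogram.
#'
#' @param sino distorted [sinogram()]
#' @param surface boundary image (true or preemptive, from
#'   [surface_from_reconstruction()])
#' @param n_sample candidate sample RI (default: the sinogram's config value)
#' @param center rotation center; default image center
#' @param contour optional precomputed contour
#' @return corrected [sinogram()]
#' @export
correct_sinogram <- function(sino, surface, n_sample = NULL, center = NULL,
                             contour = NULL) {
  cfg <- sino$config
  if (!is.null(n_sample)) cfg$n_sample <- n_sample
  tab <- build_entry_table(surface, cfg, center, contour)
  rearrange_sinogram(sino, tab)
}

#' Extract a preemptive surface from a reconstruction
#'
#' The sample silhouette reconstructs correctly even from a distorted
#' (uncorrected) sinogram, so the boundary needed by the correction can be
#' taken from a plain FBP of the raw data: Otsu threshold over the inscribed
#' circle, largest connected component, hole filling, then the one-pixel
#' edge of the filled silhouette.
#'
#' @param recon a [fbp()] result or numeric matrix
#' @return boundary gray image (255 on the closed curve)
#' @export
surface_from_reconstruction <- function(recon) {
  v <- if (inherits(recon, "recon_image")) recon$pixels else recon
  if (all(v == 0)) stop("reconstruction is identically zero")
  H <- nrow(v); W <- ncol(v)
  ctr <- image_center(v)
  rad <- min(H, W) / 2 - 1
  xs <- matrix(rep(0:(W - 1), each = H), H, W) - ctr[1]
  ys <- matrix(rep(0:(H - 1), W), H, W) - ctr[2]
  disc <- xs^2 + ys^2 <= rad^2         # ring artifacts live outside
  u <- v; u[!disc] <- min(v[disc])
  u <- (u - min(u)) / (max(u) - min(u))
  th <- EBImage::otsu(u, range = c(0, 1))
  mask <- u > th & disc
  lab <- EBImage::bwlabel(matrix(as.integer(mask), H))
  if (max(lab) == 0) stop("no component above threshold; try a manual threshold")
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  mask <- EBImage::fillHull(matrix(as.integer(mask), H)) > 0
  boundary <- matrix(0, H, W)
  boundary[mask_edge(mask)] <- 255
  trace_contour(boundary)              # validates closure
  attr(boundary, "center") <- ctr
  boundary
}

#' Correct and reconstruct a sinogram over a grid of candidate sample RIs
#'
#' When the sample RI is not known, the sinogram is rearranged under several
#' candidate RIs and the reconstructions compared; the user's eye is the
#' intended judge. A sharpness score (variance of the Laplacian over the
#' sample silhouette) is attached per candidate as a machine-readable,
#' advisory aid.
#'
#' @param sino distorted [sinogram()]
#' @param surface boundary image
#' @param n_medium medium RI (default: the sinogram's config value)
#' @param candidates vector of candidate sample RIs (>= 1 entry)
#' @param filter FBP filter, see [fbp()]
#' @return object of class `ri_sweep`: list of entries with `n_sample`,
#'   `recon` ([fbp()] result), `sharpness`
#' @export
ri_sweep <- function(sino, surface, n_medium = NULL, candidates,
                     filter = "ramp") {
  if (length(candidates) < 1) stop("at least one candidate RI is required")
  cfg <- sino$config
  if (!is.null(n_medium)) cfg$n_medium <- n_medium
  contour <- trace_contour(surface, cfg$slope_order, cfg$slope_neighbors)
  center <- attr(surface, "center") %||% image_center(surface)
  pair <- list(structure = matrix(0, nrow(surface), ncol(surface)),
               rotation_center = center)
  res <- trace_all(pair, contour, cfg, march = FALSE)
  roi <- contour$filled
  entries <- lapply(candidates, function(n2) {
    cfg2 <- cfg; cfg2$n_sample <- n2
    tab <- entry_table_from_trace(res, cfg2, center)
    corr <- rearrange_sinogram(sinogram(sino$values, cfg2), tab)
    rec <- fbp(corr, filter)
    list(n_sample = n2, recon = rec,
         sharpness = laplacian_variance(rec$pixels, roi))
  })
  structure(list(entries = entries, n_medium = cfg$n_medium), class = "ri_sweep")
}

#' @export
print.ri_sweep <- function(x, ...) {
  sc <- vapply(x$entries, `[[`, numeric(1), "sharpness")
  ri <- vapply(x$entries, `[[`, numeric(1), "n_sample")
  cat("RI sweep (medium", x$n_medium, ") - sharpness is advisory:\n")
  for (i in order(-sc))
    cat(sprintf("  n_sample %.4g  sharpness %.4g%s\n", ri[i], sc[i],
                if (i == which.max(sc)) "  <- max" else ""))
  invisible(x)
}

# variance of the 5-point Laplacian over a mask (advisory focus measure)
laplacian_variance <- function(img, mask) {
  H <- nrow(img); W <- ncol(img)
  L <- img[c(2:H, H), ] + img[c(1, 1:(H - 1)), ] +
       img[, c(2:W, W)] + img[, c(1, 1:(W - 1))] - 4 * img
  stats::var(L[mask])
}
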