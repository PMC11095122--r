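#' Regions of interest derived from the sample boundary
#'
#' Two ROIs mirror standard practice for tomogram evaluation: a
#' `whole_sample` ROI — the filled silhouette dilated by a few pixels of
#' background (the corner regions of FBP reconstructions carry ring
#' artifacts and no information) — and a `central` ROI, the silhouette
#' scaled about the rotation center, covering the interior structure that
#' remains recoverable even under strong mismatch.
#'
#' @param boundary closed boundary gray image
#' @param dilation_px background margin around the silhouette (default 5)
#' @param central_fraction linear scale of the central ROI (default 0.5;
#'   its area is about `central_fraction^2` of the silhouette)
#' @param center rotation center; default image center
#' @return list of two ROI objects (`mask` logical matrix + `label`),
#'   named `whole_sample` and `central`
#' @export
make_rois <- function(boundary, dilation_px = 5, central_fraction = 0.5,
                      center = NULL) {
  filled <- fill_boundary(boundary)
  if (sum(filled) - sum(boundary > 0) < 4) stop("open boundary")
  if (is.null(center))
    center <- attr(boundary, "center") %||% image_center(boundary)
  whole <- dilate_mask(filled, dilation_px)
  H <- nrow(filled); W <- ncol(filled)
  if (central_fraction >= 1) {
    central <- filled
  } else {
    # sample the silhouette at coordinates scaled up about the center:
    # pixel q is central iff center + (q - center)/f is inside
    xs <- matrix(rep(0:(W - 1), each = H), H, W)
    ys <- matrix(rep(0:(H - 1), W), H, W)
    sx <- round(center[1] + (xs - center[1]) / central_fraction)
    sy <- round(center[2] + (ys - center[2]) / central_fraction)
    okc <- sx >= 0 & sx < W & sy >= 0 & sy < H
    central <- matrix(FALSE, H, W)
    central[okc] <- filled[cbind(sy[okc] + 1, sx[okc] + 1)]
  }
  central <- central & whole
  list(whole_sample = structure(list(mask = whole, label = "whole_sample"),
                                class = "roi"),
       central = structure(list(mask = central, label = "central"),
                           class = "roi"))
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("ROI '%s': %d px\n", x$label, sum(x$mask)))
  invisible(x)
}

roi_mask <- function(roi, img) {
  if (is.null(roi)) return(matrix(TRUE, nrow(img), ncol(img)))
  m <- if (inherits(roi, "roi")) roi$mask else roi
  if (!all(dim(m) == dim(img))) stop("ROI dimensions do not match the images")
  if (!any(m)) stop("empty ROI")
  m
}

#' Mean absolute pixel difference (APD)
#'
#' Mean over the ROI of `|a - b|` on the 8-bit scale: 0 is a perfect match,
#' 255 (white vs black) the largest possible difference.
#'
#' @param a,b gray images on the `[0, 255]` scale, same dimensions
#' @param roi an ROI from [make_rois()], a logical matrix, or `NULL` (whole
#'   frame)
#' @return scalar in `[0, 255]`
#' @export
apd <- function(a, b, roi = NULL) {
  if (!all(dim(a) == dim(b))) stop("image dimensions differ")
  m <- roi_mask(roi, a)
  mean(abs(a - b)[m])
}

gaussian_kernel <- function(sigma, size) {
  h <- (size - 1) / 2
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Structural similarity index (SSIM)
#'
#' Standard SSIM with the canonical published constants: dynamic range
#' `L = 255`, `K1 = 0.01`, `K2 = 0.03`, an 11 x 11 Gaussian window with
#' `sigma = 1.5`. The local SSIM map is computed wherever the full window
#' fits and averaged over the ROI. 1 means identical images; values near 0,
#' structurally unrelated ones.
#'
#' @inheritParams apd
#' @param L dynamic range
#' @param K1,K2 stabilization constants
#' @param sigma,window Gaussian window parameters
#' @param map return the SSIM map instead of its ROI mean
#' @return scalar (or matrix when `map = TRUE`; `NA` at the margins)
#' @export
ssim <- function(a, b, roi = NULL, L = 255, K1 = 0.01, K2 = 0.03,
                 sigma = 1.5, window = 11, map = FALSE) {
  if (!all(dim(a) == dim(b))) stop("image dimensions differ")
  k <- gaussian_kernel(sigma, window)
  mu_a <- cpp_sepconv_valid(a, k)
  mu_b <- cpp_sepconv_valid(b, k)
  s_aa <- cpp_sepconv_valid(a * a, k) - mu_a^2
  s_bb <- cpp_sepconv_valid(b * b, k) - mu_b^2
  s_ab <- cpp_sepconv_valid(a * b, k) - mu_a * mu_b
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  m <- ((2 * mu_a * mu_b + C1) * (2 * s_ab + C2)) /
       ((mu_a^2 + mu_b^2 + C1) * (s_aa + s_bb + C2))
  if (map) return(m)
  msk <- roi_mask(roi, a) & !is.na(m)
  if (!any(msk)) stop("ROI does not intersect the valid SSIM region")
  mean(m[msk])
}
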