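#' Filtered back projection (parallel-beam, full rotation)
#'
#' Each sinogram row is filtered in the frequency domain (zero-padded FFT to
#' the next power of two to suppress wrap-around) and back-projected with
#' linear interpolation over all angles. The angular weight is `pi / P` for
#' `P` projections over 360 degrees (conjugate rays are counted twice), so a
#' sinogram of a uniform disk reconstructs to the disk's intensity. 360
#' degree data are used directly without 180-degree folding: refraction
#' breaks conjugate-ray symmetry for uncorrected data, and one code path
#' serves both.
#'
#' @param sino a [sinogram()] with uniform angular sampling over 360 degrees
#' @param filter `"ramp"` (default), `"shepp_logan"`, or `"none"`
#' @return object of class `recon_image`: list with `pixels` (`W x W`
#'   matrix), `filter`, `config`
#' @export
fbp <- function(sino, filter = c("ramp", "shepp_logan", "none")) {
  filter <- match.arg(filter)
  stopifnot(inherits(sino, "sinogram"))
  P <- sino$n_projections; W <- sino$width
  if (P < 4) stop("at least 4 projections are required")
  S <- sino$values

  if (filter == "none") {
    filt <- S
  } else {
    npad <- 2^ceiling(log2(2 * W))
    Sp <- cbind(S, matrix(0, P, npad - W))
    # band-limited ramp: FFT of the real-space kernel h[0] = 1/4,
    # h[n] = -1/(pi n)^2 for odd n (correct DC handling, unlike sampling |f|)
    m <- c(0:(npad / 2), -(npad / 2 - 1):-1)
    h <- numeric(npad)
    h[1] <- 0.25
    odd <- m %% 2 != 0
    h[odd] <- -1 / (pi * m[odd])^2
    H <- Re(stats::fft(h))
    if (filter == "shepp_logan") {
      freq <- m / npad
      s <- rep(1, npad)
      nz <- freq != 0
      s[nz] <- sin(pi * freq[nz]) / (pi * freq[nz])
      H <- H * s
    }
    Fr <- mvfft(t(Sp))                  # FFT of each sinogram row
    filt <- Re(t(mvfft(Fr * H, inverse = TRUE))) / npad
    filt <- filt[, 1:W, drop = FALSE]
  }

  thetas <- projection_angles(sino$config) * pi / 180
  ctr <- (W - 1) / 2
  rec <- cpp_backproject(filt, thetas, ctr, ctr, W) * (pi / P)
  structure(list(pixels = rec, filter = filter, config = sino$config),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("reconstruction: %d x %d (%s filter)\n",
              nrow(x$pixels), ncol(x$pixels), x$filter))
  invisible(x)
}

#' @export
plot.recon_image <- function(x, ...) {
  v <- recon_to_gray(x)
  image(t(v)[, nrow(v):1], col = gray(seq(0, 1, length.out = 256)),
        axes = FALSE, asp = 1, ...)
  invisible(x)
}

#' Straight-ray forward projector (refraction-free oracle)
#'
#' Line-integral projections with the same rotation, sampling and summation
#' conventions as the ray-tracing simulator but zero refraction: the image is
#' rotated to each projection angle (bilinear) and summed down the columns.
#' Used as the independent cross-check for the matched-RI case.
#'
#' @param image structure gray image
#' @param n_projections number of projections over 360 degrees
#' @param center rotation center; default image center
#' @return a [sinogram()] (config has matched RIs of 1.5)
#' @export
straight_projector <- function(image, n_projections, center = NULL) {
  image <- as_gray_image(image)
  if (is.null(center)) center <- image_center(image)
  angles <- (0:(n_projections - 1)) * 360 / n_projections
  rows <- vapply(angles, function(th)
    colSums(rotate_image(image, th, center)), numeric(ncol(image)))
  cfg <- optical_config(n_medium = 1.5, n_sample = 1.5,
                        n_projections = n_projections)
  sinogram(t(rows), cfg)
}

#' Inscribed-circle mask of a square (or any) image
#'
#' @param img matrix (dimensions only)
#' @param margin radius reduction in pixels
#' @return logical matrix
#' @export
inscribed_circle <- function(img, margin = 0) {
  H <- nrow(img); W <- ncol(img)
  ctr <- image_center(img)
  xs <- matrix(rep(0:(W - 1), each = H), H, W) - ctr[1]
  ys <- matrix(rep(0:(H - 1), W), H, W) - ctr[2]
  sqrt(xs^2 + ys^2) <= min(H, W) / 2 - margin
}

#' Export a reconstruction to the 8-bit gray scale
#'
#' Min-max scaling over the inscribed circle (the corner regions carry the
#' typical ring artifacts of tomograms and would distort the scaling),
#' clamped to `[0, 255]`.
#'
#' @param recon a [fbp()] result or numeric matrix
#' @param mask optional logical matrix over which to take min/max
#' @return gray image matrix in `[0, 255]`
#' @export
recon_to_gray <- function(recon, mask = NULL) {
  v <- if (inherits(recon, "recon_image")) recon$pixels else recon
  if (is.null(mask)) mask <- inscribed_circle(v)
  lo <- min(v[mask]); hi <- max(v[mask])
  if (hi <= lo) return(matrix(0, nrow(v), ncol(v)))
  pmin(pmax((v - lo) / (hi - lo) * 255, 0), 255)
}
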