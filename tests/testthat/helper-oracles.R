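# Independent oracles. These deliberately re-derive the geometry from
# scratch (own rotation, refraction and windowed-statistics code) so they
# share no code path with the package internals they check.

.rot2 <- function(v, th) {
  c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2])
}

# Brute-force geometric search for the digital rotation: the sample (a
# circle of radius R about c0) is rotated until the Snell-refracted real
# ray entering a fixed material point travels, in the sample frame, exactly
# along the unrefracted vertical path of the original pose.
oracle_delta_theta <- function(n1, n2, alpha1_signed, R = 100,
                               c0 = c(128, 128)) {
  a <- abs(alpha1_signed)
  side <- if (alpha1_signed < 0) -1 else 1
  # material entry point whose signed incident angle at pose 0 is alpha1
  E <- c(c0[1] - side * R * sin(a), c0[2] - R * cos(a))
  nh <- (E - c0) / R
  f <- function(th1) {
    np <- .rot2(nh, th1)
    d <- c(0, 1)
    ci <- -sum(d * np)
    eta <- n1 / n2
    s2 <- eta^2 * (1 - ci^2)
    if (s2 > 1) return(NA_real_)
    tdir <- eta * d + (eta * ci - sqrt(1 - s2)) * np
    ts <- .rot2(tdir, -th1)            # back into the sample frame
    atan2(ts[1], ts[2])                # 0 when aligned with vertical
  }
  grid <- seq(-0.6, 0.6, by = 0.002)
  fv <- vapply(grid, f, numeric(1))
  ok <- which(is.finite(fv))
  sc <- ok[which(diff(sign(fv[ok])) != 0)]
  if (length(sc) == 0) return(NA_real_)
  i <- sc[which.min(abs(fv[sc]))]
  j <- ok[ok > i][1]
  uniroot(f, c(grid[i], grid[j]), tol = 1e-10)$root * 180 / pi
}

# Direct (slow) SSIM: per-pixel 11x11 Gaussian-weighted window statistics,
# valid region only.
reference_ssim <- function(a, b, roi_mask = NULL, L = 255, K1 = 0.01,
                           K2 = 0.03, sigma = 1.5, window = 11) {
  h <- (window - 1) / 2
  k1d <- exp(-((-h:h)^2) / (2 * sigma^2))
  w <- outer(k1d, k1d)
  w <- w / sum(w)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  H <- nrow(a); W <- ncol(a)
  if (is.null(roi_mask)) roi_mask <- matrix(TRUE, H, W)
  vals <- c()
  for (y in (h + 1):(H - h)) {
    for (x in (w_ok <- (h + 1)):(W - h)) {
      if (!roi_mask[y, x]) next
      A <- a[(y - h):(y + h), (x - h):(x + h)]
      B <- b[(y - h):(y + h), (x - h):(x + h)]
      ma <- sum(w * A); mb <- sum(w * B)
      va <- sum(w * A^2) - ma^2; vb <- sum(w * B^2) - mb^2
      cab <- sum(w * A * B) - ma * mb
      vals <- c(vals, ((2 * ma * mb + C1) * (2 * cab + C2)) /
                        ((ma^2 + mb^2 + C1) * (va + vb + C2)))
    }
  }
  mean(vals)
}

# directed Hausdorff distance between point sets (n x 2 each)
hausdorff_distance <- function(A, B) {
  d <- function(P, Q) {
    max(vapply(seq_len(nrow(P)), function(i)
      min(sqrt((Q[, 1] - P[i, 1])^2 + (Q[, 2] - P[i, 2])^2)), numeric(1)))
  }
  max(d(A, B), d(B, A))
}
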