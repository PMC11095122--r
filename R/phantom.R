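#' Generate a potato-shaped closed sample boundary
#'
#' The boundary radius is a smooth harmonic perturbation of a circle,
#' `r(phi) = mean_radius * (1 + sum_k a_k cos(k phi + phi_k))`, with random
#' low-order amplitudes scaled so that `sum |a_k| = irregularity`. Embedding
#' compounds for SLOT are near-cylindrical, so cross sections are roundish
#' but not perfect circles; this emulates that character. The curve is
#' rasterized one pixel wide at value 255 (interior pixels touching the
#' exterior through a 4-neighbor).
#'
#' @param seed integer RNG seed (the generator is deterministic given
#'   `seed` and parameters)
#' @param size image size `c(H, W)`; default 650 x 688
#' @param mean_radius mean boundary radius in pixels
#' @param irregularity total harmonic perturbation, fraction in `[0, 0.3]`
#' @param n_harmonics number of random harmonics
#' @param center rotation center `(x, y)`, 0-based; default image center
#' @return gray image (matrix) with the one-pixel boundary at 255
#' @export
generate_boundary <- function(seed = 1, size = c(650, 688),
                              mean_radius = round(0.35 * min(size)),
                              irregularity = 0.15, n_harmonics = 6,
                              center = NULL) {
  H <- size[1]; W <- size[2]
  if (H < 64 || W < 64) stop("image size must be at least 64x64")
  if (irregularity < 0 || irregularity > 0.3)
    stop("irregularity must be in [0, 0.3]")
  if (mean_radius * (1 + irregularity) >= min(H, W) / 2)
    stop("boundary radius exceeds the image frame")
  if (is.null(center)) center <- c((W - 1) / 2, (H - 1) / 2)

  if (irregularity > 0 && n_harmonics > 0) {
    coef <- with_seed(seed, {
      a <- runif(n_harmonics) / seq_len(n_harmonics)
      list(a = a / sum(a) * irregularity, ph = runif(n_harmonics, 0, 2 * pi))
    })
  } else coef <- list(a = numeric(0), ph = numeric(0))

  rfun <- function(phi) {
    pert <- rep(0, length(phi))
    for (k in seq_along(coef$a))
      pert <- pert + coef$a[k] * cos(k * phi + coef$ph[k])
    mean_radius * (1 + pert)
  }
  xs <- matrix(rep(0:(W - 1), each = H), H, W) - center[1]
  ys <- matrix(rep(0:(H - 1), W), H, W) - center[2]
  inside <- sqrt(xs^2 + ys^2) <= rfun(atan2(ys, xs))
  img <- matrix(0, H, W)
  img[mask_edge(inside)] <- 255
  attr(img, "center") <- center
  img
}

# interior pixels with at least one 4-neighbor outside (or on the frame edge)
mask_edge <- function(inside) {
  H <- nrow(inside); W <- ncol(inside)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- inside
  nb <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
        pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  inside & !nb
}

erode_mask <- function(mask, px) {
  if (px <= 0) return(mask)
  m <- matrix(as.integer(mask), nrow(mask))
  EBImage::erode(m, EBImage::makeBrush(2 * px + 1, "disc")) > 0
}

dilate_mask <- function(mask, px) {
  if (px <= 0) return(mask)
  m <- matrix(as.integer(mask), nrow(mask))
  EBImage::dilate(m, EBImage::makeBrush(2 * px + 1, "disc")) > 0
}

# drawing helpers (0-based coordinates) -------------------------------------

draw_disk <- function(img, cx, cy, r, value) {
  H <- nrow(img); W <- ncol(img)
  x0 <- max(0, floor(cx - r)); x1 <- min(W - 1, ceiling(cx + r))
  y0 <- max(0, floor(cy - r)); y1 <- min(H - 1, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  sub <- img[ys + 1, xs + 1, drop = FALSE]
  sub[d2 <= r^2] <- value
  img[ys + 1, xs + 1] <- sub
  img
}

draw_ellipse <- function(img, cx, cy, rx, ry, angle, value) {
  H <- nrow(img); W <- ncol(img)
  r <- max(rx, ry)
  x0 <- max(0, floor(cx - r)); x1 <- min(W - 1, ceiling(cx + r))
  y0 <- max(0, floor(cy - r)); y1 <- min(H - 1, ceiling(cy + r))
  xs <- x0:x1; ys <- y0:y1
  gx <- matrix(rep(xs, each = length(ys)), length(ys)) - cx
  gy <- matrix(rep(ys, length(xs)), length(ys)) - cy
  u <- cos(angle) * gx + sin(angle) * gy
  v <- -sin(angle) * gx + cos(angle) * gy
  sub <- img[ys + 1, xs + 1, drop = FALSE]
  sub[(u / rx)^2 + (v / ry)^2 <= 1] <- value
  img[ys + 1, xs + 1] <- sub
  img
}

# thick line segment: all pixels within width/2 of the segment
draw_segment <- function(img, x0, y0, x1, y1, width, value) {
  H <- nrow(img); W <- ncol(img)
  hw <- width / 2
  bx0 <- max(0, floor(min(x0, x1) - hw)); bx1 <- min(W - 1, ceiling(max(x0, x1) + hw))
  by0 <- max(0, floor(min(y0, y1) - hw)); by1 <- min(H - 1, ceiling(max(y0, y1) + hw))
  if (bx0 > bx1 || by0 > by1) return(img)
  xs <- bx0:bx1; ys <- by0:by1
  gx <- matrix(rep(xs, each = length(ys)), length(ys))
  gy <- matrix(rep(ys, length(xs)), length(ys))
  vx <- x1 - x0; vy <- y1 - y0
  L2 <- vx^2 + vy^2
  t <- if (L2 == 0) 0 else pmin(pmax(((gx - x0) * vx + (gy - y0) * vy) / L2, 0), 1)
  d2 <- (gx - (x0 + t * vx))^2 + (gy - (y0 + t * vy))^2
  sub <- img[ys + 1, xs + 1, drop = FALSE]
  sub[d2 <= hw^2] <- value
  img[ys + 1, xs + 1] <- sub
  img
}

# filled polygon via even-odd crossing test on the bounding box
draw_polygon <- function(img, px, py, value) {
  H <- nrow(img); W <- ncol(img)
  bx0 <- max(0, floor(min(px))); bx1 <- min(W - 1, ceiling(max(px)))
  by0 <- max(0, floor(min(py))); by1 <- min(H - 1, ceiling(max(py)))
  xs <- bx0:bx1; ys <- by0:by1
  gx <- matrix(rep(xs, each = length(ys)), length(ys))
  gy <- matrix(rep(ys, length(xs)), length(ys))
  inside <- matrix(FALSE, length(ys), length(xs))
  n <- length(px); j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > gy) != (py[j] > gy)) &
      (gx < (px[j] - px[i]) * (gy - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  sub <- img[ys + 1, xs + 1, drop = FALSE]
  sub[inside] <- value
  img[ys + 1, xs + 1] <- sub
  img
}

#' Generate a structure (fluorescence) image inside a boundary
#'
#' Patterns:
#' * `logo_like`: a few filled homogeneous shapes plus thin (2-4 px)
#'   line/letter-like strokes — large uniform areas next to very small,
#'   precise structures.
#' * `beads`: `n` disks of radius `r` at uniform-random interior positions
#'   (emulating fluorescent polystyrene beads in an agarose cylinder).
#' * `bars`: resolution-test line pairs of decreasing width/gap.
#'
#' All features are clipped to the boundary interior; the background is 0.
#'
#' @param boundary boundary image from [generate_boundary()]
#' @param pattern one of `"logo_like"`, `"beads"`, `"bars"`
#' @param seed integer RNG seed
#' @param params pattern-specific parameters: for `beads`, `n` (count,
#'   default 25), `r` (radius px, default 4), `intensity` (default 255)
#' @return gray image (matrix), nonzero only strictly inside the boundary
#' @export
generate_structure <- function(boundary, pattern = c("logo_like", "beads", "bars"),
                               seed = 1, params = list()) {
  pattern <- match.arg(pattern)
  filled <- fill_boundary(boundary)
  interior <- erode_mask(filled, 3)   # keep clear of the boundary curve
  H <- nrow(boundary); W <- ncol(boundary)
  img <- matrix(0, H, W)
  center <- attr(boundary, "center")
  if (is.null(center)) center <- image_center(boundary)
  rmax <- sqrt(sum(interior) / pi)    # effective silhouette radius

  if (pattern == "beads") {
    n <- params$n %||% 25
    r <- params$r %||% 4
    val <- params$intensity %||% 255
    min_sep <- params$min_sep %||% 2   # rigid beads: cross-sections disjoint
    if (n > 0) {
      eligible <- which(erode_mask(filled, ceiling(r) + 3))
      if (length(eligible) == 0) stop("interior too small for the requested beads")
      centers <- with_seed(seed, {
        acc <- matrix(numeric(0), 0, 2)
        tries <- 0
        while (nrow(acc) < n && tries < 300 * n) {
          sel <- sample(eligible, 1)
          cxy <- c((sel - 1) %/% H, (sel - 1) %% H)
          if (nrow(acc) == 0 ||
              min(sqrt((acc[, 1] - cxy[1])^2 + (acc[, 2] - cxy[2])^2)) >=
                2 * r + min_sep) acc <- rbind(acc, cxy)
          tries <- tries + 1
        }
        acc
      })
      if (nrow(centers) < n) stop("interior too small for ", n, " disjoint beads")
      for (i in seq_len(n))
        img <- draw_disk(img, centers[i, 1], centers[i, 2], r, val)
      dimnames(centers) <- list(NULL, c("x", "y"))
      attr(img, "bead_centers") <- centers
      attr(img, "bead_r") <- r
    }
  } else if (pattern == "bars") {
    widths <- params$widths %||% c(4, 3, 2, 1)
    val <- params$intensity %||% 255
    y <- center[2] - 0.55 * rmax
    for (wdt in widths) {
      for (k in 0:2) {
        img <- draw_segment(img, center[1] - 0.5 * rmax, y,
                            center[1] + 0.5 * rmax, y, wdt, val)
        y <- y + 2 * wdt
      }
      y <- y + 2.5 * wdt
    }
  } else {  # logo_like
    img <- with_seed(seed, {
      im <- img
      # large homogeneous areas
      im <- draw_ellipse(im, center[1] - 0.35 * rmax, center[2] - 0.30 * rmax,
                         0.42 * rmax, 0.30 * rmax, runif(1, 0, pi), 220)
      nv <- sample(5:7, 1)
      ang <- sort(runif(nv, 0, 2 * pi))
      rad <- rmax * runif(nv, 0.18, 0.33)
      im <- draw_polygon(im, center[1] + 0.40 * rmax + rad * cos(ang),
                         center[2] - 0.15 * rmax + rad * sin(ang), 160)
      im <- draw_disk(im, center[1] - 0.15 * rmax, center[2] + 0.42 * rmax,
                      0.16 * rmax, 120)
      # thin letter-like strokes in the lower half and center
      for (k in 1:9) {
        a <- runif(1, 0, pi)
        len <- rmax * runif(1, 0.15, 0.4)
        ox <- center[1] + rmax * runif(1, -0.55, 0.55)
        oy <- center[2] + rmax * runif(1, 0.0, 0.55)
        im <- draw_segment(im, ox - len / 2 * cos(a), oy - len / 2 * sin(a),
                           ox + len / 2 * cos(a), oy + len / 2 * sin(a),
                           sample(2:3, 1), 255)
      }
      # a small parallel-bar group (resolution feature)
      bx <- center[1] + 0.15 * rmax; by <- center[2] + 0.15 * rmax
      for (k in 0:2)
        im <- draw_segment(im, bx, by + 5 * k, bx + 0.28 * rmax, by + 5 * k, 2, 255)
      im
    })
  }
  img[!interior] <- 0
  attr(img, "center") <- center
  img
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bundle a surface/structure image pair
#'
#' @param surface boundary gray image (closed one-pixel curve)
#' @param structure structure gray image, nonzero only inside the boundary
#' @param rotation_center `(x, y)` 0-based; default image center
#' @param validate check the containment invariant (requires filling the
#'   boundary; disable for speed when images come from the generators)
#' @return object of class `phantom_pair`
#' @export
phantom_pair <- function(surface, structure, rotation_center = NULL,
                         validate = TRUE) {
  if (!all(dim(surface) == dim(structure)))
    stop("surface and structure dimensions differ")
  if (is.null(rotation_center))
    rotation_center <- attr(surface, "center") %||% image_center(surface)
  if (validate) {
    filled <- fill_boundary(surface)
    if (any(structure[!filled] != 0))
      stop("structure has nonzero pixels outside the boundary")
    ci <- round(rotation_center) + 1
    if (!filled[ci[2], ci[1]]) stop("rotation center lies outside the boundary")
  }
  structure(list(surface = surface, structure = structure,
                 rotation_center = rotation_center), class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  cat(sprintf("phantom pair: %d x %d px, rotation center (%.1f, %.1f)\n",
              nrow(x$surface), ncol(x$surface),
              x$rotation_center[1], x$rotation_center[2]))
  invisible(x)
}

#' Save / load a phantom pair as 8-bit images
#'
#' `save_phantom()` writes `surface.png` and `structure.png` into `dir`;
#' the round trip through [load_phantom()] is bit-exact for 8-bit data.
#'
#' @param pair a [phantom_pair()]
#' @param dir output directory (created if missing)
#' @return `save_phantom`: the directory, invisibly; `load_phantom`: a
#'   `phantom_pair`
#' @export
save_phantom <- function(pair, dir) {
  stopifnot(inherits(pair, "phantom_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gray(pair$surface, file.path(dir, "surface.png"))
  write_gray(pair$structure, file.path(dir, "structure.png"))
  invisible(dir)
}

#' @param surface_path,structure_path image files (PNG/TIFF)
#' @param rotation_center `(x, y)`; default image center
#' @rdname save_phantom
#' @export
load_phantom <- function(surface_path, structure_path, rotation_center = NULL) {
  surface <- read_gray(surface_path)
  structure_img <- read_gray(structure_path)
  if (!all(dim(surface) == dim(structure_img)))
    stop("surface and structure dimensions differ")
  trace_contour(surface)   # validates single closed curve
  phantom_pair(surface, structure_img, rotation_center)
}

#' Generate a complete phantom pair
#'
#' Convenience wrapper: boundary + structure with one seed.
#'
#' @inheritParams generate_boundary
#' @inheritParams generate_structure
#' @return a [phantom_pair()]
#' @export
generate_phantom <- function(seed = 1, size = c(650, 688),
                             pattern = "logo_like", params = list(),
                             mean_radius = round(0.35 * min(size)),
                             irregularity = 0.15, n_harmonics = 6) {
  surface <- generate_boundary(seed, size, mean_radius, irregularity, n_harmonics)
  structure_img <- generate_structure(surface, pattern, seed + 1000L, params)
  phantom_pair(surface, structure_img, validate = FALSE)
}
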