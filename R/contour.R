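#' Fill a closed boundary image
#'
#' @param boundary gray image whose nonzero pixels form a closed curve
#' @return logical matrix: TRUE inside or on the boundary
#' @export
fill_boundary <- function(boundary) {
  bin <- boundary > 0
  storage.mode(bin) <- "integer"
  EBImage::fillHull(bin) > 0
}

# clockwise Moore neighborhood, (dx, dy) with y pointing down
.moore <- cbind(dx = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
                dy = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L))

#' Trace the ordered contour of a closed sample boundary
#'
#' Applies Moore-neighbor boundary tracing to the filled silhouette of the
#' boundary image, producing an ordered closed pixel chain with a local
#' tangent slope and outward unit normal per point (from polynomial
#' regression over a window of neighboring contour points, fit in a locally
#' rotated frame so vertical tangents are not degenerate).
#'
#' @param surface gray image containing exactly one closed one-pixel curve
#' @param slope_order polynomial order of the local fit (>= 1)
#' @param slope_neighbors odd number of contour points in each local fit
#' @return an object of class `surface_contour`: list with `points` (K x 2,
#'   0-based x/y), `slopes` (dy/dx), `normals` (K x 2 outward unit vectors),
#'   `curvatures`, and `filled` (logical silhouette mask)
#' @export
trace_contour <- function(surface, slope_order = 2, slope_neighbors = 7) {
  bin <- surface > 0
  if (sum(bin) < 8)
    stop("degenerate boundary: fewer than 8 nonzero pixels")
  filled <- fill_boundary(surface)
  # the curve is 8-connected and one pixel wide, so its filled silhouette is
  # solid: count components there (4-connectivity is then sufficient)
  lab <- EBImage::bwlabel(matrix(as.integer(filled), nrow(filled)))
  ncomp <- max(lab)
  if (ncomp != 1)
    stop("expected a single closed boundary component; found ", ncomp)
  if (sum(filled) - sum(bin) < 4)
    stop("open boundary: curve does not enclose an interior")

  H <- nrow(filled); W <- ncol(filled)
  inside <- function(x, y) {            # 0-based coords
    x >= 0 && y >= 0 && x < W && y < H && filled[y + 1, x + 1]
  }
  # start at the topmost-leftmost filled pixel; entered from the west
  idx <- which(t(filled))[1]            # row-major scan
  sy <- (idx - 1) %/% W; sx <- (idx - 1) %% W
  pts_x <- integer(0); pts_y <- integer(0)
  cx <- sx; cy <- sy
  dir_back <- 1L                        # neighbor index of the backtrack (W)
  start_state <- NULL
  repeat {
    pts_x <- c(pts_x, cx); pts_y <- c(pts_y, cy)
    found <- FALSE
    d <- dir_back
    for (step in 1:8) {
      d <- d %% 8L + 1L
      nx <- cx + .moore[d, 1]; ny <- cy + .moore[d, 2]
      if (inside(nx, ny)) {
        state <- c(cx, cy, d)
        if (is.null(start_state)) {
          start_state <- state
        } else if (all(state == start_state)) {
          found <- FALSE
          break
        }
        # backtrack = neighbor just before the found one, seen from `next`
        prevx <- cx + .moore[if (d == 1L) 8L else d - 1L, 1]
        prevy <- cy + .moore[if (d == 1L) 8L else d - 1L, 2]
        cx <- nx; cy <- ny
        dir_back <- which(.moore[, 1] == prevx - cx & .moore[, 2] == prevy - cy)
        found <- TRUE
        break
      }
    }
    if (!found) break
    if (length(pts_x) > 8L * (H + W)) stop("contour tracing did not terminate")
  }
  # drop the duplicated closing point if present
  K <- length(pts_x)
  if (K > 1 && pts_x[K] == pts_x[1] && pts_y[K] == pts_y[1]) {
    pts_x <- pts_x[-K]; pts_y <- pts_y[-K]
  }
  pts <- cbind(x = pts_x, y = pts_y)
  if (nrow(pts) < 8) stop("degenerate boundary: traced contour too short")
  # an inner curve nested inside the traced one would be missed by the trace
  traced <- unique(pts[, 2] * ncol(filled) + pts[, 1])
  curve_px <- which(t(bin)) - 1
  if (mean(!(curve_px %in% traced)) > 0.05)
    stop("boundary pixels remain untraced: nested or multiple components?")

  fits <- slope_fit_all(pts, filled, slope_order, slope_neighbors)
  structure(list(points = pts, slopes = fits$slopes, normals = fits$normals,
                 curvatures = fits$curvatures, filled = filled,
                 slope_order = slope_order, slope_neighbors = slope_neighbors),
            class = "surface_contour")
}

#' @export
print.surface_contour <- function(x, ...) {
  cat("surface contour:", nrow(x$points), "points,",
      sum(x$filled), "px silhouette\n")
  invisible(x)
}

# local polynomial fit at one contour index; returns tangent/normal/curvature
slope_fit_one <- function(pts, filled, index, order, n_neighbors) {
  K <- nrow(pts)
  h <- (n_neighbors - 1) %/% 2
  idx <- ((index - 1 + (-h:h)) %% K) + 1
  px <- unname(pts[idx, 1] - pts[index, 1])
  py <- unname(pts[idx, 2] - pts[index, 2])
  sec <- c(px[n_neighbors] - px[1], py[n_neighbors] - py[1])
  if (all(sec == 0)) sec <- c(px[n_neighbors] - px[h + 1], py[n_neighbors] - py[h + 1])
  ang <- atan2(sec[2], sec[1])
  co <- cos(ang); si <- sin(ang)
  u <- co * px + si * py
  v <- -si * px + co * py
  X <- outer(u, 0:order, `^`)
  fit <- tryCatch(qr(X), error = function(e) NULL)
  if (is.null(fit) || fit$rank < order + 1) {
    if (order > 1) {
      warning("rank-deficient local fit; falling back to order 1")
      return(slope_fit_one(pts, filled, index, 1, n_neighbors))
    }
    coefs <- c(0, 0)
  } else coefs <- qr.coef(fit, v)
  b1 <- coefs[2]
  b2 <- if (order >= 2) coefs[3] else NA_real_
  tloc <- c(1, b1) / sqrt(1 + b1^2)
  tangent <- c(co * tloc[1] - si * tloc[2], si * tloc[1] + co * tloc[2])
  n1 <- c(tangent[2], -tangent[1])
  # orient the normal outward: probe a couple of pixels along each candidate
  H <- nrow(filled); W <- ncol(filled)
  probe_inside <- function(nrm) {
    q <- pts[index, ] + 2 * nrm
    xi <- round(q[1]) + 1; yi <- round(q[2]) + 1
    xi >= 1 && yi >= 1 && xi <= W && yi <= H && filled[yi, xi]
  }
  normal <- if (!probe_inside(n1)) n1 else -n1
  curv <- if (is.na(b2)) NA_real_ else abs(2 * b2) / (1 + b1^2)^1.5
  list(slope = tangent[2] / tangent[1], tangent = tangent, normal = normal,
       curvature = curv)
}

slope_fit_all <- function(pts, filled, order, n_neighbors) {
  K <- nrow(pts)
  slopes <- numeric(K); curvs <- numeric(K)
  normals <- matrix(0, K, 2)
  for (i in seq_len(K)) {
    f <- slope_fit_one(pts, filled, i, order, n_neighbors)
    slopes[i] <- f$slope; curvs[i] <- f$curvature
    normals[i, ] <- f$normal
  }
  list(slopes = slopes, normals = normals, curvatures = curvs)
}

#' Local surface slope and outward normal at a contour point
#'
#' Least-squares polynomial fit of the given order to `n_neighbors` contour
#' points centered at `index`, in a locally rotated frame (so near-vertical
#' tangents are well conditioned). Falls back to order 1 with a warning if
#' the fit is rank deficient.
#'
#' @param contour a [trace_contour()] result
#' @param index 1-based contour point index
#' @param order polynomial order (>= 1)
#' @param n_neighbors odd window size, `<=` contour length
#' @return list with `slope` (dy/dx), `tangent`, outward unit `normal`,
#'   and `curvature`
#' @export
estimate_slope <- function(contour, index, order = 2, n_neighbors = 7) {
  stopifnot(inherits(contour, "surface_contour"))
  if (n_neighbors %% 2 != 1 || n_neighbors < 3) stop("n_neighbors must be odd >= 3")
  if (n_neighbors > nrow(contour$points)) stop("n_neighbors exceeds contour length")
  if (order < 1) stop("order must be >= 1")
  slope_fit_one(contour$points, contour$filled, index, order, n_neighbors)
}
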