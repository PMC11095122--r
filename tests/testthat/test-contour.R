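test_that("traced contour of a circle is closed with the right perimeter", {
  ct <- fx_circle_pair()$contour
  p <- ct$points; K <- nrow(p)
  steps <- sqrt(rowSums((p - p[c(2:K, 1), ])^2))
  expect_true(all(steps <= sqrt(2) + 1e-9))      # 8-connected closed chain
  chain_len <- sum(steps)
  expect_gt(chain_len, 0.9 * 2 * pi * 40)
  expect_lt(chain_len, 1.1 * 2 * pi * 40)
})

test_that("degenerate and multiple boundaries are rejected with diagnostics", {
  lone <- matrix(0, 64, 64); lone[32, 32] <- 255
  expect_error(trace_contour(lone), "degenerate")
  two <- matrix(0, 128, 128)
  two[mask_2 <- radial_dist2(128, 30, 63.5) <= 15^2 &
        radial_dist2(128, 30, 63.5) > 13^2] <- 255
  two[radial_dist2(128, 95, 63.5) <= 15^2 &
        radial_dist2(128, 95, 63.5) > 13^2] <- 255
  expect_error(trace_contour(two), "found 2")
})

test_that("slope regression reproduces a straight line exactly", {
  # synthetic contour along y = 2x with the filled side underneath
  xs <- 20:60
  pts <- cbind(x = xs, y = 2 * xs - 20)
  filled <- matrix(FALSE, 128, 128)
  for (i in seq_len(nrow(pts)))
    filled[(pts[i, 2] + 1):128, pts[i, 1] + 1] <- TRUE
  ct <- structure(list(points = pts, filled = filled),
                  class = "surface_contour")
  for (ord in 1:3) {
    f <- estimate_slope(ct, 20, order = ord, n_neighbors = 7)
    expect_equal(f$slope, 2, tolerance = 1e-10)
    # outward normal points away from the filled half-plane (negative y side)
    expect_lt(f$normal[2], 0)
  }
})

test_that("circle tangent, normal and curvature are recovered", {
  ct <- fx_circle_pair()$contour
  # middle of the flat top-pixel run: analytic tangent is horizontal
  ymin <- min(ct$points[, 2])
  run <- which(ct$points[, 2] == ymin)
  f <- estimate_slope(ct, run[ceiling(length(run) / 2)], 2, 7)
  expect_lt(abs(f$slope), 1e-2)
  expect_equal(f$normal, c(0, -1), tolerance = 1e-2)
  # curvature from the quadratic term: exact on analytic circle points
  th <- seq(0, 2 * pi, length.out = 252)[-252]
  pts <- cbind(x = 63.5 + 40 * cos(th), y = 63.5 + 40 * sin(th))
  filled <- radial_dist2(128) <= 40^2
  cta <- structure(list(points = pts, filled = filled),
                   class = "surface_contour")
  curv <- vapply(seq(1, 251, by = 10), function(i)
    estimate_slope(cta, i, 2, 7)$curvature, numeric(1))
  expect_true(all(abs(curv - 1 / 40) / (1 / 40) < 0.15))
  # on rasterized pixels, pointwise curvature is quantization-noisy at this
  # window size; a wider window recovers it
  curv_px <- vapply(seq(1, nrow(ct$points), by = 10), function(i)
    estimate_slope(ct, i, 2, 15)$curvature, numeric(1))
  expect_equal(mean(curv_px), 1 / 40, tolerance = 0.15)
})

test_that("outward normals are consistent with the interior", {
  ct <- fx_logo160()$contour
  p <- ct$points
  probe <- p + 3 * ct$normals
  xi <- round(probe[, 1]) + 1; yi <- round(probe[, 2]) + 1
  ok <- xi >= 1 & yi >= 1 & xi <= ncol(ct$filled) & yi <= nrow(ct$filled)
  outside <- !ct$filled[cbind(yi[ok], xi[ok])]
  expect_gt(mean(outside), 0.99)
})
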