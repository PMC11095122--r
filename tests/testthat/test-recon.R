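test_that("FBP recovers a uniform disk quantitatively", {
  N <- 128; P <- 400
  s <- 0:(N - 1) - (N - 1) / 2
  chord <- ifelse(abs(s) <= 40, 2 * sqrt(pmax(40^2 - s^2, 0)) * 100, 0)
  sino <- sinogram(matrix(chord, P, N, byrow = TRUE),
                   optical_config(1.4, 1.4, P))
  rec <- fbp(sino)$pixels
  d2 <- radial_dist2(N)
  expect_equal(mean(rec[d2 <= 35^2]), 100, tolerance = 0.05)
  bg <- d2 > 50^2 & inscribed_circle(rec)
  expect_lt(abs(mean(rec[bg])), 3)
  # ring artifacts live outside the inscribed circle
  expect_gt(max(abs(rec[!inscribed_circle(rec)])), max(abs(rec[bg])))
})

test_that("all-zero and degenerate sinograms are handled", {
  z <- sinogram(matrix(0, 40, 64), optical_config(1.4, 1.4, 40))
  expect_true(all(fbp(z)$pixels == 0))
  bad <- structure(list(values = matrix(0, 3, 64), n_projections = 3,
                        width = 64, config = optical_config()),
                   class = "sinogram")
  expect_error(fbp(bad), "4 projections")
})

test_that("project-then-reconstruct round trip preserves a smooth image", {
  g <- outer(dnorm(0:63, 30, 12), dnorm(0:63, 35, 9))
  g <- g / max(g) * 200
  rec <- fbp(straight_projector(g, 400))$pixels
  m <- inscribed_circle(g)
  expect_gt(cor(rec[m], g[m]), 0.98)
})

test_that("FBP is linear", {
  set.seed(11)
  cfg <- optical_config(1.4, 1.4, 30)
  S1 <- matrix(runif(30 * 48), 30); S2 <- matrix(runif(30 * 48), 30)
  lhs <- fbp(sinogram(2.5 * S1 - 1.2 * S2, cfg))$pixels
  rhs <- 2.5 * fbp(sinogram(S1, cfg))$pixels -
         1.2 * fbp(sinogram(S2, cfg))$pixels
  expect_lt(max(abs(lhs - rhs)), 1e-10 * max(abs(rhs)))
})

test_that("projection is rotationally equivariant", {
  img <- fx_circle_pair()$pair$structure
  P <- 36
  base <- straight_projector(img, P)$values
  k <- 5
  rotated <- straight_projector(rotate_image(img, k * 360 / P), P)$values
  shifted <- base[((0:(P - 1) + k) %% P) + 1, ]
  expect_lt(sqrt(mean((rotated - shifted)^2)), 0.02 * max(base))
})

test_that("straight projection of a disk is its chord profile in every row", {
  disk <- make_disk_image(128, 40, 100)
  sp <- straight_projector(disk, 24)$values
  s <- 0:127 - 63.5
  chord <- ifelse(abs(s) <= 40, 2 * sqrt(pmax(40^2 - s^2, 0)) * 100, 0)
  err <- abs(sweep(sp, 2, chord))
  expect_lt(max(err) / max(chord), 0.02)
  # a point at the rotation center projects to a fixed column
  pt <- matrix(0, 128, 128); pt[64, 64] <- 255
  cols <- apply(straight_projector(pt, 36)$values, 1, which.max)
  expect_lte(diff(range(cols)), 1)
})
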