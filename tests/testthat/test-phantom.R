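test_that("boundary generation is deterministic and seed-sensitive", {
  a <- generate_boundary(3, c(128, 128))
  b <- generate_boundary(3, c(128, 128))
  c <- generate_boundary(4, c(128, 128))
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("zero irregularity yields a discrete circle of the given radius", {
  surf <- generate_boundary(1, c(128, 128), mean_radius = 40, irregularity = 0)
  idx <- which(surf > 0, arr.ind = TRUE)
  r <- sqrt((idx[, 2] - 1 - 63.5)^2 + (idx[, 1] - 1 - 63.5)^2)
  expect_true(all(abs(r - 40) <= 1))
})

test_that("default-size boundary matches the reference resolution and area", {
  surf <- generate_boundary(1)
  expect_equal(dim(surf), c(650, 688))
  ct <- trace_contour(surf)
  p <- ct$points; K <- nrow(p)
  # shoelace area of the traced polygon vs the unperturbed circle
  area <- abs(sum(p[, 1] * p[c(2:K, 1), 2] - p[c(2:K, 1), 1] * p[, 2]) / 2)
  r0 <- round(0.35 * 650)
  expect_gt(area, 0.7 * pi * r0^2)
  expect_lt(area, 1.3 * pi * r0^2)
})

test_that("boundary parameter and geometry errors are caught", {
  expect_error(generate_boundary(1, irregularity = 0.5), "irregularity")
  expect_error(generate_boundary(1, c(128, 128), mean_radius = 70),
               "exceeds")
  expect_error(generate_boundary(1, c(32, 32)), "at least")
})

test_that("structure support is strictly inside the boundary for all patterns", {
  for (pat in c("logo_like", "beads", "bars")) {
    surf <- generate_boundary(2, c(160, 160))
    stru <- generate_structure(surf, pat, seed = 5)
    filled <- fill_boundary(surf)
    expect_true(all(stru[!filled] == 0), info = pat)
    expect_gt(sum(stru > 0), 0)
    # determinism
    expect_identical(stru, generate_structure(surf, pat, seed = 5))
  }
})

test_that("bead structure places the requested number of disjoint disks", {
  surf <- generate_boundary(2, c(256, 256))
  expect_true(all(generate_structure(surf, "beads", params = list(n = 0)) == 0))
  stru <- generate_structure(surf, "beads", seed = 7,
                             params = list(n = 25, r = 4))
  lab <- EBImage::bwlabel(matrix(as.integer(stru > 0), 256))
  expect_equal(max(lab), 25)
  disk_raster_area <- sum(make_disk_image(16, 4, 1, 7, 7))
  expect_lte(sum(stru > 0), 25 * disk_raster_area)
  expect_true(all(tabulate(lab[lab > 0]) <= disk_raster_area))
})

test_that("logo-like structure has large homogeneous areas and thin features", {
  surf <- generate_boundary(1, c(256, 256))
  stru <- generate_structure(surf, "logo_like", seed = 1)
  # a constant-intensity region of at least 1000 px
  vals <- sort(unique(stru[stru > 0]))
  expect_true(any(vapply(vals, function(v) sum(stru == v) >= 1000, logical(1))))
  # thin strokes: some foreground vanishes under erosion with a 5x5 disc
  strokes <- matrix(as.integer(stru == 255), 256)
  eroded <- EBImage::erode(strokes, EBImage::makeBrush(5, "disc"))
  expect_gt(sum(strokes), 0)
  expect_gt(sum(strokes & !eroded), 0.5 * sum(strokes))
})

test_that("phantom save/load round trip is bit exact and validated", {
  pair <- generate_phantom(5, c(128, 128), "beads")
  dir <- withr::local_tempdir()
  save_phantom(pair, dir)
  back <- load_phantom(file.path(dir, "surface.png"),
                       file.path(dir, "structure.png"))
  expect_equal(unname(back$surface), unname(pair$surface),
               ignore_attr = TRUE)
  expect_equal(unname(back$structure), unname(pair$structure),
               ignore_attr = TRUE)
  # rotation center defaults to the geometric image center
  expect_equal(back$rotation_center, c(63.5, 63.5))
})

test_that("phantom invariant violations are rejected", {
  surf <- generate_boundary(1, c(128, 128), mean_radius = 40)
  stru <- matrix(0, 128, 128)
  stru[3, 3] <- 200                       # outside the boundary
  expect_error(phantom_pair(surf, stru), "outside")
  expect_error(phantom_pair(surf, matrix(0, 64, 64)), "dimensions")
  # an open arc is not a valid surface
  arc <- matrix(0, 128, 128)
  th <- seq(0, pi, length.out = 200)
  arc[cbind(round(64 + 40 * sin(th)), round(64 + 40 * cos(th)))] <- 255
  d <- withr::local_tempdir()
  write_gray(arc, file.path(d, "surface.png"))
  write_gray(matrix(0, 128, 128), file.path(d, "structure.png"))
  expect_error(load_phantom(file.path(d, "surface.png"),
                            file.path(d, "structure.png")))
})
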