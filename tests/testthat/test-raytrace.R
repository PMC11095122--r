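test_that("snell_refract handles normal incidence, matched media and TIR", {
  expect_equal(snell_refract(1.33, 1.5, 0)$beta, 0)
  expect_equal(snell_refract(1.4, 1.4, 0.7)$beta, 0.7)
  expect_true(snell_refract(1.5, 1.0, 60 * pi / 180)$tir)
  expect_false(snell_refract(1.0, 1.5, 60 * pi / 180)$tir)
  # signed angles refract with preserved sign
  expect_equal(snell_refract(1.4, 1.3, -0.5)$beta,
               -snell_refract(1.4, 1.3, 0.5)$beta)
})

test_that("image rotation is the identity at 0 and near-identity at 360", {
  img <- fx_circle_pair()$pair$structure
  expect_equal(rotate_image(img, 0), img)
  expect_lt(max(abs(rotate_image(img, 360) - img)), 1)
  r4 <- img
  for (k in 1:4) r4 <- rotate_image(r4, 90)
  expect_lt(mean(abs(r4 - img)), 2)
})

test_that("matched-RI ray integral equals the analytic chord integral", {
  surf <- generate_boundary(1, c(128, 128), mean_radius = 50, irregularity = 0)
  stru <- make_disk_image(128, 45, 80)
  pair <- phantom_pair(surf, stru, validate = FALSE)
  cfg <- optical_config(1.4, 1.4, 16)
  ct <- trace_contour(surf)
  for (sx in c(63, 50, 35)) {
    rr <- trace_ray(pair, ct, scan_x = sx, cfg)
    chord <- 2 * sqrt(45^2 - (sx - 63.5)^2) * 80
    expect_equal(rr$integrated_intensity, chord, tolerance = 0.02)
  }
  miss <- trace_ray(pair, ct, scan_x = 2, cfg)
  expect_false(miss$hit)
  expect_equal(miss$integrated_intensity, 0)
})

test_that("rays fan away from the center when the sample RI is lower", {
  fx <- fx_circle_pair()
  cfg <- optical_config(1.4, 1.3, 16)
  right <- trace_ray(fx$pair, fx$contour, scan_x = 94, cfg)   # right of center
  left <- trace_ray(fx$pair, fx$contour, scan_x = 33, cfg)
  expect_gt(right$exit_direction[1], 0)
  expect_lt(left$exit_direction[1], 0)
  # Snell identity at the entry point
  expect_equal(1.4 * sin(right$incident_angle),
               1.3 * sin(right$refracted_angle), tolerance = 1e-9)
})

test_that("a centered circular phantom gives identical sinogram rows", {
  fx <- fx_circle_pair()
  sim <- simulate_sinogram(fx$pair, optical_config(1.4, 1.4, 24), fx$contour)
  v <- sim$sinogram$values
  to8 <- 255 / max(v)
  dev <- max(apply(v, 2, function(col) diff(range(col))))
  expect_lt(dev * to8, 1)
})

test_that("matched simulation conserves mass and matches the straight projector", {
  fx <- fx_logo160()
  cfg <- optical_config(1.4, 1.4, 60)
  sim <- simulate_sinogram(fx$pair, cfg, fx$contour)
  v <- sim$sinogram$values
  # mass conservation: every projection row sums to the structure total
  expect_true(all(abs(rowSums(v) / sum(fx$pair$structure) - 1) < 0.03))
  # row-wise RMS against the independent straight-ray projector
  oracle <- straight_projector(fx$pair$structure, 60, fx$pair$rotation_center)
  rms <- sqrt(rowMeans((v - oracle$values)^2))
  expect_true(all(rms <= 0.02 * apply(oracle$values, 1, max)))
})

test_that("Snell's identity holds for every traced entry", {
  fx <- fx_logo160()
  cfg <- optical_config(1.45, 1.33, 24)
  tab <- simulate_sinogram(fx$pair, cfg, fx$contour)$entry_points
  sel <- tab$hit & !tab$tir
  expect_gt(sum(sel), 1000)
  lhs <- cfg$n_medium * sin(tab$alpha[sel])
  rhs <- cfg$n_sample * sin(tab$beta[sel])
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("optical_config validates its invariants", {
  expect_error(optical_config(n_medium = 0.9), "between 1 and 99")
  expect_error(optical_config(n_sample = 120), "between 1 and 99")
  expect_error(optical_config(n_projections = 3), "4 projections")
  expect_error(optical_config(slope_neighbors = 4), "odd")
})
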