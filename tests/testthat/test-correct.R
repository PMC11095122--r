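test_that("delta_theta obeys the trivial identities", {
  expect_equal(delta_theta(1.4, 1.4, 0.6), 0)
  expect_equal(delta_theta(1.52, 1.33, 0), 0)
  expect_equal(delta_theta(1.3, 1.45, -0.4), -delta_theta(1.3, 1.45, 0.4))
  # no refraction-free correspondence at steep incidence when n2 > n1
  expect_true(is.na(delta_theta(1.33, 1.5, 1.2)))
  # the debug ratio variant is a different function
  expect_false(isTRUE(all.equal(delta_theta(1.4, 1.3, 0.5),
                                delta_theta(1.4, 1.3, 0.5, "inverted"))))
})

test_that("delta_theta matches the ray-traced rotation-search oracle", {
  d <- delta_theta(1.4, 1.3, 30 * pi / 180)
  o <- oracle_delta_theta(1.4, 1.3, 30 * pi / 180)
  expect_equal(d, o, tolerance = 0.1 / abs(o))
})

test_that("vertical offset converts degrees to sinogram rows with wraparound", {
  expect_equal(vertical_offset(1, 800), 800 / 360)         # 2.2 recurring
  expect_equal(vertical_offset(0, 800), 0)
  expect_equal(vertical_offset(-1, 400), 400 - 400 / 360)
  expect_error(vertical_offset(1, 800, 180), "360")
})

test_that("horizontal offset is the lab-frame shift of the rotated entry", {
  expect_equal(horizontal_offset(c(80, 40), 0, c(64, 64)), 0)
  expect_equal(horizontal_offset(c(64, 64), 33, c(64, 64)), 0)
  expect_equal(horizontal_offset(c(64 + 30, 64), 90, c(64, 64)), -30)
})

test_that("matched-RI rearrangement is the identity", {
  fx <- fx_circle_pair()
  cfg <- optical_config(1.4, 1.4, 40)
  sim <- simulate_sinogram(fx$pair, cfg, fx$contour)
  tab <- build_entry_table(fx$pair$surface, cfg, fx$pair$rotation_center,
                           fx$contour)
  expect_true(all(tab$delta_theta[tab$valid] == 0))
  out <- rearrange_sinogram(sim$sinogram, tab)
  to8 <- 255 / max(sim$sinogram$values)
  expect_lt(max(abs(out$values - sim$sinogram$values)) * to8, 1)
})

test_that("unrecoverable-ray fraction is reported and grows with n2 > n1", {
  fx <- fx_circle_pair()
  frac <- vapply(c(1.40, 1.45, 1.52), function(n2) {
    cfg <- optical_config(1.4, n2, 12)
    invalid_fraction(build_entry_table(fx$pair$surface, cfg,
                                       fx$pair$rotation_center, fx$contour))
  }, numeric(1))
  expect_equal(frac[1], 0)
  expect_true(all(diff(frac) > 0))
})

test_that("entry table exports to a tidy data frame", {
  fx <- fx_circle_pair()
  cfg <- optical_config(1.4, 1.35, 8)
  tab <- build_entry_table(fx$pair$surface, cfg, fx$pair$rotation_center,
                           fx$contour)
  df <- as.data.frame(tab)
  expect_named(df, c("projection", "column", "entry_x", "entry_y",
                     "alpha1_deg", "delta_theta_deg", "tir", "valid"))
  expect_true(all(df$projection >= 0 & df$projection < 8))
  expect_equal(nrow(df), sum(tab$hit))
})

test_that("correction restores bead circularity after a mismatch", {
  demo <- fx_bead_demo()
  mm <- demo$beads$mismatched
  cc <- demo$beads$corrected
  expect_gte(max(mm$axis_ratio, na.rm = TRUE), 2)
  expect_lte(median(cc$axis_ratio, na.rm = TRUE), 1.3)
  expect_gt(mean(cc$axis_ratio <= 1.3, na.rm = TRUE), 0.8)
})

test_that("preemptive surface extraction recovers the true boundary", {
  # transmission-like contrast: the structure fills the whole silhouette,
  # so the reconstruction shows the sample outline
  surf <- generate_boundary(1, c(128, 128), mean_radius = 40,
                            irregularity = 0)
  stru <- make_disk_image(128, 38, 150)
  pair <- phantom_pair(surf, stru, validate = FALSE)
  contour <- trace_contour(surf)
  cfg <- optical_config(1.4, 1.4, 120)
  rec <- fbp(simulate_sinogram(pair, cfg, contour)$sinogram)
  got <- trace_contour(surface_from_reconstruction(rec))$points
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  truth <- cbind(63.5 + 38 * cos(th), 63.5 + 38 * sin(th))
  expect_lt(hausdorff_distance(got, truth), 2)
  # a mismatched acquisition still yields a closed boundary
  recx <- fbp(simulate_sinogram(pair, optical_config(1.4, 1.31, 120),
                                contour)$sinogram)
  expect_silent(surface_from_reconstruction(recx))
  expect_error(surface_from_reconstruction(matrix(0, 64, 64)), "zero")
})

test_that("RI sweep is consistent and peaks at the true sample RI", {
  sim <- fx_logo160_mismatch()
  pair <- fx_logo160()$pair
  # single candidate reproduces the one-shot pipeline bit for bit
  sw1 <- ri_sweep(sim$sinogram, pair$surface, 1.4, 1.30)
  direct <- fbp(correct_sinogram(sim$sinogram, pair$surface, n_sample = 1.30,
                                 center = pair$rotation_center))
  expect_identical(sw1$entries[[1]]$recon$pixels, direct$pixels)
  # a candidate equal to the medium RI reduces to plain FBP
  swm <- ri_sweep(sim$sinogram, pair$surface, 1.4, 1.4)
  plain <- fbp(sim$sinogram)
  to8 <- 255 / max(abs(plain$pixels))
  expect_lt(max(abs(swm$entries[[1]]$recon$pixels - plain$pixels)) * to8, 1)
  # sharpness maximal at the true RI (1.30) within one grid step
  sw <- ri_sweep(sim$sinogram, pair$surface, 1.4, seq(1.25, 1.35, 0.01))
  sc <- vapply(sw$entries, `[[`, numeric(1), "sharpness")
  ri <- vapply(sw$entries, `[[`, numeric(1), "n_sample")
  expect_lte(abs(ri[which.max(sc)] - 1.30), 0.0100001)
})
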