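# shared fixtures, memoized across test files (expensive simulations are
# computed once per test run)
.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx[[name]])) assign(name, force(expr), envir = .fx)
  .fx[[name]]
}

# analytic disk image builder (0-based center coords)
make_disk_image <- function(N, r, value = 100, cx = (N - 1) / 2,
                            cy = (N - 1) / 2) {
  xs <- matrix(rep(0:(N - 1), each = N), N)
  ys <- matrix(rep(0:(N - 1), N), N)
  img <- matrix(0, N, N)
  img[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- value
  img
}

radial_dist2 <- function(N, cx = (N - 1) / 2, cy = (N - 1) / 2) {
  xs <- matrix(rep(0:(N - 1), each = N), N)
  ys <- matrix(rep(0:(N - 1), N), N)
  (xs - cx)^2 + (ys - cy)^2
}

# circle boundary + radially smooth structure (rotation-symmetric phantom)
fx_circle_pair <- function() fixture("circle_pair", {
  surf <- generate_boundary(1, c(128, 128), mean_radius = 40, irregularity = 0)
  d2 <- radial_dist2(128)
  stru <- 200 * exp(-d2 / (2 * 15^2))
  stru[d2 > 35^2] <- 0
  list(pair = phantom_pair(surf, stru, validate = FALSE),
       contour = trace_contour(surf))
})

# small logo phantom for correction tests
fx_logo160 <- function() fixture("logo160", {
  pair <- generate_phantom(1, c(160, 160), "logo_like")
  list(pair = pair, contour = trace_contour(pair$surface))
})

# mismatched simulation on the small logo phantom (medium 1.4, sample 1.3)
fx_logo160_mismatch <- function() fixture("logo160_mismatch", {
  fx <- fx_logo160()
  cfg <- optical_config(1.4, 1.3, n_projections = 200)
  simulate_sinogram(fx$pair, cfg, fx$contour)
})

# acceptance-scale sweep: 256x256 logo phantom, 400 projections, medium 1.4
fx_sweep <- function() fixture("sweep", {
  run_mismatch_sweep(experiment_config(), keep_images = FALSE)
})

fx_bead_demo <- function() fixture("bead_demo", end_to_end_bead_demo())
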