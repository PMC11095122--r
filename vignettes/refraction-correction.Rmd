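---
title: "Simulating and correcting refractive-index mismatch in SLOT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and correcting refractive-index mismatch in SLOT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slotsim)
```

## The imaging model

Scanning laser optical tomography (SLOT) rotates a sample through a focused
"needle" beam and records, for each rotation angle and lateral scan position,
the integrated fluorescence excited along the beam path. Over a full rotation
this yields a sinogram — one row per projection angle, one column per scan
position — that is reconstructed by filtered back projection (FBP) exactly as
in parallel-beam CT.

The optical difference from CT is refraction. When the refractive index (RI)
of the sample, `n2`, differs from that of the immersion medium, `n1`, each
scan ray bends at the sample boundary according to Snell's law,
`n1 sin(alpha) = n2 sin(beta)`, where `alpha` is the incident angle against
the local surface normal. The beam then excites fluorescence along the *real*,
tilted path while the instrument files the measurement under the *expected*,
vertical path. Reconstruction of such a sinogram shows a shrunken silhouette
when `n2 < n1` (rays fan away from the center), an enlarged interior when
`n2 > n1` (rays converge), and tangential, star-like smearing of compact
structures away from the rotation center.

`simulate_sinogram()` implements this forward model on a two-dimensional
phantom: a *surface* image (the closed sample boundary) and a *structure*
image (the fluorescence pattern). For each projection the vertical lab-frame
ray is transformed into the sample frame, intersected with the traced boundary
polygon (subpixel, by segment intersection), refracted at the local normal,
and marched in one-pixel steps along the refracted direction, summing bilinear
samples of the structure image until it crosses the boundary again or leaves
the frame. The sample RI is assumed homogeneous — rays travel straight inside
— and refraction at the exit face is ignored, since fluorescence is collected
omnidirectionally. Rays that miss the sample write zero; so do rays lost to
total internal reflection (TIR), which physically leave a dark sinogram spot
that no post-processing can recover.

The boundary normal at each entry point comes from least-squares polynomial
regression (order 2 over 7 neighboring contour points by default) in a locally
rotated frame, so near-vertical tangents are well conditioned. On rasterized
contours the *tangent* from this window is accurate; pointwise *curvature* at
this window size is dominated by the half-pixel quantization of the contour
(the sagitta over a 7-pixel arc at realistic radii is smaller than the
rasterization noise) and only becomes quantitative with wider windows or
subpixel contour points. Nothing in the correction uses curvature; it is
exposed for diagnostics.

## The rearrangement correction

Because the sample rotates a full turn, every boundary point is eventually hit
from every direction: the information that an unrefracted ray *would* have
measured at pose `theta0` was actually recorded at some other pose `theta1`.
The correction therefore never invents data; it only moves sinogram samples to
where they belong.

At the entry point the geometry is fully determined by the incident angle.
Requiring that the refracted ray at the rotated pose make the same angle with
the surface normal as the unrefracted expected ray gives
`n1 sin(alpha1 + dtheta) = n2 sin(alpha1)`, so the digital rotation is

```
dtheta = alpha1 - asin((n2 / n1) * sin(alpha1))
```

(`delta_theta()`). Two conventions in this formula are genuinely open — the
direction of the ratio `n2/n1` and the sign of `dtheta` relative to the
package's rotation convention — and both are pinned by a brute-force oracle in
the test suite: a ray-traced search over rotation angles of a circular sample
for the pose at which the real refracted path coincides with the expected
vertical path. The closed form above agrees with that search to better than
1e-6 degrees over hundreds of random `(n1, n2, alpha1)` triples; the inverted
ratio `n1/n2`, which also circulates in derivations of this correction,
disagrees by several degrees and is exposed only behind a debug flag.

The digital rotation is converted into sinogram offsets: vertically,
`dtheta * P / 360` fractional rows for `P` projections (with the typical 800
projections over 360 degrees, one degree is 2.2 rows), wrapped modulo `P`
because a full-rotation sinogram is periodic in angle; horizontally, the shift
of the lab-frame entry point when rotated by `dtheta` about the rotation
center. `rearrange_sinogram()` then pulls each output sample from the offset
position by bilinear interpolation. Samples with no refraction-free
correspondence — `|(n2/n1) sin(alpha1)| > 1`, which happens at steep incidence
when `n2 > n1` — and TIR samples are written as zero rather than clamped:
clamping would fabricate data. The affected fraction is reported by
`invalid_fraction()` and grows with the mismatch, which is why the outer rim
of strongly mismatched samples cannot be restored.

The per-ray tables (`build_entry_table()`) are computed by the same ray
propagation as the simulator, run on the surface image rotated to every
projection angle. In a real workflow the surface comes from the data
themselves: the silhouette reconstructs correctly even from a distorted
sinogram, so `surface_from_reconstruction()` extracts a *preemptive surface*
from a plain FBP of the uncorrected transmission data (Otsu threshold inside
the inscribed circle, largest component, hole filling, one-pixel edge). When
the sample RI is unknown, `ri_sweep()` corrects under a grid of candidate RIs
for visual comparison; the attached variance-of-Laplacian sharpness score is
advisory only — selecting the RI remains the user's judgment.

## Reconstruction

`fbp()` filters each sinogram row in the frequency domain and back-projects
with bilinear accumulation. The ramp filter is the FFT of the band-limited
real-space kernel (`h[0] = 1/4`, `h[n] = -1/(pi n)^2` for odd `n`), not a
direct sampling of `|f|`: the sampled version misallocates the DC term and
biases a uniform disk's interior by several percent, which the kernel form
reduces to below 0.1 percent. Rows are zero-padded to the next power of two to
suppress convolution wrap-around. The angular weight is `pi / P` for `P`
projections over 360 degrees — conjugate rays are counted twice, and the data
are deliberately not folded to 180 degrees because refraction breaks
conjugate-ray symmetry in uncorrected sinograms; one code path serves both.
Values are reported in the structure image's intensity units; 8-bit export
(`recon_to_gray()`) min-max scales over the inscribed circle, outside of which
FBP corner artifacts live.

`straight_projector()` — rotate the image, sum the columns — is a deliberately
independent forward model used as the oracle for the matched-RI case
(simulator and projector agree to well under 2 percent RMS) and for FBP
round-trip tests.

## Phantoms: what they emulate and what they do not

Real SLOT samples are cleared specimens embedded in a near-cylindrical
adhesive compound. `generate_boundary()` emulates such cross sections with a
harmonically perturbed circle, `r(phi) = R (1 + sum_k a_k cos(k phi + phi_k))`
— roundish but "potato shaped", with total perturbation `irregularity`
(default 0.15, up to 0.3) spread over 6 low-order harmonics. The default frame
is 650 x 688 pixels with `R = 0.35 * min(H, W)`; the sweep experiments default
to 256 x 256 with 400 projections so a full mismatch study runs in minutes,
with the full-scale setup (650 x 688, 800 projections) available through the
same configuration.

Three structure patterns cover the validation needs: `logo_like` (large
homogeneous shapes plus 2-3 pixel strokes — contrast-rich detail at both
scales, used for the quality sweeps), `beads` (disjoint disks at uniform
random interior positions, emulating fluorescent polystyrene beads; disjoint
because rigid bead cross sections do not interpenetrate, and the bead-shape
measurement needs distinct ground-truth objects), and `bars` (resolution line
groups). All generators are deterministic given a seed.

The phantoms are two-dimensional by design: out-of-plane refraction, which
occurs when the compound's wall is not perpendicular to the imaging plane,
moves light off the reconstruction plane and cannot be corrected by in-plane
rearrangement. The simulator also omits Fresnel transmission losses, surface
scattering, absorption along the path, and the beam waist — all of which
reduce real-data quality in ways the correction does not address. Passing
tests on these phantoms therefore demonstrate the geometric correctness of the
simulation and rearrangement, not robustness to those photometric effects; on
real data the corrected image additionally shows an intensity drop-off toward
the sample edge that originates in the measurement, not in the rearrangement.

## Evaluation

Reconstructions are compared on the 8-bit scale against the matched-RI
(`n1 = n2`) reconstruction of the same phantom, with two metrics over two
regions of interest (`make_rois()`): the filled silhouette dilated by 5 pixels
(`whole_sample` — FBP corner artifacts carry no information and are excluded),
and the silhouette scaled by 0.5 about the rotation center (`central` — the
region that remains recoverable under strong mismatch). `apd()` is the mean
absolute pixel difference (0 perfect, 255 maximal); `ssim()` is the standard
structural similarity index with the canonical constants (`L = 255`,
`K1 = 0.01`, `K2 = 0.03`, 11 x 11 Gaussian window, `sigma = 1.5`), computed
wherever the full window fits and averaged over the ROI. The SSIM
implementation is cross-checked in the tests against an independent direct
windowed implementation to 1e-6.

Bead circularity is measured by `measure_beads()`: the reconstruction is
thresholded at a quarter of its maximum — the star-like smearing wings sit
well below half-max but clearly above background, so a half-max (FWHM)
isophote would understate them — and each known bead center is assigned the
connected component covering it. The axis ratio from the pixel covariance
eigenvalues is 1 for a circular bead and grows with tangential smearing;
components covering no bead center (e.g. the thin line artifacts that a
corrected reconstruction may retain) are excluded from bead statistics.

## Numerical choices and degenerate inputs

* Pixel coordinates are 0-based, `x` = column, `y` = row, origin top-left;
  the rotation center defaults to the geometric image center
  `((W-1)/2, (H-1)/2)` and is configurable everywhere.
* Ray marching uses a fixed 1-pixel step (configurable) and stops at the
  first step outside the silhouette, without fractional weighting of the last
  step; the resulting quantization is about one structure sample per ray,
  visible only against sharp-edged structures.
* The incident angle is taken from the slope fit at the contour vertex
  nearest to the subpixel entry point.
* Entry tables computed at `n1 = n2` short-circuit to exactly zero offsets,
  making the matched-RI correction the identity to machine precision.
* Rank-deficient slope fits fall back to order 1 with a warning; contours
  with multiple, nested, or open components are rejected with diagnostics.
* `ri_sweep` grid edges: candidates equal to the medium RI reduce to plain
  FBP of the raw sinogram.

## Problem sizes

The test suite and the acceptance script run the full pipeline at 256 x 256
with 400 projections (the sweep over six mismatches takes on the order of a
minute), module-level checks at 128-192 pixels with 16-240 projections, and
the boundary generator additionally at the full 650 x 688 frame. These sizes
were chosen so that a complete mismatch study is an interactive, desk-scale
computation; all quality conclusions are scale-stable in our tests down to
128 pixels.

## Known limitations

Refraction *inside* the specimen is not modeled and cannot be corrected by
this method; samples must be homogeneous after clearing. TIR losses and
steep-incidence information loss for `n2 > n1` are reported, not recovered.
The corrected reconstructions show mildly reduced contrast (information is
redistributed, and unrecoverable samples are zeroed), so APD against the
matched reference does not reach zero even for perfect geometry. The
correction assumes a full 360-degree acquisition with uniform angular
sampling and a single closed boundary per imaging plane.
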