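---
title: "RT-DIC conversion and kinematic chirality analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RT-DIC conversion and kinematic chirality analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtdic)
```

## The problem

Differential interference contrast (DIC) microscopy images unstained,
photosensitive cells with very low phototoxicity, but renders them as
shadow-cast reliefs: the recorded intensity mixes the optical-path
*gradient along the prism's shear axis* with absorption contrast. Such
images cannot be thresholded, rendered in 3D, or fed to voxel-wise motion
estimators. `rtdic` converts single-shot DIC images into "self-luminous"
intensity images with one frequency-domain filter, then quantifies chiral
cell motility — which way filopodia screw, which way amoebae turn — from
the converted movies.

## The composite Riesz filter

Write the DIC image model as $d = -I + \partial I/\partial \hat s$ with
$\hat s$ the shear direction (default 45 degrees). In the frequency
domain the package builds:

* the directional Hilbert transform $H(\omega) = -i\,\mathrm{sgn}(\omega
  \cdot \hat s)$ — removes shadows but is blind to features along the
  shear axis and rings along it;
* the first-order directional Riesz transform $-i\,(\omega \cdot \hat
  s)/|\omega|$ — a smooth HT that integrates the gradient term;
* the second-order Riesz transform $-(\omega \cdot \hat
  s_\perp)^2/|\omega|^2$ along the *orthogonal* axis — real and even, it
  re-inverts the absorption term for shear-aligned features;
* their sum times a Gaussian high-pass $1 - e^{-|\omega|^2/2\sigma_{hp}^2}$
  that removes DC and slowly varying shading bias.

All filters are exactly Hermitian-symmetrized (the self-conjugate Nyquist
bins of even grids are handled explicitly) so real images stay real, and
$|H| \le 1$ everywhere. Images are mirror-padded by 25% per side before
the FFT to suppress wrap-around ringing.

Tunable parameters: the shear angle (degrees, must match the prism
orientation; 45 by default), and the high-pass scale `hp_sigma` in
cycles/pixel (default 0.01, i.e. 1/50 of Nyquist — wide enough to pass
cellular features, tight enough to remove quadrant-scale shading).
Thresholding the filtered image at zero yields the self-luminous image.

A single-shot composite cannot equal multi-shot inverse-transform
restoration: for features whose frequency content lies *along* the shear
axis at low spatial frequency, the first-order term leaves a quadrature
(phase-shift) artifact. Restoration quality is therefore assessed in the
band $|\omega| \approx 0.3$–$0.8$ rad/px where cellular features live at
microscope sampling rates; there the binary star-target test restores
with thresholded-overlap Jaccard above 0.7 while the plain HT stays near
0.4 and misses shear-aligned spokes entirely.

## Preprocessing chain

The standard order for Z-scanned time-lapse stacks is: 12-bit range
expansion (one global linear map per sequence) → XY drift cancellation →
Z-position correction → RT-DIC conversion → spatiotemporal smoothing →
isotropic resampling.

* **Drift**: plane-wise translations between successive stacks are
  estimated by symmetric phase-only matched filtering (cross-power
  spectrum whitened by its magnitude; 3-point quadratic subpixel peak
  fit), averaged over Z, accumulated, and removed by Fourier resampling.
  Low-confidence frames inherit interpolated drift.
* **Z correction**: each plane's axial offset (bounded to half a plane
  spacing) minimizes the mean square difference to the Lagrange
  interpolation of its neighbours; planes are then resampled at nominal
  positions. Offsets whose objective does not improve on zero are kept at
  zero and flagged.
* **Smoothing**: separable Gaussians along X, Y and time only — never Z —
  with unit DC gain (circular boundaries, so total intensity is
  preserved exactly).
* **Isotropic resampling**: Catmull-Rom interpolation along Z with
  linearly extrapolated virtual boundary planes (exact for linear-in-z
  intensity), e.g. 250 nm spacing, fourfold → 62.5 nm.
* **Deconvolution** is a generic Richardson-Lucy hook taking a
  user-supplied PSF; PSF synthesis from optical models is out of scope.

## Structure tensor and certainties

The structure tensor $S = G_{\sigma_{out}} * (\nabla I \nabla I^T)$ uses
Gaussian-derivative gradients at the inner scale and integration at the
outer scale (the "diameter of interest"; about 0.6 um for filopodium-scale
protrusions, with inner scale about a third of that). Its sorted eigen
system classifies local shape; the eigenvector of the smallest eigenvalue
is the fiber axis. The polarity vector $P = G_{\sigma_{out}} * \nabla I$
marks fiber end-points where local gradients do not cancel.

The exact certainty formulas are a design point: the package uses the
Westin-style fiber measure $C_a = (\lambda_2 - \lambda_3)/(\lambda_1 +
\varepsilon)$ with $\varepsilon = 10^{-3}\max\lambda_1$, and the tip
measure $C_t = |e_p \cdot e_3| \cdot \min(\lambda_p/\bar\lambda_p, 1)
\cdot C_a$, chosen to be high on fiber trunks and at end-caps
respectively; both are clipped to $[0,1]$ and zeroed below a tensor-trace
floor. Fiber axes are oriented base-to-tip by aligning with the outward
radial direction from the cell body; retrograde tracing integrates the
negated axis at half-voxel steps and calls a voxel *tractable* when the
path reaches the base region with fiber certainty intact.

For 2D still images the signed fiber curvature is the directional
derivative of the outward-oriented tangent angle along the tangent.

## Chirality conventions (load-bearing)

Arrays are indexed `[x, y(, z)(, t)]` with **x right, y down on screen, z
away from the viewer** — a right-handed frame. Positive angular
quantities are **clockwise on screen** (2D) and **right-screw about the
reference axis** (3D: local base-to-tip fiber axis, chord, or outward
radial axis). Positive axial velocity is extension; negative is
retraction. Every sign-carrying output states this convention in its
sidecar, because mirroring conventions silently flips every biological
conclusion. Parity is pinned by tests: mirrored phantoms must negate
every chirality-signed quantity.

## Optical flow and kinematics

Horn-Schunck flow is generalized to 3D with 6-neighbour Jacobi averaging,
frame-averaged central-difference gradients, and Neumann boundaries;
coarse-to-fine Gaussian pyramids (factor 2, blur sigma 1 voxel) handle
large motions, with three warping refinements per level to remove the
one-sided linearization bias. Defaults `alpha = 0.2`, 300 iterations per
solve, update tolerance `1e-5` were fixed by phantom recovery: uniform
translations of 1 and 6 voxels are recovered within 10% and 15%, and an
isolated Gaussian blob (whose featureless core gets its flow purely from
the smoothness prior) within about 6% over its full-width-half-maximum
support when the solver is run to convergence. Flow magnitudes carry a
small multiplicative attenuation; ratio-based quantities such as the
Frenet angular velocity are insensitive to it because numerator and
denominator attenuate together.

From five frames, four displacement sets (single/double-frame,
forward/backward) feed the symmetric stencils

$$v = \frac{8(d_{sf+} - d_{sf-}) - (d_{df+} - d_{df-})}{12\,\Delta t},
\quad a = \frac{d_{sf+} + d_{sf-}}{\Delta t^2}, \quad
j = \frac{d_{df+} - 2d_{sf+} + 2d_{sf-} - d_{df-}}{2\,\Delta t^3},$$

all exact on cubic paths (the velocity stencil uses all four sets; the
plain central difference would carry a $j\Delta t^2/6$ error). The
angular velocity is the Frenet rotation rate $\omega = (v \times
a)/|v|^2$; in 2D the scalar $(v_x a_y - v_y a_x)/|v|^2$ with curvature
$\omega/|v|$. Voxels are masked — excluded from statistics, not
zero-filled — below intensity (10% of max) and speed (0.2 voxel/frame)
floors and where $|v \times a|$ degenerates.

## Segmentation, tracking, and statistics

Converted 2D movies are smoothed and segmented by a watershed on the
foreground above the Otsu threshold, with an h-maxima-style tolerance
(10% of the dynamic range) merging shallow peaks. Centroids are linked
greedily in order of increasing distance under a gate (twice the median
step once enough steps are seen), optionally predicting positions with
the mean optical flow inside each particle; unmatched detections start
tracks, unmatched predictions terminate them. Per step, the heading
change wrapped to (-180, 180] accumulates into per-track mean angular
velocity (deg/min) and signed curvature (rad/mm); steps below a 0.5 px
displacement gate, and steps spanning a border-reflection event of the
synthetic walkers, contribute no heading change. Contact is defined by
mask dilation (2 px default) intersecting another particle.

The two statistical tiers are the per-trial Wilcoxon signed-rank test
against zero (zeros dropped, normal approximation above n = 25) and the
across-trial one-sample t-test on trial means, reported as mean ± s.e.m.
Its size was checked on 500 replicate null suites (6 trials x 12
unbiased walkers each): rejection stays within 7% at nominal 5%.

## What the phantoms do and do not show

The generators produce: the radial grating and its synthetic DIC
rendering (restoration tests), a Gaussian blob on a helix with
closed-form velocity/acceleration/jerk/angular velocity, a retracting
cylinder whose material texture advects toward the base while a surface
bump revolves at a prescribed axial spin, and 2D walkers whose headings
drift clockwise at +0.8 deg/min with 10 deg/sqrt-min noise at 8 um/min —
the amoeboid study conditions. Phantom geometry is rendered noise-free at
voxel centers with no optics or photon noise; passing tests therefore
demonstrate correctness of the *computational* pipeline (filters,
estimators, sign conventions, statistics), not robustness to shot noise,
uneven illumination beyond smooth shading, or segmentation of touching
cells, which real data adds.

Problem sizes used by the test-suite and the acceptance script — 256 px
gratings, 32-48 voxel cubes for flow, a 36-voxel cube for the circular
orbit (frame interval 6 s, so the centripetal signal $a\Delta t^2$ spans
about 0.7 voxel), 50 walkers over 25 frames on a 960 x 840 px arena —
are the package's chosen desk-scale validation conditions. For the
tracking phantom the walkers are spawned on a grid and confined each to
its own cell by reflection, which guarantees the non-interacting premise
of the identity-switch check; reflected steps are flagged and excluded
from heading statistics.

## Known limitations

* Single-shot composite restoration is inherently anisotropic at low
  spatial frequency along the shear axis (see above); multi-shot inverse
  reconstruction is out of scope.
* Horn-Schunck underestimates flow magnitude on isolated compact objects;
  magnitude-sensitive conclusions should rely on ratio quantities or be
  calibrated on phantoms.
* Tracking has no merge/split (mitosis, collision) handling: a gap or
  merge terminates the track and a new identity begins.
* TIFF output is range-normalized 32-bit integer (the value range lives
  in the JSON sidecar); the available TIFF writer has no float sample
  format.
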