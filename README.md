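# rtdic

Quantifying chiral cell motility from label-free DIC microscopy.

Differential interference contrast (DIC) microscopy images unstained,
photosensitive cells — neuronal growth cones, amoebae — with almost no
phototoxicity, but its shadow-cast images (optical-path gradient along the
prism's shear axis, mixed with absorption) defeat thresholding, 3D
rendering, and voxel-wise motion analysis. `rtdic` is an R package that

1. converts single-shot DIC images into self-luminous intensity images
   with a **composite directional Riesz-transform frequency filter**
   (first-order RT along the shear axis + second-order RT along the
   orthogonal axis + Gaussian high-pass):
   `H(ω) = [-i (ω·ŝ)/|ω| − (ω·ŝ⊥)²/|ω|²] · (1 − e^{−|ω|²/2σ²})`;
2. runs the downstream **computational kinematic analysis**: preprocessing
   (drift/Z correction, smoothing, isotropic resampling), structure-tensor
   geometry (fiber orientation `e3`, polarity vector, fiber/tip
   certainties, retrograde tracing, signed 2D neurite curvature), dense
   2D/3D Horn–Schunck optical flow with coarse-to-fine pyramids,
   five-frame kinematic stencils (velocity, acceleration, jerk, Frenet
   frame, angular velocity `ω = v×a/|v|²`), chirality-signed projections
   onto local/chordal/orbital/radial axes, watershed segmentation with
   centroid tracking, and the two-tier per-trial/across-trial statistics;
3. ships **synthetic phantom generators with analytic ground truth**
   (radial grating + synthetic DIC, helical blob, retracting/spinning
   filopodium, clockwise-biased 2D walkers) so the whole pipeline is
   validated end-to-end without any external data.

Sign conventions are load-bearing: arrays are `[x, y(, z)(, t)]` with x
right, y **down** on screen, z away from the viewer (right-handed), so a
positive angular quantity is clockwise on screen / right-screw about the
reference axis.

## Worked example

Restore a synthetic DIC image of a star target and measure the overlap
with the ground truth:

```r
library(rtdic)
g   <- radial_grating(c(256, 256), 16, binary = TRUE)  # ground truth
dic <- synth_dic(g)                  # -I + dI/d(45 deg): shadow-cast DIC
rec <- apply_filter(dic, composite_filter(c(256, 256)))
f   <- mean(g > 0.5)                 # matched positive-area fraction
jac <- function(a, b) sum(a & b) / sum(a | b)
jac(rec >= quantile(rec, 1 - f), g > 0.5)
#> [1] 0.7193525
```

0.72 means the thresholded restoration overlaps 72% (Jaccard) with the
true star; the plain directional Hilbert transform reaches only 0.39 and
misses the shear-aligned spokes.

Track clockwise-biased amoeba-like walkers and recover their chirality:

```r
w   <- walker_movie_2d(n = 50, shape = c(960, 840), n_frames = 25,
                       spawn = "grid", cell_confine = TRUE, seed = 61)
seg <- lapply(1:25, function(k) segment_cells(w$movie[, , k]))
cs  <- chirality_stats(link_tracks(seg), dt_s = 30, pitch_um = 2.58)
cs$summary["angular_velocity_deg_min", ]
#>      mean        sd       sem
#> 0.4650468 3.1911535 0.4512973
```

The tracked mean angular velocity (+0.47 ± 0.45 deg/min, clockwise
positive) recovers the generator's +0.8 deg/min bias — the signature of
right-handed clockwise migration.

The methods vignette (`vignettes/rtdic-methods.Rmd`) documents the model,
the conventions, every tunable parameter, and what the phantoms do and do
not validate.

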