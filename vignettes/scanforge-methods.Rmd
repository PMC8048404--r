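---
title: "From focal stacks to pose priors: the methods behind scanforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From focal stacks to pose priors: the methods behind scanforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

scanforge implements the image-processing and metrology core of a
low-cost photogrammetry workflow for pinned arthropod specimens. The
specimen sits on a two-axis gimbal (a horizontal tilt axis X, limited to a
100° span so an illumination dome always backs the view, and a vertical
rotation axis Y that turns freely) inside a diffusely lit dome; a macro
camera on a linear rail captures, for every (X, Y) orientation, an ordered
*focal stack* of 20–50 images as the focal plane sweeps through the
specimen. This vignette explains the models each processing stage assumes,
the tunable parameters and their defaults, the numerical choices, and what
the synthetic fixtures do and do not demonstrate.

```{r setup}
library(scanforge)
```

## Focus filtering

Macro depth of field is tiny compared to a specimen's extent, so many stack
images contain no in-focus content at all and only degrade the subsequent
merge. Sharpness is scored as the **variance of the response of the 3×3
Laplacian kernel** `[[0,1,0],[1,−4,1],[0,1,0]]`: in-focus texture produces
strong second derivatives and a high variance, defocus suppresses them.
Planes scoring below a threshold are discarded.

Numerical choices: the convolution uses replicate padding so the response
matches the input size; RGB images are reduced with the channel-average
grey projector (the same projector blending uses, so the two stages agree
on what "sharp" means); ties at the threshold are *retained* (`≥`). The
default threshold is 0 — retain everything — because the useful value
depends on sensor noise, z step, aperture and magnification and must be
found empirically per setup; thresholds belong in the project
configuration, not in code.

## Stack registration

As the camera advances, magnification grows slightly and the rail
introduces in-plane jitter. The rig constrains the motion: no rotation, no
shear. Each plane is therefore related to the most distal plane (z index 0,
the widest field of view, which stays untouched as the reference) by an
**isotropic scale plus a translation**,
`x_moving = s·(x_ref − c) + c + t` about the image centre `c`.

Estimation is spectral: the translation-invariant log-polar profile of the
magnitude spectrum turns scaling into a 1-D shift, which seeds a direct
refinement that maximizes image-domain correlation of the fully
compensated pair (evaluated on a central crop so edge replication cannot
bias the optimum); translation then comes from phase correlation with
parabolic sub-pixel interpolation. Because focus overlap between *distant*
planes is shallow, each plane is registered against its z-neighbour and
the neighbour transforms are composed to the reference
(`S_i = s_i·S_{i−1}`, `T_i = s_i·T_{i−1} + t_i`). Resampling is bilinear
with edge replication; featureless inputs return the identity flagged
`low_confidence`. The contract the test-suite enforces on fixtures:
translations recovered to 0.5 px, scales to 0.005.

## EDOF blending

Blending is **winner-takes-all** ("hard mask"): per pixel, the plane with
the highest local contrast — the windowed variance of the Laplacian
response, window 7 px by default — supplies the output pixel *verbatim*.
Copying rather than averaging preserves detail and avoids halos where
focal planes overlap. Luminance and saturation deliberately play no role
in selection; colour is copied untouched from the winning plane, and only
the selection analysis runs on a grey projection (channel average by
default; CIE L\* is selectable when faint halos in highlights or shadows
need suppressing).

The raw per-pixel argmax is cleaned with a 5×5 majority filter before
copying, which suppresses salt-and-pepper plane switching in near-tied
regions while keeping the defining invariant intact: every output pixel is
bit-identical to the plane named by the returned index map. Contrast ties
break towards the lowest z index, so blending is deterministic and a stack
of identical planes returns the first plane exactly. The window size is a
tunable with the ground-truth PSNR property (≥ 30 dB on the three-plane
fixture) as its contract; 7 px balances localization against noise.

## Automatic masking

Reconstruction quality improves markedly when the background is removed:
background features otherwise corrupt camera matching, spawn floating
artefacts, and blur the model's contours. Masking runs in five steps, each
its own function:

1. **Enhance** (`enhance`): grey projection → 5×5 Gaussian blur → 5×5
   median blur → CLAHE (clip 2.0, 64 px tiles). The blurs remove the noise
   edge detectors amplify; CLAHE lifts faint cuticle/background contrast.
   Constant images pass through unchanged, since histogram equalisation is
   undefined on them.
2. **Outline** (`detect_outline`): normalized Scharr gradient magnitude,
   values in [0, 1]. The normalization is floored (peak gradient at least
   0.05 in intensity units) so a bare background's vignette is not
   amplified into spurious edges — this is what makes "no specimen"
   detectable. A pre-trained structured-forest edge detector is the
   higher-quality alternative on real photographs; it requires an external
   model file and inference runtime that this package does not bundle, so
   requesting it raises an explicit configuration error rather than
   silently falling back.
3. **Largest shape** (`largest_shape_mask`): binarize at 0.2, close 1–2 px
   contour gaps (disc radius 3), fill enclosed regions, keep the largest
   8-connected component — the specimen.
4. **Infill removal** (`remove_infill`): the filled outline wrongly
   includes background the specimen encloses (between a leg and the body).
   Within the current foreground, a pixel brighter than its 101 px
   local mean by more than 5 intensity levels (8-bit scale) is
   background-like and flips to background — luminance keying against the
   uniformly lit dome. The sign matters: keying on *brighter than the
   local mean* leaves uniform dark specimen interiors stable (their
   intensity matches their local mean) while bright enclosed background,
   whose neighbourhood mean is dragged down by the surrounding dark
   cuticle, flips. It also trims the bright overshoot the filled edge band
   leaves around the true silhouette. Background pixels are never flipped
   to foreground, and the assumption is the one the hardware provides:
   near-uniform lighting of the image centre.
5. **Cleanup** (`clean_mask`): connected-component labelling removes
   foreground islands and fills holes smaller than `1e-4` of the image
   area — the operational form of a cleanup threshold "determined by the
   image resolution". Components exactly at the threshold survive; the
   largest foreground component always survives. Foreground is
   8-connected, background 4-connected (the standard duality that avoids
   topological paradoxes). The operation is idempotent.

The mask is written as a binary PNG (white = specimen), and the cut-out
either zeroes the background or attaches the mask as an alpha channel;
foreground pixels are bit-identical to the input in both modes.

## Camera-pose priors

Feature-based camera solving can fail for small or self-similar specimens.
Because the gimbal geometry is known, approximate extrinsics can be
computed analytically and handed to the reconstruction software as a
starting point. Under the equivalent-camera-motion model the specimen's
rotation is inverted onto the camera:
`centre = R_y(−y)·R_x(−x)·(0, 0, r)` with X tilt applied before Y rotation
(the tilt stage rides on the rotation stage), so every camera sits on the
sphere of radius `r` and looks at the origin.

Frame conventions (a documented choice, validated by invariants rather
than by diffing against any particular tool's output): right-handed world,
+Y up along the gimbal's vertical axis, +Z from dome centre towards the
camera home position; the camera looks along its local −Z; the look-at up
vector is world +Y, replaced by +X if the viewing axis is numerically
vertical (unreachable given the 100° tilt range, but the code should not
divide by zero). The invariants enforced for the full 6 × 20 grid:
orthonormality to 1e-9, determinant +1, centres on the sphere to 1e-9 mm,
look-at error below 1e-7 rad.

Scenes serialize to an AliceVision-dialect `.sfm` JSON (views, one shared
intrinsics record, poses with row-major rotations; numbers stored as
strings as that dialect expects) with fixed float formatting, so identical
scenes produce byte-identical files. All views share one camera serial so
the intrinsics are solved once and reused. The 35 mm-equivalent focal
length is user-supplied configuration, not derived from a crop factor —
the sensor-width ratio does not reproduce vendor-quoted equivalents, so no
derivation is assumed.

Camera metadata travels with the images: `write_exif` embeds Make, Model,
CameraSerialNumber, FocalLength, FocalLengthIn35mmFormat and SensorWidth
in the PNG `eXIf` chunk (a little-endian TIFF IFD). EXIF has no standard
sensor-width tag — external tools write it as a maker/composite field — so
it is stored under a private tag id that `read_exif` understands; the
other fields use their standard ids. Pixel data are untouched, which the
tests check by checksum.

## Mesh metrology

The gauge-block protocol quantifies metric accuracy: certified blocks
(e.g. 1.50/1.10/1.05 mm against a 1.00 mm reference) are scanned in pairs
and the reconstructed step is the difference of the mean up-axis
coordinates of the two top planes. Region selection uses axis-aligned
bounding boxes — the scriptable equivalent of manually isolated vertex
groups. The reported spread is the quadrature combination of the two
regions' standard deviations; published tables do not define their spread
column, so this definition is documented and tested only against synthetic
fixtures.

Surface area is the triangle-area sum; volume is the divergence-theorem
sum of signed tetrahedra, taken as an absolute value so global winding
does not matter. Volume is *refused* for non-watertight meshes (every
undirected edge must be shared by exactly two opposed half-edges) rather
than silently misreported; area remains available. The longest body axis
is the maximum pairwise vertex distance — exact by blocked brute force up
to 20k vertices, above that after reduction to support vertices over 2048
quasi-uniform directions (the diameter's endpoints are extreme points, so
the reduction error is a discretization effect that the tests bound by
comparing against brute force).

## CV-equality statistics

Measurement precision across observers is compared with the coefficient of
variation `c_v = σ/µ` and the **Feltz–Miller asymptotic test** for equality
of CVs across k groups: with `m_i = n_i − 1`, `c_i = sd_i/mean_i` and
pooled `c = Σ m_i c_i / Σ m_i`,

$$D = \frac{\sum_i m_i (c_i - c)^2}{c^2(0.5 + c^2)} \;\sim\; \chi^2_{k-1}.$$

The API takes summaries (n, mean, sd) because published tables print
summaries, with a raw-sample wrapper on top. The plain asymptotic form is
implemented and named in the output; no small-sample correction or
likelihood-ratio variant is offered. Reported CVs are conventionally
rounded to 3 decimals. A seeded simulation (two normal groups, n = 50,
true CV 0.1, 5000 replicates) checks the empirical type-I error at
α = 0.05 sits within ±0.01 of nominal; a companion check confirms power
approaches 1 for clearly unequal CVs at large n.

## Synthetic fixtures: what they emulate, and what they don't

All fixtures are pure functions of their arguments including the seed
(bit-reproducible, RNG-state-neutral), and every generator returns its
ground truth:

* `make_focal_stack`: smooth seeded texture plus a dark blob; plane j
  blurs each vertical band by a Gaussian whose σ grows linearly with the
  band's distance from its sharp plane, optionally with recorded per-plane
  magnification/jitter. Gaussian defocus linear in depth offset is a
  deliberate simplification — it exercises winner-takes-all selection
  without modelling a thin-lens PSF, bokeh shape, or chromatic effects.
* `make_specimen_edof` (400×400 px default): dark articulated body
  (ellipses), six 4–5 px appendages, an antenna, one enclosed background
  hole, on a light-grey background (0.80) with mild radial vignetting
  (0.03) and optional pixel noise; specimen level 0.15 with ±0.05 surface
  texture, softened by a σ = 0.7 px blur at the silhouette. These levels
  represent a dark insect under a well-lit dome. Not modelled: specular or
  iridescent cuticle, translucent wings, out-of-focus background
  structure, colour — so a passing mask IoU (≥ 0.95 clean, ≥ 0.93 at 2%
  noise) demonstrates the pipeline logic, not performance on shiny or
  transparent specimens, which remain the hard cases in practice.
* `make_step_cubes`: two triangulated plates at the protocol's nominal
  heights with optional i.i.d. vertical vertex noise. Real reconstructions
  add correlated, non-Gaussian error; the fixture only validates the
  measurement procedure, not the scanner's accuracy.
* `make_cv_groups` and `make_icosphere` feed the statistics and metrology
  checks.

## Problem sizes and determinism

The test and acceptance workloads are sized for a single CPU: 128 px
registration/blending fixtures, one 400×400 masking fixture per noise
level, the 120-pose grid, 100 noisy gauge replicates at 10⁴ vertices per
plate, and 5000 CV-test replicates at n = 50. All randomness flows through
explicit seeds; reruns are bit-identical, which the pipeline test asserts
end to end (identical PNGs and `.sfm` across runs).

## Known limitations

* The registration model is scale + translation only, by design; a tilted
  or rotating camera would need a fuller similarity/affine model.
* The gradient edge detector is weaker than a trained structured forest on
  textured real-world backgrounds; the package's masking contract is
  defined on the dome-background regime the hardware guarantees.
* Pose priors are exactly as good as the rig model — they are starting
  points for bundle adjustment, not measurements.
* EXIF support covers the pipeline's six required fields in PNG; it is not
  a general metadata library.
* The Feltz–Miller implementation is the plain asymptotic test; at very
  small n its size can drift from nominal, which is why the calibration
  simulation is part of the acceptance checks.
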