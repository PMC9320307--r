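---
title: "Methods: semi-automatic PET/CT lesion labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-automatic PET/CT lesion labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petctlabel)
```

## Overview and assumptions

`petctlabel` turns one professional's click per lesion into a polygon and
bounding-box annotation on a CT slice, using the paired PET slice to find
the lesion extent. The pipeline assumes:

* slices are 2-D, single-frame, grayscale, with intensities on (or mapped
  to) the 8-bit range `[0, 255]`;
* uptake polarity is inverted: strong 18F-FDG absorption appears as *low*
  gray on the PET, so lesions are dark blobs;
* the PET-to-CT geometric discrepancy is well modeled by a planar affine
  transform (global scanner scaling plus the small shifts caused by
  breathing and cardiac motion between the two acquisitions);
* a human picks the click; the package never decides *which* dark region
  is pathological, only *where its boundary lies*. Physiologic high-uptake
  organs (liver, bone) are excluded by the professional, not by the code.

Coordinates everywhere are 0-based, `x` = column, `y` = row, origin at the
top-left pixel.

## Enlargement and gray enhancement

PET rasters (typically 128×128 or 168×168) are enlarged to the CT raster
with **align-corners bilinear interpolation**: output corner pixels
coincide with source corner pixels, and interior pixels interpolate the
four surrounding source pixels. Align-corners was chosen over the
half-pixel convention because it makes the two main contracts exact and
testable: enlarging an image to its own size is the identity, and constant
images are fixed points at every size. Interpolated values are clamped to
the source range so the enlargement can never overshoot.

The segmented gray transform

$$G = \begin{cases} 0 & F < \mathrm{PET}_{\min} \\
\frac{255}{255-\mathrm{PET}_{\min}}\,(F-\mathrm{PET}_{\min}) & F \ge \mathrm{PET}_{\min}\end{cases}$$

zeroes the sub-threshold range and stretches the rest onto `[0, 255]`. It
is monotone with `G(PETmin) = 0` and `G(255) = 255` exactly.
`PETmin = 255` would divide by zero and is rejected.

**`PETmin` default.** There is no principled universal threshold, so the
package exposes it as a config value with `"auto"` as default: the
nearest-rank 1st percentile of the image's intensity distribution. That
suppresses only the darkest 1% tail — on an inverted-uptake PET, the
strongest uptake — while keeping the transform parameter-free. Whether a
fixed or per-image threshold suits a given study is left to the user; the
pipeline accepts either. Note that on images whose lesions occupy less
than 1% of the pixels the auto rule can map lesion cores to 0, which
degenerates the region grower (a seed value of 0 grows nothing); for
high-contrast inputs such as phantoms, setting `pet_min = 0` (the identity
transform) is the appropriate choice.

Enhanced images stay floating point until export; quantization (round half
up) happens once, at PNG write time, to avoid double rounding through the
pipeline.

## Landmark affine registration

With landmark pairs $(x_i, y_i) \to (x'_i, y'_i)$, the fitted transform
minimizes $C = \sum_i r_{x,i}^2 + \sum_i r_{y,i}^2$ with
$r_{x,i} = a x_i + b y_i + h - x'_i$ and
$r_{y,i} = c x_i + d y_i + k - y'_i$. The two coordinate systems decouple
into three-parameter linear fits, solved in closed form with centered
sums ($S_{xx} = \sum x_i^2 - n\bar x^2$, etc.):

$$a = \frac{S_{xx'}S_{yy} - S_{yx'}S_{xy}}{S_{xx}S_{yy}-S_{xy}^2},\quad
b = \frac{S_{yx'}S_{xx} - S_{xx'}S_{xy}}{S_{xx}S_{yy}-S_{xy}^2},\quad
h = \bar x' - a\bar x - b\bar y,$$

and symmetrically for $c, d, k$ with $y'$ in place of $x'$. The package
also ships a normal-equation solver (`method = "normal"`) for the stacked
$2n \times 6$ design; the test suite checks both routes agree to below
1e-9 on random geometries, and that the fitted residuals satisfy the
normal-equation identities $\sum r_x = \sum r_y = 0$ and zero
cross-moments with $x$ and $y$.

**Minimum landmark count.** Six parameters need at least three
non-collinear pairs for a unique solution, so `control_points()` enforces
`n >= 3` and non-collinearity (second singular value of the centered
source cloud above `1e-9` relative tolerance). In practice 4–5 landmarks
are used.

**Pre-alignment.** `frame_prealign()` supplies a coarse, landmark-free
axis-aligned scale-and-shift that maps the PET foreground bounding box
onto the CT one. Foreground is defined parameter-free as pixels differing
from the modal border intensity (the field-of-view frame). In the full
pipeline the landmark fit runs *in pre-aligned coordinates* and the final
transform is the composition (landmark fit ∘ pre-alignment): the coarse
step absorbs the gross scale difference, the landmarks correct the
residual. A degenerate one-pixel-wide foreground box falls back to a pure
shift; an empty foreground raises a geometry error.

**Resampling.** `apply_affine()` warps pull-based: each output pixel is
bilinearly sampled at its inverse-mapped input location, with 0 fill
outside the raster. The linear part must have `|det| >= 1e-12`.

## Wavelet fusion

Fusion runs in the 2-D discrete wavelet domain with the sym8 orthogonal
filter bank (16 taps, support width 15, near-symmetric, vanishing moments
8); the standard published filter coefficients are embedded as constants.
No pre-installed R package provides a 2-D DWT, so the transform is
implemented in the package: separable row/column convolution with
boundary extension, downsampling by 2 keeping
`floor((n + L - 1)/2)` coefficients per subband. That slightly expansive
convention makes the transform perfectly invertible under *every*
extension mode; the synthesis side upsamples, convolves with the
time-reversed filters and trims `L - 2` samples per side. Round-trip
error on 8-bit-scaled images is ~1e-10 (relative ~4e-13), against a
contract of 1e-8.

Numerical detail: the high-pass filter is the quadrature mirror of the
printed low-pass taps, whose sum is only zero to ~1e-12 at double
precision; the residual mean is removed from the high-pass so that the
zeroth vanishing moment (constant images produce exactly zero detail
coefficients) holds to ~1e-14 rather than ~1e-10.

Choices left open by the problem statement, decided here:

* **Decomposition depth**: default 3 levels, the customary depth for
  512×512 rasters — deep enough that the approximation band carries organ-
  scale structure, shallow enough to stay cheap and well-conditioned.
  Configurable; infeasible depths (`2^levels > min(width, height)`) are
  rejected.
* **Extension mode**: symmetric by default (no artificial edge
  discontinuity, hence no ring at the frame); periodic and zero are
  available.
* **Weights apply to every band** (approximation and details alike), the
  simplest reading of proportional synthesis: fusion is then exactly
  linear, which yields the testable identities — weights 100:0 return the
  PET, fusing an image with itself is the identity, and fusing constants
  `p` and `c` at 40:60 gives exactly `0.4p + 0.6c`.
* **Soft threshold**: the optional shrinkage
  `sign(x)·max(|x| − t, 0)` on detail coefficients is off by default
  (`t = 0`), since it trades edge energy for noise suppression and the
  right `t` is data-dependent.
* **Pseudocolor** is a fixed 256-entry piecewise-linear ramp
  black→blue→cyan→green→yellow→red→white, applied to the *fused* output
  for display only; segmentation never reads RGB.

## Click-seeded region growing

`refine_seed()` searches the `±8` pixel window around the click (clipped
at image borders) for the minimum gray value; ties break to the first
occurrence in row-major order (top-to-bottom, then left-to-right), a
deterministic convention that makes flat windows reproducible.

`region_grow()` performs stack-based 8-neighborhood growth from the
refined seed. A pixel joins iff

* `gray < ValueMin · (1 + threshold_increase)` — strictly, with the
  default increase of 100% this is `gray < 2·ValueMin`; and
* its Chebyshev distance from the seed is at most `max_radius`
  (default 10).

The stop rule "10 pixels up, down, left and right" is read as a hard
Chebyshev-radius cap around the refined seed: it is the only reading that
terminates deterministically regardless of image content. Real lesions can
exceed 10 pixels at CT resolution, so the cap is a config value. The
strict `<` is kept exactly as specified; in particular `ValueMin = 0`
yields a single-pixel region rather than an error. The implementation is
verified against an independent brute-force flood-fill oracle (iterated
masked dilation) with exact set equality on random images.

The click is taken on the fused display, but intensities are read from the
registered enhanced PET — the modality that actually carries the uptake
signal.

`trace_boundary()` walks the Moore contour clockwise from the
topmost-then-leftmost member; every vertex is a member pixel with an
edge-adjacent non-member (the classical contour characterization — pixels
exposed only diagonally lie inside the walked contour). Thin one-pixel
parts are traversed in both directions, as in any contour walk.
`bounding_rect()` is the tight min/max rectangle of the member set.
`map_region_to_ct()` transfers coordinates to the CT: the identity after
in-pipeline resampling, otherwise an affine map with round-half-up
snapping and recomputed polygon/box.

SUV is computed as `concentration / (dose / weight)` — the conventional
grouping of the concentration-dose-weight chain, i.e. concentration per
injected dose per kilogram — and classified malignant (`> 2.5`), critical
(`2.0–2.5`, both ends inclusive), or benign (`< 2.0`).

## The phantom: what it emulates, and what it does not

`phantom_spec()` / `make_phantom_pair()` generate the study conditions
synthetically: a 512×512 CT (dark air at gray 20, an elliptical body at
120, lesions 40 levels brighter) and a 168×168 PET (air white at 255, body
at high gray 200, lesions as low-gray disks, default 60) related by a
known affine misalignment, plus exact per-lesion disk masks in CT
coordinates and five landmark pairs at the body-ellipse extrema and
center. The PET pixel at `(x, y)` samples the continuous scene at
`misalign(S(x, y))`, `S` being the align-corners PET→CT scale, so the
phantom is exactly what a scanner misaligned by `spec$misalign` would
record, and fitting the emitted landmarks recovers the misalignment to
machine precision. Gaussian noise (default sigma 2 gray levels, truncated
to `[0, 255]`) is optional; generation is fully deterministic given
`rng_seed`. Lesion intensity must stay below half the body uptake value so
the doubled-threshold criterion can separate lesion from body, and lesions
must fit inside the body ellipse with radius at least 2.

The phantom emulates geometry and contrast, not physics: no sinogram
reconstruction, attenuation, partial-volume effect, scanner noise
texture, or anatomical heterogeneity. Passing tests on the phantom
therefore demonstrate the *geometric and numerical* correctness of the
pipeline, not clinical segmentation accuracy on patient scans.

**Exact end-to-end recovery needs grid-aligned conditions.** Sub-pixel
resampling necessarily mixes intensities at the lesion rim, and rim pixels
then fall on the wrong side of the strict growth criterion — on the
default 168×168 phantom the grown region recovers ~82% of the truth mask
(see the README example). The end-to-end exactness check therefore uses a
same-resolution phantom (PET grid = CT grid) with a whole-pixel
translation misalignment and `pet_min = 0`: under those conditions every
resampled value is exact, and the pipeline must — and does — recover the
truth mask at 100% recognition with 0% false positives, with the
misalignment itself recovered to below 1e-6 per parameter. This is a
design choice about what "exact" can mean under interpolation, not a
tuning of the generator: the low-resolution default still exercises
enlargement, registration recovery and fusion everywhere else.

## Problem sizes and runtime

The test and acceptance workloads were sized for a desk-scale run as the
package's own convention: 100 random landmark sets for the registration
equivalences, 100 random 64×64 images for the region-growing oracle,
64×64 rasters for the wavelet identities, and one 512×512 phantom pair
for the end-to-end check. The full suite runs in well under a minute on a
single core.

## Known limitations

* Slice-wise only: no 3-D volumes, DICOM-RT, or NIfTI.
* DICOM support is a minimal single-frame uncompressed reader
  (explicit/implicit VR little endian) with min–max windowing — written
  in-package because no pre-installed R DICOM reader was available;
  scanner windowing metadata (window center/width, rescale slope) is not
  interpreted.
* Registration is landmark-only; no intensity-based (mutual-information)
  or deformable registration.
* Region growing is intensity-thresholded; necrotic (bright-core) lesions
  or lesions touching other high-uptake structures will be under- or
  over-grown and need a corrected click or adjusted `max_radius`.
* The pseudocolor ramp is a display convention, not a calibrated
  perceptual map.
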