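---
title: "Cone-marker fusion of microCT volumes and histological sections: methods"
author: "coneFuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cone-marker fusion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coneFuse)
```

## The localization problem and the cone-marker idea

A stained histological section is a 2D image cut out of a resin-embedded
block; a microCT scan of the same block is a 3D volume. Fusing the two
requires knowing *where* inside the volume the physical cutting plane lies —
a 2D-in-3D search that is expensive and ambiguous if attempted by image
content alone. Truncated-cone fiducial markers solve it geometrically. A cone
standing upright in the block (axis along the stack/z axis) has a circular
cross-section whose diameter shrinks *linearly* with height:

$$ w(h) = d_{base} - (d_{base} - d_{apex})\,\frac{h}{H} , $$

with defaults $H = 11$ mm, $d_{base} = 3$ mm, $d_{apex} = 0.5$ mm, i.e.
0.2273 mm of width per mm of height. A section that cuts the block therefore
carries, in the diameter of each cone's elliptical footprint, a direct
reading of the height at which it was cut. Three cones give three
(x, y, z) points, which determine the cutting plane completely — including
its in-plane orientation and scale, since the three 2D-3D correspondences
define a full affine embedding, not merely a point and normal.

The markers are 3D-printed from UV-curable resin mixed with an iodine-based
contrast agent so they are conspicuous in both modalities. The mixture is
planned with a linear attenuation model: a target CT number $CT_{goal}$
between the attenuation of pure resin and pure contrast agent requires the
mixing fraction

$$ k = \frac{CT_{goal} - CT_{resin}}{CT_{CA} - CT_{resin}} , $$

implemented by `mixingCoefficient()` with `predictedCT()` as its exact
inverse. Targets outside the two pure-component values are physically
unreachable; the function warns and reports the achievable range rather than
failing, since the caller may be exploring.

## Pipeline overview

`runPipeline()` chains six stages; each is exposed individually:

1. **detect** — sample slices, find conic cross-sections
   (`detectConeSections()`).
2. **calibrate** — cluster detections per cone and fit each cone's
   width-height taper (`calibrateCones()`).
3. **locate-markers** — find and match the marker ellipses in the section
   image (`detectSectionEllipses()`, `matchToCones()`).
4. **extract-plane** — convert widths to heights, embed the plane, resample
   the oblique in-silico slice (`locateConePoints()`, `buildEmbedding()`,
   `extractObliqueSlice()`).
5. **register** — rigid MSE alignment of section to plane
   (`rigidRegister()`).
6. **score** — absolute-value local normalized cross-correlation with
   heatmap and layer sweep (`lncc()`, `lnccLayerSweep()`).

## Detection: rule-based chain plus promptable-mask refinement

Slice-wise detection follows the classical chain: adaptive thresholding,
Canny edge detection, morphological opening and closing, contour extraction,
and a direct least-squares conic fit (the Halir-Flusser formulation) per
contour, filtered by area and eccentricity. Where Canny edge pixels trace a
component's rim they replace the raw contour points, so the fit uses
gradient-localized boundaries. All thresholds are relative to the image's
dynamic range, making the output invariant under affine intensity rescaling.

No published values exist for the chain's tunables, so the defaults are
engineering choices, all exposed via `detectionParams()`:

| parameter          | default | rationale |
|--------------------|---------|-----------|
| `blockSize`        | 51 px   | larger than marker texture, smaller than illumination scale |
| `offset`           | 2% of range | keeps flat background below threshold under mild noise |
| `cannyLow/High`    | 0.1 / 0.3 of max gradient | conventional 1:3 hysteresis ratio |
| `morphRadius`      | 2 px    | removes speckle without eroding small apex sections |
| `maxEccentricity`  | 0.9     | admits obliquely cut cones, rejects elongated tissue |
| `areaBounds`       | from cone geometry | 0.5x apex disc to 2x base disc when `pixelSize` is known |

The rule-based chain alone loses cross-sections wherever a marker touches
tissue of intermediate intensity (the thresholded components merge). This is
expected, not pathological: a detection rate well below 100% for the pure
rule-based chain on real data motivates the second pass. The refinement uses
a *promptable-mask* backend: per-cone point prompts (the median center of
each detection cluster — medians, because merged-contour false positives
drag means) are handed to a segmentation backend which returns one mask per
prompt, and each mask is re-measured by its second-moment ellipse
(`maskToEllipse()`). The bundled backend (`thresholdBackend()`) is a seeded
region grow: pixels within 20% of the dynamic range of the prompt's
intensity, lightly opened, connected component containing the prompt. Masks
covering more than a quarter of the image are treated as background hits and
dropped. Any neural promptable segmenter (e.g. a SAM-family model) can be
plugged in as a plain function with the same contract; nothing in the
package requires one, and all tests run with the built-in backend.

## Taper calibration: two-pass robust regression

Detections are clustered on their centers by k-centroid with farthest-point
seeding (deterministic; `clusterDetections()`), then filtered by distance to
the cluster's median center (default threshold: three base radii) and by
physically possible widths. `fitTaper()` regresses width in mm on slice
index by ordinary least squares, flags points whose absolute residual
exceeds 3x the MAD of the pass-1 residuals (a fixed-mm override is
available), and refits on the survivors. The regression is deliberately on
*slice index* rather than mm height, because the downstream lookup needs a
(continuous, sub-slice) z index; the unit conversion lives in the model. The
same inlier set also yields a per-axis linear drift model of the center
versus slice index, which interpolates marker positions across unsampled
layers and absorbs small deviations of the cone axis from vertical.

Sampling a subset of slices (the `nSample` argument, with a seeded,
reproducible draw) rather than the full stack is part of the method: the
taper model interpolates the unsampled layers.

## Section analysis and matching

The section image passes through the same detection chain after polarity
normalization: stained sections typically show the resin markers *dark* on a
bright background while CT shows them bright, so with `polarity = "auto"`
both polarities are tried and the one yielding more valid candidates wins.
The refinement pass additionally scans the top quarter of the intensity
range for compact components — by construction of the radiopacity planning,
markers are the intensity extreme in both modalities — so markers lost by
the threshold chain to adjacent tissue are still prompted and measured.

Matching ellipses to cones uses only the *relative layout*: both point sets
are translated to their centroid and scaled to unit RMS radius, then all
cone-to-ellipse injections are enumerated (exhaustive; intended for three
cones) and the minimum total squared distance wins. The assignment is
invariant to global translation and isotropic scaling of the section. Two
(near-)tied assignments — e.g. a symmetric layout under 180° rotation —
raise an error rather than guessing; asymmetric cone placement is the
practical fix and the recommended design.

The width entering the height lookup is the **major** axis of the section
ellipse: an oblique cut through an upright cone lengthens only the major
axis, so the major axis is the less biased width proxy for the CT
comparison. (At tilts up to 5° this bias is below half a voxel for the
default geometry.)

## Plane embedding and oblique extraction

`buildEmbedding()` solves the unique affine map $A(u,v) = o + u\,b_u +
v\,b_v$ with $A(p_i) = P_i$ for the three correspondences; collinear inputs
are rejected. The embedded plane carries its own in-plane frame and scale,
so the extracted slice is already approximately aligned with the section —
the rigid registration only refines.

Coordinate convention, used everywhere: arrays are `[z, y, x]`, voxel
centers sit at integer 0-based coordinates, physical mm = index x voxel
size. `extractObliqueSlice()` samples the volume by trilinear interpolation
at each output pixel. Two numerical details: trilinear interpolation is
exact for globally trilinear fields (tested to machine precision), and
coordinates within 1e-9 voxel of a lattice point are snapped so that an
axis-aligned plane at an integer slice reproduces that slice bit-exactly
despite mm-to-voxel unit round trips. Samples outside the volume take a
fill value (default 0), so planes that leave the scanned extent degrade
gracefully instead of failing.

## Rigid registration

`rigidRegister()` minimizes the mean squared intensity difference over the
overlap (optionally restricted to a tissue mask), with a deterministic
optimizer: three resolution levels (block-mean downsampling by 4, 2, 1),
exhaustive rotation-translation grids refined level by level, then
Nelder-Mead at full resolution with one restart. Scale is carried from the
initial transform but not optimized — pixel sizes are known, not estimated.
Two intensity decisions matter:

* Both images are lightly Gaussian-prefiltered (sigma 0.8 px) before the
  metric. Sub-pixel resampling smooths the moving image, which under noise
  systematically lowers MSE away from the true optimum; prefiltering both
  images equalizes that advantage. Without it, the recovered rotation on
  noisy self-registration tests is biased by several tenths of a degree.
* `polarity = "auto"` registers the moving image and its intensity inversion
  and keeps the lower MSE, because histology and CT render the same
  structures with opposite contrast and raw MSE would otherwise be *maximal*
  at true alignment.

## The alignment score

The score is a local normalized cross-correlation in which each window's NCC
enters as its absolute value,

$$ \mathrm{LNCC}(I,J) = \frac{1}{|N_W|}\sum_{k \in N_W}
   \left|\,\mathrm{NCC}_{W_k}(I, J)\,\right| , $$

so locally contrast-inverted but structurally matching regions score high
instead of cancelling. The default window is 45 x 45 px. Conventions chosen
and documented here:

* The heatmap contains one value per *fully interior* window, so its
  dimensions are `dim(input) - window + 1` — the standard valid-window
  count (one more than "reduced by the window size" would give).
* Windows where either image has zero variance have undefined NCC and
  contribute 0. The zero-variance guard is relative (1e-12 of the window's
  energy), so numerically constant windows do not produce spurious scores.
* The implementation uses integral images; it is algebraically identical to
  the literal per-window double loop, and the test suite holds the two
  routes to within 1e-6 (observed agreement is at machine precision).

`lnccLayerSweep()` implements the validation logic: scoring a section
against every flat z layer must peak at the true layer for a flat cut, and
the extracted oblique plane must beat every flat layer for a tilted cut.

## The phantom generator: what it emulates, what it does not

`generatePhantomVolume()` replaces the physical chain (printing, embedding,
scanning) with a synthetic volume carrying analytic ground truth: uniform
embedding background (default 0.25), upright cones of the default geometry
painted voxel-center-exactly with attenuation 0.75, an optional linear
intensity gradient inside the marker emulating contrast-agent sedimentation
(default 0, as a printed marker is nominally uniform), a tissue blob —
a band-limited random field (trilinear upsampling of a small uniform
lattice), thresholded inside an ellipsoidal region, with intensities capped
below the marker half-contrast — and additive Gaussian noise. The default
study conditions used throughout the tests are a 256^3 grid of 0.05 mm
voxels (a desk-scale stand-in for micrometer-scale synchrotron scans, where
the taper spans ~220 slices) with noise at 5% of the marker-medium contrast;
smaller unit-test phantoms use 128^2 x 120 at 0.1 mm. `sampleSectionImage()`
renders the matching "histology": marker footprints drawn from the *exact*
conic section of each truncated cone by the cutting plane, the identical
tissue field re-rendered with histology-like (inverted, re-mapped) contrast,
plus stain noise.

What the phantom does **not** emulate — and hence what passing tests do not
certify on real data: X-ray physics (beam hardening, phase contrast, phase
retrieval), reconstruction and stitching artifacts, partial-volume blur at
marker boundaries, printing defects and sectioning damage to the markers,
stain variability, tissue deformation between scanning and sectioning (the
pipeline is rigid; elastic refinement is delegated to external tools, with
the embedding and rigid result exported as the initial guess), and tilted
cone axes (the drift model absorbs only small tilts). Real deployments
should expect to re-tune `detectionParams()`; the phantom defaults
demonstrate the mechanics, not universal parameter values.

## Degenerate inputs and tie-breaks

Collinear correspondences, empty overlap at the registration start, windows
larger than the image, all-outlier tracks, ambiguous matchings and planes
that miss a cone raise errors naming the offending object. Ties in the layer
sweep resolve to the first (lowest) layer; overlapping detections resolve to
the larger-area fit; the pass-1 residual threshold falls back to "keep
everything" when the MAD is zero (exact fits).

## Problem sizes used by the automated checks

The test suite and the acceptance script generate all inputs at run time:
the 256^3 / 0.05 mm phantom above for calibration, plane recovery, layer
sweep, registration and detection-rate checks; 64-128 px random images for
the LNCC oracle comparisons; 1000 random triples for the mixture round trip.
On one CPU the full suite runs in a few minutes.
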