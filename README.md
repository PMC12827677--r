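# coneFuse

Fusion of 2D histological sections with 3D microCT volumes using 3D-printed
truncated-cone fiducial markers.

## The problem and who this is for

Histology gives high-specificity 2D images of a sectioned specimen; microCT
of the same resin-embedded block gives 3D context but different contrast.
Fusing them requires localizing each 2D section inside the 3D volume — an
ill-posed search if attempted from image content alone. This package is for
imaging scientists who embed radiopaque cone markers next to their specimen:
the cones turn slice localization into geometry. Because a truncated cone's
cross-section width falls linearly with height,

```
w(h) = d_base − (d_base − d_apex) · h / H        (default 3 mm → 0.5 mm over 11 mm)
```

the diameter of each cone's elliptical footprint in a section encodes the
height at which the block was cut. Three cones give three (x, y, z) points,
which determine the cutting plane — position, orientation, in-plane frame
and scale — as a full affine embedding.

The package implements the complete chain:

* **Radiopacity planning** — the mixing fraction
  `k = (CT_goal − CT_resin)/(CT_CA − CT_resin)` for resin/contrast-agent
  mixtures (`mixingCoefficient()`, `predictedCT()`).
* **Detection** — slice-wise conic-section detection: adaptive threshold,
  Canny edges, morphology, direct least-squares ellipse fits, plus a
  pluggable promptable-mask backend for refinement (`detectConeSections()`).
* **Calibration** — per-cone two-pass robust regression of width vs slice
  index with center-drift interpolation across unsampled layers
  (`calibrateCones()`, `fitTaper()`, `widthToHeight()`).
* **Section matching** — marker extraction from the stained section and
  layout-based assignment to cones (`detectSectionEllipses()`,
  `matchToCones()`).
* **Plane extraction** — three-point affine embedding and trilinear oblique
  resampling of the in-silico plane (`buildEmbedding()`,
  `extractObliqueSlice()`).
* **Registration & scoring** — rigid MSE registration and an
  absolute-value local normalized cross-correlation,
  `LNCC(I,J) = mean_k | NCC over window W_k |`, robust to local contrast
  inversion between modalities, with heatmaps and layer-sweep validation
  (`rigidRegister()`, `lncc()`, `lnccLayerSweep()`).
* **Phantom generation** — synthetic marker volumes and sections with
  analytic ground truth, so the whole pipeline is testable without data
  downloads (`generatePhantomVolume()`, `sampleSectionImage()`).

See `vignettes/cone-marker-fusion.Rmd` for the methods account.

## Worked example

Generate a phantom block (three cones, 12.8 mm cube, 0.05 mm voxels, 5%
noise), calibrate the tapers, cut a tilted synthetic section, and recover
the cutting plane:

```r
library(coneFuse)
cones <- list(coneSpec(c(3.4, 3.4)), coneSpec(c(9.4, 3.8)), coneSpec(c(6.2, 9.6)))
ph <- generatePhantomVolume(cones, shape = c(256, 256, 256),
                            voxelSize = 0.05, noiseSigma = 0.025, seed = 42)
ph$volume
#> VoxelVolume: 256 x 256 x 256 voxels [z, y, x], 0.05 mm/voxel (12.8 x 12.8 x 12.8 mm)
#>   intensity range: [0.1206, 0.8776]

dets <- detectConeSections(ph$volume, nSample = 100, seed = 7,
                           params = detectionParams(pixelSize = 0.05))
calib <- calibrateCones(dets, pixelSize = 0.05)
calib$models[[1]]
#> TaperModel (cone 1): width = 3.00153 -0.0113578 * slice  [mm], 88 inliers, residual cut 0.0173 mm
```

The recovered slope, −0.01136 mm of width per slice, is the analytic taper
(3 − 0.5)/11 mm per mm times the 0.05 mm voxel size, recovered here to 0.05%.
Now the section — cut 5.5 mm up, tilted 3° about x — and the plane recovery:

```r
th <- 3 * pi / 180
plane <- planeFromNormal(c(0, 0, 5.5), c(0, sin(th), cos(th)))
sec <- sampleSectionImage(ph$truth, plane, pixelSize = 0.05, seed = 5)

det <- detectSectionEllipses(sec$image, detectionParams(pixelSize = 0.05))
layout <- do.call(rbind, lapply(calib$tracks, meanCenter))
rownames(layout) <- vapply(calib$tracks, coneId, integer(1))
mk <- matchToCones(det, layout, pixelSize = 0.05)
pts <- locateConePoints(mk, calib$models, 0.05)
round(pts, 3)
#>     x   y     z
#> 1 3.4 3.4 5.276
#> 2 6.2 9.6 4.987
#> 3 9.4 3.8 5.270
```

Each cone's measured footprint width has been turned into a cutting height:
the cone at y = 9.6 mm is cut lower (z ≈ 4.99 mm) than the two near
y ≈ 3.5 mm (z ≈ 5.27 mm) — the 3° tilt, read straight off the marker
geometry, with every height within one voxel of truth.

```r
emb <- buildEmbedding(cbind(mk@ellipses$cx[mk@assignment],
                            mk@ellipses$cy[mk@assignment]) * 0.05, pts)
normalAngle(emb@normal, plane@normal)
#> [1] 0.304          # degrees between recovered and true plane normal

insilico <- extractObliqueSlice(ph$volume, emb)
reg <- rigidRegister(sec$image, insilico)
reg$transform
#> RigidTransform2D: rotation 0 deg, translation (0, 0) px, scale 1
res <- reg$resampled; res[is.na(res)] <- 0
lncc(imageData(insilico) / max(imageData(insilico)), res, window = 45)
#> LNCCResult: window 45 px, heatmap 212 x 212, mean 0.5311, max 0.9933
```

The embedding alone already aligns the extracted in-silico plane with the
section (the rigid refinement is the identity), and the absolute-value LNCC
over 45 px windows scores the fusion at 0.53 mean / 0.99 max — against ~0.02
for unrelated noise images.

A command-line front end over the same functions ships in
`inst/cli/conefuse.R` (`simulate`, `mix`, `detect`, `calibrate`,
`locate-markers`, `extract-plane`, `register`, `score`, `run`), and
`runPipeline()` executes the whole chain from a YAML config with all
intermediates written as plain TIFF/CSV/JSON.

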