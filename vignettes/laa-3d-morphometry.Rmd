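---
title: "Surface-based morphological and functional assessment of the left atrial appendage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based morphological and functional assessment of the left atrial appendage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laa3d)
```

## The problem

The left atrial appendage (LAA) is the principal site of thrombus formation
in atrial fibrillation. Both its *function* — how strongly it contracts over
the cardiac cycle — and its *morphology* — the area of the ostium that a
closure device must seal — matter for risk stratification and preprocedural
planning. The clinical standard extracts these quantities by manually
tracing the appendage contour on stacks of 2D slices and summing slabs
(Simpson's method), which is slow and operator-dependent. `laa3d` implements
a surface-based 3D alternative: the contrast-enhanced blood pool is
segmented once per phase, a triangle surface is extracted, the appendage is
cut off at a landmark-defined ostium plane, and volume and ostium area are
read directly off the resulting closed 3D model, phase by phase.

## The processing model

Each phase of a multi-phase CT acquisition passes through the same chain:

1. **Threshold segmentation.** An automatic initial threshold is computed by
   Otsu's between-class-variance criterion on a 256-bin intensity histogram;
   this models the "automatically defined" starting point of an interactive
   workflow, and a manual override is accepted wherever the threshold is
   used. Comparison is inclusive (`intensity >= threshold`). The connected
   component (26-neighbourhood) containing a seed point isolates the left
   atrium from other enhancing structures. Trabeculations are not
   subdivided: whatever the threshold captures is blood pool.
2. **Surface extraction.** The binary mask is padded by one background voxel
   and contoured at iso-level 0.5. We use the tetrahedral-decomposition
   variant of marching cubes (each grid cube is split into the six Kuhn
   simplices around its main diagonal). This variant needs no case tables,
   its cube decomposition is face-consistent between neighbours, and the
   result is guaranteed watertight and consistently oriented — properties
   everything downstream depends on. On a digitized 15 mm sphere at
   0.419 x 0.419 x 1 mm the extracted surface volume is within 0.01% of the
   analytic value; the smallest admissible input, a single voxel, yields the
   known discretization-dominated result of half a voxel volume.
   Laplacian smoothing is available but off by default, because smoothing
   biases volume; when enabled the induced volume change is recorded on the
   output.
3. **Appendage crop.** The manual freehand crop of the clinical tool is
   replaced by a reproducible plane cut: triangles crossing the plane are
   split exactly along it and the connected open submesh nearest a keep-side
   seed is retained. The crop plane is deliberately *not* the ostium plane —
   by default it sits `crop_margin_mm` (3 mm) proximal to it, so the ostium
   measurement is independent of the preliminary crop, mirroring the
   two-stage crop-then-cut workflow.
4. **Ostium definition and measurement.** At least three `ostium_cut`
   landmarks define the cutting plane (exact through three points,
   total-least-squares via SVD beyond that). The plane-mesh intersection is
   chained into closed loops; the loop with the largest enclosed area is the
   ostium by default, with an anchor override for unusual anatomies. The
   ostium area is the shoelace area of the loop in the plane's 2D frame.
5. **Closure and volumetry.** The open appendage surface is capped across
   the ostium contour: a triangle fan from the planar centroid when the
   contour is star-shaped about it, otherwise ear clipping. The closed model
   is voxelized at the source CT spacing — a voxel centre is inside when a
   +z ray crosses the surface an odd number of times — and the volume is the
   inside count times the voxel size. The divergence-theorem mesh volume is
   carried alongside as an independent cross-check; the two definitions
   agree within 2% on every phantom we test.
6. **Function.** Per-phase volumes form the volume-time curve; the diastolic
   and systolic phases are its maximum and minimum (first occurrence on
   ties) and the ejection fraction is `(Vmax - Vmin) / Vmax`. Ostium area
   and volume can be normalized by body surface area (Mosteller,
   `sqrt(height_cm * weight_kg / 3600)`).

The slice-stack reference method is also provided (`simpson_volume`): the
sum of traced contour areas times the slice thickness, the quantity the 3D
measurements are validated against in practice.

## Numerical choices

* **Units.** All geometry is world millimetres; areas and volumes are
  converted to cm^2 / cm^3 only in reported results. STL files carry no
  units and are read and written as millimetres.
* **Coordinates.** Voxel `(i, j, k)` (1-based) has its centre at
  `origin + (c(i, j, k) - 1) * spacing`. DICOM series must be axis-aligned;
  anything else is rejected rather than resampled.
* **On-plane robustness.** Signed distances within `1e-9 * scale` of a
  cutting plane are pushed to the positive side deterministically before
  classification. Crop and intersection therefore make identical decisions
  and produce bit-identical boundary points, which is what lets
  `close_surface` verify boundary/contour coincidence at 1e-6 mm.
* **Grazing rays.** Voxelization columns whose ray passes within a
  barycentric tolerance of a triangle edge are retried with a fixed jitter
  schedule (six deterministic offsets), so results are reproducible and
  independent of triangle order.
* **Canonical STL.** Vertices are quantized to 32-bit floats *before* facet
  normals are computed from them, making write-read-write a byte-identical
  fixed point in both the binary and ASCII dialects. Vertices are merged on
  read by exact coordinate match.
* **Sliver triangles.** Splitting triangles along a cutting plane, and
  capping boundaries with numerically collinear runs, can create triangles
  whose area underflows to exactly zero. These slivers are harmless (zero
  area and volume contribution, edge parity preserved) and are tolerated in
  internally constructed meshes; ear clipping defers them unless the
  polygon forces one, and user-supplied meshes are still validated
  strictly.
* **Degenerate inputs.** Empty masks, empty meshes, non-watertight models,
  collinear landmarks, constant volumes, and sub-resolution voxelization
  (fewer than 10 interior voxels, which warns but returns) all have defined
  behaviour covered by tests.

## The phantom and what it does (not) show

The study data this kind of method is validated on clinically are patient
CTs that cannot be redistributed, so the package ships a fully synthetic
stand-in with analytic ground truth. The phantom is a static left-atrial
sphere (radius 22 mm) joined through a cylindrical neck (radius 11 mm) to a
lobed ellipsoid appendage (semiaxes 20 x 13 x 11 mm, three cosine lobes of
1.5 mm), rendered at 0.419 x 0.419 x 1 mm over 10 phases — the native
resolution and phase count of retrospectively gated cardiac CT — with blood
intensity 300 over background 0 and Gaussian noise (sd 15). These sizes were
chosen once so the phantom's diastolic ostium area (~3.8 cm^2) and appendage
volume (~10 cm^3) fall in the range reported for appendage-closure
candidates.

Per phase the appendage (only) is scaled about a fixed point on the ostium
plane by the profile `s(t) = (1, 0.98, 0.93, 0.89, 0.87, 0.89, 0.93, 0.96,
0.99, 1)`. Because central scaling about a point in the plane maps the plane
to itself, the true appendage volume is exactly `s(t)^3` times the base
volume and the true ostium area exactly `s(t)^2` times the base disc, with
true ejection fraction `1 - 0.87^3 = 0.3415`. The base volume has no closed
form once lobes are on, so it is integrated once on an indicator grid
oversampled 10-fold per axis relative to the rendering spacing — an oracle
that shares only the solid's definition with the pipeline, none of its
segmentation or geometry code.

Running the full pipeline on the default phantom recovers the prescribed
ejection fraction within 0.002 absolute and every per-phase volume within
1% of truth (the acceptance script recomputes both). What this shows is
that the geometry chain — threshold, surface, crop, cut, cap, voxelize — is
essentially unbiased at CT resolution on a smooth, high-contrast, rigidly
scaled target. What it does not show: performance under realistic LAA
morphology variants (chicken-wing and similar), contrast inhomogeneity,
motion artefact, or neighbouring structures touching the appendage; real
interobserver variability in landmark placement (the acceptance script
emulates it with 0.5 mm landmark jitter, which is optimistic); and any
claim about patient populations.

## Statistical conventions

Reproducibility tables in this literature pair a coefficient of variation
with Bland-Altman bias and confidence limits. Two conventions had to be
fixed here because they are rarely written out:

* **CoV** is the within-subject (root-mean-square) two-rater form,
  `100 * sqrt(mean(d^2 / 2)) / grand mean` — the standard reproducibility
  CoV for paired raters. The output carries a `definition` column so the
  convention travels with the number.
* **The interval** around the bias is reported as the 95% limits of
  agreement, `bias +/- 1.96 * SD(d)` with the sample SD, rendered in the
  open-interval style `]lower; upper[`.

The paired t-test is the closed form `mean(d) / (SD(d) / sqrt(n))` with
`n - 1` degrees of freedom; the all-differences-zero case is defined as
`t = 0, p = 1`. The test suite cross-checks it against `stats::t.test` and
a numerically integrated t-distribution tail.

## Problem sizes used in validation

The shipped tests exercise the pipeline end-to-end on a phantom rendered at
1 x 1 x 1.5 mm (about 0.2M voxels per phase) and the acceptance script on
the full-resolution default (about 1.4M voxels per phase, 10 phases);
analytic-solid checks use a 15 mm sphere digitized at CT spacing and
icospheres at subdivision 3-4. These sizes were chosen as the smallest at
which discretization effects are representative of the full-resolution
setting.

## Known limitations

* The crop and the ostium cut are single planes; strongly curved ostia or
  appendages that fold back across the cut plane would need the anchor
  override, or would produce multiple boundary loops and a clean error
  rather than a silent mis-measurement.
* DICOM support is deliberately minimal: uncompressed, single-frame,
  little-endian, axis-aligned series. NIfTI is the recommended interchange
  format.
* The voxelization grid is aligned to the model's bounding box, not to the
  source CT grid: only the voxel *size* matches the CT. Volumes are
  grid-placement dependent at the sub-voxel level, which is well below the
  method's other error sources.
* `mesh_volume` verifies watertightness but trusts the input's orientation
  consistency; meshes produced by this package are consistently oriented by
  construction.
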