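---
title: "Quantifying ligament insertion footprints from 3D label volumes"
author: "footprintr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ligament insertion footprints from 3D label volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footprintr)
```

## The measurement problem

The distal radioulnar ligaments (DRULs) of the triangular fibrocartilage
complex (TFCC) insert on the ulna in two bundles: a deep bundle anchored in
the fovea at the base of the ulnar styloid and a superficial bundle on the
styloid itself. The size and shape of these insertion *footprints* --
their area, dorsal--volar (DV) and radial--ulnar (RU) maximal lengths, and
their visual class (irregular quadrilateral, ribbon, or semilunar) -- bear
directly on anatomical repair of the distal radioulnar joint.

`footprintr` measures these quantities from multi-label 3D segmentation
volumes (radius = 1, ulna = 2, TFCC = 3, at millimetre voxel spacing, as a
segmentation network or manual rater would produce). Because no public
reference segmentations exist for this joint, the package also ships a
synthetic phantom generator whose footprint geometry is known in closed
form, so every stage of the measurement chain can be validated against
analytic ground truth.

## The extraction chain

`extract_footprint()` composes five stages, each exposed as its own
function:

1. **Label smoothing** (`smooth_labels`). Each label's indicator is
   convolved with an isotropic Gaussian (`smoothing_sigma`, default 1
   voxel) and voxels are reassigned by argmax, ties going to the lower
   label code. This removes speckle without inventing labels; `sigma = 0`
   is the identity.
2. **Boundary delineation** (`boundary_voxels`). The 3D Sobel gradient
   magnitude of each structure's indicator (components scaled by
   1/spacing) is normalised to [0, 1] and thresholded at a fraction of its
   maximum (`sobel_threshold`, default 0.1); boundary voxels are the mask
   voxels passing the threshold. Isolated single voxels, whose central
   gradient vanishes by symmetry, are flagged explicitly.
3. **Overlap detection** (`candidate_overlap`). Both boundaries are
   dilated by an ellipsoidal ball of physical radius `dilation_radius_mm`
   (default 0.3 mm; per-axis voxel radii, so anisotropic grids get
   anisotropic structuring elements) and intersected. Voxels with fewer
   than two face-connected neighbours are suppressed (single-voxel
   bridges and speckle), and the result is clipped to the union of the two
   boundary supports plus a one-voxel guard band. The operation is
   symmetric in its arguments.
4. **Component selection and interface refinement.** Connected components
   (`component_connectivity`, default 26) below `min_component_voxels`
   are dropped; the component nearest the region seed is kept (the fovea
   landmark for the deep bundle, the styloid apex for the superficial
   one; without a seed, the largest component). The component is then
   restricted to the *contact interface*: voxels of one structure that
   are face-adjacent to the other, evaluated on the input labels. This
   step is essential for unbiased areas -- the dilation in stage 3 is a
   detector, and without refinement its radius would smear the footprint
   outward by a perimeter ring of roughly `dilation_radius_mm`, a 10--20%
   area inflation for ribbon-like patches.
5. **RANSAC plane refinement** (`ransac_plane`). Classical three-point
   RANSAC (`ransac_iterations`, default 1000; inlier threshold
   `ransac_inlier_threshold_mm`, default 0.15 mm; explicit seed) followed
   by a total-least-squares refit on the inliers (centroid plus
   smallest-variance direction, refreshed once). The largest connected
   inlier subset becomes the final patch. RANSAC runs on voxel centres,
   not on a meshed surface.

Every stage's output is a subset of its input support plus at most the
one-voxel guard band, the chain is deterministic for a fixed seed, and all
stages commute with axis-aligned 90-degree rotations of the grid.

## Morphometry conventions

* **Area** (`patch_area`) is measured on the RANSAC plane: inlier points
  are projected, rasterised at `raster_resolution_mm` (default the
  smallest voxel spacing), closed with a one-pixel morphological closing,
  and counted. It is a planar projected area, not a curved-surface area;
  on phantoms with the default geometry the difference is below the
  raster tolerance because the contact facet is flat.
* **DV/RU lengths** (`max_extent`) are ranges of point projections onto
  the axes of an `anatomical_frame` supplied by the caller -- the package
  never infers anatomical directions from the image. Because points are
  voxel centres, extents underestimate the continuous extent by up to one
  voxel per side.
* **Centre thickness** (`center_thickness`) ray-casts the sheet mask
  along the plane normal through the in-plane centroid (falling back to
  the nearest non-empty column within one voxel) and adds one voxel
  thickness along the normal.
* **Shape classification** (`classify_shape`) operationalises the
  three-way visual taxonomy with two descriptors of the projected patch:
  *elongation* (convex-hull diameter over the orthogonal extent) and
  *solidity* (raster area over convex-hull area). A patch is semilunar if
  solidity < 0.80, else a ribbon if elongation >= 2.5, else an irregular
  quadrilateral. The thresholds are exposed as arguments and recorded
  with every classification; they were fixed once so that a convex
  13.40 x 3.98 mm band (elongation about 3.4) is a ribbon, a compact
  convex quadrilateral (elongation near 1, solidity near 1) is a
  quadrilateral, and crescents (solidity near 0.55) are semilunar.

## The phantom and what it does (not) emulate

`phantom_spec()`/`generate_phantom()` build an analytic distal forearm:

* an **ulna** modelled as a sphere (default radius 12 mm) truncated by a
  flat circular articular facet, plus a conical styloid just beyond the
  facet rim;
* a **radius** slab on the radial side (a dummy structure so volumes
  carry all three foreground labels);
* a **TFCC sheet** of constant thickness (default 0.6 mm) suspended
  1.0 mm above the facet, dipping down to touch it over the designed
  contact patches. The 1.0 mm gap is more than twice the default
  detection radius, so no spurious contact is detected away from the
  patches.

The deep patch is one of three planar templates laid out in the facet
plane, so its continuous area is closed-form: a stadium for ribbons
(`(L - W) W + pi (W/2)^2`), a fixed asymmetric convex quadrilateral
(shoelace area), or a crescent (disc of radius `L/2` minus the same disc
offset by `W`, via the lens formula). Because the facet is flat, the patch
lies exactly in its tangent plane and the truth area carries no projection
distortion. The superficial patch is a disc of the requested area on the
same facet, at least 2 mm from the deep patch and adjacent to the styloid
base; the styloid apex is its landmark. Default dimensions (DV 13.40 mm,
RU 3.98 mm, superficial 20.11 mm^2, TFC thickness 0.6 mm) follow the
cadaveric means reported for this joint; the validation suite additionally
uses a 9 x 6 mm quadrilateral, a compact geometry of the kind reported
for quadrilateral footprints.

Two seeded random elements make repeated generation informative:

* **Sub-voxel placement jitter.** The whole assembly is shifted by a
  uniform sub-voxel offset, so different seeds sample different
  voxel-lattice alignments -- the dominant source of discretisation
  variability between acquisitions.
* **Boundary noise.** `noise_level > 0` adds Gaussian jitter (in voxels)
  to each structure's signed distance before thresholding, mimicking
  ragged segmentation boundaries.

The phantom deliberately does **not** emulate grayscale MRI intensities,
partial-volume effects, curved foveal anatomy, inter-subject shape
variability, or segmentation-network failure modes. Passing the phantom
suite therefore demonstrates that the measurement chain is unbiased on
clean geometry at working resolution -- not that any particular
segmentation model is accurate on real wrists.

## Segmentation metrics

`dice_score` implements the standard per-class overlap
`2|A n B| / (|A| + |B|)`; `multiclass_dice` reports per-class values with
both macro (mean over classes) and pooled reductions, since either
convention appears in practice. Two empty masks score 1 (perfect agreement
on absence), with a warning. `soft_iou_loss` is the differentiable
surrogate `1 - sum(y yhat) / (sum(y + yhat - y yhat) + eta)`; `eta`
defaults to 1, a common smoothing choice. For binary predictions and
`eta = 0` it reduces to `1 - IoU`, and `Dice = 2 IoU / (1 + IoU)` -- both
identities are verified numerically in the test suite.

## Agreement statistics

* **ICC.** `icc_two_way` computes the single-measure two-way
  random-effects ICC from the two-way ANOVA mean squares. The default is
  the absolute-agreement form, ICC(2,1) --
  `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` -- the standard
  choice for method comparison, where a systematic offset between methods
  must count against agreement; a consistency form is available behind
  `type = "consistency"`, and the formulation used is recorded in
  `model_tag`. Estimates are banded poor (< 0.5), moderate (0.5--0.75),
  good (0.75--0.9), excellent (> 0.9); the published band limits overlap
  at their endpoints, so the package fixes boundary values to the
  lower-named band (0.5 and 0.75 are moderate, 0.9 is good).
* **Regression.** `fit_multiple_regression` wraps ordinary least squares
  (`stats::lm`) with standardized betas from z-scored variables, variance
  inflation factors, Cohen's `f^2 = R^2 / (1 - R^2)`, the overall F test,
  and residual/theoretical quantiles for Q--Q inspection. Rank-deficient
  designs fail with the aliased columns named.
* **Power.** `posthoc_power` evaluates the fixed-model
  R-squared-deviation-from-zero F test: noncentrality `lambda = f2 * n`,
  critical value from the central F(k, n-k-1), power from the noncentral
  F upper tail. The alternative convention `lambda = f2 (n - k - 1)` is
  deliberately rejected; it corresponds to a different error-variance
  scaling and produces much smaller powers at small n. Published power
  figures are sensitive to this convention and to the exact inputs fed to
  GUI tools; with `f2 = 2.62, n = 11, k = 6, alpha = 0.05` this
  implementation yields 0.539.
* Summaries use the sample (n-1) standard deviation; tests are two-sided
  at 0.05 unless stated.

## Numerical and design choices

* Voxel indexing is 0-based; world coordinates are voxel centres,
  `origin + index * spacing`; orientation tag defaults to LPS. Readers
  reorient into this convention via the JSON sidecar.
* Label codes are fixed at 0--3 for background/radius/ulna/TFCC; named
  landmark labels are allowed at codes >= 10.
* Nearest-neighbour assignment is the only label interpolation
  (`resample_labels`); labels are categorical.
* Ties: argmax smoothing prefers the lower label code; equal-size
  components resolve to the one containing the smallest linear voxel
  index; RANSAC count ties resolve to the smaller mean absolute residual.
* Degenerate inputs fail with typed conditions (`fp_error_*` classes)
  carrying the failing stage or field name, so callers and the CLI can
  map them to exit codes.
* NIfTI I/O is delegated to RNifti; NRRD support is a minimal built-in
  NRRD0004 reader/writer (raw and gzip encodings, integer types). NIfTI
  headers store spacing as float32, so the JSON sidecar keeps the
  full-precision geometry and takes precedence on read.

## Validation problem sizes

The shipped test suite validates the chain on 0.15 mm isotropic phantom
grids (about one million voxels each, roughly 3 s per phantom on one
core): 20 seeds per shape class for area/shape recovery, with mean
absolute relative area error required below 5% and at least 18/20 correct
classifications per class; ICC recovery uses 200 simulated 50-specimen
tables at each of four agreement levels. One full-resolution (0.1 mm)
check confirms that the discretised template area is within 2% of closed
form and shrinks further with resolution.

## Known limitations

* Areas are planar projections onto the fitted plane; strongly curved
  insertions would be underestimated relative to true surface area.
* Extents are point-set ranges and carry a systematic half-voxel-per-side
  underestimate; at 0.1 mm spacing this is negligible, at coarse spacing
  it is not.
* The contact-interface refinement assumes the two structures genuinely
  touch in the label volume; segmentations with a systematic gap larger
  than one voxel between TFCC and ulna will yield empty interfaces (the
  error then names the failing stage).
* Only the two-body-plus-sheet configuration is supported; multi-bone
  contact analysis is out of scope.
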