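# footprintr

Morphometry of ligament insertion footprints from multi-label 3D
segmentation volumes of the distal radioulnar joint.

The distal radioulnar ligaments (DRULs) of the triangular fibrocartilage
complex (TFCC) insert on the ulna in a deep (foveal) and a superficial
(styloid) bundle. Surgeons and anatomists characterise these insertions by
their footprint area, dorsal–volar (DV) and radial–ulnar (RU) maximal
lengths, and shape class (irregular quadrilateral / ribbon / semilunar).
`footprintr` computes these quantities from labelled volumes (radius,
ulna, TFCC) such as those produced by a segmentation network or a manual
rater, and ships the statistics used to compare measurement methods.

## What it computes

**Extraction** (`extract_footprint`): Gaussian one-hot label smoothing →
3D Sobel boundary delineation → dilation-based TFCC–ulna overlap
detection → connected-component selection near an anatomical landmark →
refinement to the true contact interface → RANSAC plane fitting
(3-point samples, total-least-squares refit), yielding a `footprint_patch`.

**Morphometry** (`measure_patch`): planar projected area (occupancy
raster with one-pixel closing), DV/RU maximal extents along a declared
`anatomical_frame`, centre thickness of the fibrocartilage sheet, and a
quantitative shape rule — semilunar if solidity < 0.80, ribbon if
elongation ≥ 2.5, irregular quadrilateral otherwise.

**Segmentation metrics**: Dice, `2|A∩B| / (|A|+|B|)`, per class with
macro and pooled reductions, and the differentiable Soft IoU loss
`1 − Σyŷ / (Σ(y + ŷ − yŷ) + η)`.

**Agreement statistics**: two-way random-effects absolute-agreement ICC,
ICC(2,1) = `(MSR − MSE) / (MSR + MSE + (2/n)(MSC − MSE))`, banded
poor/moderate/good/excellent at 0.5 / 0.75 / 0.9; multiple linear
regression with standardized betas, VIF, R², adjusted R², F; Cohen's
`f² = R²/(1 − R²)`; post hoc power of the fixed-model F test from the
noncentral F distribution with noncentrality `λ = f²·n`.

**Synthetic phantoms** (`generate_phantom`): seeded wrist phantoms — a
truncated-sphere ulnar head with a flat articular facet, conical styloid,
radius slab, and a constant-thickness TFCC sheet touching the facet over
template patches (stadium / convex quadrilateral / crescent) whose area,
lengths and shape class are known in closed form. These provide analytic
ground truth for end-to-end validation.

## Worked example

```r
library(footprintr)

spec  <- phantom_spec(spacing = c(0.15, 0.15, 0.15), seed = 42)
ph    <- generate_phantom(spec)
patch <- extract_footprint(ph$volume, cfg = pipeline_config(seed = 42),
                           region_seed = ph$truth$landmarks$fovea)
measure_patch(patch)
#> footprint_morphometry (deep)
#>   area           50.60 mm^2
#>   DV length      13.35 mm
#>   RU length       3.90 mm
#>   shape       ribbon (elongation 3.24, solidity 1.000)
#>   provenance  seed 42, config 501369be
ph$truth$deep_area
#> [1] 49.93262
```

The extracted area is within 1.5% of the phantom's closed-form truth
(49.93 mm²), the DV/RU lengths are within one voxel of the designed
13.40 × 3.98 mm band, and the band is classified as a ribbon.

```r
posthoc_power(f2 = 2.62, n = 11, k = 6, alpha = 0.05)
#> power_result: power = 0.539 at alpha = 0.050
#>   f^2 = 2.620, n = 11, k = 6, lambda = 28.82, critical F(6, 4) = 6.163

tab <- simulate_paired_measurements(50, 9, 1, 1, seed = 42)
icc_two_way(tab$method_a, tab$method_b)
#> ICC = 0.9292 (excellent), n = 50 pairs
#>   model: ICC(2,1) two-way random, absolute agreement, single
```

Volumes are read and written as NIfTI (`.nii`, `.nii.gz`) or NRRD with a
JSON sidecar carrying origin, orientation and the label schema
(`read_volume` / `write_volume`); patches export to JSON/CSV/PLY.

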