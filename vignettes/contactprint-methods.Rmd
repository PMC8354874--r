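---
title: "Contact-print morphometry: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact-print morphometry: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactprint)
```

## The problem

When a radiofrequency ablation catheter is pressed against heart-muscle
tissue, the footprint it leaves — its area and its shape — depends on the
contact force and on the angle between the catheter shaft and the tissue
plane.  The footprint area is a proxy for the area of the eventual
ablation lesion, so electrophysiologists care how it scales with force at
each working angle.  Ex vivo, the footprint can be visualized by coating
the metal tip electrode with soluble ink, pressing it onto flattened
porcine heart tissue, and photographing the print.

`contactprint` implements the quantitative side of that experiment as a
reusable pipeline:

1. **image analysis** — grayscale conversion, binarization, calibrated
   area measurement, centroid alignment, principal-axis rotation, and
   replicate averaging of the prints;
2. **shape typing** — a four-class morphology (T1 rectangular, T2
   semi-ellipsoidal, T3 circular, T4 ellipsoidal) driven by moment-based
   descriptors;
3. **force-area modelling** — per (tip shape, contact angle), ordinary
   least squares of area on the natural log of force,
   `area = a * ln(F) + b`, with `R^2`; percentage contact area
   (area over the tip's electrode surface area); gf-to-Newton
   conversion;
4. **synthetic data** — a seeded generator that renders contact prints
   with the study's statistical and geometric structure, because the
   original photographs are not publicly deposited.

The study design replicated here is 2 tip shapes x 5 contact angles
(0, 30, 45, 60, 90 degrees) x 8 contact forces (2, 4, 6, 10, 15, 20, 30,
40 gf) x 6 replicates = 480 prints.  The published per-condition mean
areas, their SDs and integer percentage contact areas, and the published
per-angle fit coefficients are bundled as plain-text tables
(`paperAreaTable()`, `paperFitTable()`).

## The image-analysis chain and its conventions

Coordinates are (row, column) with the origin at the top left; angles are
measured from the image vertical, positive counterclockwise, and reported
in (-90, 90].

**Binarization.** The published procedure binarizes a grayscale image but
does not state a threshold, so the default is Otsu's method — an
exhaustive scan of the 256 candidate thresholds k/256 maximizing the
between-class variance, computed from the exact partition statistics of
the raw intensities (not bin centers).  A fixed threshold is available as
an override.  Manual segmentation of the raw photographs is replaced by
retaining only the largest connected component after thresholding, which
is exact for single-print images.  A constant image yields an empty mask
with a warning rather than an error.

**Area.** Foreground pixel count times the square of the mm-per-pixel
calibration.  At the default calibration (0.02 mm/px) every footprint in
the study grid spans well over 50 px along its shortest axis, and
rasterization error stays below 0.2% — comfortably inside the 2%
guarantee the tests assert.

**Alignment.** Each mask's centroid is translated to the canvas center
and the mask is rotated about it so the major axis (from the second
central moments) is vertical.  Nearest-neighbour resampling is used on
purpose: it preserves binarity so area bookkeeping stays integral; the
tests assert conservation within 2% and idempotence within 1% of
foreground pixels.  Two degenerate cases need conventions:

* *no meaningful axis* — below eccentricity 0.1 (a near-circular print)
  the rotation would be noise-driven, so it is skipped;
* *180-degree ambiguity* — after rotation the mask is flipped, if
  necessary, so the half with the larger area faces the canvas bottom.
  This matters only for the asymmetric T2 prints and makes the average
  morphology deterministic.  The flip fires only when the halves differ
  by more than 2% of the foreground, so symmetric shapes are not
  flip-flopped by raster noise.

**Replicate averaging.** Aligned masks are accumulated into a per-pixel
occupancy map on a common canvas (the largest input padded by 25%); the
consensus mask keeps pixels with occupancy >= 0.5, ties included — a
majority vote.  The published work derived an "average morphology" from
six images without stating the combination rule; both the continuous
occupancy and the thresholded consensus are exported so either reading is
available.

**Descriptors and classification.** Four descriptors feed the
classifier: eccentricity of the moment ellipse; rectangularity, defined
as area over the bounding box taken *along the principal axes* (this
makes the descriptor rotation-invariant — with an axis-aligned box a
rectangle tilted by the generator's 5-degree pose jitter would leak
class); and axial asymmetry, the fraction of pixels whose mirror image
across the minor axis through the centroid falls outside the footprint.
The decision rule is sequential: eccentricity < 0.3 is circular (T3);
else rectangularity > 0.9 is rectangular (T1); else asymmetry > 0.15 is
semi-ellipsoidal (T2); else ellipsoidal (T4).  All thresholds are
configurable via `studyConfig()`.

One geometric subtlety: a half-*disk* is wider than it is tall, so its
moment major axis runs along the flat cut and it is symmetric about its
minor axis — it does not read as T2 under this rule.  The T2 prints the
generator produces are elongated half-ellipses (height at least 1.5x the
width), whose major axis is the symmetry axis; their reflection
asymmetry is 0.186 regardless of scale (the quantity is affine
invariant), safely above the 0.15 cutoff.

## The synthetic generator

The generator is phenomenological by design: it reproduces the
*statistical* structure the analysis assumes, not the contact mechanics
(no tissue deformation model).  Its defaults are the study conditions:

| parameter | default | rationale |
|---|---|---|
| grid | 2 tips x 5 angles x 8 forces x 6 replicates | the study design (480 prints) |
| ground-truth laws | published per-angle (a, b) | `defaultLaws()` transcribes the published fit table |
| replicate noise CV | 0.08 | matches the SD/mean ratios of the published tables (0.05-0.15) |
| pixel scale | 0.02 mm/px, 512 x 512 canvas | >= 50 px across the smallest footprint at 2 gf |
| pose jitter | rotation <= 5 deg, offset <= 5 px | exercises the alignment code |
| intensities | foreground 0.9, background 0.1, noise SD 0.05 | bimodal histogram, well-posed binarization |
| tip diameter | 2.33 mm | the catheters' stated tip dimension; the 7 Fr/4.5 mm vs 2.33 mm labelling is ambiguous, so the diameter is configurable |

Each replicate's area is `a*ln(F) + b` times `(1 + eps)`,
`eps ~ N(0, CV)`, drawn from a per-image seed derived from the dataset
seed, so datasets are byte-identical under identical inputs and the
manifest of an unrendered dataset (`render = FALSE`) equals the rendered
one.

**Shape dimensioning.** The footprint class fixes the geometry family
and one free dimension is solved from the target area:

* T1 rectangle: width fixed at the tip diameter, length = area/width;
* T3 circle: radius from the area;
* T4 ellipse: the *inclined-tip projection* template — a tilted cylinder
  of diameter d projects an ellipse of aspect 1/sin(angle), so the
  solved minor axis is capped at d once the print has grown to the tip
  width, and below that cap the template scales isotropically.  This
  keeps eccentricity >= 0.5 at every grid cell; a naive
  "shrink toward a circle" fallback would misclassify small T4 prints
  as circular;
* T2 half-ellipse: width fixed at the tip diameter, the cap extent
  solved from the area.  A stadium shape (half-ellipse plus rectangle)
  was considered and rejected: its principal-frame rectangularity is
  about 0.92 and its reflection asymmetry about 0.08, so the
  classification rule above can never recover T2 from it.  The pure
  half-ellipse satisfies the rule at every area in the grid.

Small-area fallbacks (T1 at 2:1, T2 at 3:1) only engage below the
smallest grid areas and keep each class's elongation, so classification
remains well-defined under strong negative noise draws.

**What the generator does not emulate** — and therefore what passing
tests do *not* show about real data: ink bleed and partial transfer,
illumination gradients, tissue texture, multi-print scenes, perspective
and lens distortion, or any force-angle interaction beyond the per-angle
law.  Results on real photographs depend on a segmentation step this
package deliberately keeps simple (threshold + largest component).

## The model layer

Fits use `stats::lm` of area on `ln(force)`; the natural log is used
throughout (the published formulas print "ln").  `R^2` is the ordinary
`1 - SSres/SStot` about the mean; reproducing the published flat-tip
0-degree triple (a = 2.685, b = 7.782, R^2 = 0.837) from the published
means confirms that definition.  Fits default to the 8 per-force *mean*
areas rather than the 48 replicate points; with balanced replicates the
coefficient estimates are algebraically identical (a property the tests
assert), but the means route reproduces the published `R^2`.  The sample
(n-1) standard deviation is used for the per-condition SD; the published
work does not state its convention, and no test asserts SD reproduction
since the raw replicates are unpublished.  Conditions with fewer than 6
replicates, singleton conditions, and (tip, angle) groups with fewer
than 3 distinct forces are carried through with flags rather than
dropped or smoothed; non-monotonic cells in the published tables (e.g.
flat tip 90 degrees between 15 and 20 gf) are reported as-is.

Report-layer rounding follows the published print precision: areas and
coefficients to 3 decimals, percentage contact area to the nearest
integer.

## Known inconsistencies in the reference values

Three facts about the bundled tables, found by recomputation and
documented here because the test suite asserts around them:

* Refitting the published mean areas reproduces 8 of the 10 published
  (a, b, R^2) triples to within 0.001.  The flat-tip 45-degree and
  round-tip 30-degree rows do not refit (deviations up to 0.15 in a
  and 0.22 in b); a single-cell back-solve shows each row is consistent
  with a slightly different mean in one cell (40 gf and 30 gf
  respectively) than the one printed, i.e. the published tables are
  internally inconsistent for those rows.  Fits on replicates cannot
  explain it (they equal fits on means under balanced designs).
* The round-tip 30-degree / 30 gf cell prints mean 17.693 mm2 and
  percentage contact area 65; recomputation gives 68.9.  A mean of
  about 16.69 mm2 would match both the printed percentage and the
  printed fit row, so this looks like a typo in the printed mean.  It
  is the only cell (of 80) whose percentage round trip misses by more
  than 1 point.
* The published Newton equivalents of the gf grid are truncations, not
  roundings (6 gf = 0.05886 N prints as 0.0588); the conversion test
  checks agreement at the printed precision accordingly.

Two further tolerance notes.  The published round-tip 45-degree
intercept is 0.012 mm2; with a near-zero reference, *relative* recovery
bounds are not meaningful — sub-pixel rasterization error (about
0.001 mm2 in absolute terms, i.e. droplets of a single pixel row) already
exceeds 1% of it, and no replicate-noise level allows a 10% relative
band on it.  Recovery statements in the tests therefore either use
absolute deviations for intercepts near zero or use the flat-tip
0-degree law (the largest intercept, and the study's worked example) for
the noisy-recovery simulation.  Under the generator's own conditions
(CV 0.08, 6 replicates, 8 forces) the slope estimate's relative standard
error is about 5%, so a +/-10% band captures roughly 90% of seeded
repetitions — the honest recovery rate the acceptance script reports.

## Problem sizes used by the tests

The unit tests run on reduced grids (a few angles and forces, 2-3
replicates) and on rasterized analytic shapes at 300-500 px canvases;
the end-to-end acceptance checks run the full noiseless 480-print grid
at the default calibration and a 200-repetition noisy-recovery
simulation without rendering.  These sizes were chosen so the complete
suite exercises every code path, including the full study design, in a
few minutes on a single core.

## Worked example

```{r example, eval = FALSE}
laws <- defaultLaws(noiseCV = 0.08)
ds <- generateDataset(laws, seed = 1)       # 480 prints, ~15 s
report <- runStudy(ds, seed = 1)
fits(report)                                # 10 rows of (a, b, R^2)
exportReport(report, "study-out")           # tables + morphology PNGs
```
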