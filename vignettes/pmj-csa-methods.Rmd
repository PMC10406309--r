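---
title: "Measuring and normalizing spinal cord CSA from the pontomedullary junction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and normalizing spinal cord CSA from the pontomedullary junction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmjcsa)
```

## The measurement problem

Cervical spinal cord cross-sectional area (CSA) shrinks with cord atrophy
in neurodegenerative disease, but healthy inter-subject variability (a
coefficient of variation around 10%) drowns much of the signal. Two things
help: a better anatomical reference for *where* the cord is measured, and
statistical normalization for *who* is being measured.

The conventional reference is vertebral: average CSA over the slices
spanning the C2 and C3 vertebral levels. Vertebral bodies, however, are an
imprecise surrogate for spinal segments, and neck flexion moves the cord
relative to them. This package implements the alternative: measure at a
fixed *arc-length distance along the cord centerline* from the
pontomedullary junction (PMJ), a landmark of the central nervous system
itself. The reference distance is 64 mm - the population mean distance
between the PMJ and the C2-C3 disc - and slice-wise CSA is averaged over a
20 mm extent centered there.

## The measurement pipeline

Inputs are a binary cord segmentation and single-voxel point labels (PMJ
code 50; intervertebral discs C1-C2 = 2, C2-C3 = 3, C3-C4 = 4), both as
NIfTI volumes. All volumes are canonicalized at load: grid axes are
permuted and flipped (never resampled) so axis 1 runs right-left, axis 2
anterior-posterior and axis 3 inferior-superior (RAS). Geometry downstream
is in physical millimetres through the affine; the affine follows the
NIfTI convention of mapping 0-based voxel indices, while R-facing array
indices stay 1-based.

1. **Medial-plane refinement** (`findMedialSlice`). A PMJ candidate
   detected on the mid-sagittal slice may be off the anatomical medial
   plane when the head is tilted. For each sagittal slice near the
   candidate, a window (default 30 x 30 mm in-plane, full
   superior-inferior span) is correlated with its right-left mirror
   image about that slice; the correlation peaks at the right-left
   symmetry slice. The search operates at whole-slice resolution - the
   refinement selects a slice, not a continuous plane - so its precision
   is half a voxel by construction.
2. **Centerline** (`extractCenterline`). The center of mass of every
   axial mask slice, with fully missing interior slices filled by linear
   interpolation against slice index. The PMJ coordinate is appended as
   the superior terminus, because segmentations stop short of the PMJ.
   In-plane coordinates are then smoothed (the superior-inferior
   coordinate and the PMJ anchor are never displaced); tangents are
   central differences, one-sided at the termini.
3. **Arc length** (`arcLengthFromPMJ`). Cumulative polyline distance from
   the PMJ. Arc length rather than straight-line distance matters because
   cervical lordosis curves the cord; on a straight cord the two
   coincide.
4. **Slice metrics and aggregation** (`sliceMetrics`, `csaPMJ`,
   `csaVertebral`). Planar area is voxel count x pixel area on the
   binary mask - no sub-voxel contouring, since the input is already a
   hard segmentation. The angulation correction multiplies by
   cos(theta), theta being the angle between the local tangent and the
   slice normal, estimating the area perpendicular to the cord. `csaPMJ`
   averages corrected areas over the slices whose arc-length from the
   PMJ falls in the closed interval 64 +/- 10 mm; `csaVertebral`
   averages over slices whose centerline point lies between the C1-C2
   and C3-C4 disc positions (the C2-C3 vertebral span), interval closed
   on both ends. Slices are unweighted in both averages.

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `distance_mm` | 64 | mm | extent center, arc-length from the PMJ |
| `extent_mm` | 20 | mm | averaging window along the centerline |
| `smoothing_mm` | 30 | mm | arc-length window of the centerline smoother |
| `window_mm` | 30 x 30 | mm | in-plane symmetry-search window |
| `search_range_mm` | 15 | mm | sagittal half-range of the symmetry search |
| `alpha` | 0.05 | - | entry and exit significance for stepwise selection |

The smoother is a Hann-weighted *local linear* regression over the
arc-length window rather than a plain weighted moving average: at the
centerline's ends the window is one-sided, where a weighted mean has
first-order bias (it drags endpoints toward the interior and corrupts the
endpoint tangents that the angulation correction uses), while a degree-1
local fit is exact for straight segments everywhere. In the interior the
two behave equivalently.

A deliberate fidelity note: appending the PMJ label to the centerline and
interpolating is not a true extrapolation of the centerline - the polyline
takes a chord across the unsegmented gap below the PMJ, slightly
shortening distances when the cord is curved there. This behavior is
replicated, not corrected; with the default 5 mm phantom gap and
anatomically plausible curvature the bias is well under 0.1 mm.

## Regression-residual normalization

Measured CSA is adjusted toward the cohort mean along the fitted
regression plane:

CSA_norm,i = CSA_meas,i + sum_j c_j (X_j,mean - X_j,meas,i)

where c_j are multilinear regression slopes of CSA on the predictors and
X_j,mean are cohort predictor means. Six published coefficient sets ship
in `publishedModels()`: three families - thalamus + brain volume; those
plus sex and the sex x brain-volume interaction; and a thalamus-free
variant for cohorts where thalamus volume is unavailable or biased by
thalamic atrophy - for each of the two references (PMJ, C2-C3). Sex is
coded 0 = female, 1 = male (forced by the published mean 0.437 matching a
43.7% male cohort); interaction terms are raw, uncentered products, and
their published means are means of the product. Fractional sex values in
[0, 1] are accepted as cohort-mean plug-ins; values outside are rejected
as coding errors.

Two published quirks are preserved verbatim rather than silently fixed:
the C2-C3 four-predictor model's sex coefficient is -1.235 as printed
(an order of magnitude off its companions, -15 and -15.23, most likely a
typographical loss of a digit) and using that model warns loudly; and one
published C2-C3 regression summary prints an adjusted R-squared exceeding
the raw R-squared, which is arithmetically impossible, so no consistency
check is applied to that pair. Refitting on your own cohort
(`fitResidualModel`) is the sanctioned alternative to both.

`fitResidualModel` refits the family by OLS and derives mu_norm /
sigma_norm from the normalized values on the fitting cohort. Two exact
algebraic identities follow from residualization and are enforced by the
tests: the cohort mean is preserved, and STD(CSA_norm)/STD(CSA_meas) =
sqrt(1 - R^2) - so with predictors explaining ~27% of variance the COV
drops by 1 - sqrt(1 - 0.27), i.e. about 14-15%. The z-score is
(CSA_norm - mu_norm)/sigma_norm, and COV is 100 x STD/mean. Sample
(n - 1) STDs are used throughout - the cohort is a sample; the choice is
fixed and documented rather than inferable.

`stepwiseSelect` reproduces the selection procedure: candidates ordered
by decreasing |Pearson r| with CSA (ties broken lexicographically for
determinism), entered if their term p-value in the joint model is below
alpha, with any term whose p-value rises above alpha removed after each
entry; the same alpha governs entry and exit. Correlation-based
collinearity screening (e.g. dropping white/gray-matter volumes that
correlate at 0.94-0.96 with whole-brain volume) is the caller's
responsibility, mirroring practice. P-values come from the t
distributions of OLS terms, uncorrected for multiple comparisons - the
exploratory correlation matrix in `cohortStatistics` is likewise
deliberately uncorrected, and its two-sample sex t-test assumes equal
variances.

## What the synthetic data does and does not emulate

`makeTubePhantom` voxelizes a tube around a parametric curve (straight,
circular arc, or polynomial offsets, optionally tilted) by voxel-center
membership, with analytically known centerline, tangents, arc-length and
perpendicular CSA (pi r(s)^2). The PMJ sits at the curve's superior end
with the mask starting 5 mm of arc below it, mimicking segmentations that
stop short of the PMJ. Rasterization choices are deterministic: no
partial-volume weighting, and the tube axis is placed 0.5 mm off the
voxel-center lattice - an axis exactly on voxel centers puts 12 lattice
points exactly on a radius-5 circle and inflates the disc area by 3%,
while the offset placement keeps the voxel-count error at 1.9% at 1 mm
and strictly decreasing with voxel size (0.9% at 0.5 mm, 0.03% at
0.25 mm).

`makeCohort` samples predictors from a Gaussian copula with sex-dependent
mean shifts solved so the *total* correlations hit their targets, then
builds CSA as a known linear predictor plus Gaussian noise. Defaults
reproduce the published cohort's structure: n = 804, 43.7% male, brain
and thalamus volume means of 1,156,171 and 15,266 mm^3, thalamus-brain
correlation 0.79, sex-brain 0.49, sex-thalamus 0.36, generative slopes
from the published two-predictor fit, and noise calibrated so the
predictors explain R^2 = 0.267 of CSA variance. Published reports do not
include predictor SDs; 110,000 and 1,500 mm^3 (roughly 10% coefficients
of variation) are used as realistic volumetric spreads.

What the generators do *not* emulate - and therefore what passing tests
cannot show about real data: MRI intensities and artifacts, segmentation
errors and their correlation with image quality, anatomical variation in
cord radius profile and curvature beyond the parametric families, PMJ
labeling variability, and any non-linearity or heteroscedasticity in the
predictor-CSA relationships. The phantoms validate the geometry engine;
the cohorts validate the statistical machinery; neither validates the
upstream segmentation this package deliberately does not perform.

## Numerical choices and test design

* Extent and disc-span intervals are closed on both ends; ties at
  interval edges are thus deterministic.
* Tangents at centerline termini use one-sided differences (central
  differences are undefined there).
* Angles are clamped to [0, pi/2) via |t_z|; corrected area never exceeds
  planar area.
* The NIfTI-1 sform is float32; affines with exactly representable
  entries round-trip bit-identically, others to ~1e-7 relative.
* Monte-Carlo checks use fixed seeds and a priori statistical tolerances:
  the 2-SE slope-recovery coverage (nominal P(|t_801| <= 2) ~ 95.4%) is
  compared against its one-sided 99% binomial lower bound over 200
  replicates x 2 slopes, and the 13-16% COV-reduction band is asserted
  on the mean of 50 replicates, whose per-replicate sampling SD
  (~1.6 percentage points at n = 804) is wider than the band's half-width.
* Problem sizes throughout - 120 mm phantoms at 1 mm isotropic
  resolution, cohorts of n = 804, 200 and 50 replicate batches - are
  the package's validation choices: large enough for the asymptotics the
  identities rely on, small enough to re-run casually.

## Known limitations

The symmetry search cannot return sub-voxel planes; the vertebral span
uses physical superior-inferior disc positions rather than a per-slice
vertebral labeling; the voxel-count area is conservative relative to
contour-based areas (a systematic, calibration-like offset, consistent
across subjects); and the published models embed the segmentation and
brain-volumetry conventions of their source cohort, so applying them to
data processed differently inherits a systematic offset - refit when in
doubt.
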