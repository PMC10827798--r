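---
title: "Stratified choroidal binarization: models, parameters and design choices"
author: "ChoroidStrat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified choroidal binarization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChoroidStrat)
```

## The problem

Enhanced depth imaging OCT (EDI-OCT) resolves the full thickness of the
choroid, the vascular bed between the retinal pigment epithelium (RPE) and
the sclera.  The choroid is conventionally stratified into three sublayers
of growing vessel caliber: the choriocapillaris (CC) directly under the
RPE, Sattler's layer (SL) of medium vessels, and Haller's layer (HL) of
large vessels.  Because vessel lumina are optically dark and the fibrous
stroma bright, binarizing a choroidal region of interest separates luminal
from stromal tissue, and the luminal/choroidal area ratio (L/C, in percent)
summarizes the vascular status of each sublayer.

ChoroidStrat implements this analysis end to end: a 1500-um foveal analysis
window is carved out of a B-scan between two annotated curves (the RPE
lower edge and the choroid-scleral interface, CSI); a brightness floor is
calibrated from the darkest vessel lumina of Haller's layer; the window is
converted to 256 gradations above that floor and binarized; the two
internal sublayer boundaries (CC/SL and SL/HL) are detected from depth
profiles by differentiation and fitted with quadratic curves; and per-layer
areas, L/C ratios and central thicknesses are measured.  A statistics
module reproduces the reliability and regression battery usually reported
with such measurements (two-rater ICC, Bland-Altman, Spearman, standardized
multiple regression on age / spherical equivalent / axial length,
Kruskal-Wallis across sublayers).

Because no clinical image data ship with the package, a synthetic-data
module generates B-scan phantoms with exact ground truth and simulated
subject cohorts.  Every stage of the pipeline is tested against that ground
truth.

## The phantom model

`generatePhantom()` renders, from top to bottom: dimly reflective retina, a
bright RPE band, three stacked choroidal sublayers, and sclera.  The
default geometry is a 768 x 496 px raster at 3.9 x 1.95 um/px, typical of
SD-OCT exports; no standard fixes these values, so they are package
defaults, not facts about any device, and both scales are per-image inputs
everywhere else in the package.

Each sublayer is populated with axis-aligned elliptical lumens
(axial/lateral aspect 0.6, since vessels appear flattened in B-scans) whose
lateral radius is drawn uniformly from a per-layer range — 4-8 um in CC,
8-18 um in SL, 25-60 um in HL, encoding the caliber growth from CC to HL.
Ellipses may overlap within a layer and are clipped at layer boundaries.
Placement continues until the realized luminal pixel fraction is within
0.01 of the per-layer target, with two refinements that keep the spatial
distribution honest:

* a proposal that would overshoot the tolerance is rejected (up to 200
  rejections, then the closest achievable configuration is kept), and
* near the target the proposal radius is capped by the remaining deficit,
  because otherwise only proposals that overlap existing lumens are
  acceptable and coverage becomes spatially clumped.

Default layer thicknesses (16.2 / 72.7 / 170.4 um) and luminal fractions
(0.790 / 0.676 / 0.633) are population means for healthy adult eyes.
Intensities follow the OCT convention that lumina are dark: lumen 40,
stroma 140, sclera 120, RPE 220 on a 0-255 scale.  Three darker (gray
level 30) "reference" lumens are planted well apart in Haller's layer —
the ground-truth counterpart of the manual selection of representative
dark lumens that calibrates the binarization floor.  Additive Gaussian
noise (default sd 10 gray levels) is applied last.  All four boundary
curves share one gentle quadratic (1e-4 rows per squared column offset
from the fovea) by default: over a 1500-um window the sublayers run
essentially parallel to the RPE.

What the phantom does *not* emulate: multiplicative/Rayleigh speckle,
A-scan shadowing under large vessels, motion artifacts, pathology, or
non-parallel sublayer boundaries.  Passing recovery tests on these
phantoms therefore demonstrates the internal consistency and calibration
of the pipeline under a controlled forward model, not clinical-grade
performance on real scans.  One phantom-specific feature deserves
emphasis: because lumens are clipped at sublayer boundaries, a thin bright
"seam" of stroma marks each internal boundary.  Real boundaries are
defined by the caliber transition rather than a stromal gap, which is why
the default boundary detectors (below) are chosen per boundary and are
fully configurable.

## Cohort simulation

`generateCohort()` draws age, spherical equivalent (SE) and axial length
(AL) from independent Gaussians (59.6 +/- 14.8 y, -2.06 +/- 3.52 D,
24.61 +/- 1.71 mm; independence is a simplification — myopic eyes are in
truth longer).  Each structural target (three sublayer thicknesses, three
luminal fractions) follows a linear model on the z-scored covariates with
standardized slopes plus Gaussian residuals scaled so the marginal moments
match the requested means and sds.  The default slopes encode the
established signs: age thins every sublayer and lowers L/C; axial length
thins SL and HL but barely affects CC.  Thickness floors at one pixel;
fractions are clamped to [2, 98] percent.  In parametric mode the metrics
are emitted directly (areas for the rectangular window approximation,
thickness x width); in imaging mode one phantom is rendered per subject —
with lumen radii capped so the smallest proposable lumen still fits in a
thin subject's layer — and the metrics come from the measurement pipeline.
`simulateSecondRater()` adds per-metric Gaussian measurement noise
(default 0.15 of each metric's between-subject sd, which yields ICCs in
the high 0.9s), plus optional fixed and proportional bias terms for
calibration experiments.

## Binarization

The brightness floor is the mean reflectance of `k = 3` reference lumens.
The automatic search smooths the window (Gaussian, sigma 2 px), restricts
to the Haller region — by default the deepest half of each column's
choroid span, since detected boundaries do not exist yet at this stage of
the pipeline — and takes the darkest local minima separated by at least
twice the assumed maximum lumen radius (16 px).  Inside a large flat lumen
the literal minimum can sit anywhere, so each minimum is re-centred on the
darkness-weighted centroid of its surrounding basin (pixels within 6 gray
levels of the minimum).  Manual coordinates bypass the search entirely.

`rescaleTo256()` maps [floor, window maximum] linearly onto [0, 255],
clipping below the floor, so the darkest vessel interiors land at 0
regardless of scanner gain.  16-bit input is used as-is up to this point;
the 8-bit conversion happens only here.

For the threshold itself the source procedure is ambiguous: the
lumen-derived floor is called the "lowest brightness cut value", which can
be read either as the binarization threshold or as a contrast-normalization
minimum followed by a local method.  Taken literally as a global threshold
the floor labels almost nothing luminal (it *is* the darkest tissue); and a
pure Niblack local threshold cannot reproduce truth exactly even on
noise-free phantoms, because inside any window fully contained in one
class the local threshold equals the local mean and splits homogeneous
lumen interiors arbitrarily.  The package therefore treats the floor as
contrast normalization and defaults to a global Otsu threshold computed on
the histogram of choroidal pixels (`EBImage::otsu`), which recovers
noise-free phantoms exactly and is insensitive to the phantom's intensity
settings.  `method = "niblack"` (window 25 px, k = -0.05) and
`method = "global"` (explicit threshold) remain available, and every mask
records the method and threshold used.  Ties at the threshold are stroma
(lumen is strictly below); the tie-break is fixed and documented rather
than platform-dependent.

## Boundary detection

Detection runs on the floor-rescaled window (configurable), in an
RPE-aligned frame: each column's choroid trace is indexed by depth below
the floored RPE row, which removes the shared curvature of the boundaries.
Two feature images are available:

* **intensity** — the rescaled gray levels;
* **gradient** — the absolute lateral first difference, an edge-density
  measure that tracks vessel caliber: many small lumens produce dense
  lumen/stroma edges, few large lumens produce sparse ones.

Detection is hierarchical:

1. **Profile stage.**  The feature image is smoothed (axial sigma 1 px,
   lateral sigma 16 px, normalized convolution so the ragged lower margin
   and anything outside the choroid contribute nothing) and averaged
   across columns into a mean depth profile.  The boundary depth is the
   sub-pixel extremum (three-point parabolic interpolation) of the
   profile's first or second difference inside a search band.
2. **Column stage.**  The same change-point is re-detected per column
   inside a narrow band (+/- 8 px) around the profile depth; columns whose
   peak change does not exceed 1.5x the median absolute difference in
   their band are omitted.
3. **Fit stage.**  A quadratic `row = a col^2 + b col + c` is fitted to
   the per-column points by least squares with one pass of residual
   trimming at 2.5 sd, then shifted vertically so its mean RPE-relative
   depth equals the profile-stage estimate.  The profile estimate pools
   hundreds of columns and is nearly free of texture bias, while the
   per-column points are individually noisy but carry the curvature
   information; anchoring combines the strengths of both.

Per-boundary defaults follow each boundary's anatomical signature.  The
CC/SL boundary separates the darkest, most luminal sublayer from SL and is
marked by a bright stromal seam; it is detected as the negative extremum
of the second derivative of the intensity profile (a ridge detector —
second-order differentiation in the plain sense) within 2-60 um below the
RPE (the CC is ~10-20 um thick).  The SL/HL boundary separates two layers
of nearly equal mean brightness but very different caliber; it is detected
as the falling step edge of the gradient (edge-density) profile, searched
from 20 um below the fitted CC/SL boundary down to the CSI.  The
anatomically sensible reading of "search between the RPE and the CC/SL
boundary" for the SL/HL step would place SL/HL above CC/SL, which
contradicts the layer order; the implementation searches below CC/SL and
flags this as a deliberate interpretation.  Both boundaries' features,
derivative orders, change directions and bands are `boundaryConfig()`
options, not constants.

Fitted curves are clipped column-by-column to the ordering chain
`rpe <= ccSl <= slHl <= csi`.  Crossings deeper than 1 px at more than 10
percent of columns abort detection with an error — surfacing a bad fit
beats silently clipping it; sub-pixel overshoot at a few columns is
treated as benign.  A degenerate Sattler band (fitted CC/SL within a few
pixels of the CSI) yields `slHl = ccSl` with a warning rather than a
crossing.

The standalone operations keep their own contracts: `depthProfile()`
resamples each column's span to a uniform 200-sample depth axis (linear
interpolation) before averaging, so columns of different thickness are
placed "in a rectangle of uniform height"; `profileChangepoints()` returns
all qualifying second-derivative extrema (threshold 1.5x the median
absolute second difference, shallower depth on ties);
`columnChangepoints()` requires a peak 5x the median absolute difference
when used without pre-localization, a level at which fewer than ~10
percent of structureless noise columns qualify while genuine steps pass
comfortably.

## Quantification

Boundary curves are real-valued; rasterization floors them once, at mask
construction, with half-open row intervals `[floor(upper), floor(lower))`
so every choroidal pixel belongs to exactly one sublayer.  Areas are pure
pixel counts times the pixel area (no sub-pixel polygon integration — the
method is a binarized-pixel method), converted to mm^2 once at the end,
so `CA = LA + SA` and the sublayer-sum identity hold exactly in integer
pixel counts.  L/C is `100 * LA / CA`; an empty layer propagates as a
missing value with a warning, never as zero.  Central thickness is the
real-valued boundary gap at the fovea column times the axial scale; the
strictest reading of "central" is a single column, and `cctBand` widens it
to an average over +/- N columns for users who prefer a band.

## Statistics

* **ICC** — two-way random-effects, absolute-agreement ICC(2,1) and
  ICC(2,k), k = 2, from the ANOVA mean squares; this is the standard model
  for interchangeable human raters, and the exact model behind published
  single/mean ICC pairs is rarely stated, so the choice is a documented
  default with `model = "oneway"` behind a flag.  Significance is the F
  test of the between-subject effect on ((n-1), (n-1)(k-1)) df.
* **Bland-Altman** — fixed bias as the mean difference with t-based 95
  percent CI and one-sample t p; proportional bias as the Pearson
  correlation of differences on means (the slope is also reported); limits
  of agreement at 1.96 sd for plots.
* **Spearman** via `cor.test` (mid-ranks, t approximation), **Kruskal-
  Wallis** via `kruskal.test` (tie-corrected H), and **standardized
  regression** as OLS on z-scored response and predictors with listwise
  deletion.  No multiple-testing correction is applied by default,
  matching the way such tables are conventionally reported; adjusted
  p-values are one `p.adjust` call away for users who want them.

## Numerical choices and degenerate inputs

Sub-pixel peak localization uses three-point parabolic interpolation and
falls back to the discrete argmax at band edges.  Gaussian smoothing is
separable normalized convolution, written in-package because the choroid
window is ragged (NA below the CSI) and standard image blurs are not
NA-aware.  Boundary ties in change-point magnitude keep the shallower
depth.  Constant profiles yield zero candidates; constant windows and
zero-variance inputs raise errors or return missing values as documented
per function.  All generators are pure functions of (spec, seed); cohort
subjects receive child seeds drawn once from the cohort seed, so identical
seeds give bit-identical phantoms, masks and CSV outputs.

## Problem sizes in the test suite

The suite exercises default-geometry phantoms (384-column ROI) in batches
of 20 noisy and 6 noise-free scans for boundary and L/C recovery, 1000
null replicates for Bland-Altman CI calibration, n = 2000 for ICC
consistency, and one imaging-mode cohort of 189 subjects for the
qualitative findings (L/C ordering CC > SL > HL, negative age effects on
all sublayer areas, negative axial-length effects on SL and HL but not
CC).  These sizes were chosen to give stable estimates at interactive
runtimes; all tolerances are stated in the tests themselves.

## Known limitations

The phantom's boundary seam makes internal boundaries easier to localize
than in real scans, where the caliber transition is gradual; real-scan
boundary accuracy cannot be inferred from phantom recovery.  The cohort
model is cross-sectional, linear and Gaussian with independent covariates.
The rectangular-window area approximation in parametric mode ignores
boundary curvature.  Fovea position and the two outer curves (RPE lower
edge, CSI) are inputs — the package deliberately does not claim automatic
retinal-layer segmentation or fovea detection.
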