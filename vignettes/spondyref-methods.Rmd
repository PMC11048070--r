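---
title: "Lumbar disc metrics, reference data, and standardized scores: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lumbar disc metrics, reference data, and standardized scores: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spondyref)
```

## The measurement problem

On a lateral lumbar radiograph, each vertebral body from L1 to S1 can be
reduced to four corner landmarks.  From adjacent landmark pairs, spondyref
computes, for each intervertebral level L1L2..L5S1, nine sagittal plane
offset (SPO) and disc metrics plus four composites.  "SPO" is used for any
anterior-posterior displacement of one vertebra relative to its neighbour;
"spondylolisthesis" is reserved for *abnormal* SPO, which is precisely what
the reference data exist to define.

Radiographic magnification varies between exams and the source radiographs
carry no scaling device, so no metric is ever reported in millimetres: all
heights and offsets are percentages of the anterior-posterior width W of the
superior endplate of the inferior vertebra, angles are in degrees, and disc
area is in units of W².  This makes every output invariant under rigid motion
and uniform scaling of the landmarks, a property the test suite asserts to
1e-9.

### Corner-based (method 1) metrics

With the superior endplate of the inferior vertebra as the reference line:

* **ADH, PDH** — perpendicular distances of the superior vertebra's
  antero-/postero-inferior corners to the reference line (% W).
* **DA** — angle between the two facing endplates; negative when ADH < PDH.
* **ASPO** — along-endplate offset of the superior vertebra's antero-inferior
  corner relative to the inferior vertebra's antero-superior corner
  (positive = anterior).
* **PSPO** — the posterior-corner analogue (positive = posterior, i.e. into
  the canal).

Offsets are measured along the endplate direction rather than along the image
x axis, which is what makes them rotation invariant; the source description
is silent on this and the choice only matters for tilted exposures.

### Midplane-based (method 2, Frobin-style) metrics

Each vertebra's midplane is the line through the midpoints of its anterior
and posterior walls; the **bisectrix** bisects the angle between the two
midplanes of a level (for midplanes parallel within 1e-6 rad the midway
parallel line is used instead, because the intersection point becomes
numerically unstable).  **VDH/DDH** sum the perpendicular distances of the
facing anterior (posterior) corners to the bisectrix; **MPA** is the midplane
angle with the DA sign convention; **CSPO** is the signed distance along the
bisectrix between the perpendicular projections of the two vertebral
centroids.

One geometric subtlety is worth recording: rotating the superior vertebra
about its own centroid leaves both centroids fixed but tilts the bisectrix by
half the rotation, so CSPO picks up `|c_sup - c_inf| * sin(theta/2)` — about
3.9 %EPW at 5 degrees on the rectangle fixture.  This is a real property of
the centroid-projection construction, not an artifact, and the geometry tests
assert the analytic value.

### Composites

`avg_dh = (ADH+PDH)/2`; `disc_area` is the shoelace area of the disc
quadrilateral (absolute signed area, so digitization order cannot flip its
sign) in W² units; `epwr` is the superior vertebra's inferior endplate width
over W; `hw_ratio` is the superior vertebra's mean wall length over its mean
endplate width.

## Reference data: exclusion and trimming

`trim_population()` implements a two-pass exclusion.  Pass 1 drops every
level flagged for definite osteophytes/sclerosis (the flag is an *input*,
e.g. from an image-grading network).  On the remainder, level-specific means
and SDs of seven gating metrics (DA, ASPO, PSPO, average disc height, disc
area, EPWR, height/width ratio) define mean ± 1.96 SD reference intervals,
and pass 2 keeps only levels inside all seven.  Exactly two passes are run;
an `iterate` flag repeats pass 2 to a fixed point for exploration only.

The 1.96 multiplier reads "95% confidence interval" as an interval for
observations, not for the mean — the use made of it (trimming individual
levels, and later calling a Z score of 2 "just outside" the interval) only
makes sense for an observation interval.  Trimming is stratified by level
because the reference data are level-specific.

`build_reference()` then tabulates, per (level, metric): n, mean, sample SD,
median, CV, moment skewness (`m3/m2^1.5`) and non-excess moment kurtosis
(`m4/m2^2`, normal ≈ 3), the Hodges-Lehmann location, the Qn scale, and the
1.96-SD interval limits.

### Robust estimators

The Hodges-Lehmann estimate is the median of all Walsh averages
`(x_i+x_j)/2, i <= j`; Qn is `2.2219 * d(n)` times the `choose(h,2)`-th order
statistic of the pairwise absolute differences (`h = floor(n/2)+1`), with the
published Rousseeuw-Croux finite-sample factors `d(n)`.  Both need an order
statistic of an O(n²) set; spondyref selects it exactly in O(n log n) by
binary search on the value with pairwise counting via `findInterval`,
followed by exact extraction of the smallest achievable pairwise value above
the converged bound.  The result is bit-identical to full enumeration (the
test suite checks 200 random samples against a naive double loop) and takes
well under a second at n = 100,000, so no subsampling or approximation is
ever used.

## Standardized scores

* **Z score** `(x - mean)/sd` and **robust score** `(x - HL)/Qn`, both
  level-specific.  On clean Gaussian reference data the two are nearly
  identical, which the tests verify; the robust pair matters when the
  reference build is contaminated.
* **Prevalence**: fractions of levels with |z| above 2 and 3 (a score of 2 is
  just outside the 95% interval; 3 is definitively abnormal).  One-sided
  fractions are reported alongside because "scores > 2" is ambiguous between
  the absolute and the signed reading; the absolute version is the default.
* **Age model**: expected standardized average disc height follows
  `zAvgDH = b0 * exp(b1 * age)`, with reference coefficients b0 = -0.0037,
  b1 = 0.078 (per year).  Note these printed coefficients evaluate to -1.19
  at age 74 while the source narrative quotes -1.4 for that age; the
  coefficients are evidently rounded.  spondyref evaluates with the printed
  values and does not attempt to reconcile the two.  `fit_age_model()` refits
  by Levenberg-Marquardt nonlinear least squares (start
  `b0 = sign(mean z)*0.001, b1 = 0.05`).

## The SpondyIndex

Z-scoring raw SPO against a neutral-position reference fails on
flexion-extension exams: SPO depends strongly on disc angle, and a reference
built from a narrow angle range cannot be extrapolated (the acceptance test
reproduces this: ~55% of truly normal flexed levels exceed |z| = 2).  The
SpondyIndex instead *predicts* normal SPO from disc geometry and scales the
residual:

    SI = (observed SPO - predicted SPO) / residual SD(level)

The prediction is an OLS regression of ASPO (anterior index) or PSPO
(posterior index) on disc area, EPWR, the two disc heights, and level
indicators, trained on radiographically normal levels from wide-angle
flexion-extension exams.  Disc angle itself is excluded as a predictor: the
two disc heights carry the angle information, and the source analysis found
dropping the angle costs almost no explained variance.  One pass of outlier
exclusion at |studentized residual| > 3 precedes the final fit; per-level
residual SDs provide the scale, so the index is mean-0/SD-1 on its training
set by construction.  The exact regression form (predictor set, indicator
coding, the single trimming pass, the cutoff) is this package's
reconstruction — the original appendix is not reproduced here — and every
choice is exposed as an argument.  An SI > 2 lies above the 95% interval for
normal SPO; a posterior SI > +2 suggests retrolisthesis.  Models serialize
to versioned JSON and a deserialized model predicts identically.

Per-spine summaries take the maximum anterior SI, maximum posterior SI and
minimum zAvgDH over available levels; `outcome_association()` relates them
to a binary outcome by univariable logistic regression, reporting the odds
ratio per unit, p value, and McFadden pseudo-R² (the pseudo-R² convention is
fixed and labeled, since the source's R² type is unstated).

## Synthetic population generator

Every stage is testable without any radiograph because the generator draws
landmark populations with the statistical structure the analysis assumes.
Conditions (all config-exposed, all engineering choices):

* **Normal metrics** per level: average disc height 30 (SD 4) %EPW; disc
  angle graded -2 to +12 degrees (SD 3) from L1L2 to L5S1 (side-lying
  posture); EPWR 1.00 (SD 0.03); height/width 0.60 (SD 0.05).
* **SPO structural model**, shared between the side-lying and
  flexion-extension generators because a single model of normal SPO across
  positions is the premise of the SpondyIndex:
  `aspo = a0(level) + 5*disc_area + 0.25*adh - 0.25*pdh + N(0, 1.5)` and the
  mirrored form for PSPO.  Intercepts are centred at each level's typical
  geometry, so normal SPO means are near zero and the realized marginal SD is
  ~2 %EPW.  There is deliberately no EPWR term: a pure translation slip
  leaves endplate widths unchanged, so the EPWR predictor's true coefficient
  is zero.
* **Degeneration** (prevalence 0.3): graded severity s ~ U(0.5, 1.5) scales a
  mean -3 SD height shift; the osteophyte/sclerosis flag fires with
  probability min(1, 0.8 s) — mild narrowings are the ones the grader
  misses — with a 5% false-positive rate among normals.  Degenerated levels
  also draw their SPO residuals, disc angle, EPWR and height/width deviations
  with a 5x SD multiplier (2.5x--3.5x on heights): osteophytes and irregular
  endplates corrupt every landmark-derived metric, and this is what gives the
  pre-trim population the heavy tails that make trimming worthwhile.  A
  contaminant that only shifted heights would leave the other gating metrics
  exactly Gaussian, and hard trimming of a clean Gaussian at 1.96 SD
  necessarily leaves kurtosis near 2.4 — nothing like the near-normality the
  trimmed real data show.
* **Age**: ages 25-74 skewed older (beta(2,1)); the exponential age model
  above shifts the avg_dh z draw.
* **Injection**: labeled anterolisthesis/retrolisthesis replaces the level's
  SPO residual with `shift * sigma` (default 3), so the true offset exceeds
  the normal prediction by exactly the configured amount.  Replacement, not
  addition, is what makes a "+3 residual-SD slip" a well-defined ground
  truth.
* **Flexion-extension pairs**: each subject gets both exams; disc-intrinsic
  draws are shared, the disc angle is uniform on -8..+5 (flexion) or +5..+18
  (extension) degrees, and the SPO residual is redrawn per exam (neutral-zone
  repositioning).

`metrics_to_landmarks()` inverts the method-1 construction exactly.  The four
corner targets (ADH, PDH, ASPO, PSPO) pin both inferior corners of the
superior vertebra, which fixes its inferior endplate width; the EPWR target
therefore governs its *superior* endplate, and the measured EPWR equals the
implied value `sqrt((1+(aspo+pspo)/100)^2 + ((adh-pdh)/100)^2)` — an identity
the round-trip tests assert in closed form.  The drawn disc angle is realized
exactly by a short fixed-point pass, because the height split depends on the
along-endplate extent `100 + aspo + pspo`, whose SPO sum is itself
along-independent by the symmetry of the structural coefficients.  Whole
spines are chained bottom-up from a rectangular S1 so adjacent levels share
their common vertebra in one global frame; method-2 metrics are not
independently targetable and simply emerge from the construction.

What the generator does **not** emulate: landmark digitization error,
vertebral shape beyond four corners (endplate curvature, osteophyte
geometry), pelvic parameters, facet anatomy, and any image content.  Passing
tests therefore demonstrate the correctness and calibration of the
*pipeline*, not clinical performance on radiographs.

## Projection-error study

A two-vertebra level is extruded laterally by ±half-width (default half the
endplate width) into a 3D phantom, posed by rotations about the vertical
(axial) and anterior-posterior (coronal) axes, and projected from a point
source (default source-detector distance 1016, object-detector 150, in
landmark units) onto the detector plane.  Left/right corner pairs are
collapsed to single landmarks by their midpoint (a nearest-corner variant is
available), the collapsed level is re-measured, and |measured - true| is
standardized by the level-specific reference SD.

At zero out-of-plane pose the divergent beam multiplies every collapsed
landmark by the same factor (all mid-sagittal corners share one depth), so
the %-EPW and angular metrics are exact to machine precision at any
magnification — the control row of the study.  Out-of-plane poses bias the
collapsed landmarks; the study grid (default 0-20 degrees on both axes, the
acceptance run uses the diagonal) shows monotonically growing median errors,
with 95th-percentile standardized errors beyond 0.5-2.5 SD at 20 degrees.
The published experiment's specific error figures are not reproducible here
(its projection geometry and pose distribution are not in the main text);
the study reports its own table and checks only the qualitative signature:
zero at ideal projection, up to the order of one reference SD when badly out
of plane.

## Problem sizes and numerical choices

The validation suite uses the sizes it states rather than the full survey
scale: 10,000 subjects per level stratum for the trimming study, 100,000
held-out levels for score calibration, 2,000 training levels for the
SpondyIndex, 200 phantoms across the pose grid, 30,000 points for the age
fit.  Tolerances: geometric identities at 1e-9; near-parallel midplanes
switch the bisectrix to the midway line below 1e-6 rad; degenerate endplates
(coincident corners) and infeasible generator targets raise errors rather
than producing values.  Trimming audits conserve rows exactly
(removed + kept = input) and attribute each removal to its first triggering
rule, with the full violation list alongside.

## Known limitations

* The reference tables produced here describe the synthetic population, not
  any real cohort; applying the pipeline to real landmarks requires real
  reference data built with the same code.
* After trimming, the height-linked metrics' kurtosis sits near 2.8 rather
  than 3.0: a doubly-truncated Gaussian at the effective ±3 SD cut cannot do
  better, which quantifies how much of the real data's post-trim normality
  depends on the contaminant structure rather than the trimming rule alone.
* The SpondyIndex regression is a reconstruction; its predictive form is
  validated only against the generator's structural model.
* Landmark-level digitization noise is out of scope; the projection module
  quantifies pose-induced error only.
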