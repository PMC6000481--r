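---
title: "Quantifying test-retest reproducibility of body-map symptom drawings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying test-retest reproducibility of body-map symptom drawings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodymapr)
```

## The measurement model

A digital symptom drawing is a set of per-view rasters: for each of four
body views (front, back, left, right) a patient shades the regions where a
symptom is felt, with a 0–10 visual-analog-scale (VAS) intensity recorded
per pixel. Drawing is meaningful only inside the body outline, so every
raster is paired with a binary interior mask and all metrics are restricted
to it. A patient may enter several symptoms, each with its own textual
specification (descriptors, depth categories, VAS range, burden) and its
own per-view maps.

The package's core assumption, shared by the field's reproducibility
studies, is that for *pattern-level* analysis the multiple symptoms of one
drawing can be collapsed into a single map per view by taking the
**maximum VAS at each pixel** (`mergeSymptomMaps()`): where two symptoms
overlap, the stronger one defines the pixel. Three consequences matter:

- the merge is commutative, associative and idempotent, so symptom entry
  order is irrelevant (property-tested);
- presence/absence metrics (extent, clusters, overlap) are invariant to the
  merge beyond the union of the supports, because binarization at
  threshold 0 commutes with it;
- intensity-weighted overlap is deliberately *not* offered: overlap here is
  a claim about **where** symptoms are, not how strong they are.

## Test-retest metrics

For a drawing pair of one patient, `analyzePair()` computes per view:
extent (drawn pixels), cluster count (connected components of the
binarized map), intersection, union and the Jaccard index. Whole-drawing
extent and cluster totals are sums over included views; the whole-drawing
Jaccard **pools pixels** across included views into one ratio rather than
averaging per-view ratios — a patient who draws one large and one tiny view
should not have the tiny view dominate the average. Per-view values and
their max/mean are also reported, since both granularities are informative.

Two readings of the view-exclusion rule are defensible; the package decides
it explicitly and exposes the alternative:

- default (`excludeWhen = "both"`): a view is excluded only when blank in
  *both* sessions. A view drawn once and forgotten once stays in with
  Jaccard 0 — forgetting a body view is itself a reproducibility failure;
- `excludeWhen = "either"`: the lenient reading, excluding any view not
  used in both sessions.

A Jaccard ratio with empty union is undefined and propagates as `NA`,
never as 0 or 1; cohort means report the number of contributing patients.

### Cluster connectivity

Connected components are counted under 8-connectivity by default — the 2-D
analogue of the 26-neighbourhood convention of the neuroimaging cluster
tools this analysis style descends from — with 4-connectivity as an option.
The choice is consequential (diagonally touching blobs merge under 8,
split under 4) and is therefore surfaced in the CLI (`--connectivity`).
Both variants are verified against an independent flood-fill oracle in the
test suite.

## Agreement statistics

**ICC(3,1).** Reliability of extent and cluster counts across a cohort is
the Shrout–Fleiss two-way mixed, single-measure, *consistency* intraclass
correlation: patients are random, the two sessions fixed, and a constant
session shift is not penalised. From the two-way ANOVA mean squares,

\[
\mathrm{ICC} = \frac{MSR - MSE}{MSR + (k-1)\,MSE},
\qquad F = MSR/MSE,
\]

with the conventional F-based confidence bounds
\(F_L = F / F_{1-\alpha/2}(n-1,(n-1)(k-1))\),
\(F_U = F \cdot F_{1-\alpha/2}((n-1)(k-1),n-1)\), each mapped through
\((F-1)/(F+k-1)\). Degenerate inputs are handled explicitly: a perfectly
consistent matrix (MSE = 0, subject variance present) returns ICC 1 with a
[1, 1] interval; a constant matrix has no variance to apportion and is an
error rather than a silent 0 or 1. The implementation is required by its
tests to match a brute-force `lm`/`anova` computation to 1e-10 and to be
invariant to per-session constant shifts.

**Bland–Altman.** Pair differences against pair means, with limits of
agreement mean ± 1.96·SD using the literal normal quantile, per the
original convention; a percent-of-mean mode serves the common situation
where the spread of differences grows with the drawn area. Percent mode
refuses pairs with zero mean instead of producing infinities.

**Summary t tests and chi-square.** Usability tables print (n, mean, SD)
triples; `tTestFromSummary()` reconstructs the two-tailed two-sample test
from them. The default is the pooled-variance Student test — the
unqualified "t test" of the literature this serves — with Welch available;
for the published comparisons this package re-derives, both variants round
to the same reported p values. The chi-square for count tables is Pearson's
without continuity correction, which is what reproduces the printed
p values of the demographic comparisons this targets; the Yates-corrected
statistic does not.

**Sample-size planning.** The expected width of the ICC confidence
interval at planning value ρ with k sessions and n subjects,

\[
w(n) = 2\, z_{1-\alpha/2}\, (1-\rho)\,(1+(k-1)\rho)\,
\sqrt{\frac{2}{k(k-1)n}},
\]

is inverted by `iccSampleSize()` to the smallest integer n (≥ 2) with
w(n) ≤ target; the closed-form inverse is guarded on both sides of the
integer boundary, and tests enforce w(n) ≤ width < w(n−1). At ρ = 0.95,
k = 2, a 0.1-width target gives n = 15; at ρ = 0.92, n = 37 — planning is
very sensitive to ρ near 1, which is why the anticipated reliability must
come from prior studies, not hope.

**p-value formatting.** `formatP()` follows the common journal style (two
decimals, three below .01, no leading zero, "<.001" floor), so recomputed
values can be compared with printed ones at the precision they were
printed.

## The synthetic cohort generator

No clinical drawings ship with the package, so `generateCohort()` exists as
a first-class, tested module that defines the simulated study conditions.

**What it emulates.** Each patient draws 1–3 symptoms. Per view, the number
of drawn clusters follows a negative binomial whose per-view means and SDs
default to values reported for chronic-pain outpatient cohorts (front
5.5 (SD 7.3), back 4.9 (5.7), left 4.5 (5.2), right 4.2 (5.4)); the strong
overdispersion produces both blank views and heavily marked patients, which
exercises the view-exclusion rule and creates realistic between-subject
extent variance. A cluster is a union of 1–3 filled disks at a single VAS
level, placed at a uniformly sampled interior pixel; clusters may merge by
overlap, so the drawn-cluster count is an upper bound on the connected
component count, as with real patients. The retest drawing reuses the test
clusters under a perturbation model: Gaussian centre translation
(`translationSigma`, px), signed radius change (`boundarySigma`, px),
per-cluster dropout and per-view addition probabilities — the latter two
modelling forgotten and newly remembered regions.

**Default calibration.** The canvas is 320 × 200 px per view, the 1.6
aspect ratio of the 800 × 1280 acquisition tablets scaled down for
simulation speed; extents scale quadratically with canvas but all ratio
and correlation metrics are scale-free. The blob radius is log-normal with
median 10 px. `translationSigma = 5` px was chosen from the closed-form
overlap of two equal disks: a centre offset around half a radius gives a
per-cluster Jaccard near 0.45, the middle of the partial-overlap regime
test-retest studies of pain drawings report; dropout and addition default
to 0.05 each, and `boundarySigma = 1` px adds mild boundary noise. Under
these defaults a 25-patient cohort lands at a mean whole-drawing Jaccard
near 0.5 with extent ICC above 0.9.

**Determinism.** One master seed; per-patient substreams are split
arithmetically by patient index, so regenerating a cohort is byte-stable
and *extending* it never changes earlier patients. `generateOutline()` is
purely deterministic in (view, dims).

**What it does not emulate — and what passing tests therefore do not
show.** Silhouettes are schematic (rectangles, ellipses), not anatomical;
there are no dermatome-shaped or radiating patterns, no correlation between
symptom descriptors and location, no doctor-vs-patient concordance
structure, and the perturbation model is stationary across patients. Tests
passing on this cohort validate the *pipeline arithmetic* — merging,
counting, overlap, ICC — under realistic magnitudes; they say nothing about
how real patients redraw their pain.

## Numerical and design choices

- Rasters are row-major, origin top-left; the real-acquisition canvas
  default is 800 × 1280 (a common tablet resolution), configurable — the
  drawable resolution is a convention of this package, not a property of
  the drawings themselves.
- VAS values are stored as integers 0–10; slider input is rounded half-up
  (`vasRound()`), so 2.5 becomes 3, avoiding R's round-half-even surprise
  at ingestion boundaries.
- PNG serialization uses a single-channel 8-bit level `round(255·VAS/10)`;
  nearest-level decoding makes the round trip lossless, which is proven by
  test rather than assumed. A saturation decoder (HSV saturation → VAS,
  configurable transfer curve) accepts colour exports whose intensity was
  encoded as saturation.
- NIfTI export writes a rows × cols × 1 volume with identity affine and
  nominal 1 mm spacing: a carrier format for cluster-tool interop, not a
  spatial claim.
- Out-of-outline ink is a *reported violation* (`validateDrawing()`), never
  silently clipped: the acquisition app prevents it at source, so its
  presence in a file is diagnostic of a provenance problem.
- Binarization threshold defaults to 0 (any ink counts); it is exposed for
  sensitivity analyses but the shipped metrics never apply an intensity
  cutoff.

## Problem sizes

The test suite runs oracle comparisons on hundreds of small random rasters
and matrices (up to 16 × 16 pixels, n ≤ 12 subjects), Monte-Carlo checks on
100–500 replicates (ICC recovery at n = 25 and n = 200; Jaccard
monotonicity at 100 pairs per perturbation setting on 128 × 80 canvases),
and full-pipeline runs on 25-patient cohorts at the default 320 × 200
canvas. These sizes were chosen so the whole suite completes in about a
minute while keeping Monte-Carlo standard errors well inside the asserted
bands.

## Known limitations

- Only ICC(3,1) is provided; absolute-agreement and average-measure forms
  (2,1), (k) are out of scope, as are repeated-measures models beyond two
  sessions (the ANOVA core accepts k > 2, the pipeline is built for pairs).
- No multiple-testing correction is applied to per-item usability
  comparisons, matching the descriptive reporting style they come from.
- No registration or resampling between differently sized outlines: pairs
  must share one outline set, and cross-study comparisons at different
  resolutions are the user's responsibility.
- The AttrakDiff item map ships with a standard order and all-positive
  polarity; deployments with randomised or reversed item presentation must
  supply their own map file.
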