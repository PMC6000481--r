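# bodymapr

Quantitative analysis of digital body-map symptom drawings.

Pain and related bodily symptoms are often recorded by asking patients to
shade the affected regions on an outline of the human body. When such
drawings are acquired digitally — here on four views (front, back, left,
right) with a per-pixel 0–10 visual-analog-scale (VAS) intensity — their
location, extent and stability can be quantified instead of eyeballed.
`bodymapr` is for researchers who run or re-analyse test–retest
reproducibility studies of such drawings, and for methodologists who need a
controlled synthetic cohort to validate an analysis pipeline before (or
instead of) touching clinical data.

## What it computes

For a pair of drawings by the same patient, the package merges multiple
symptoms per view by the pixelwise **maximum VAS**, restricts everything to
the body-outline interior, and derives per view and pooled over views:

- **symptom extent** — number of drawn (nonzero) pixels;
- **cluster count** — connected components of the binarized drawing
  (8-connectivity by default, 4 available);
- **overlap** — intersection, union, and the Jaccard index
  `J = |A ∩ B| / |A ∪ B|` of the two presence masks.

Views left blank in both sessions are excluded; a view drawn in only one
session stays in with Jaccard 0. Cohort-level agreement uses:

- **ICC(3,1)** (Shrout–Fleiss two-way mixed, single measure, consistency):
  `ICC = (MSR − MSE) / (MSR + (k−1)·MSE)` with a 95% CI from the F ratio
  `MSR/MSE`;
- **Bland–Altman** limits of agreement `mean(d) ± 1.96·SD(d)`, absolute or
  in percent of the pair mean;
- **two-sample t tests from summary statistics** (pooled or Welch) and the
  uncorrected Pearson **chi-square**, for usability-table re-analysis;
- **ICC sample-size planning** from the expected CI width
  `w(n) = 2·z·(1−ρ)(1+(k−1)ρ)·√(2/(k(k−1)n))`;
- scoring of the **SUS** (0–100), **AttrakDiff 2** (4 subscales, −3..3) and
  **ISONORM 9241/10** (7 categories, −3..3) usability instruments.

A synthetic cohort generator (`simParams()`, `generateCohort()`) draws
test–retest pairs with known ground truth — negative-binomial cluster counts
per view, disk-union blobs, and a retest perturbation model (translation,
boundary noise, cluster dropout/addition) — so every stage of the pipeline is
testable without patient data.

## Worked example

```r
library(bodymapr)

params  <- simParams(nPatients = 8, seed = 42)   # defaults = study conditions
cohort  <- generateCohort(params)
results <- lapply(cohort, function(p) analyzePair(p$test, p$retest))
s <- cohortSummary(results)

cat(sprintf("Mean Jaccard: %.3f (SD %.3f)\n", s$jaccardMean, s$jaccardSD))
#> Mean Jaccard: 0.490 (SD 0.079)
subset(s$icc, scope == "whole")
#>  scope   metric n       icc     ciLow    ciHigh
#>  whole   extent 8 0.9313946 0.6986218 0.9858775
#>  whole clusters 8 0.9833275 0.9194066 0.9966397
blandAltman(s$patients$extent1, s$patients$extent2)
#> Bland-Altman (absolute): mean diff 360.250, LoA [-1622.363, 2342.863]
```

The mean Jaccard near 0.5 says consecutive drawings overlap on about half of
their union — substantial repositioning of ink, even though the *amount*
drawn per patient is highly stable (extent ICC 0.93, i.e. between-patient
differences dwarf within-patient test–retest noise). The Bland–Altman limits
quantify how far a single patient's two extents may drift apart.

The statistics are available directly:

```r
icc31(rbind(c(1, 2), c(2, 4), c(3, 6)))
#> ICC(3,1) = 0.800, 95% CI [-0.625, 0.994] (n = 3, k = 2)
tTestFromSummary(3.38, 2.89, 52, 1.86, 2.16, 51)
#> Two-sample t test (pooled): t = 3.019, df = 101.0, p = .003
iccSampleSize(rho = 0.95, k = 2, width = 0.1)
#> [1] 15
```

## Command line

A thin CLI wraps the same functions (see `?bodymaprCLI`):

```sh
Rscript inst/cli/bodymapr.R simulate --seed 1 --patients 25 --out cohort/
Rscript inst/cli/bodymapr.R repro --in cohort/ --out results/cohort
Rscript inst/cli/bodymapr.R samplesize --rho 0.95 --k 2 --width 0.1
```

`repro` writes `<prefix>_patients.csv` (one row per test–retest pair:
patientId, extent1/2, clusters1/2, intersection, union, jaccard,
jaccardMeanViews, jaccardMaxViews), `<prefix>_summary.csv` (Jaccard mean/SD
plus the ICC block, rows ordered whole/front/back/left/right by metric), and
Bland–Altman points/plots.

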