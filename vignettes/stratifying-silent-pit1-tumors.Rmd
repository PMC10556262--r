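---
title: "Stratifying silent PIT1-lineage pituitary tumors from digital pathology"
author: "PitDIA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying silent PIT1-lineage pituitary tumors from digital pathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PitDIA)
```

## The problem

Silent PIT1-lineage pituitary neuroendocrine tumors (PitNETs) stain for
the PIT1 transcription factor — and variably for its lineage hormones GH,
PRL and TSH — without clinical or biochemical hormone excess.  A subset
behaves aggressively, but the histological criteria separating that
subset (nuclear pleomorphism, focal or absent hormone staining) are
subjective enough that pathologists frequently disagree.  PitDIA
implements an objective, reproducible alternative: quantitative cell
morphometry and quantitative immunostaining, each clustered without
supervision, combined into a three-tier recurrence-risk profile.

The pipeline has two inputs: per-cell measurements (either computed by
the imaging stage from RGB slide images, or supplied as tables) and a
per-patient follow-up record.  Its output is, per patient, a morphology
cluster (MC1/MC2), per-hormone staining calls, one of eight staining
subtypes, an immunostaining cluster (IC1/IC2), and the combined risk
tier, plus cohort-level survival and comparison statistics.

## Stain model and imaging stage

Brightfield stains absorb light log-linearly (Beer-Lambert), so an
8-bit pixel is converted to optical density per channel as
$OD = -\log_{10}(\max(I, 1)/255)$, and the OD of a pixel is the
concentration-weighted sum of unit stain vectors:
$OD = c^\top M$.  With a fixed, invertible $M$ (`heStainMatrix()`,
`hdabStainMatrix()` — the standard published H&E and H-DAB vector sets),
`deconvolve()` recovers per-stain concentrations exactly for any
nonnegative mixture; negative solutions (noise outside the stain
simplex) are clipped to zero and reported.  Automatic stain-vector
estimation is deliberately out of scope: any estimator re-calibrates
itself per slide and makes downstream numbers irreproducible; users with
calibrated vectors can pass their own `stainMatrix()`.

Nucleus detection (`detectNuclei()`) is a transparent
threshold-plus-split detector on the haematoxylin channel: Gaussian
smoothing (sigma 1.5 px), fixed OD threshold 0.15 (Otsu fallback when
the fixed threshold selects nothing), hole filling, 4-connected
labelling, optional distance-transform watershed to split touching
nuclei, and an area filter of 10–400 µm².  The defaults are stated
choices, not estimates of any particular scanner or software
configuration; all are exposed in `detectionParams()`.  Cells are
reconstructed from nuclei by constrained Voronoi dilation
(`expandCells()`): each nucleus grows outward up to the expansion radius
(default 2.5 µm) and stops at the equidistance line between competing
nuclei, ties broken toward the lower label so results are deterministic.
DAB quantification subtracts the mean nuclear OD from the mean
cytoplasmic OD per cell (`perCellIntensity()`), suppressing nonspecific
nuclear signal that otherwise inflates positivity; the raw difference is
kept alongside the zero-clipped value.

## Morphometry: 13 features, 39 per patient

For every nucleus and its cell, `shapeDescriptors()` measures area,
perimeter, circularity $4\pi A/P^2$, maximum and minimum Feret (caliper)
diameter, and moment-based eccentricity $\sqrt{1-(b/a)^2}$; the
nucleus-to-cell area ratio is the thirteenth feature.  Two numerical
choices matter:

* **Perimeter** is the length of the traced marching-squares contour
  after a circular moving-average smoothing (window 5 vertices).  A raw
  pixel-edge perimeter overestimates a disc's boundary by ~27% and a raw
  staircase contour by ~7%, which would corrupt circularity — the most
  discriminative feature downstream.  The smoothed estimator is accurate
  to <0.5% on discs and ellipses across the nucleus size range.
* **Calipers** are computed on the convex hull of pixel centres by
  rotating calipers, matching a brute-force sweep over 1° rotations to
  <0.5%.

`aggregatePatient()` reduces each feature to its mean, 25th and 75th
percentile (linear interpolation between order statistics — the default
convention of the major statistical environments; the source material
for this scheme does not state one), giving the fixed-order 39-feature
patient vector of `patientFeatureNames()`.

## Morphology clustering

Patient vectors are z-scored column-wise (`standardizeFeatures()`;
zero-variance columns dropped with a warning) and fitted with Gaussian
finite mixtures over component counts 1–5 and four covariance families
— spherical, diagonal, tied, full — selecting the model that minimises
$BIC = p\ln n - 2\ln L$ (`fitGmmBIC()`).  The EM machinery is mclust's,
with its deterministic model-based hierarchical initialisation; the four
families map onto the mclust parameterisations EII/VII, EEI/VVI, EEE and
VVV.  Note the sign convention: mclust maximises the negation of this
quantity; the two are equivalent and the package reports the minimised
form to match the phrase "lowest BIC".

On 39 strongly correlated dimensions at cohort scale (n ≈ 10²) the
globally best BIC model is often a single full-covariance component,
because an unconstrained covariance can absorb bimodality along a few
directions at lower parameter cost than a second component.  The
morphological dichotomy is nevertheless the object of interest, so
`assignMC()` uses the best two-component model (refitting one if the
selected K differs, with a message) and names **MC2** as the cluster
with the larger mean nucleus max-caliper — the enlarged, pleomorphic
phenotype — making the naming invariant to arbitrary EM component ids.
Cluster tightness and separation are summarised on the correlation
distance $D_{ij} = 1 - r_{ij} \in [0, 2]$ (`separationSummary()`), and a
seeded exact t-SNE (`tsneEmbed()`, perplexity 10) is provided for
visualisation only — nothing downstream consumes it.

## Immunostaining scoring

Per hormone, each cell's nucleus-corrected DAB OD is binned
negative/weak/intermediate/strong at thresholds 0.2 / 0.4 / 0.6 OD
(`intensityBins()`, right-closed).  The thresholds follow the common
weak/moderate/strong convention of cell-detection software and are
configurable, since no universal calibration exists.  Three scoring
systems are implemented on the bins:

* **Allred** (`allredScore()`): proportion score 0–5 on the classical
  cut-points (0, ≤1%, ≤10%, ≤1/3, ≤2/3, >2/3), intensity score 1–3 as
  the mean bin over positive cells rounded half-up, total TS = PS + IS
  with exactly eight attainable values {0, 2–8}.  Positive requires
  TS > 3 **and** >5% stained cells; the second guard keeps focal
  staining of entrapped normal pituitary from flipping a call.
* **H-score** (`hScore()`): $1\cdot pct_1 + 2\cdot pct_2 + 3\cdot
  pct_3 \in [0, 300]$, positive when >5.
* **Percentage** (`percentageCall()`): percent of cells with any
  staining, positive when >10%.

All positivity comparisons are strict inequalities.  The Allred rule
drives subtyping by default; the two alternatives are retained because
their disagreement structure is informative — against the percentage
rule, disagreement is exactly the band of 5–10% positive cells with
TS > 3.  One property worth knowing: the Allred total is *not* monotone
under recruiting additional weakly-positive cells, because a weak
recruit can pull the averaged intensity score down a rounding boundary
while the proportion bin is unchanged.  That is inherent to the
classical definition (the tests pin the counterexample); H-score and
percentage are monotone under any bin increase.

The three per-hormone booleans map bijectively to eight subtypes (GH,
PRL, GH+PRL, TSH, GH+TSH, PRL+TSH, GH+PRL+TSH, and PIT1 for
triple-negative).  **IC1** comprises GH, PRL and GH+PRL; every
TSH-containing subtype and the triple-negative subtype form **IC2**,
the group enriched for aggressive behaviour.

## Risk tiers and survival

`assignTier()` is the exhaustive 4-to-3 mapping: low = MC1 and IC1,
high = MC2 and IC2, medium = the two discordant combinations.  Survival
is standard right-censored machinery via the survival package behind
thin surfaces: product-limit curves with log-log Greenwood intervals
(`kmCurve()`, `rfsAt()`), the log-rank test (`logrankTest()`), and Cox
proportional hazards with Efron tie handling and Wald intervals
(`coxHR()`); Breslow is available, and the two agree to numerical
precision on tie-free data.  Monotone likelihood (complete separation
of events) is flagged rather than reported as an estimate.

Cohort tables (`buildCohortTable()`) follow clinical convention:
"n (xx.x%)" or "mean (sd)" cells, Yates-corrected chi-square for 2×2
cross-tabs, plain Pearson chi-square for larger tables, Welch t-test
for two-group continuous comparisons (one-way ANOVA beyond two).  The
Yates statistic clamps the correction at zero so exactly proportional
tables give p = 1.  `referenceContingencyTables()` embeds the published
reference-cohort cross-tabs (146 patients; MC 119/27, IC 68/78, tiers
57/73/16), and `referenceCohortStats()` recomputes their p-values from
the counts — the package's deterministic regression anchor.  No
multiple-testing correction is applied in these tables, matching the
convention they reproduce; `p.adjust` (BH or Bonferroni) can be applied
by the user for feature screens.

## The synthetic cohort generator

No public slide or patient-level data exist for this tumor entity, so
the package validates itself on synthetic cohorts with known ground
truth (`generateCohort()`, `renderSlides()`).  The generator emulates
exactly the statistical structure the analysis assumes:

* **Two morphological phenotypes.**  Cells are ellipses; the regular
  phenotype draws nucleus equivalent diameters around 7.0 µm (sd 0.7)
  with near-unity axis ratios (log-normal, median 1.15), the aggressive
  phenotype around 9.5 µm (sd 1.3) with axis ratios around 1.7 and
  three times the spread — enlarged, eccentric, pleomorphic.  A
  patient-level random effect (sd 0.45 µm) keeps cells within a patient
  correlated.  The aggressive prevalence defaults to 27/146 ≈ 18.5%,
  the reference cohort's MC2 fraction.
* **Eight staining subtypes** at the reference cohort's frequencies
  (24, 13, 31, 8, 20, 7, 20, 23 of 146 for GH, PRL, GH+PRL, TSH,
  GH+TSH, PRL+TSH, GH+PRL+TSH, PIT1).  A positive hormone stains 50% of
  cells with intensity bins distributed 15/45/40% across weak/
  intermediate/strong at OD levels 0.30/0.50/0.75; a negative hormone
  retains a 1% weak residual; nonspecific nuclear DAB sits at 0.05 OD.
  These levels are chosen so that binning at the default thresholds
  recovers the intended bins and the Allred calls recover the subtype.
* **Recurrence times** are exponential with tier hazards
  $\lambda_0 e^{\beta}$: baseline 0.03/yr (4-year recurrence-free
  survival ≈ 89%, the benign end of the published range), log-hazard
  increments log 3 (medium) and log 9 (high), a 6-year administrative
  horizon and 0.10/yr random censoring.  Exponential times keep every
  recovery check closed-form.
* **Slides.**  `renderSlides()` places cells by dart-throwing with
  bounded retries (failure is an explicit error), composes haematoxylin,
  eosin and DAB concentrations through the Beer-Lambert model on a
  white 8-bit canvas (0.25 µm/px), and returns the nucleus/cell label
  masks and a tumor/stroma/hemorrhage region mask as ground truth.
  Rendering with `quantize = FALSE` is exactly invertible by
  deconvolution; quantised output differs by at most one 8-bit step.
* **Cohort covariates.**  Stromal fraction and two aggressiveness
  indicators (giant tumor, suprasellar extension) are drawn with
  tier-dependent rates in the vicinity of the published per-tier
  proportions, so the cohort-statistics stage has realistic targets.

What the generator does **not** emulate: chromatin texture, tissue
architecture, scanner noise and compression, slide-to-slide staining
drift, segmentation-error correlation, or non-exponential hazards.
Passing tests therefore demonstrate that the pipeline recovers known
structure through its own imaging, scoring and clustering mathematics —
not that it would achieve the same accuracy on scanned human slides.

## Pipeline and reproducibility

`runPipeline()` executes simulate → (segment) → features → score →
cluster → stratify → stats → report; a single global seed derives
per-stage seeds, and a rerun with the same configuration reproduces
every artifact byte-for-byte.  By default patient features come from
the generator's analytic per-cell tables; `render_n` routes that many
patients through rendered slides and the full imaging chain instead, as
an integration check — rendering all patients adds runtime but no
statistical information, since the imaging chain's accuracy is
established on dedicated slides.  Artifacts (CSV at 12 significant
digits, JSON reports, a manifest with seed and per-stage row counts)
are written when `outdir` is given.  A thin command-line wrapper with
subcommands lives at `system.file("scripts/pitdia", package =
"PitDIA")`.

Problem sizes used by the test suite and the acceptance script — a
120-patient default cohort (~300 cells each), 25-nucleus rendered
slides, n = 200–500 mixture benchmarks, 20-seed survival replicates at
150–300 patients per arm, and a 2,000-patient closed-form KM check —
were chosen so every recovery check has comfortable statistical power
while the whole suite runs in minutes on one core.

```{r example}
run <- runPipeline(cohortConfig(n_patients = 60,
                                cells_per_patient = c(80L, 120L),
                                seed = 1), embed = FALSE)
run
run$confusion
run$survival$hr_tier
```

## Known limitations

* Stain vectors are fixed; slides stained far from the standard H&E /
  H-DAB calibration need user-supplied vectors.
* The detector is threshold-based; heavily overlapping nuclei beyond
  what the watershed separates will be merged or dropped by the area
  filter.
* The three-tier mapping presumes the two-cluster structure exists; in
  a cohort without a morphological dichotomy the forced two-component
  naming still labels an "MC2", and its hazard ratio should be read
  with that in mind.
* Hazard-ratio estimates on small tiers (few events) carry wide
  intervals; the pipeline flags non-estimable contrasts instead of
  extrapolating.
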