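# PitDIA — digital image analysis stratification of silent PIT1-lineage pituitary tumors

Silent PIT1-lineage pituitary neuroendocrine tumors stain for the PIT1
transcription factor (and variably for GH, PRL and TSH) without
clinical hormone excess. Some recur aggressively, but the histological
criteria that mark the aggressive subset — nuclear pleomorphism, focal
or absent hormone staining — are subjective, and pathologists often
disagree on them. PitDIA is an R package for neuropathology and
computational-pathology groups that turns that judgement into
reproducible arithmetic on whole-slide images (or precomputed per-cell
tables):

1. **Imaging** — Beer-Lambert optical density
   (OD = −log₁₀(I/255)), colour deconvolution OD = cᵀM with fixed
   H&E / H-DAB stain vectors, threshold-plus-watershed nucleus
   detection, Voronoi cell expansion, and per-cell DAB quantification
   with nuclear correction (cytoplasm mean OD − nucleus mean OD).
2. **Morphometry** — 13 shape features per cell (area, perimeter,
   circularity 4πA/P², max/min Feret calipers, moment eccentricity
   √(1−(b/a)²), for nucleus and cell, plus the nucleus/cell ratio),
   aggregated per patient as {mean, q25, q75} → a 39-feature vector.
3. **Morphology clustering** — z-scored vectors fitted with Gaussian
   finite mixtures across covariance families, model chosen by lowest
   BIC = p·ln n − 2·ln L; the two-component split is named MC1/MC2 by
   nucleus enlargement.
4. **Immunostaining scoring** — per-hormone Allred score (proportion
   0–5 + intensity 1–3; positive if total > 3 and > 5 % cells stained),
   H-score (0–300, positive > 5) and percentage (> 10 %); eight
   GH/PRL/TSH subtypes; IC1 = {GH, PRL, GH+PRL}, IC2 = the rest.
5. **Risk profile** — low (MC1∧IC1), high (MC2∧IC2), medium otherwise;
   Kaplan-Meier curves, log-rank tests and Cox hazard ratios (Efron
   ties) across tiers; Yates/Pearson chi-square cohort tables.

Because no slide-level data for this entity are public, the package
ships a first-class synthetic generator (`generateCohort()`,
`renderSlides()`) that emulates the two morphological phenotypes, the
eight staining subtypes at published cohort frequencies, rendered
H&E/IHC slides invertible by deconvolution, and tier-ordered recurrence
hazards — with full ground truth, so every stage can be validated end
to end. See the vignette (`vignettes/stratifying-silent-pit1-tumors.Rmd`)
for the model details and design rationale.

## Worked example

```r
library(PitDIA)
run <- runPipeline(cohortConfig(n_patients = 60,
                                cells_per_patient = c(80L, 120L),
                                seed = 1), embed = FALSE)
run
#> PitDIA pipeline run: 60 patients, 6153 cells
#>   clustering: K = 1 ( full ), MC2 = 8
#>   tiers: high=2, low=22, medium=36
#>   tier agreement with ground truth: 100.0%
run$survival$hr_tier
#>        contrast        HR     lower     upper           p flagged
#> 1 medium vs low  2.938741 0.6434835  13.42101 0.164198157   FALSE
#> 2   high vs low 16.366111 2.1953057 122.01016 0.006387738   FALSE
```

Reading: the mixture's globally best BIC model on 39 correlated
features is a single full-covariance component (common at this n and
dimension), so MC naming falls back to the best two-component model —
the 8 MC2 patients are exactly the generated aggressive phenotype, all
60 risk tiers match ground truth, and the estimated recurrence hazard
rises monotonically across tiers (high vs low HR ≈ 16 here; the small
high tier makes the interval wide).

The deterministic anchor — recomputing the published reference cohort's
contingency statistics from its printed counts — is available directly:

```r
head(referenceCohortStats(), 3)
#>   grouping          variable    chisq            p
#> 1       mc       giant_tumor 9.980391 0.0015821606
#> 2       mc sphenoidal_clivus 8.017009 0.0046340035
#> 3       mc       suprasellar 14.38493 0.0001489901
```

A command-line wrapper with `run-all` / `simulate` / `segment` /
`stats` subcommands is installed at
`system.file("scripts/pitdia", package = "PitDIA")`.

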