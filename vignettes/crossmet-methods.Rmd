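---
title: "crossmet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{crossmet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmet)
```

`crossmet` implements a cross-species untargeted metabolomics analysis:
LC-HRMS feature-table preprocessing, metabolome-wide association testing in
a human cohort and in *C. elegans* tauopathy experiments, putative adduct
annotation, permutation-based pathway enrichment, direction-concordant
cross-species overlap, and worm phenotype derivations (extracellular-flux
respiration states, Kaplan–Meier survival). This vignette records the
models, the parameters that matter, and the design decisions taken where
the method description left the choice open.

## Preprocessing model

A feature table holds raw detector intensities, features as rows. `NA`
means "not detected"; zero is an observed value. The worm pipeline is
`blank_filter → missingness_filter_impute → glog_transform`; the human
pipeline is `detection_filter → glog_transform → batch_adjust`. The order
is fixed and recorded in the table's provenance. The human screen retains
well-detected features rather than imputing; the worm tables are imputed
because the downstream factorial tests need complete cells.

**Blank filter** (ratio 1.5, dimensionless). A feature is kept only if
every *observed* study intensity is at least 1.5× the summarised blank
intensity. Two points were open and are settled as follows. The blank
summary across blank replicates is the mean (configurable to max); and
because the blank rule runs before imputation, missing study cells cannot
be compared to the blank — the "all samples" quantifier ranges over
observed cells, with missing blanks treated as 0 (not detected in blank).
Features absent from the blank table are an error, never a silent pass.

**Missingness rule** (threshold 0.5). Features missing in ≥ 50% of samples
are removed; exactly 50% counts as removed (the description bounds "fewer
than 50%" for imputation and "more than 50%" for removal, leaving the
boundary unspecified — strictness is the conservative choice and is
documented here). Remaining missing cells become half the per-feature
minimum observed intensity; observed cells are never altered.

**Detection filter** (fraction 0.8 primary, 0.2 sensitivity). Strictly
greater than: a feature detected in exactly 80% of samples is removed.

**glog transform.** `glog(x) = log2((x + sqrt(x² + a²))/2)`, with
`glog(0) = log2(a/2)` and the log2 asymptote for `x ≫ a`. The scale
parameter `a` is not stated by the method being implemented; the default is
the per-table minimum positive intensity, recorded in provenance, so the
transform adapts to the detector's floor without user input.

**Batch adjustment.** Deliberately *not* an empirical-Bayes method: per
feature, each batch's values are centred and scaled to the pooled mean and
SD. After adjustment every batch mean equals the pooled mean exactly —
which also means a one-way ANOVA of intensity on batch finds nothing at
all (between-batch sum of squares ≈ 0, p ≈ 1 for every feature), a stronger
statement than null-uniformity and the one the test suite asserts. The
trade-off versus empirical-Bayes shrinkage: with small batches the
location/scale estimates are noisy and standardisation can slightly deflate
real signal; the cohort batches here are large (≈ 47 samples per batch at
the default 3 batches), where the difference is immaterial. Singleton
batches are refused. Whether batch adjustment runs before or after glog was
unstated; the pipeline fixes glog-then-adjust, since location-scale
standardisation is only meaningful on the stabilised scale.

## Association testing

`mwas_linear` fits, per feature, OLS of glog intensity on the outcome
(CSF p-tau, pg/mL) plus covariates (sex, age, analysis batch — the stated
covariate list; diagnosis is deliberately not included). The reported p is
the two-sided t test on the outcome slope. Complete features share one QR
decomposition; features with missing cells get complete-case refits, and
rank-deficient refits are flagged rather than dropped. With a single binary
predictor and no covariates the result equals a pooled-variance t test, a
property the suite checks to 1e-10.

`ttest_two_group` uses the Welch (unequal-variance) form — the method
description says only "multiple t tests", and Welch is the robust default.
The estimate is mean(group 2) − mean(group 1) with group order fixed by the
caller. Zero-variance degenerate features return t = 0, p = 1 when means
agree.

`anova_twoway` fits `y ~ A*B` per feature and reports type-II F tests
(`car::Anova`); the designs in scope are balanced, where the SS types
coincide. Tukey's HSD on the interaction cell means (studentized range,
ANOVA error term) is attached for features crossing the omnibus threshold.
Empty cells are an error identifying the cell.

No multiple-testing correction is applied by default — the downstream
pathway enrichment is designed for raw *P* < 0.05 feature lists — but a
Benjamini–Hochberg column is emitted for users.

## Annotation

Monoisotopic masses come from a packaged element table (CHNOPS, halogens,
Na/K/Se and the other symbols common ESI adducts need). Cationic adduct
shifts use the electron-corrected convention — proton 1.0072765 Da,
Na⁺ 22.9892207, K⁺ 38.9631581 (element mass minus one electron per positive
charge); anionic shifts add the electron back. This convention reproduces
the three printed mass-error anchors the acceptance script recomputes
(2 ppm, 9 ppm, 1 ppm after integer rounding); the neutral-atom convention
does not. The M+1 isotopologue spacing is fixed at 1.003355 Da (¹³C−¹²C)
per charge. Matching tolerance is 10 ppm, inclusive.

Confidence levels: 3 for a unique compound match, 4 for isobaric multiple
matches, 2 when an M+1 partner feature co-occurs (Δm/z = 1.003355/|z|
within tolerance, retention time within ±5 s — the co-elution window is
unstated upstream and configurable here), and 1 only with user-supplied MS2
evidence. Retention time is carried but plays no role in mass matching
itself. Two caveats inherited from the source material: the formula of the
dihydroxylated DDE derivative is inferred from its name (C14H8Cl4O2), and
the piperine acetonitrile–sodium row could not be anchored to a unique
mass convention, so it is not used as a test anchor.

## Pathway enrichment

Significant and reference feature lists are mapped to putative KEGG
compounds through the annotation module, ambiguity retained (one feature
may contribute several isobars, each counted once per pathway). For each
pathway, `hits` counts significant compounds in the pathway;
`expected = |pathway ∩ reference compounds| × |sig|/|reference|`; the
enrichment ratio is `hits/expected`. Significance comes from resampling:
`n_perm` draws of `|sig|` features without replacement from the reference
list, re-mapped, with `p = (1 + #{permuted ≥ observed})/(n_perm + 1)`.
The empirical form with the +1 correction is assumption-free; fitting a
gamma distribution to the permutation null (as mummichog does) would
extrapolate smaller p-values and is noted as a future option. The reference
universe is all features surviving preprocessing. Currency-metabolite
exclusion lists are not replicated.

## Cross-species overlap

A species result collapses significant (p < α), KEGG-annotated features to
one entry per KEGG ID. The direction is that of the minimum-p supporting
feature; if supporting features disagree in sign the ID is excluded with a
warning — never resolved by vote, because a sign conflict within one
compound usually signals an annotation problem, not evidence. The overlap
of two species results is the intersection on KEGG ID with equal signs;
discordant shared IDs are reported separately. Comparisons run pairwise
(worm vs plasma, worm vs CSF). Matching is on KEGG ID only; requiring the
same adduct in both species was considered and rejected since the two
platforms ionise differently. Overlap is symmetric, and monotone in α
except for IDs that turn direction-ambiguous as more features become
significant (the exclusion rule can then remove them — the test suite
checks monotonicity on the stable set).

## Phenotypes

The 18-measurement flux protocol is baseline 1–5, FCCP 6–14, azide 15–18.
Non-mitochondrial respiration is the azide-plateau mean (all four
measurements — whether a subset was used upstream is unstated); basal uses
measurements 2–5 only (measurement 1 is routinely unstable); maximal is the
FCCP mean minus non-mitochondrial; spare = maximal − basal; everything is
divided by worms per well. Negative derived states are flagged, not
clipped — clipping would bias group means upward.

Kaplan–Meier curves come from the product-limit estimator
(`survival::survfit` behind the module surface; the test suite re-derives
the estimator by brute force as an independent check). The per-group mean
lifespan is the area under the survival curve up to the largest observed
time — the restricted mean, flagged when that time is censored. The
log-rank test is the standard 1-df statistic.

## What the synthetic data emulates — and what it does not

The generators define the study conditions; their defaults are the
documented cohort and design parameters:

* **Human cohort** (`cohort_spec`): plasma n = 46/51/45 and CSF
  n = 25/26/27 for NC/AD/MCI; CSF p-tau (pg/mL) drawn from zero-truncated
  normals with moments 32 ± 14 / 74 ± 30 / 51 ± 25 (plasma cohort) and
  32 ± 13 / 79 ± 32 / 53 ± 20 (CSF subset); group ages and male fractions
  likewise; 7,249 plasma and 6,028 CSF features by default. Intensities
  follow baseline + slope × p-tau + batch shift + noise on the glog scale
  (baseline ~ N(14, 2) log2 units, noise SD 1, 3 batches with per-feature
  shift SD 0.5), then back-transform. Effects are planted on the glog scale
  so the planted slope is exactly the regression estimand; the default
  effect size is 1 noise-SD per p-tau-SD. Missingness is a logistic
  function of glog intensity (centre 9, scale 1.5), mimicking
  detection-limit censoring; about 3% of cells at the baseline mean.
* **Worm experiments** (`worm_experiment_spec`): nonaggregating vs
  aggregating strains (plus an optional DMSO/DDT factor), 6 replicates of
  500 pooled worms per cell (the protocol pooled four-to-six replicates),
  1,000 features, strain effects of 2 noise-SD on 10% of features.
  The interaction is planted as a *sum-to-zero cell deviation* (± effect/2
  across the four cells), the orthogonal parameterisation that leaves both
  main effects untouched; at 2 noise-SD and 5 replicates/cell this gives
  interaction-test noncentrality ≈ 4.5 and ~98% power, whereas shifting a
  single cell by the same amount would leave only ~57% power. A blank
  channel places genuine features ~20× above the blank and a 35%
  contaminated fraction only 1.2× above, so the 1.5× rule removes roughly
  the fraction of features the worm bookkeeping describes. Worm feature
  intensities are log-normal — a modelling choice, not an upstream fact.
* **Cross-species plants** (`generate_crossspecies_study`): shared
  compounds planted at their exact M+H m/z in both matrices, 4 with
  concordant and 2 with discordant signs, exercising both branches of the
  overlap rule. Planted compounds get effect 3 noise-SD, baselines 2 SD
  above the mean, and no blank contamination — shared, cross-platform
  detectable metabolites are by construction abundant endogenous
  compounds — so per-compound detection power is ≈ 99% and exact recovery
  is the expected outcome of the design rather than a property of a lucky
  seed (verified at several seeds during development).
* **OCR traces**: plateau means (basal + nonmito)·n, (maximal + nonmito)·n,
  nonmito·n for n worms, Gaussian measurement noise (default 5 pmol O₂/min
  per well), 3–30 worms per well.
* **Survival**: Weibull lifespans with the four observed group means
  (24 / 19.4 / 8 / 11.8 days) as defaults, shape 4 (steep worm survival
  curves), independent uniform censoring at rate 0.05.

Not emulated: chromatographic drift, isotope envelopes beyond M+1,
between-platform effects, correlated metabolite modules, non-Gaussian
heavy-tailed intensity noise, and real annotation ambiguity structure.
Passing tests therefore demonstrate correctness of the rules and
calibration of the statistics under the generative model — not robustness
to everything real data does.

## Numerical and testing choices

Tolerances: mass arithmetic is checked at 1e-4–1e-5 Da, statistical
equalities (OLS vs t test, ANOVA vs brute-force sums of squares, KM vs
brute-force product-limit) at 1e-8–1e-12. Degenerate inputs have defined
behaviour: zero-variance features (t = 0, p = 1 when means agree),
all-censored survival groups (restricted mean, flagged), singleton batches
(error), empty design cells (error naming the cell).

Calibration tests use 2,000 features per model family with a fixed seed and
accept a null-rejection fraction in [0.04, 0.06] (±2 binomial SDs around
0.05). The enrichment null pools 300 pathway p-values over 5 generator
seeds at 199 permutations and accepts [0.01, 0.10] — wider because pathway
p-values within one run share permutation draws. Power checks use 1,000
features at n = 100 samples (effect 1 noise-SD per outcome-SD), and the
planted-pathway check runs 20 seeds at 500 permutations. Survival recovery
compares each group's restricted mean to its planted value within 3 SE: a
2-SE bound applied jointly to four independent groups would fail about one
run in five by sampling alone, so the joint check is sized at ~99%
coverage. These problem sizes keep the full suite around a minute of
runtime while leaving the binomial tolerances meaningful.

## Known limitations

* The batch adjustment is a location-scale standardisation, not an
  empirical-Bayes method; with many small batches it will overfit the
  batch parameters.
* Level-1 annotations require external MS2 evidence; the package performs
  no spectral matching.
* Pathway enrichment never contacts KEGG; membership comes entirely from
  the user's GMT file.
* The Cox proportional-hazards interaction model for survival and the
  full mummichog activity-network machinery are out of scope.
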