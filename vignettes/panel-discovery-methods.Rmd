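---
title: "Methods: triple-threshold biomarker panel discovery and its behaviour at small n"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triple-threshold biomarker panel discovery and its behaviour at small n}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabopanel)
```

## The problem

Untargeted metabolomics of a biofluid yields a sample × metabolite table of
peak heights for a few hundred detected compounds. In a longitudinal
two-group design — here modelled on repeated NSAID dosing in cats, with urine
sampled before treatment and at several time points during it — the question
is which metabolites consistently discriminate treated from control animals,
and whether that panel generalises to an independent cohort. The group sizes
typical of such studies (5–6 animals per arm) make this a severely
small-sample problem, and every design choice below is shaped by that.

## Preprocessing

The pipeline order is fixed: imputation → SD filtering → generalized log →
autoscaling.

* **Imputation** (`impute_missing()`): each missing cell becomes half the
  minimum observed value of that metabolite, the usual stand-in for
  below-detection-limit peaks. Metabolites observed nowhere are dropped.
* **SD filter** (`filter_low_sd()`): the `floor(fraction · p)` metabolites
  with smallest raw-intensity SD are removed as uninformative. The default
  fraction is 0.05 for tables of at least 250 metabolites and 0 otherwise;
  the cutoff is configuration, not an inference about any particular
  historical analysis. Filtering runs on raw (imputed) intensities, before
  any transform, since "low variance" is a property of the raw data.
* **Generalized log** (`glog2()`): `log2((x + sqrt(x^2 + a^2))/2)` with
  offset `a = 1` by default (detector units; the transform is insensitive to
  `a` for peaks well above it). It is strictly increasing, so every
  rank-based quantity downstream — in particular the univariate AUC — is
  invariant to it; its role is variance stabilisation for the two
  model-based rankers.
* **Autoscaling** (`autoscale()`): per-metabolite mean 0, SD 1 (n−1
  denominator). Scaling parameters are stored so held-out or cross-cohort
  samples can be projected with `autoscale_apply()` without refitting.
  Within the discovery run, scaling is re-derived from exactly the samples
  entering each per-time-point analysis.

## The three rankers

**PLS-DA VIP.** Classes are dummy-coded 0/1 and centred; a NIPALS PLS1
model with `A = 2` components (default) is fitted per time point. Component
counts are nowhere canonical at n ≈ 11; two components capture a dominant
direction plus one correction while keeping `A ≪ n`, and `q2_loocv()`
exposes the Q2-vs-A curve for inspection. VIP uses the SS-weighted Wold
form, whose mean square over metabolites is exactly 1, making "VIP > 1"
a scale-free "more than an average share" rule. Leave-one-out Q2 re-centres
the response inside each fold; the predictor matrix is consumed as passed,
so callers decide the scaling regime.

**Random-forest MDA.** 500 trees, 7 candidate predictors per split (the
conventional parameterisation for this assay size), Gini splitting, raw
(unscaled) out-of-bag permutation importance. Raw proportions are reported
because the selection threshold (0.004 = 0.4 %) is on that scale; negative
chance values are preserved. `mtry` larger than the metabolite count — which
happens when a 7-metabolite panel is refitted — is clamped with a warning.

**Orientation-free AUC.** Mann-Whitney AUC with midrank ties,
`max(AUC, 1−AUC)`. The dominant treatment signal in this design is a
*decrease* in intensity, yet published per-metabolite AUCs sit near 1.0;
only a direction-agnostic AUC is consistent with both, so all thresholding
uses it.

## Selection rule

Metabolites with orientation-free AUC > 0.85 at the pre-treatment time point
are baseline confounders: they separated the groups before any treatment
existed, so they are excluded *before* any treatment-time-point ranking
(order matters — exclusion precedes ranking). A metabolite is then selected
iff it is present at every treatment time point and satisfies VIP > 1.0,
MDA ≥ 0.004 and AUC > 0.85 **jointly at a single time point** (at least
one). The joint reading is the stricter of the two readings of
"three criteria in at least one time point" and is the one consistent with
the reference panel's per-time-point metrics, where every selected
metabolite clears all three bars together at its qualifying time points; the
disjoint reading remains available (`selection_criteria(joint = FALSE)`).
The MDA bar uses ≥ while VIP and AUC are strict, following the reference
thresholds literally. Selection is monotone: raising any threshold never
adds a metabolite.

## Validation

`mccv_roc()` draws class-stratified 2/3 train/test splits (default 100
repetitions), refits scaling and classifier inside each fold, and averages
each sample's held-out scores; the aggregate confusion matrix thresholds
those averages at 0.5, and the ROC curve sweeps that threshold. PLS-DA
scores are clamped to [0, 1]; random-forest scores are treated-class vote
fractions. `cross_cohort_predict()` fits on all samples of one training time
point and predicts the day-aligned testing time point
(`timepoint_pairing()`: 2→2, 4→3, 5→4). The two cohorts are autoscaled
independently — they were acquired a year apart and no cross-cohort
calibration step exists to emulate; applying the training scaling to the
test cohort is available as an option. Whether within-cohort reference rows
are cross-validated or resubstitution predictions is ambiguous in such
reports, so `run_validation()` computes both and labels them distinctly.

## The synthetic cohort generator

`generate_cohort()` emulates the study design so that every stage is
testable without the (undeposited) original data. Per metabolite *m*, log
intensity is

```
log X = mu_m + cat_intercept + dilution_sample + N(0, sigma_m) + effects
```

* `mu_m` uniform on [8, 13] natural-log units (peak heights ~3·10^3–4·10^5);
  the 114 library-identified metabolite names occupy the upper half of the
  abundance range, since spectral library matching succeeds preferentially
  for abundant peaks, and the planted panel and confounders are drawn from
  the named set (published panels consist of identified compounds).
* `sigma_m` uniform on [0.2, 0.6]: metabolite-specific biological plus
  technical noise.
* `cat_intercept ~ N(0, 0.2)`: repeated measures on the same animal are
  correlated; the per-time-point analyses ignore this, and the pipeline must
  work in its presence.
* `dilution_sample ~ N(0, 0.6)`: a per-sample factor shared by **all**
  metabolites of that sample. Unnormalized urine peak heights are dominated
  by urine concentration, which varies several-fold between voids; this
  term is the main source of inter-metabolite correlation and the single
  most consequential realism choice (below).
* **Effects** are additive on the natural-log scale (multiplicative on
  intensities) in units of the metabolite's *total* log SD
  `sqrt(sigma_m^2 + 0.2^2 + 0.6^2)` — i.e. standardized mean differences.
  Defaults: 7 planted metabolites at −2.5 SD from time point 2 onward
  (0 before treatment); 30 % of background metabolites drift by −0.5 SD
  (the assay-wide intensity decrease seen under treatment); 7 baseline
  confounders at −5 SD at time point 1 only; the censored treated animal
  (a non-responder) receives no effect and is excluded by flag, not
  deleted. Cells go missing independently at 2 %.
* The planted effect size −2.5 was calibrated once against the published
  statistics of the reference study: it reproduces per-metabolite
  orientation-free AUCs of ~0.93–0.98 at the treatment time points
  (published panel mean ≈ 0.95) and LOOCV Q2 of ~0.25–0.5 (published
  0.33–0.55), and was not revisited.

Metabolite-level parameters (abundances, noise scales, planted and
confounder identities, effect profile) are drawn from the seed *before* any
cohort-specific randomness, so training and testing cohorts generated from
one configuration share a single ground truth — the same analytical
platform measuring different animals.

**What the generator does not emulate**: correlated metabolite modules
(pathway co-regulation) beyond the single dilution factor,
intensity-dependent (left-censored) missingness, retention-index drift or
batch effects, and any pharmacokinetics. Passing tests on synthetic cohorts
therefore demonstrate correctness of the procedure and its behaviour under
a realistic noise model, not performance on any particular real data set.

## Small-sample behaviour the user should expect

With 5 treated vs 6 controls, the null distribution of the orientation-free
AUC is coarse rank combinatorics: the probability that a completely
uninformative metabolite exceeds 0.85 at a given time point is 5.19 %
exactly. Three consequences follow, all visible in the package's own tests:

1. **Baseline exclusion over-excludes.** Of ~300 metabolites, ~15 exceed the
   0.85 bar at the pre-treatment time point by chance and are excluded along
   with any genuine confounders. Because the dilution factor correlates
   metabolites, these exceedances cluster: most runs exclude few, occasional
   runs exclude many.
2. **The triple threshold is not chance-proof.** The three statistics are
   driven by the same random group separation, so a lucky null metabolite
   tends to clear all three bars at once; with ~300 metabolites × 4
   treatment time points, a handful of false joint passes per run is
   expected (measured ≈ 3 per run with no background drift). Selected
   panels at this design size should be read as *enriched for* true
   markers, not as exact recoveries; a published run with zero false
   inclusions is consistent with a single fortunate realization.
3. **Out-of-bag error is biased at tiny n.** Under permuted labels at
   n = 12, OOB error sits near 70 %, not 50 %: each held-out sample's class
   is under-represented in the bootstraps of the trees that vote on it.
   Chance-level behaviour re-emerges at moderate n (~51 % at n = 30).

## Numerical and degenerate-input choices

Sample SD uses the n−1 denominator throughout. Zero-SD metabolites are
dropped (recorded) at autoscaling; all-missing metabolites are dropped
(recorded) at imputation. A PLS component whose weight vector has zero norm
aborts with an explicit error, as does a LOOCV fold that loses a class, an
MCCV split that cannot hold both classes on both sides, and a confusion
metric with an empty denominator (never a silent zero). Forest vote ties
are broken deterministically by the underlying implementation, and every
stochastic stage (generator, forests, MCCV splits) is reproducible from an
integer seed, with per-stage sub-seeds derived by `sample.int()`.

Problem sizes in the test suite mirror the emulated design (318 metabolites,
5–6 animals per arm, 4–5 time points) with 10–20 seed replicates for
stochastic claims and reduced replicate counts where a property does not
depend on scale; these sizes were chosen as representative of the study
class the package targets.
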