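---
title: "Estimating the Cognitive Age Delta in biomarker-stratified cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the Cognitive Age Delta in biomarker-stratified cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cogagedelta)
```

## The model

Chronological age is a coarse proxy for how a person's cognition is actually
aging. The Cognitive Age Delta (CAD) replaces it with a model-based
individual marker: a linear model, trained on cognitively unimpaired,
biomarker-negative adults, predicts each participant's age from a battery of
age-sensitive neuropsychological test scores; the difference

$$\mathrm{CAD} = \hat{y} - y$$

between the bias-corrected predicted cognitive age $\hat y$ and chronological
age $y$ is positive when someone's test profile looks older than the calendar
says, and negative when it looks younger. CAD is then related, per clinical
group, to demographic, genetic, lifestyle and cognitive-reserve factors with
general linear models.

The pipeline has five stages, each an exported function, chained by
`run_cad_pipeline()`:

1. **Biomarker classification** (`classify_cohort()`). CSF markers define
   AT(N) status with literal threshold conventions: A+ iff
   A$\beta_{42}$ < 580 pg/mL (strict), T+ iff p-tau > 61 pg/mL, N+ iff
   t-tau > 350 pg/mL. The default amyloid cutoff is the operationally
   adjusted 580 (the 550 assay cutoff widened by a 5% confidence margin);
   550 is available through `biomarker_cutoffs()`. Vascular burden is
   V+ iff Fazekas $\ge$ 2 or microbleed count $\ge$ 4. The three analysis
   groups are CUA-V- (A-T-N- and V-), CUA+ (A+ and V-, irrespective of T/N)
   and CUV+ (V+ with A-T-N-); every other profile falls into `other`, and
   cortical superficial siderosis or established ischemic lesions force
   `other` as an exclusion rather than a V+ contribution.

2. **Feature screening** (`screen_features()`). Within the reference group,
   each candidate score is Pearson-correlated with age; candidates passing
   Bonferroni correction ($p < \alpha/m$, with $m$ defaulting to the number
   of candidates — one family) enter a greedy scan in descending $|r|$ (ties
   by input order) that drops any feature whose $|\rho|$ with an
   already-kept feature exceeds 0.7. The greedy rule operationalizes
   "prioritize the strongest age correlates"; balancing coverage across
   cognitive domains is a human judgment we deliberately do not automate.

3. **Education correction** (`fit_education_model()`,
   `apply_education_correction()`). Per feature, a simple regression on
   education years is fitted **on the reference group only**, and every
   participant's score is replaced by
   $X_{corrected} = \bar X + (X - \hat X)$: the residual recentered on the
   fitting-sample mean, which preserves the test's scale and range. Fitting
   on the reference group keeps the pathology groups from influencing the
   normative education effect. Sex and APOE $\varepsilon4$ load are not
   residualized by default — in the diagnostic model CAD ~ education +
   sex + APOE4 their effects are null — but the diagnostic GLM itself can be
   reproduced with `fit_association()`.

4. **Age model and bias correction** (`fit_age_model()`, `predict_cad()`).
   A z-score scaler (fitted once on the full reference sample; a per-fold
   variant is available via `scale_within_folds`) feeds an unregularized
   least-squares regression of age on the selected features. A shuffled,
   seed-controlled 5-fold cross-validation yields an out-of-fold prediction
   for every training participant. Age models regress to the mean —
   overpredicting the young, underpredicting the old — so the raw
   out-of-fold error is regressed on age and the fitted line $a y + b$
   subtracted from every raw prediction. Fitting that line on out-of-fold
   rather than refit predictions is essential: in-sample errors are
   optimistically small and would miscalibrate the correction. An
   alternative correction that regresses $\hat y$ on $y$ and inverts the
   line is available (`bias_method = "invert"`); we default to the
   subtraction form, which requires chronological age at prediction time —
   always available, since CAD is defined relative to it.

5. **Associations** (`run_association_suite()`). CAD across groups is
   compared with Kruskal-Wallis tests. Per clinical group, each factor is
   tested univariately (CAD ~ factor), with CAD left in years and the factor
   z-scored — so $\beta$ reads as *years of cognitive age per SD of the
   factor*; binary factors are 0/1-coded and standardized like everything
   else. p-values are Benjamini-Hochberg-adjusted within one factor group
   $\times$ clinical group family; factors are deliberately analyzed in
   small thematic families so a modest sample is not corrected against
   every factor ever measured. Post-FDR-significant factors are re-tested
   with sex, APOE4 load and education as covariates; these sensitivity
   models inherit the univariate FDR decision and report raw p-values. CSF
   markers travel through the same code path with those covariates.

### Which predictions feed the associations?

For participants the model was *not* trained on (the pathology groups), CAD
uses the full-sample refit model. For the training group itself,
`run_cad_pipeline()` defaults to each participant's out-of-fold prediction
(`fit_rows = "out_of_fold"`). This matters: a refit model's in-sample
residuals are orthogonal to every direction the model has learned, including
the coherent profile displacement a real (or planted) factor effect induces,
so in-sample CAD systematically under-expresses such effects. In simulation,
a planted effect of $-1.5$ years/SD is recovered at about $-1.16$ with refit
predictions but $-1.29$ with out-of-fold predictions at $n = 140$. The
remaining attenuation is the expected consequence of the subtraction-form
bias correction, which rescales nothing: effects expressed through the
prediction are shrunk by roughly the model's out-of-sample $R^2$
($\approx 0.88$ under the default generator).

## The synthetic cohort generator

No public version of the motivating cohort exists, so `generate_cohort()`
builds tables with the statistical structure the analysis assumes, and every
claim the test suite makes about the pipeline is a claim about these
synthetic conditions:

* **Group sizes** default to 140 reference, 23 amyloid-positive, 14
  vascular-positive participants (177 rows).
* **Ages** are uniform on 40-80 years; the pathology groups' lower bound is
  raised so their mean age sits about 5 years above the reference group's,
  reproducing the age confound such cohorts typically carry.
* **Biomarkers** are drawn by reflecting Gaussian draws about the
  classification cutoffs, so each row is on the correct side of every
  threshold by construction and classification recovers the requested label
  for 100% of rows. CUA+ rows get an enriched APOE ε4 carrier fraction and a
  30%/20% admixture of T+/N+ profiles.
* **Test scores** are affine in age and education plus Gaussian noise. The
  default noise levels put each score's age correlation near
  $|r| = 0.68$-$0.73$: strong enough that all twelve tests survive
  Bonferroni screening at $n = 140$, while the shared age signal keeps every
  pairwise $|\rho|$ under the 0.7 collinearity cap with margin for sampling
  variability. (Raising the correlations much beyond this makes the battery
  collide with the cap, since two tests correlated $r_1, r_2$ with age are
  themselves correlated $\approx r_1 r_2$.) Education slopes are mild
  (e.g. 0.6 points per education year for symbol-coding).
* **Covariates** (vocabulary, a reserve questionnaire, daily sitting hours,
  smoking) are drawn independently of age with zero effect by default. A
  planted effect of $\delta$ years/SD displaces every feature by
  `age_slope` $\times\,\delta\,z$(covariate) — the whole profile moves as if
  the participant were $\delta z$ years older — so recovery tests exercise
  the full pipeline, not just the final GLM. The standardization uses the
  covariate's theoretical moments, keeping the planted effect independent of
  the realized sample.
* **Missingness** (`inject_missingness()`) is completely at random, matching
  the unspecific nature of real score exclusions.

What the generator does *not* emulate: longitudinal visits, attrition,
practice effects, floor/ceiling effects and skewed score distributions,
assay batch effects, or any correlation between covariates and age or
biomarker status beyond the built-in age shift. Passing tests therefore
demonstrate internal statistical correctness of the pipeline under its own
assumptions, not external validity on clinical data.

## Numerical choices and degenerate inputs

* All regressions are ordinary least squares via R's QR path; the test suite
  cross-checks coefficients against explicit normal-equation solutions at
  tolerance 1e-8.
* Rank-deficient designs abort with the names of the dependent columns;
  constant features, zero education variance, and constant factors are hard
  errors rather than silent drops.
* A fully tied Kruskal-Wallis input (every observation equal) is reported as
  H = 0, p = 1 instead of the 0/0 the tie-corrected statistic would produce.
* Missing values are `NA` end to end — never sentinel numbers — and each
  model stage reports the rows it excluded.
* Fold assignment is a seeded shuffle into near-equal folds; the full-sample
  coefficients are independent of it, only the bias line varies slightly.
* Boundary conventions on cutoffs are strict `<`/`>` for CSF positivity and
  `>=` for the two vascular criteria, following each printed clinical
  inequality literally; values exactly at a CSF cutoff are negative.

## Problem sizes in the tests

The suite's simulation-based checks use the defaults above: 100 seeded
cohorts for label consistency, 400 replicate reference groups (pooling the
four null covariates, 1600 tests) for the empirical type-I error, and 50
replicates per arm for planted-effect recovery at $n = 140$ versus $n = 23$
— the small-group arm documents the attenuated power a 23-person group
implies, which is why null results in small pathology groups should be read
as absence of evidence. `scripts/acceptance.R` re-runs the same analyses at
reduced replication (10 recovery replicates, 100 null cohorts) and writes
the headline numbers as JSON.

## Known limitations

* The education correction assumes a linear education effect common to all
  groups; nonlinear or group-specific effects would leak into CAD.
* The subtraction-form bias correction leaves effect sizes attenuated by the
  model's $R^2$; the inversion form rescales but amplifies noise when the
  prediction-on-age slope is small.
* The collinearity screen is greedy, not optimal: it maximizes nothing
  globally, it just never keeps a violating pair.
* `other` and `unclassifiable` rows receive CAD values but enter no group
  analysis; whether mixed-pathology (e.g. A+V+) participants deserve their
  own group is a design question the data structure leaves open.
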