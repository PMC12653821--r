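# cogagedelta

Cognitive Age Delta (CAD) estimation and biomarker-stratified association
analysis for neuropsychological cohort studies.

## What it does, and for whom

Researchers studying preclinical cognitive aging need an individualized
outcome that is more sensitive than chronological age but computable from a
standard neuropsychological battery. This package implements the CAD
pipeline: a linear model, trained on cognitively unimpaired,
biomarker-negative adults, predicts each participant's age from
age-sensitive test scores; after correcting the regression-to-the-mean bias
that afflicts all age-prediction models, the **Cognitive Age Delta**

```
CAD = ŷ − y
```

(bias-corrected predicted cognitive age ŷ minus chronological age y) is
positive when cognition looks older than the calendar says. Participants are
stratified by CSF amyloid/tau status within the AT(N) framework (A+ iff
Aβ42 < 580 pg/mL, T+ iff p-tau > 61 pg/mL, N+ iff t-tau > 350 pg/mL) and by
MRI cerebrovascular burden (V+ iff Fazekas ≥ 2 or ≥ 4 microbleeds) into
CUA-V- (all negative), CUA+ (amyloid pathology) and CUV+ (vascular
pathology) groups, and CAD is related to demographic, genetic, lifestyle and
cognitive-reserve factors through grouped general linear models with
Benjamini-Hochberg FDR control and covariate-adjusted sensitivity models.

The pipeline stages are:

1. `classify_cohort()` — AT(N) + vascular status → analysis groups;
2. `screen_features()` — Bonferroni-corrected age-correlation screen with a
   greedy |ρ| > 0.7 collinearity prune, in the reference group;
3. `fit_education_model()` / `apply_education_correction()` — per-feature
   education residualization recentered on the original mean,
   `X_corrected = X̄ + (X − X̂)`;
4. `fit_age_model()` / `predict_cad()` — z-scaler + least-squares age
   regression with 5-fold CV; the out-of-fold error-on-age line is
   subtracted from predictions to remove regression-to-the-mean bias;
5. `kruskal_wallis()` / `run_association_suite()` — group comparisons and
   CAD ~ factor GLMs (factors z-scored, so β is years of cognitive age per
   SD), FDR within factor-group × clinical-group families.

Because no public cohort of this design exists, the package ships a
first-class synthetic-cohort generator (`generate_cohort()`) whose rows
classify back into their intended groups by construction and whose
covariates can carry *planted* cognitive-age effects that propagate through
the test scores — so the whole pipeline, not just the final model, is
testable end to end.

## Worked example

Simulate the default cohort (140 reference, 23 amyloid-positive, 14
vascular-positive participants) with a planted vocabulary effect of −1.5
years of cognitive age per SD in the reference group, then run everything:

```r
library(cogagedelta)

cds <- default_covariate_defs()
cds$planted_cad_effect[cds$name == "vocabulary"] <- -1.5
cds$groups_affected[[1]] <- "CUA-V-"

cohort <- generate_cohort(cohort_spec(covariate_defs = cds, seed = 11))
res <- run_cad_pipeline(cohort)
res
#> CAD pipeline: 177 participants, 12 features selected, model fit n = 140
#>   CAD across groups: H(2) = 2.26, p = 0.324
#>   associations: 13 fitted, 1 significant after FDR
res$age_model
#> Cognitive age model: 12 features, fit on CUA-V- (n = 140)
#>   5-fold CV RMSE: 3.37 years; bias line (subtract): slope -0.089, intercept 5.20
```

All twelve battery tests survive screening; the model predicts age to about
3.4 years RMSE out of fold, and the fitted bias line shows the usual
regression-to-the-mean slope. CAD does not differ across biomarker groups
(Kruskal-Wallis H(2) = 2.26, p = 0.324) — pathology status and cognitive
aging are distinct axes here. The associations in the reference group:

```r
subset(res$associations, clinical_group == "CUA-V-",
       c(factor, model, beta, ci_low, ci_high, p_raw, p_fdr))
#>                            factor              model    beta ci_low ci_high    p_raw    p_fdr
#> 1                      vocabulary         univariate -1.0070 -1.527  -0.487 0.000193 0.000386
#> 2 cognitive_reserve_questionnaire         univariate  0.2178 -0.328   0.763 0.431135 0.431135
#> 3                      vocabulary covariate_adjusted -1.0020 -1.527  -0.477 0.000238       NA
#> 4             daily_sitting_hours         univariate -0.0832 -0.630   0.463 0.763847 0.763847
#> 5                   active_smoker         univariate -0.2538 -0.799   0.291 0.358767 0.717533
```

The planted vocabulary effect is detected after FDR (β = −1.01, i.e. one
year of younger-looking cognition per SD of vocabulary; effects expressed
through a predictive model are attenuated by its out-of-sample R², here
≈ 0.88) and survives the sex/APOE/education-adjusted sensitivity model; the
three null covariates stay null. Averaged over replicate cohorts the
recovered β centers near −1.29 with 100% detection at n = 140.

A command-line front end mirrors the same chain:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "cad.R", package = "cogagedelta"))')
Rscript $CLI simulate --out cohort.csv --seed 11
Rscript $CLI classify --in cohort.csv --out labeled.csv
Rscript $CLI select-features --in labeled.csv --out selection.json
Rscript $CLI fit --in labeled.csv --selection selection.json --out model.json --seed 11
Rscript $CLI predict --in labeled.csv --model model.json --out cad.csv
Rscript $CLI associate --cad cad.csv --cohort labeled.csv --out associations.csv
```

Identical seeds produce byte-identical CSVs.

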