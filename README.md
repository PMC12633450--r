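# phenokit

Digital phenotyping of movement and communication in developmental cohorts.

Autism Spectrum Disorder (ASD) and ADHD frequently co-occur in youths, and
their behavioral signatures — how a child moves, speaks, and recounts a
story — overlap with each other and with ordinary development. `phenokit`
implements the quantitative analysis chain needed to disentangle them from
recordings of semi-structured interviews, for researchers working with
cohort-scale behavioral data:

- **Cohort coding** — DSM-5 ADHD *presentations* (Inattentive,
  Hyperactive-Impulsive, Combined) are re-coded as two binary *status*
  flags, with Combined positive on both; other/unspecified cases are
  excluded from modeling. Descriptive tables and male-to-female ratios
  reproduce the conventions of published cohort characteristics tables.
- **Movement quantification** — landmark time-series (30 Hz face and pose
  trajectories in image-normalized coordinates) pass two sliding-window
  quality checks (missingness > 10% in a 2-second window; x-coordinate SD
  above 0.1 for face / 0.01 for pose in 10-frame windows), face landmarks
  are aligned to a canonical template by per-frame least-squares affine
  maps, body landmarks are normalized by the frame-wise inter-shoulder
  distance, and movement is summarized as the log mean frame-to-frame 3D
  displacement per anatomical region.
- **Semantic typicality** — each interview answer's text embedding is
  scored by cosine similarity against the component-wise median embedding
  of older typically developing respondents (ages 14–22) for the same
  question, averaged into conceptual domains (narrative detail, factual
  memory, self-emotion description, ...) and Fisher-Z transformed
  (artanh) before regression.
- **Effect-size modeling** — every behavioral metric is fitted with robust
  (Tukey bisquare, c = 4.685) multivariate regression

  ```
  metric ~ age + IQ + sex + ADHD-Inatt + ADHD-Hyper + ASD
  ```

  and each predictor's effect size is `ES = t / sqrt(DFE)`, comparable
  across models with different missingness. Binary diagnosis outcomes use
  logistic models reported as odds ratios `OR = exp(beta)`. Families of
  models are Bonferroni-corrected with significance drawn at p < 0.01.
- **Synthetic cohorts** — because the motivating recordings are restricted
  (available only under a data-use agreement), a first-class simulator
  generates participant tables, behavioral features, landmark series, and
  answer embeddings with the generative structure the analysis assumes and
  stores the ground truth, so every stage is testable by parameter
  recovery.

## Worked example

Simulate a comorbid cohort of 2,000 youths, generate one behavioral metric
with a known standardized effect structure, and refit it:

```r
library(phenokit)
library(dplyr)

cohort <- simulate_cohort(n = 2000, seed = 1)
sex_ratio(cohort)
#> [1] 2

features <- simulate_feature_table(
  cohort,
  list(lexical_diversity = c(age = 0.40, iq_full = 0.27, sex = 0.08,
                             adhd_inatt = 0.00, adhd_hyper = 0.12, asd = 0.13)),
  seed = 2
)
fit <- left_join(cohort, features, by = "participant_id") |>
  fit_phenotype_model("lexical_diversity")
fit
#> <pheno_fit> robust_linear for 'lexical_diversity'  n_used=1795  dfe=1788  converged=1
#> # A tibble: 7 x 7
#>   term        estimate std_error statistic   dfe effect_size  p_value
#>   <chr>          <dbl>     <dbl>     <dbl> <int>       <dbl>    <dbl>
#> 1 (Intercept)  -3.31     0.179      -18.5   1788     -0.438  2.84e-70
#> 2 age           0.139    0.00831     16.7   1788      0.395  3.27e-58
#> 3 iq_full       0.0173   0.00146     11.8   1788      0.280  4.24e-31
#> 4 sex           0.154    0.0521       2.96  1788      0.0700 3.10e- 3
#> 5 adhd_inatt   -0.103    0.0555      -1.85  1788     -0.0437 6.48e- 2
#> 6 adhd_hyper    0.347    0.0594       5.84  1788      0.138  6.14e- 9
#> 7 asd           0.492    0.0696       7.06  1788      0.167  2.34e-12
```

`n_used` is 1,795 rather than 2,000 because excluded (ADHD
other/unspecified) records and rows with missing IQ are dropped listwise
for this model. The recovered effect sizes (`0.395`, `0.280`, `0.0700`,
`-0.0437`, `0.138`, `0.167`) sit near the generating values — the mild
shrinkage (e.g. 0.395 for a generated 0.40) is the expected
partial-correlation attenuation among correlated predictors. `tidy()`,
`glance()`, and `autoplot()` work on every fit, and
`run_pipeline()` orchestrates whole blocks of outcomes into effect-size
matrices with Bonferroni-masked significance flags (see
`vignette` sources in `vignettes/` for the full methods account).

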