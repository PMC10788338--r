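# endolca

Comorbidity endotype discovery for critical-care cohorts via binary latent
class analysis.

Patients admitted with an acute condition such as traumatic brain injury
carry very different chronic-disease burdens, and those conditions co-occur
in patterns (heart failure with arrhythmia, renal failure with hypertension,
alcohol with drug abuse). `endolca` finds such patterns as *endotypes* —
latent subgroups over binary Elixhauser comorbidity flags — and tests whether
the subgroups differ in survival, neurosurgical intervention and length of
stay after covariate adjustment. It is aimed at clinical researchers working
with administrative ICD-9 data (or any binary indicator matrix) who want a
tested, reproducible version of this analysis rather than a one-off script.

## The model

For patient *i* with binary indicators *x<sub>ij</sub>*, the K-class latent
class model assumes

&nbsp;&nbsp;&nbsp;&nbsp;f(x<sub>i</sub>) = Σ<sub>k</sub> π<sub>k</sub> Π<sub>j</sub> ρ<sub>kj</sub><sup>x<sub>ij</sub></sup> (1 − ρ<sub>kj</sub>)<sup>1 − x<sub>ij</sub></sup>,

fit by EM with random restarts (`lca()`); K is chosen at the AIC elbow
(`lca_k_range()`, `detect_elbow()`); endotype stability is established by
meta-clustering class profiles from 30 replicate fits with a diagonal
Gaussian mixture (`replicate_lca()`, `meta_cluster()`). Around the model sit
an ICD-9 → Elixhauser mapper with cohort rules (`elixhauser_map()`,
`map_codes()`, `filter_cohort()`, `bin_gcs()`, `bin_age()`), a co-occurrence
relative-risk network (`all_pairs()`, `build_network()`), a suite of outcome
comparisons (`outcome_table()`, `pairwise_chisq()`, `adjusted_binary_model()`,
`ancova_los()`, `stratified_rates()`, `model_comparison()`), a synthetic
cohort generator with known ground truth (`default_endotype_scenario()`,
`generate_cohort()`), and a config-driven end-to-end driver
(`run_pipeline()`). See `vignette("endotype-discovery")` for the methods.

## Worked example

Generate a synthetic 2,629-patient cohort with five planted endotypes, select
the class count, and compare outcomes:

```r
library(endolca)
co  <- generate_cohort(default_endotype_scenario(seed = 42, n_patients = 2629))
cv  <- lca_k_range(co$matrix, 1, 8, nrep = 10, seed = 42)
cv
#> AIC curve over K = 1..8; selected K = 5
#>  k    loglik      aic      bic converged
#>  1 -16199.51 32459.02 32635.25      TRUE
#>  2 -15189.02 30500.03 30858.37      TRUE
#>  3 -14648.43 29480.85 30021.29      TRUE
#>  4 -14159.58 28565.16 29287.71      TRUE
#>  5 -13789.19 27886.38 28791.03      TRUE
#>  6 -13760.53 27891.07 28977.83      TRUE
#>  7 -13740.59 27913.17 29182.03      TRUE
#>  8 -13718.73 27931.46 29382.43      TRUE
```

The AIC drops steeply up to five classes and flattens after — the elbow rule
selects K = 5, the number of planted classes. The winning fit behaves like
any R model object (`print`, `summary`, `coef`, `predict`, `simulate`,
`plot`):

```r
fit <- cv$fits[[cv$selected_k]]
fit
#> Binary latent class model: K = 5 classes, 30 items, N = 2629
#> logLik -13789.191 | AIC 27886.38 | BIC 28791.03 | 154 parameters
#> converged: TRUE after 133 iterations (best of 10 restarts)
#> mixing weights: 0.472, 0.342, 0.073, 0.063, 0.049

tab <- outcome_table(fit$assignments, co$patients)
tab[, c("endotype", "n", "survival_rate", "intervention_rate", "los_mean")]
#>   endotype    n survival_rate intervention_rate  los_mean
#> 1        1 1271          74.0              21.2  7.292447
#> 2        2  867          52.1              27.8  7.931834
#> 3        3  193          68.9              20.2 11.358031
#> 4        4  166          33.7              26.5  9.936145
#> 5        5  132          49.2              17.4  8.686364
```

Class 1 is the large low-comorbidity ("healthy") endotype with the highest
survival (74.0%); class 4 is the cardiac endotype with the lowest (33.7%);
class 3, the alcohol-abuse endotype, shows the long stays (11.4 days).
Survival rates are percentages rounded half-up to one decimal, the printing
convention of clinical outcome tables. Pairwise differences are tested with
Yates-corrected chi-squared tests, Holm-adjusted:

```r
head(pairwise_chisq(tab, "survival"), 3)
#>  group_a group_b statistic  test         p     p_adj significant
#>        1       2   107.098 chisq 4.236e-25 3.813e-24        TRUE
#>        1       3     1.929 chisq 1.649e-01 3.297e-01       FALSE
#>        1       4   109.791 chisq 1.089e-25 1.089e-24        TRUE
```

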