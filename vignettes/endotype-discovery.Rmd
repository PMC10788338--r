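---
title: "Discovering comorbidity endotypes with binary latent class analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering comorbidity endotypes with binary latent class analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endolca)
```

## The problem

Critically ill patients with an acute condition such as traumatic brain injury
(TBI) arrive with very different burdens of chronic disease, and those chronic
conditions do not occur independently: heart failure travels with arrhythmia,
renal failure with hypertension, alcohol abuse with drug abuse. An *endotype*
is a patient subgroup defined by such a shared underlying pattern. `endolca`
implements a complete pipeline for discovering comorbidity endotypes from
administrative diagnosis codes and for asking whether the discovered subgroups
differ in survival, neurosurgical intervention and length of stay (LOS) after
adjusting for age, sex and injury severity.

The pipeline has six stages, each usable on its own:

1. **Flag construction** — ICD-9-CM codes are mapped to Elixhauser chronic
   condition flags by prefix matching (`elixhauser_map()`, `map_codes()`,
   `comorbidity_matrix()`), with cohort rules for keeping one admission per
   patient (`filter_cohort()`) and binning GCS (mild 14–15 / moderate 9–13 /
   severe 3–8) and age (16–39 / 40–69 / 70+).
2. **Co-occurrence network** — pairwise relative risks with Fisher exact
   p-values (`all_pairs()`), filtered into a network (`build_network()`).
3. **Latent class model** — `lca()` fits a mixture of independent Bernoulli
   items by EM with restarts.
4. **Model selection** — `lca_k_range()` sweeps the class count and
   `detect_elbow()` picks the AIC elbow.
5. **Stability** — `replicate_lca()` reruns the fit, `meta_cluster()`
   compresses the pooled class profiles with a Gaussian mixture (latent
   profile analysis) and scores their recurrence.
6. **Outcome comparison** — contingency rates, Holm-adjusted pairwise tests,
   covariate-adjusted logistic models, ANCOVA with Tukey comparisons,
   stratified rates and nested-model AUC/F comparisons.

## The latent class model

For patient $i$ with binary indicators $x_{ij}$, $j = 1,\dots,J$, the
$K$-class model assumes

$$ f(x_i) \;=\; \sum_{k=1}^{K} \pi_k \prod_{j=1}^{J}
   \rho_{kj}^{x_{ij}} (1-\rho_{kj})^{1-x_{ij}} , $$

with mixing weights $\pi_k$ and class-specific item probabilities
$\rho_{kj}$: conditional on class, items are independent. The EM iteration
alternates responsibilities
$\tau_{ik} \propto \pi_k p_k(x_i)$ with weighted-average updates of $\pi$ and
$\rho$. Implementation notes:

* **Restarts.** Each of `nrep` (default 20) restarts draws initial
  responsibilities from a flat Dirichlet per response pattern and applies an
  M-step first; the restart with the best final log-likelihood wins. A restart
  whose smallest class mass falls below $10^{-8} N$ is abandoned and redrawn.
* **Tolerances.** Iteration stops when the relative log-likelihood change is
  below `tol = 1e-8` or after `max_iter = 5000` iterations; item
  probabilities are clamped to $[\varepsilon, 1-\varepsilon]$ with
  $\varepsilon = 10^{-6}$. These defaults make the degenerate
  separated-block examples hit their closed forms to three decimals or
  better.
* **Aggregation.** Duplicate response patterns are collapsed to weighted
  unique rows before EM; this leaves the likelihood identical and makes the
  per-iteration cost scale with the number of distinct patterns (typically a
  third of the patients for cohorts of this kind). The inner loop is
  compiled (RcppArmadillo).
* **Degrees of freedom.** AIC $= -2L + 2m$ and BIC $= -2L + m\log N$ with the
  unconstrained count $m = (K-1) + KJ$, regardless of clamped boundary
  estimates.
* **Missing data** are not supported in the indicator matrix; cohort
  construction must resolve them (incomplete cases are excluded upstream).
* **Ties and labels.** Modal assignments break posterior ties toward the
  lower class index; classes are reported in decreasing-$\pi$ order. Label
  switching across fits is resolved where needed by `align_labels()`, an
  exact Hungarian-algorithm matching of class profiles.

## Choosing the number of classes

`detect_elbow()` rescales the $(K, \mathrm{AIC})$ curve to the unit square
and returns the point with the largest distance below the chord joining the
first and last points. The normalisation makes the choice invariant to affine
rescaling of either axis; ties break toward the smaller $K$. Two guards
declare a curve elbow-free (returning the smallest $K$ with a warning): no
point lies below the chord, or the curve is not *predominantly decreasing* —
the net drop from the first point to the minimum is less than half the total
variation of the curve. The second guard matters in practice: for $J = 30$
binary items the AIC penalty of one extra class ($2(J+1)$) is close to the
typical EM overfitting gain, so the AIC curve of structureless data is nearly
flat with random wiggles, and an unguarded chord rule would return an
arbitrary interior point. The one-half threshold encodes "most of the curve's
movement must be downward" and is fixed, not data-tuned.

A distance-to-chord knee is one of several reasonable elbow definitions
(second-difference rules are another); it was chosen because it is
deterministic, scale-aware and verifiable by brute force.

## Stability by replicate meta-clustering

Because EM is stochastic, one fitted model is not evidence that the endotypes
recur. `replicate_lca()` reruns the full best-of-restarts fit $R$ times
(default 30) with distinct seeds; pooling the $R \times K$ class profiles
gives a point cloud in $[0,1]^J$ that `meta_cluster()` summarises with a
Gaussian mixture with diagonal covariances (the continuous-variable analogue
of LCA), $G$ chosen by BIC over $1..g_{\max}$ via **mclust** with a
regularising prior. Diagonal covariances are a deliberate restriction: with
$RK$ rows against $J = 30$ dimensions, full covariances would be singular.
The searched $G$ range is capped at the number of distinct profiles, since a
mixture cannot support more components than distinct points.

The report carries three complementary quantities:

* the **stability score** — the fraction of replicates contributing exactly
  one profile to each of the $K$ most populated meta-clusters (1.0 means
  every rerun found the same set of classes); this score is a package
  definition, chosen because it is interpretable and exact under the ideal
  outcome;
* the **representative fit** — the replicate with the lowest AIC (ties toward
  the lowest index), the model carried forward to outcome analysis;
* the **maximum aligned profile difference** — the largest elementwise
  difference between any replicate's profiles and the representative's after
  optimal label alignment, an explicit distance in probability units rather
  than a significance claim about "identical" profiles.

## The synthetic cohort generator

No patient-level data ship with the package; the generator provides cohorts
with *known* latent structure so that every stage is testable end to end.
`default_endotype_scenario()` fixes a 5-class, 30-item configuration whose
observable summaries follow the published TBI endotype tables: class sizes
187/1254/136/177/875 (scaled to the requested $n$), per-class age means and
SDs (80±10, 44±20, 79±11, 55±15, 74±15 years, truncated to 16–100),
GCS severity mixes, male fraction 0.62, class-level survival
(27.8/78.5/40.4/70.1/51.4%) and intervention (27.3/21.5/13.2/23.2/25.7%)
rates, and LOS means (10.2/7.3/8.7/10.6/7.7 days, lognormal with
$\sigma_{\log} = 0.7$, rounded to 0.1 day). Survival and intervention are
generated through logistic models (age slope −0.04, GCS slope +0.15 on the
log-odds scale for survival; GCS slope −0.02 for intervention) whose
per-class intercepts are solved so the class-mean covariates reproduce the
target rates; the age/endotype confounding this creates is intentional, so
covariate-adjusted code paths face a realistic adjustment problem. The source
study discovers endotypes rather than generating them, so no published
class-conditional outcome mechanism exists; these values are package
conventions.

The item-probability profiles are *sharpened* relative to what one would
estimate from real cohorts, and deliberately so. Each non-healthy class
carries at least two "anchor" items at probability 0.95–0.96 that are rare
(0.002–0.005) in every other class; mid-range probabilities appear only in
the two large classes. Two facts force this design if parameter recovery is
to be verifiable at $n = 5000$ with the published class-size ratios:

* a class separated from its neighbours by a *single* strong item is not
  identifiable — a two-class mixture differing in one item is
  indistinguishable from an independence model, and the ML solution drifts
  to a boundary mode where that item's probability is exactly 1 and the
  class absorbs background carriers of the item (we verified that
  truth-initialised EM flows to the same mode, i.e. this is the MLE, not a
  bad local optimum);
* the smallest class has $\approx 260$ members at $n = 5000$, so an item
  with mid-range probability in that class has a binomial standard error
  near 0.03 and cannot be pinned down to ±0.05 reliably.

Consequently, passing recovery tests on this generator demonstrates that the
estimator finds well-separated structure at realistic cohort sizes; it does
**not** demonstrate that five classes are recoverable from real TBI data,
where profiles overlap far more and class counts are a modelling judgement.
The generator also emits one admission per patient (the first-admission
filter is exercised with a handcrafted multi-admission fixture in the tests)
and, optionally, ICD-9 codes consistent with the flag matrix
(`emit_icd9_codes()`), sampled only from codes that map back to exactly their
own category so the mapping round-trips exactly.

## Statistical conventions in the outcome stage

* Printed rates are percentages rounded **half-up** to one decimal
  (`round_half_up()`), matching printed clinical tables; base `round()`
  rounds half to even.
* Pairwise 2×2 comparisons use the Yates-corrected chi-squared test, falling
  back to Fisher's exact test when any expected cell is below 1; families of
  pairwise p-values are Holm-adjusted.
* Pairwise LOS tests are Welch (unequal variance) t-tests: the pooling
  behaviour was unspecified in the source analysis and Welch is the safer
  default.
* Stratified survival comparisons use two-proportion tests: proportions in
  disjoint strata are not pairable observations, so a paired test would be
  inappropriate even though the source describes one.
* The adjusted models are maximum-likelihood logit fits with Wald intervals;
  perfect separation triggers a ridge-penalised refit (penalty $10^{-4}$)
  that is flagged in the result.
* Model comparison reports *both* the rank-based AUC / McFadden pseudo-$R^2$
  of the logit fits and the $R^2$/F statistics of matching
  linear-probability (OLS) fits, because published F/R² patterns for such
  analyses are consistent with linear-model arithmetic while the effect
  tables are odds ratios; reporting both avoids guessing.
* The co-occurrence relative risk is $RR_{ij} = C_{ij} N / (P_i P_j)$ with a
  Katz-style log-scale interval $\log RR \pm z_{0.975}/\sqrt{C_{ij}}$
  (undefined at $C_{ij} = 0$) and a two-sided Fisher exact p-value. No
  multiple-testing adjustment is applied across the 435 pairs by default, and
  the display cap (RR 5) never alters the stored estimate. Published
  intervals for such networks are sometimes far narrower than any
  count-based interval at these cohort sizes; the construction used there is
  unknown and is not replicated.

## Problem sizes used in the checks

The automated checks run the generator at $n = 2629$ (selection, stability,
outcomes) and $n = 5000$ (recovery), with 20 EM restarts for single fits, 10
restarts per point of the $K = 1..8$ selection sweep, 5 restarts inside each
of the 30 stability replicates, and 500 replications for the null-calibration
checks. These sizes mirror the cohort scale of the motivating study while
keeping a full run in minutes on one core.

## Known limitations

* Conditional independence within classes is an assumption, not a finding;
  strongly correlated items inside a true subgroup will be split or absorbed.
* The AIC elbow is a heuristic; bootstrapped likelihood-ratio tests for $K$
  are out of scope.
* ICD-10, Charlson scores and van Walraven weights are not implemented; the
  embedded mapping is the enhanced ICD-9-CM Elixhauser table with a
  split/combined hypertension switch (31 or 30 categories).
* The published TBI endotype coefficient tables derive from credentialed
  external data and are not reproducible here; the package validates its
  machinery on synthetic cohorts and on the published count tables it embeds.
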