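# qolclasses

Heterogeneity analysis of multi-attribute quality-of-life (QoL) responses
in clinical cohorts, built around the adolescent AQoL-6D (20 ordinal items
in six dimensions). The package is aimed at researchers in youth mental
health and health economics who want to go beyond a single utility number:
it identifies latent groups of respondents with distinct QoL profiles and
validates them against demographic and clinical characteristics.

## What it does

* **Scoring** — unweighted dimension totals; standardised dimension scores
  `100·(max_total − total)/(max_total − min_total)` on the theoretical
  anchors (0 worst, 100 best); pluggable 0–1 utility specifications with a
  packaged multiplicative-disvalue surrogate; Cronbach's α per dimension.
* **Item structure** — two-step polychoric correlation matrix
  (thresholds from margins, then 1-D likelihood maximisation over the
  latent correlation) and a classical MDS network layout of
  `d = sqrt(2(1 − r))`.
* **Latent class analysis** — the multinomial mixture
  `P(x_i) = Σ_k π_k Π_j ρ_{k,j,x_ij}` fitted by multi-start EM (C++ inner
  loop), with AIC/BIC, posteriors, modal assignment, and classes
  canonically ordered by mean utility.
* **Class-number selection** — 10-fold, leave-one-site-out and split-half
  cross-validation; selection on pooled held-out BIC
  `−2·Σ_f ℓ_test,f + p·ln N`; k-means-on-principal-components sensitivity
  check with adjusted Rand agreement.
* **3-step validation** — modal class regressed on covariates by
  multivariate multinomial logistic regression (own Newton fit, Wald
  covariance), with chained-equations multiple imputation and Rubin
  pooling of relative risk ratios; two nested covariate models
  (demographics + diagnosis + staging; plus symptom scales).
* **Synthetic cohorts** — a seeded generator with known latent-class ground
  truth; the packaged profile emulates a 1107-person, five-site,
  four-class help-seeking cohort with 40 incomplete responders and
  calibrated covariate structure.

## Worked example

```r
library(qolclasses)

profile <- aqol_reference_profile()                 # packaged 4-class profile
cohort  <- generate_cohort(profile, seed = 1)   # N = 1107, 40 incomplete
items   <- complete_case_filter(cohort$items)
items
#> <item_matrix> 1067 persons x 20 items (0 rows with missing items)

scores <- dimension_scores(items, aqol_surrogate_utility())
fit <- rank_classes_by_utility(fit_em(items, K = 4, seed = 1), scores)
fit
#> <lca_fit> K = 4, N = 1067, loglik = -17808.03, AIC = 36262.1, BIC = 37868.2 (converged)
#> prevalences: 0.316 0.307 0.241 0.136

assigned <- fit$class_labels[classify_modal(fit)]
round(sort(tapply(scores$utility, assigned, mean), decreasing = TRUE), 2)
#>      No/Mild Moderate-Psy Moderate-Phy       Severe
#>         0.87         0.58         0.52         0.26
```

1067 of the 1107 generated persons have complete AQoL-6D responses and
enter the analysis. The four fitted classes, ordered by mean utility, span
the range from no-to-mild impairment (mean utility 0.87) through two
moderate profiles — one dominated by mental-health/coping impairment, one
by pain — down to a severe class at 0.26; these means recover the values
the generator profile was calibrated to. Scale reliability and item
structure follow the same pattern as clinical cohorts
(`cronbach_alpha(items, "pain")` → 0.87; polychoric correlations up to
0.78 between pain items).

Class-number selection and covariate validation run the same way:

```r
folds <- make_folds(nrow(items$values), "kfold", n_folds = 10, seed = 11)
cv    <- run_cv(items, k_range = 1:6, folds = folds, seed = 42)
select_k(cv)$selected_k        # 4

labels <- factor(fit$class_labels[classify_modal(fit)], levels = fit$class_labels)
rrr_report(labels, covariates, m = 20, seed = 7)   # pooled RRR tables
```

`run_pipeline(config)` drives all stages (simulate → score → describe →
select → fit → validate) from one YAML/list configuration and writes CSV/JSON
outputs plus a run manifest.

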