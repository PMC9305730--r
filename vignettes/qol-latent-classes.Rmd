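---
title: "Latent class analysis of quality-of-life profiles: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent class analysis of quality-of-life profiles: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`qolclasses` implements a complete workflow for studying heterogeneity in
multi-attribute quality-of-life (QoL) responses in clinical cohorts:
instrument scoring, item-structure description, latent class modelling with
cross-validated selection of the number of classes, and external validation
of the classes against demographic and clinical covariates. This vignette
records the models, their assumptions, and the design decisions behind the
defaults.

## The instrument and its scores

The adolescent AQoL-6D has 20 ordinal items in six dimensions: independent
living (4 items), social and family relationships (3), mental health (4),
coping (3), pain (3) and senses (3). Response codes run from 1 (best) to an
item-specific maximum (worst); the package's default metadata uses five
categories per item, which is configurable per item.

Three summaries are computed per person:

* **Unweighted dimension totals** — the sum of the item codes in a
  dimension; higher is worse.
* **Standardised dimension scores** — the reverse min–max scaled total,
  `100 (max_total − total) / (max_total − min_total)`, so 0 is the worst
  health state and 100 the best *on the theoretical scale anchors*.
  Observed minima/maxima are never used: the quoted anchors ("worst/best
  health state") are properties of the scale, not the sample. Dimension
  scores are not pro-rated; a person missing any item of a dimension has a
  missing score, and all multi-item analyses use complete AQoL-6D cases
  only (`complete_case_filter()`).
* **Utility** — a preference-weighted index on 0 (worst) to 1 (best).
  The instrument's adolescent weighting algorithm is proprietary, so the
  utility function is a pluggable specification. The packaged surrogate is
  a multiplicative-disvalue model: with dimension disvalue
  $D_d = 1 - S_d/100$ and weights $w_d \in (0,1]$,
  $$u = \frac{\prod_d (1 - w_d D_d) - u_0}{1 - u_0},
    \qquad u_0 = \prod_d (1 - w_d).$$
  The linear rescaling pins the best health state to exactly 1 and the
  worst to exactly 0, and every factor is decreasing in every item code, so
  utility is monotone. Users holding the licensed weights can supply their
  own specification; any spec must satisfy the same endpoint invariants
  (checked to 1e-9 at scoring time).

Internal consistency is summarised by Cronbach's $\alpha$ per dimension,
computed listwise within the dimension. Listwise computation was chosen
over pairwise-complete covariances for reproducibility: the statistic is
then a deterministic function of a single analysis set.

## Item structure: polychoric correlations and the MDS layout

Associations between ordinal items are estimated on the latent scale by
two-step polychoric correlation: thresholds are standard-normal quantiles
of each item's cumulative margins, then the latent correlation maximises
the bivariate-normal contingency-table likelihood with thresholds held
fixed. Two-step estimation is the standard practical choice; full joint
maximum likelihood changes estimates negligibly at these sample sizes and
costs far more. Bivariate normal rectangle probabilities use a 64-point
Gauss–Legendre rule on the arc-sine form of the tetrachoric integral,
accurate to well below 1e-7 in absolute terms, so the estimator can be
validated against an exhaustive grid search of the same likelihood to
0.002. Estimates are clipped to (−0.999, 0.999).

The item network layout is classical (Torgerson) multidimensional scaling
of the dissimilarity $d_{ij} = \sqrt{2 (1 - r_{ij})}$, which embeds more
strongly associated items closer together. The exact variant used for such
figures is rarely reported; classical MDS on this transform is a documented
choice, deterministic up to rigid motion, and the package fixes the
reflection by making the largest-magnitude coordinate on each axis
positive. Negative eigenvalues of the double-centred matrix (possible,
since a correlation-derived dissimilarity need not be Euclidean) are
truncated with a warning. The edge-list display threshold defaults to
$r \ge 0.3$; both the threshold and the dissimilarity transform are
arguments, not constants.

## The latent class model

Responses are modelled as a finite mixture: person $i$ belongs to one of
$K$ unobserved classes with prevalences $\pi_k$, and given the class the 20
items are independent, each multinomial over its categories with
class-specific probabilities $\rho_{kjc}$. The log-likelihood is
$\sum_i \log \sum_k \pi_k \prod_j \rho_{k j x_{ij}}$ and the model has
$p = (K-1) + K \sum_j (C_j - 1)$ free parameters.

Fitting is by EM with random restarts. Design choices:

* **Initialisation** — per restart, responsibilities drawn from a flat
  Dirichlet per person; 20 restarts by default. Restarts are the guard
  against local maxima; the best final log-likelihood wins.
* **Convergence** — relative log-likelihood change below 1e-6, cap of
  1000 iterations.
* **Smoothing floor** — after each M-step, item-category probabilities are
  floored at 1e-6 and renormalised. This is a deliberate, documented
  deviation from raw maximum likelihood: it prevents sampling zeros from
  producing degenerate cells and keeps held-out log-likelihoods finite when
  a category appears only in a test fold.
* **Complete cases only** — missing items are an error at fit time, not
  marginalised, matching the analysis-cohort definition above.
* **Ties and ordering** — modal assignment breaks posterior ties toward the
  lowest class index. Label switching is resolved by reordering classes by
  the mean utility of their modal members (class 1 highest). For four-class
  solutions the two middle classes are ordered by their mean standardised
  pain score — the class with *less* pain impairment second
  ("Moderate-Psy"), the other third ("Moderate-Phy") — mirroring the
  conventional naming of psychological- versus physical-dominant moderate
  impairment profiles.

The EM inner loop is implemented in C++ (via Rcpp) for speed; a pure-R
`em_step()` exposes a single step for verification, and the test suite
checks the fitted end point is a fixed point of the R step and that the
likelihood agrees with a brute-force enumeration oracle on small instances.

## Choosing the number of classes

Three cross-validation schemes are provided: 10-fold (seeded random
partition), leave-one-site-out (one fold per recruitment site), and
split-half (each random half held out once). For every `(K, fold)` pair the
model is fitted on the training rows and the log-likelihood of the held-out
rows is evaluated.

How to penalise a *held-out* log-likelihood is genuinely open. Applying the
BIC penalty $p \ln N_{\text{test}}$ within each small fold double-counts
complexity: the held-out log-likelihood is already an unbiased estimate of
predictive fit, while the penalty scales with $p \ln N$ against a signal
that scales with $N_{\text{test}}$ — for 10 folds of ~100 persons the
penalty per additional class (~380) exceeds any plausible per-fold gain, and
the criterion collapses toward one class regardless of the true structure.
The package therefore selects on the **pooled held-out BIC**
$$-2 \sum_f \ell_{\text{test},f} + p \ln \textstyle\sum_f N_{\text{test},f},$$
which is well scaled because the folds partition the sample: the summed
out-of-fold log-likelihood is an honest predictive log-likelihood of all
$N$ persons. The per-fold mean criterion remains available
(`select_k(criterion = "mean")`), as does a train-N penalty in
`holdout_indices()`. An elbow diagnostic (first $K$ whose successive
improvement falls below 10% of the largest improvement) accompanies the
argmin.

As a sensitivity analysis, items are treated as numeric, centred and
scaled, reduced to principal components covering ≥80% of variance, and
clustered by k-means (25 seeded restarts); agreement with the modal LCA
classes is reported as the adjusted Rand index.

## Validating the classes: the 3-step approach

Step one fits the measurement model; step two assigns each person to their
modal class; step three regresses assigned class on covariates by
multivariate multinomial logistic regression. The package uses plain modal
assignment without a classification-error correction (BCH/ML): with the
entropy levels the calibrated cohorts produce (assignment accuracy ~98%),
attenuation from misclassification is negligible, and corrections are left
as an extension point.

Two models are fitted, reflecting the overlap between diagnosis/staging and
self-reported symptoms: model 1 uses demographics (age, sex, LGBTIQ, NEET,
region), primary diagnosis and clinical staging; model 2 adds PHQ-9, GAD-7,
SIQ-JR and PSQI totals. Conventions: the reference outcome class is the
highest-utility class ("No/Mild"); clinical staging enters with stages
0–1a collapsed as the reference band against 1b and 2–4; the four symptom
totals are standardised (centred, divided by s.d. — observed by default,
fixed external values optionally) so RRRs refer to a one-s.d. change; age
and dummy variables are left on their natural scales. Prediction accuracy
is computed in sample, as the share of persons whose highest fitted
probability matches their assigned class.

The regression is fitted by full Newton–Raphson with step halving; the Wald
covariance is the inverse observed information. Separation (coefficients
diverging, or a saturated linear predictor) triggers a warning and a ridge
fallback with penalty 1e-4. `nnet::multinom` serves as an independent
cross-check in the test suite, not as the implementation.

Covariate missingness is handled by chained-equations multiple imputation
(m = 20, 10 cycles, seeded): type-1 predictive-mean matching with a
Bayesian coefficient draw and 5-donor pools for continuous variables,
logistic regression with a coefficient draw for binary variables, and
multinomial draws from fitted category probabilities (no coefficient draw —
a documented simplification) for multi-category variables. The modal class
label is included as a predictor in every imputation model so the
imputations are congenial with the analysis model. Estimates and variances
are pooled by Rubin's rules with the classical degrees of freedom (between
variance zero reduces exactly to single-fit inference); confidence
intervals are formed on the log scale and exponentiated.

## The synthetic-cohort generator

The paper-style cohort this package targets is not publicly deposited, so
the generator produces cohorts with *known* class structure against which
every downstream stage is testable. The packaged profile
(`aqol_reference_profile()`) encodes a 1107-person cohort with four classes
(prevalences 0.33/0.28/0.26/0.13), five recruitment sites (three
metropolitan, ~63% of the cohort), exactly 40 rows with incomplete AQoL-6D
responses, and class-linked covariates with realistic missingness counts
(e.g. 42 for LGBTIQ, 48 for PSQI at N = 1107, scaled proportionally at
other sizes).

Item responses are binomial(4, p) + 1 discretisations, with one disvalue
level p per class and dimension. Two properties make this parameterisation
attractive: the expected item disvalue equals p exactly, and — because
utility is multilinear in conditionally independent item disvalues — the
expected class utility has the closed form
$(\prod_d (1 - w_d p_d) - u_0)/(1 - u_0)$. Calibration of the packaged
profile to the target class utilities (0.87/0.59/0.54/0.25) is therefore
analytic; the script `scripts/calibrate_profile.R` in the source repository
reproduces it. The contrast between the two Moderate classes (pain versus
mental-health/coping) was sized by a Kullback–Leibler calculation so that
held-out-likelihood selection can resolve four classes at N ≈ 1100.
Class-conditional covariate models (normals with equal within-class s.d.s,
class-specific binary/categorical probabilities) embed the target summaries
directly — e.g. suicidal-ideation medians of ~4 (best class) and ~40 (worst
class), and a clinical-staging relative risk of ~14.6 for full-threshold
staging, Severe versus No/Mild. Because items and covariates are drawn
independently given class, the induced model for class membership given
covariates is *exactly* a multinomial logit, so the 3-step regression
estimates a well-defined generator truth.

What the generator deliberately does not emulate — and hence what passing
tests do not certify about real data:

* **Within-class dependence.** Items are conditionally independent given
  class (the LCA assumption). Real cohorts show residual local dependence;
  one visible consequence here is that within-class utility spread is
  narrower than the spreads seen in real cohorts, and a strongly contrasting class pair can
  induce mildly *negative* marginal inter-item correlations, whereas real
  AQoL-6D matrices are typically all-positive.
* **Missingness mechanisms.** Item and covariate missingness are MCAR with
  fixed counts; informative missingness is out of scope.
* **Response styles.** Item margins are unimodal and symmetric around the
  class disvalue level; real items show floor effects and idiosyncratic
  anchors.

Every cohort is driven by a single seeded stream, so identical
configurations and seeds are byte-identical; stage-local seeds in the
pipeline derive deterministically from one master seed.

## Numerical conventions and problem sizes

Tolerances: EM 1e-6 relative; polychoric optimisation 1e-6 on ρ with
rectangle probabilities accurate to <1e-7; Newton fits iterate to a 1e-8
gradient norm; probability floors 1e-6 (EM) and 1e-12 (likelihood cell
probabilities). Degenerate inputs fail loudly: single-category variables,
zero-variance dimensions, rank-deficient designs (naming the aliased
columns), empty reference classes and all-missing variables are errors, not
silent repairs.

The test-suite simulation sizes are chosen to make each property sharply
testable at interactive cost: consistency checks at n = 50,000 per
correlation; generator convergence at N = 10,000–20,000; parameter recovery
at N = 2,000; class-number recovery at N = 1,500 over ten replicate seeds
per true K with split-half validation; the full cohort analyses at the
profile's native N = 1107.

## Known limitations

Modal (uncorrected) 3-step regression understates uncertainty when classes
are poorly separated; the entropy of a fitted solution should be checked
before interpreting RRRs. The surrogate utility is calibrated, not the
licensed algorithm: absolute utility levels are comparable only within a
specification. Ordinal measurement models (cumulative logits), covariates
inside the measurement model, bootstrap likelihood-ratio tests and
longitudinal extensions are out of scope.
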