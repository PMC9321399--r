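---
title: "Predicting anti-TNF treatment response from plasma proteomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting anti-TNF treatment response from plasma proteomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Roughly a third of rheumatoid arthritis patients prescribed anti-TNF
biologics do not benefit from them, at substantial cost and at the price of
months of uncontrolled disease. `tnfresponse` implements a complete
discovery-and-deployment pipeline for predicting, before therapy starts,
whether a patient will respond: preprocessing of targeted plasma proteomics
(Olink-style NPX data), resampling-based biomarker discovery with
elastic-net logistic regression under nested cross-validation, a packaged
published 17-protein clinical scorer, PCA-based endotype exploration, and a
synthetic cohort generator that makes every stage testable without any
patient data.

## NPX preprocessing

NPX (Normalised Protein Expression) is a log2-scale *relative*
quantification unit: real abundance is proportional to 2^NPX and values are
not comparable across proteins. The ingest module therefore:

1. **QC masking** — all measurements of a (sample, panel) pair that carries
   a QC warning are set missing.
2. **LoD masking** — values *strictly below* the protein's limit of
   detection become missing. The boundary case is retained: the assay floor
   is defined by "below", and a value exactly at the LoD carries the same
   information as one just above it.
3. **k-NN imputation** — each missing cell is filled with the unweighted
   mean of the protein's values in the `k = 5` nearest samples (Euclidean
   distance over mutually observed proteins, scaled by the number of shared
   proteins). `k = 5` is the conventional small-cohort default; the method
   (but not `k`, the metric, or the weighting) is fixed by the upstream
   protocol, so all three are configurable. Imputation refuses to run above
   a 10% missing ceiling — with the expected < 2% missingness anything
   higher signals a data problem, not a task for imputation.
4. **Standardisation** — every protein is scaled to zero mean and unit
   sample SD. The pre-scaling means/SDs are retained as `reference_stats`,
   because a *new* patient must be placed on the same z-scale with
   `standardize_new()` — the deployment-time analogue of the cohort
   preprocessing.

QC and LoD masking only ever add missingness, so they are idempotent and
commute; the tests assert both.

A protein assayed on two panels is two distinct features during discovery
(ids get a `:PANEL` suffix). The published signature, however, lists one
merged coefficient for such a protein; at scoring time two supplied panel
values are standardised separately and their z-scores averaged. The true
merge rule of the original tool is not documented anywhere; averaging is
symmetric, scale-free, and reduces to the single-panel case trivially.

## The learner

All model fitting uses penalized logistic regression with the elastic-net
objective in the glmnet parameterisation:

$$\min_{b,\beta}\; \frac1n\sum_i \ell(y_i, b + x_i^\top\beta)
  \;+\; \lambda\sum_j\Big[\tfrac{1-\alpha}{2}\beta_j^2 + \alpha|\beta_j|\Big]$$

with `alpha = 0.9` (90% lasso / 10% ridge: lasso for sparse protein
selection, a ridge touch so correlated proteins do not saturate the lasso).
Features are standardised upstream, so the learner's internal scaling is
disabled. The penalty weight is tuned on a log-spaced path of 100 values
from `lambda_max` (the smallest all-zero-solution penalty) down to
`1e-4 * lambda_max`, by stratified 10-fold cross-validation; λ\* maximises
the **mean per-fold out-of-fold AUC**, the study's universal metric. The
cross-validated deviance and a one-standard-error rule are available by
configuration.

Two numerical notes. First, the AUC criterion has a structural quirk worth
knowing: at `lambda_max` all out-of-fold predictions are constant, so the
AUC curve is exactly 0.5 there, and on *pure-noise* data spurious maxima at
smaller λ win the argmax — the tuned model on noise is typically *not*
empty. Under the deviance criterion noise does collapse to the null model;
the unit tests pin this behaviour down under deviance and the discovery
stage's AUC > 0.5 gate (below) is what protects the pipeline itself from
noise models. Second, fits at a requested λ are obtained by terminating a
warm-started path exactly at that λ, so coordinate-descent zeros are exact
and `nonzero_features()` needs no epsilon.

## Feature importance by resampling

500 simulations (seed 200 by default): each draws a stratified 80:20 split,
tunes and fits the elastic net on the 80%, and measures AUC on the held-out
20%. If that AUC is better than random (> 0.5), the fitted model's nonzero
features are appended to a feature list. A feature's importance (FI) is its
frequency in the list — occurrence count over the number of simulations. The
gate is evaluated on the 20% split because it is the only out-of-sample
quantity available inside one simulation. Splits are stratified by class
because unstratified 80:20 splits of an 89-patient, 29-positive cohort can
produce one-class test sets. Gender and baseline DAS28-ESR compete in the
feature universe like every protein (they receive FI values of their own),
but the stepwise stage below always includes them as base covariates.

FI ties are broken by descending mean |coefficient| across gated models,
then lexicographically. Determinism holds within one build of the package:
the seed cannot reproduce draws made by other languages' RNGs, so
cross-implementation FI values agree statistically, not bitwise.

## Stepwise model sizes under nested cross-validation

Model sizes are evaluated with 5 stratified outer folds. For each size `k`,
the candidate model holds gender, baseline DAS, and the top-`k` proteins by
FI; within each outer-training set λ is re-tuned by inner 10-fold CV, and
AUC is recorded on the outer-training and outer-test sets. Every outer-test
sample is scored by a model that never saw it; the tests assert the fold
partition structurally.

The selected size is the smallest `k` maximising mean test AUC **among
sizes whose mean training AUC did not drop relative to `k − 1`** — the
"highest test AUC without a decrease in training AUC" rule. That phrase is
ambiguous (decrease vs. the previous size? vs. the baseline? strictly?);
comparing to the previous size, non-strictly, is the reading that actually
constrains the argmax, and a plain argmax is available by configuration.

The final model is refit on the whole cohort at a freshly tuned λ (the
original description does not say whether λ was re-tuned or carried over;
re-tuning uses all data and is self-consistent), and its decision threshold
is set at the Youden best point (max sensitivity + specificity − 1) of the
full-cohort score ROC, with ties broken toward higher specificity and then
the lower threshold.

## The published scorer

The packaged `published_model()` carries the published signature: 17 protein
coefficients, gender (M = 1, F = 0) at 0.116, baseline DAS at 2.133,
intercept b = 3.800, threshold t = 0.7136. The score is
$S = \sum_i \beta_i x_i + b$ and the response probability
$p = 1/(1 + e^{-(S - t)})$; a patient is called a responder iff p > 0.5
(equivalently S > t). Exactly p = 0.5 is called non-responder: at exact
indifference the tool does not promise benefit.

Two deployment decisions deserve emphasis:

* **Baseline DAS is standardised** against the reference cohort like the
  proteins, although the published description only states protein scaling.
  A raw DAS of ~5 times β = 2.133 would contribute ~11 to a score compared
  against a threshold of 0.71 and swamp every protein term; only the z-scale
  makes the printed coefficients jointly coherent. Gender stays raw 0/1, as
  its coding is printed explicitly.
* **The reference statistics of the original 89-patient cohort are not
  public.** The package ships a clearly labelled *synthetic* stand-in
  (`synthetic_reference_stats.csv`; the baseline-DAS mean 5.4 / SD 1.3 are
  the printed combined-cohort values, the protein rows are plausible
  invented NPX statistics frozen once). Scores computed with the stand-in
  are exact in the coefficients but *not* clinically meaningful; real use
  requires supplying the true cohort statistics via
  `published_model(reference = ...)`.

## Endotype discovery

PCA (SVD of the column-centered z-matrix) explores molecular structure.
The number of meaningful components is chosen by leave-one-out PRESS: each
held-out sample is reconstructed from a PCA fitted without it using `q`
components. The *naive* reconstruction projects the full held-out row onto
the training loadings, so each cell participates in predicting itself and
PRESS decreases toward `q = max` — a known bias. The *pseudoinverse* method
predicts each cell from the row's other coordinates via least-squares scores
on the loadings with that coordinate's row removed (computed in closed form
by a rank-one Sherman–Morrison downdate and verified in the tests against an
explicit least-squares oracle); its PRESS minimum sits at the true rank on
structured fixtures. A third, "approximate", variant used by some
implementations is not included because no published description of its
algorithm exists.

Endotypes are defined by the *sign* of a chosen component's score (the third
component by default, where the bimodal split appears in this kind of
cohort): positive scores form endotype 1, negative endotype 2; an exact zero
goes to endotype 2. Because SVD signs are arbitrary, the component is
oriented so that endotype 1 has the higher mean baseline DAS when clinical
data are available, otherwise so that the largest-|loading| protein loads
positively. `compare_endotypes()` then tests each demographic/clinical
variable between the groups — Welch t-tests for continuous variables,
chi-square without continuity correction for binary ones (whether the
original analysis used Yates' correction is unknowable from its description;
both are exposed).

## The synthetic cohort generator

`generate_cohort()` draws protein z-values from a block-correlated Gaussian
factor model (`z = sqrt(rho) f_block + sqrt(1-rho) e`), optionally adds a
±strength bimodal latent factor to one block (the planted endotype), and
generates the response from a logistic model in the standardised features —
the same family the pipeline fits, so parameter recovery is a fair oracle.
The intercept is solved numerically so the mean response probability equals
the configured prevalence. Defaults emulate the published cohort: n = 89,
352 proteins on 4 panels, prevalence 60/89, male prevalence 21/89, gender
log-odds effect −1.4 and +0.9 per SD of baseline DAS (both back-computed
from the printed responder/non-responder contingency and means), DAS
~ N(5.4, 1.3²) truncated to [0, 10], below-LoD rate 1.5% with the LoD placed
on an order statistic (a type-1 quantile) so the realised missing rate
tracks the configured one, and a QC-warning rate of 0.2% chosen so combined
QC + LoD missingness stays below the ~2% a real cohort of this kind shows.
`make_paper_like_cohort()` additionally fixes the responder count to exactly
60 by weighted sampling and plants 17 proteins at the published
coefficient magnitudes (jittered ±10%).

What a green test on synthetic data does and does not establish: the
generator is Gaussian, blockwise-exchangeable and logistic-in-features; real
plasma proteomes have heavier tails, batch structure, and effects that are
not linear in z. Recovery results validate the *pipeline's logic*, not the
clinical signature. One consequence embraced by the acceptance tests: the
individual-protein recovery criterion is evaluated on an *uncorrelated*
cohort, because with correlated blocks the elastic net deliberately shares
weight among correlated neighbours of a planted protein — the same
weight-sharing the original study describes for its own highly correlated,
low-coefficient signature proteins — which makes "the planted protein ranks
in the top 15" an unidentifiable demand. The correlated regime is exercised
by the end-to-end smoke test and the module tests instead. A
misspecification stress knob (t-distributed noise) was considered and left
out: none of the stated checks depend on it.

## Numerical and degenerate-input choices

* Coordinate-descent threshold 1e-7, max 1e5 passes; both in
  `enet_control()`.
* Single-feature designs are padded with an all-zero dummy column (the
  solver requires two); the dummy's coefficient is exactly zero under any
  penalty and is dropped from results.
* ROC candidate thresholds are midpoints between consecutive distinct
  scores plus ±∞, so curves always contain (1, 0) and (0, 1); AUC is the
  Mann–Whitney probability with ties counting ½.
* MCC is defined as 0 whenever a 2×2 marginal is 0.
* Leave-one-out λ tuning degrades from per-fold AUC to pooled out-of-fold
  AUC (a per-fold AUC needs both classes in the fold).
* Model JSON is written with 17 significant digits, which round-trips
  doubles losslessly.

## Known limitations

* The packaged scorer's stand-in reference makes its *probabilities*
  synthetic; only the coefficient arithmetic is exact.
* FI values reproduce bitwise only within one build (RNG portability).
* The CLI reads JSON configuration, not YAML.
* No confidence intervals on AUC, no alternative learners, no
  enrichment/network analysis: all outside this package's scope.
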