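---
title: "Gene-pair survival signatures: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-pair survival signatures: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairsurv)
```

## The model

`pairsurv` builds prognostic indices from *relative expression orderings*.
For a canonically ordered gene pair $(g_1, g_2)$ (alphabetical,
$g_1 < g_2$) and a sample with expression vector $x$, the pair indicator is

$$ s = \begin{cases} 0 & x_{g_1} > x_{g_2} \\ 1 & \text{otherwise,} \end{cases} $$

and a signature with pairs $k = 1, \dots, K$ and weights $w_k$ scores a
sample as $\mathrm{index} = \sum_k w_k s_k$ — a Cox proportional-hazards
linear predictor over binary within-sample comparisons. Ties score 1, the
literal "otherwise" branch; ties are essentially absent on continuous
array data but common in integerized or coarsely quantized data, so the
convention is fixed and tested rather than left to chance.

The load-bearing property is **monotone invariance**: any strictly
increasing transform applied to all values of one sample leaves every
indicator, hence every score, unchanged. Platform response curves, log
transforms, and scale factors all act within samples, so a signature
trained on one set of platforms applies verbatim to another. This is why
the pipeline performs *no* cross-sample normalization or batch
correction: the feature space, not a preprocessing step, absorbs
platform effects. The invariance is asserted as an exact (bitwise)
equality in the test suite: the entire pipeline — selected pairs,
weights, cutoff, per-sample scores — is identical with and without
per-cohort monotone distortions.

## The training pipeline

`pair_signature()` runs, in order:

1. **Enumeration.** All $G(G-1)/2$ unordered pairs of the harmonized
   gene set (genes present in every cohort), in canonical order.
2. **Constancy filter.** A pair whose indicator is constant (all 0 or
   all 1) within *any single cohort* is dropped. The rule's motive is
   cross-platform robustness: a pair that never flips on one platform is
   either uninformative there or an artefact of that platform's dynamic
   range. "Constant in each dataset" could also be read as "constant in
   the pooled data"; we adopt the stricter per-cohort reading as the
   default and expose `scope = "pooled"` for the lenient one. An optional
   minority-frequency filter (`min_freq`) exists but is off by default,
   since the constancy rule is the only documented exclusion.
3. **Log-rank screen.** Each surviving pair dichotomizes the training
   samples; pairs with two-group log-rank $p < 0.05$ (unadjusted — an
   intentionally liberal screen; a Benjamini–Hochberg mode is available
   but off by default) proceed. The screen runs as one vectorised pass
   (`logrank_screen()`), algebraically identical to the per-pair test.
4. **LASSO-Cox selection.** The screened indicators enter an
   L1-penalized Cox model (`glmnet`); the penalty is chosen by 10-fold
   cross-validated partial-likelihood deviance at the one-standard-error
   rule (`lambda_rule = "1se"`, with `"min"` as fallback). Indicators are
   *not* standardized by default: each coefficient then reads directly as
   the log-hazard step of one pair flip. Fold assignment is stratified by
   event status — with ~37% events, unstratified folds vary widely in
   event count and the fold deviances the 1-SE rule compares become
   incommensurable.
5. **Re-fit.** Weights are the unpenalized Cox coefficients re-fitted on
   the selected pairs (Breslow ties). Building the final index by
   ordinary Cox regression *after* selection motivates the re-fit
   default; `weights = "penalized"` keeps the shrunken path coefficients
   instead, since either convention is defensible and published tables
   rarely say which was used.
6. **Cutoff.** The risk cutoff maximizes Youden's $J$ =
   sensitivity + specificity − 1 on the training time-dependent ROC at a
   reference horizon (default 1825 days = 5 years, a conventional
   landmark for early-stage lung cancer; clamped to the last observed
   event time when follow-up is shorter). Ties break toward the smaller
   threshold. The cutoff criterion itself is a design choice — published
   gene-pair indices typically state the cutoff but not the rule — so the
   rule is fixed, logged in the model metadata, and configurable.

Classification is `high` iff score `>` cutoff (a score exactly at the
cutoff is `low`); the boundary convention is arbitrary but fixed and
tested.

`build_acpi()` combines a signature score with clinical covariates by a
multivariate Cox fit on (score, stage, age); stage is coded I = 1, II = 2
and enters as a continuous covariate in raw units, as does age in years
(the magnitudes of the published combination imply raw, unstandardized
inputs). Stages beyond II are rejected: the intended population is
early-stage disease.

## Survival machinery and numerical choices

Standard estimators are delegated to the `survival` and `glmnet`
packages: Kaplan–Meier (`survfit`), log-rank (`survdiff`), Cox PH
(`coxph`, Breslow ties by default, Efron available), penalized Cox CV
(`cv.glmnet`). The test suite still checks each against an independent
oracle — hand-summed hypergeometric log-rank terms, grid maximization of
a hand-coded Breslow partial likelihood (agreement to $10^{-4}$), KKT
subgradient conditions along the LASSO path and agreement with the
unpenalized fit as $\lambda \to 0$ (to $10^{-3}$), a 10,000-permutation
null distribution for the log-rank p-value.

Implemented in the package because no installed dependency provides them:

* **Time-dependent ROC** (`td_roc()`): cumulative-case/dynamic-control
  sensitivity and specificity at a horizon, with the conditional survival
  $S(t \mid \text{marker})$ estimated by a weighted Kaplan–Meier over a
  nearest-neighbour window in marker percentile. The span default
  $0.25\,n^{-0.2}$ is the conventional rate for this smoother. The
  estimator guarantees monotone ROC curves; AUC is the trapezoidal area.
  Degenerate inputs error: a horizon outside follow-up, no cases or no
  controls at the horizon, a flat curve at cutoff selection.
* **Harrell's C** (`harrell_c()`): concordant over comparable pairs,
  tied markers counting 0.5; a pair is comparable when the earlier
  observation is an event (or an event tied in time with a censoring).
  Computed with per-observation contributions, which makes the
  leave-one-out jackknife in `compare_concordance()` an $O(n^2)$
  operation rather than $O(n^3)$. The jackknife SE of the paired
  difference of two C statistics was validated against a 1000-replicate
  bootstrap (within 20%) and holds its nominal type-I error (rejection
  rate in (0.03, 0.08) at $\alpha = 0.05$ over 500 null simulations);
  a closed-form U-statistic variance would also do, but the jackknife is
  simpler to state and verify.
* **RMST** (`rmst()`): exact step-function area under the Kaplan–Meier
  curve on $[0, \tau]$; equals `mean(pmin(T, tau))` on uncensored data.
* **RMS curves** (`rms_curve()`): model-based
  $\mathrm{RMST}(x) = \int_0^\tau S_0(t)^{\exp(\beta x)} dt$ from a
  single-covariate Cox fit with Breslow baseline. Whether published RMS
  curves are model-based or smoothed empirical values is usually
  unstated; the model-based form is adopted because it is well-defined at
  every index value and inherits the PH assumption already made. Grid
  points outside the observed index range are flagged as extrapolation.

Convergence and degeneracy: Newton iterations in `coxph` run to
`eps = 1e-10`; monotone likelihoods (perfect separation) are detected by
a coefficient bound ($\|\beta\|_\infty > 15$) and reported as a classed
error instead of returning astronomically large hazard ratios; collinear
covariates are rejected up front; an empty selection at the 1-SE penalty
is a classed error advising the `lambda_rule = "min"` fallback rather
than a silent null model.

## What the synthetic generator emulates — and what it does not

`simulate_cohorts()` provides ground truth for every pipeline stage. Per
sample: latent log-normal expression with gene-specific location and
scale; the two genes of each *true pair* share a latent factor and a
common location with a small offset, so their indicator is non-degenerate
(minority frequency roughly 20–50% — with fully independent genes many
pairs would sit near-constant); age $\sim N(65, 8)$ truncated to
[35, 90]; stage II with prevalence 0.25; survival from a Weibull
proportional-hazards model via inverse-transform sampling with linear
predictor $\sum_j \beta_j z_j + \gamma_{age}(age - 65) +
\gamma_{stage}(stage - 1)$; censoring $\sim U(0, c)$. Each cohort's
expression then passes through its own strictly increasing platform
transform (affine, power, log-logistic, identity); a transform that fails
strict monotonicity *on the data actually present* — including
floating-point saturation — is rejected, since a collapsing map silently
destroys pair information.

Defaults describe a desk-scale version of a merged multi-cohort
microarray study: 4 cohorts × 200 samples, 30 genes, 5 true pairs with
$|\beta| \in [0.8, 1.0]$, $\gamma_{age} = 0.03$ per year and
$\gamma_{stage} = 0.65$ per step (hazard ratios ≈ 1.03 and 1.9, the
magnitudes reported for age and stage in early-stage lung
adenocarcinoma cohorts), and a baseline/censoring calibration
(scale 11000 days, shape 1.2, $c = 5500$ days) chosen so the event
fraction is ≈ 0.37 and the median observed time ≈ 1700 days, matching
published cohort tables. `tie_fraction` snaps a share of log-values to a
coarse grid to exercise the tie rule; it is 0 (continuous) by default.

What passing tests on this generator do **not** show about real data: the
generator has no probe-level artefacts, no missing values, no correlation
structure beyond the per-pair latent factor, hazards that are exactly
proportional, and true effects concentrated in a handful of pairs.
Recovery rates and concordance gains measured on it are best-case
figures; on real cohorts the screen and the LASSO face correlated,
weaker, and more numerous signals.

Test problem sizes are the package's own choices: recovery uses 50 seeded
runs at n = 800 (≥ 4 of 5 planted pairs in ≥ 90% of runs) and
coefficient recovery 20 runs at n = 1500 (mean error ≤ 0.15 per
coefficient); the clinical-combination comparison uses 50 runs at
n = 700 per arm. The full suite runs in well under five minutes on one
CPU, the two simulation experiments in about two.

## The frozen published index

`published_atgpi()` returns the 10-pair, 15-gene autophagy index for
overall survival in early-stage lung adenocarcinoma with its published
coefficients (shipped digit-for-digit as a JSON fixture) and cutoff 1.35;
`published_acpi()` returns the clinical combination
$0.6657 \cdot \mathrm{ATGPI} + 0.4445 \cdot \mathrm{stage} +
0.0199 \cdot \mathrm{age}$ with cutoff 1.31. Scoring, bounds and worked
single-pair profiles are covered by exact tests; the attainable score
range of the published model, computed from its coefficients, is
$[-1.365474,\; 0.6505269]$.

One internal inconsistency of the published values is worth knowing: the
published cutoff 1.35 exceeds the maximum attainable score 0.6505269, so
the frozen scorer classifies every possible profile as low risk at its
own cutoff. The published linear predictor was evidently on a different
scale than the tabulated coefficients reproduce. Re-deriving the cutoff
would require the original patient-level cohorts and is out of scope;
users training their own signatures get a self-consistent cutoff from
their own training ROC.

## Known limitations

* No time-varying covariates, competing risks, stratified Cox, or
  interval censoring.
* The constancy filter needs at least two samples per cohort, and the
  cutoff needs at least one event before the reference horizon.
* Screening is marginal (pair-at-a-time); jointly weak but collectively
  informative pairs can be missed at the screen.
* The published cutoff caveat above.
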