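---
title: "Engineering a polytomous item bank: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engineering a polytomous item bank: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catbank)
```

`catbank` implements the complete engineering workflow behind a calibrated
item bank for a patient-reported experience measure: descriptive screening,
item-response-theory (IRT) assumption checks, generalized partial credit
model (GPCM) calibration, differential item functioning (DIF) screening,
expected-a-posteriori (EAP) scoring, and a computerized adaptive testing
(CAT) simulator. This vignette is the package's own account of the science:
the models, their assumptions, the tunable parameters and why their defaults
are what they are, and the places where a design decision was genuinely open.

## 1. The measurement model

An item with `m` ordered categories (coded `0 … m−1`) follows the GPCM:
adjacent-category log-odds are linear in the latent trait,

$$\log \frac{P(X = x \mid \theta)}{P(X = x - 1 \mid \theta)} = a\,(\theta - b_x),$$

so that

$$P(X = x \mid \theta) =
  \frac{\exp \sum_{k=0}^{x} a(\theta - b_k)}
       {\sum_{c=0}^{m-1} \exp \sum_{k=0}^{c} a(\theta - b_k)},$$

with the $k=0$ term defined as zero. The discrimination $a > 0$ measures how
sharply the item separates respondents; the category-boundary thresholds
$b_1, \dots, b_{m-1}$ locate the points on the trait continuum where adjacent
categories are equally likely. The partial credit model (PCM) constrains a
single $a$ across items, and the two are compared by a likelihood-ratio test
plus AIC/BIC (`compare_models()`). With `m = 2` the GPCM reduces exactly to
the two-parameter logistic model, which the test suite exploits as an oracle.

The latent metric is identified by the standard-normal prior on $\theta$ —
no post-hoc rescaling is applied. Reverse-worded items are flipped
(`reverse_score()`) before any analysis, so higher codes consistently mean a
better experience.

**Missing and "not applicable".** The two non-response kinds are distinct in
storage and in the CSV interchange format (`NA` vs `NAP`) but both are
treated as ignorable by every likelihood: a "not applicable" answer carries
no ordinal information about the trait, and the marginal likelihood simply
omits those terms. A trait-dependent missingness mechanism exists in the
generator (off by default) precisely so users can probe how sensitive their
results are to that ignorability assumption.

## 2. Calibration: marginal maximum likelihood via EM

`calibrate()` integrates $\theta$ out over a quadrature grid — 61 equally
spaced nodes on $[-4, 4]$ with N(0,1) weights, renormalized — and maximizes
the marginal likelihood by EM. The E-step forms each person's posterior over
the nodes; the M-step maximizes the expected complete-data log-likelihood
item by item with quasi-Newton updates in slope/intercept parameterization
(numerically stabler than slope/threshold; parameters are converted back on
output). For the PCM the intercepts are optimized per item and the common
slope by a one-dimensional search, alternating once per cycle; both steps
increase the expected complete-data log-likelihood, so the marginal
log-likelihood is non-decreasing — a property the tests assert at `1e-8`
tolerance on every fit.

Numerical choices, all overridable:

* **Grid**: 61 nodes on $[-4, 4]$. The tests compare the 61-node EAP against
  a 2001-node oracle and require agreement within $10^{-3}$; 61 nodes is the
  conventional density at which the discretization error is negligible
  relative to sampling error.
* **Convergence**: largest absolute parameter change $< 10^{-4}$, at most
  500 EM cycles. Hitting the cap returns a result flagged `converged =
  FALSE` with a warning rather than an error, because a near-converged bank
  is still diagnosable.
* **Overflow**: every probability evaluation is guarded by log-sum-exp.
* **Low discrimination**: items with $a < 0.50$ are *flagged*, never
  auto-removed — content relevance can outweigh low information, and the
  judgment belongs to the analyst. Removal is a trivial `subset_items()`
  call.
* **Empty categories**: a category with zero observations makes its
  intercept unidentified, so `calibrate()` refuses with an error naming the
  item and category; `collapse_empty_categories()` folds such categories
  into their lower neighbour first (leading empty categories merge upward).

Item fit is summarized by the infit mean square (`infit()`): the
information-weighted ratio of observed to expected squared residuals at the
EAP trait estimates, conventionally acceptable in $[0.7, 1.3]$. Because EAP
estimates are shrunken toward the prior mean, infit on model-consistent data
sits slightly *below* 1, more so for short banks — worth knowing before
reading a value of 0.8 as "overfit".

## 3. Assumption checks

IRT scoring presumes (essential) unidimensionality, local independence and
monotonicity. The package checks all three on the ordinal-appropriate
substrate, a polychoric correlation matrix (`polychoric_corr()`): two-step
maximum likelihood with thresholds from the marginals, pairwise correlations
from the bivariate tables (0.5 continuity correction for empty cells), and
eigenvalue-clipping smoothing if the assembled matrix is not positive
semidefinite (the smoothing is reported).

* **Dimensionality** (`eigen_and_parallel()`): sorted eigenvalues, the
  first-to-second eigenvalue ratio, the first factor's variance share, and
  parallel analysis against random normal data — 500 replicates, 95th
  percentile. These two settings are conventional defaults; the method's
  originators left them open and results are insensitive in the tested
  range.
* **One-factor fit** (`fit_one_factor()`): unweighted least squares (ULS) on
  the polychorics. The reported chi-square is formed from the ULS
  discrepancy with $(n-1)$ scaling, RMSEA with a noncentrality-based 95%
  confidence interval, and CFI/TLI against the independence baseline. These
  indices are *estimator-dependent*: they are comparable across models fit
  by this function but not numerically interchangeable with indices from
  other estimators (e.g. weighted least squares in other software), which is
  why the package's validation is property-based — a perfectly one-factor
  population matrix must yield $\chi^2 = 0$, RMSEA $= 0$, CFI $=$ TLI $= 1$,
  and a two-factor population forced into one factor must misfit (RMSEA
  $> 0.10$). Heywood loadings are clamped to 0.999 with a warning.
* **Local independence**: residual correlations after the one-factor fit,
  flagged above 0.25.
* **Bifactor structure** (`bifactor()`): a confirmatory orthogonal bifactor
  model (general factor on all items, one group factor per cluster) fit by
  ULS, yielding hierarchical omega ($\omega_h$), per-group
  omega-hierarchical, and explained common variance (ECV). Group membership
  defaults to the highest absolute loading in an obliquely rotated
  three-factor principal-axis solution; the rotation is promax — the oblique
  rotation available in base R — chosen over other oblique criteria as a
  package decision. Two technical points matter here: a zero group loading
  is a *saddle* of the ULS surface, so starting values are staged (general
  factor from a one-factor fit, group factors from residual blocks); and a
  bifactor model with only **two** group factors of near-equal loadings is
  unidentified — the general/group variance split forms a continuum of
  exact solutions — so at least three group factors should be used, as in
  the package's own validation.
* **Monotonicity** (`monotonicity_check()`): rest-score means across decile
  bins; an item fails when a drop between adjacent bins exceeds twice the
  pooled standard error. Ten bins and the two-SE tolerance are the package's
  defaults for a ~500-person study; both are arguments.
* **Category recoding** (`recode_categories()`): categories that are never
  modal anywhere on the trait grid after a provisional GPCM fit are
  collapsed into their lower neighbour. "Never modal" is a reproducible,
  code-level criterion standing in for the visual inspection of item
  characteristic curves that practitioners often describe; the returned map
  (item → old category → new category) makes every collapse auditable.

## 4. DIF screening

`dif_test()` fits three nested proportional-odds models by maximum
likelihood (via `MASS::polr`): `item ~ θ`, `+ group`, `+ θ×group`. Overall
DIF is the model-1-vs-model-3 likelihood-ratio test at the conventional
gate $p < 0.01$; magnitude is the pseudo-$R^2$ change, McFadden's measure by
default with Nagelkerke as an option (the field's reporting is often
ambiguous about which; the choice is explicit here). Magnitude classes are
negligible ($< 0.13$), moderate ($[0.13, 0.26)$) and large ($\ge 0.26$) —
boundary values deliberately go to the *higher* class so the classification
is total and deterministic. Only large DIF with a significant overall test
triggers exclusion.

The matching criterion is the model-based EAP $\theta$, not a raw sum score,
and the screen is single-pass (no iterative purification). A grouping
variable with a degenerate level collapses all three models together
($\Delta R^2 = 0$, $p = 1$); separation or non-convergence flags the result
rather than silently dropping it. A three-level diagnosis variable enters as
two indicator contrasts, doubling the interaction degrees of freedom — the
row count of the sweep is always items × variables. Under a simulated null
the gate holds its nominal 1% rate over 500 replicates, which the acceptance
suite re-verifies on every run.

## 5. Scoring and the 0–100 scale

`eap_score()` returns the posterior mean and SD of $\theta$; a person with
no observed responses receives the prior (mean 0, SD 1). The 0–100 transform
is linear between two anchors, clipped at the ends; the default anchors are
the EAP estimates of the all-minimum and all-maximum response patterns, so
the most negative expressible pattern scores 0 and the most positive 100.
Any other anchor pair (for instance, one frozen from a reference
calibration) can be passed explicitly — the default is a reproducible
convention, not a claim about the instrument's published scaling, whose
anchors are not recoverable from printed results.

## 6. The CAT simulator

`run_cat()` implements the standard adaptive loop: the first item maximizes
Fisher information at the prior mean $\theta = 0$; after each response the
trait and its SEM are re-estimated by EAP over the administered items; the
next item maximizes information at the current estimate, ties broken by
lowest item index; the test stops when SEM $\le$ the threshold or the bank
is exhausted. Three design points are deliberate:

* **SEM is the EAP posterior SD**, not $1/\sqrt{\text{information}}$ — the
  estimator is EAP throughout, and the posterior SD is its natural
  uncertainty (the two agree asymptotically).
* The stopping comparison is $\le$; with a continuous SEM the difference
  from $<$ is immaterial, and $\le$ makes the boundary case well-defined.
* The SEM trajectory is *not* asserted to be non-increasing — a surprising
  response can transiently widen the posterior — but a stop reported as
  `SEM_REACHED` always has final SEM at or below the threshold.

`simulate_cat_study()` replays the CAT for every person at each stopping
level (defaults 0.33, 0.44, 0.55, spanning reliabilities
$1 - \text{SEM}^2 \approx 0.90$ to $0.70$) and reports the correlation and
RMSE between CAT and full-bank trait estimates, mean items administered, and
the median (IQR) of final 0–100 scores. Tightening the threshold must trade
burden for precision monotonically, and as SEM $\to 0$ the CAT estimate
equals the full-bank estimate exactly — both are asserted in tests. Because
a real cohort has missing responses, `impute_complete()` first fills gaps
with draws from the fitted model at each person's EAP estimate (seeded, so
reproducible); the simulator then runs on the completed matrix.

## 7. What the synthetic cohort emulates — and what it does not

`generate_bank()` and `simulate_cohort()` reproduce the *structure* of a
541-person severe-mental-illness calibration study: 37 five-category items
with discriminations drawn uniformly in $[0.48, 2.70]$ and thresholds in
$[-1.96, 3.25]$ (sorted within item; a `disorder` flag skips the sort to
exercise category-collapse logic), ten reverse-worded items, per-item
missingness up to ~50% following the published per-item profile
(`premium_dt_items()`), "not applicable" masking, covariates with realistic
base rates (54.7% men, 93.2% outpatient, diagnosis mix 61.9/19.6/18.5%, age
centred on a median of 36), and trait-linked adherence, quality-of-life and
satisfaction proxies (default correlations 0.3, 0.3, 0.65, matching the
weak-to-strong published associations). Optional DIF injection shifts the
thresholds and/or scales the discrimination of chosen items for a focal
group, giving every downstream detector a known target.

What it does **not** emulate: multidimensional content clusters (responses
are generated from a strictly unidimensional GPCM, so dimensionality checks
on synthetic data are clean by construction — eigenvalue ratios far exceed
those of real multi-facet instruments); item-wording effects; longitudinal
structure; and informative missingness unless explicitly switched on.
Passing tests on this cohort therefore validate the *machinery* — parameter
recovery, error rates, trade-off curves — not the substantive psychometrics
of any real instrument.

## 8. Problem sizes used in validation

The package's own validation suites run at sizes chosen to make Monte-Carlo
error small relative to the asserted tolerances while staying desk-scale:
parameter recovery on 26 items × 1000 persons (discrimination correlation
> 0.9, threshold RMSE < 0.25); DIF type-I error over 500 null replicates at
n = 1000; CAT accuracy on 500 persons with a 26-item bank (r ≥ 0.95, RMSE
≤ 0.30 at SEM ≤ 0.33); distributional checks at n = 5000–20000 with
3-standard-error bands. The end-to-end script (`scripts/acceptance.R`) uses
the study-scale 541 × 37 configuration throughout.

## 9. Known limitations

* ULS fit indices are not interchangeable with those of other estimators;
  compare like with like.
* The GPCM/PCM pair is the only model family; graded-response or
  multidimensional models are out of scope.
* DIF screening is observed-score-anchored ordinal regression without
  purification; IRT-parameter-based DIF tests are not provided.
* The CAT simulator has no exposure control or content balancing — it is a
  measurement-precision simulator, not a live test-delivery engine.
* Polychoric estimation assumes an underlying bivariate normal per pair;
  gross violations (e.g. strong floor effects with very few categories) are
  only partially absorbed by the continuity correction.
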