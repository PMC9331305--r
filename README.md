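# catbank

Item-bank engineering for patient-reported experience measures (PREMs):
screening, calibration, differential item functioning (DIF) checks, scoring,
and computerized adaptive testing (CAT) simulation for polytomous
questionnaires — with a synthetic-cohort generator so the whole pipeline can
be exercised and validated without access to patient data.

The package is aimed at psychometricians and health-services researchers who
build item banks for instruments such as experience-of-care questionnaires
in mental health (five-point Likert items, reverse-worded items, "not
applicable" response options, substantial item-level missingness).

## The model

Items are calibrated under the **generalized partial credit model (GPCM)**.
For an item with ordered categories `x = 0, …, m−1`, discrimination `a > 0`
and category-boundary thresholds `b_1, …, b_{m−1}`,

```
P(X = x | θ) = exp( Σ_{k=0}^{x} a(θ − b_k) ) / Σ_{c=0}^{m−1} exp( Σ_{k=0}^{c} a(θ − b_k) )
```

with the `k = 0` term defined as zero. The **partial credit model (PCM)** is
the nested special case with a common `a` across items. Calibration is by
marginal maximum likelihood: the latent trait θ is integrated out over a
61-node quadrature grid under a N(0,1) prior and the marginal likelihood is
maximized by an EM algorithm. Person scores are **expected a posteriori
(EAP)** estimates; the EAP posterior SD is the per-person standard error of
measurement (SEM), and a linear transform maps θ onto an interpretable
0–100 scale.

Around the calibration core the package provides the full pipeline:

| stage | functions |
|---|---|
| synthetic cohorts with known truth | `generate_bank()`, `simulate_cohort()` |
| descriptive screening | `describe_items()`, `screen_items()`, `cronbach_alpha()` |
| IRT assumptions | `polychoric_corr()`, `eigen_and_parallel()`, `fit_one_factor()`, `bifactor()`, `monotonicity_check()` |
| category management | `collapse_empty_categories()`, `recode_categories()` |
| calibration & fit | `calibrate()`, `compare_models()`, `infit()`, `information()` |
| scoring | `eap_score()`, `score_persons()`, `transform_score()` |
| DIF screening | `dif_test()`, `dif_sweep()` |
| CAT simulation | `impute_complete()`, `run_cat()`, `simulate_cat_study()` |
| external validity | `build_validity_table()` |

## Worked example

Generate a 26-item cohort with known ground truth, screen it, calibrate the
retained items, score the respondents, and simulate a CAT:

```r
library(catbank)

bank   <- generate_bank(n_items = 26, seed = 42)   # a in [0.48, 2.70]
cohort <- simulate_cohort(bank, cohort_spec(n_persons = 800,
                                            missing_rate = 0.05, seed = 43))

screen <- screen_items(cohort$responses)
screen
#> <screening_report: 23 retained, 3 excluded, alpha = 0.955>
#>   DT23, DT4, DT7

resp <- collapse_empty_categories(
  subset_items(cohort$responses, screen$retained))$responses
fit <- calibrate(resp, "GPCM")
fit
#> <calibration: GPCM, 23 items, n = 800, logL = -16249.40, AIC = 32726.79, BIC = 33260.84>

idx <- match(screen$retained, bank$labels)
cor(fit$bank$a, bank$a[idx])
#> recovered vs true discrimination: r = 0.977

scores <- score_persons(resp, fit$bank)
head(scores, 3)
#>   person_id theta   sem score_0_100
#> 1        P1 -0.47 0.199        37.6
#> 2        P2 -1.63 0.217        20.2
#> 3        P3 -0.26 0.187        40.7

complete <- impute_complete(resp, fit$bank, seed = 44)
simulate_cat_study(complete$responses, fit$bank)
#> <cat_study>
#>  sem_stop     r  rmse mean_items median_score iqr_lo iqr_hi pct_bank_exhausted
#>      0.33 0.968 0.248       3.53         43.7   32.5   54.1              0.375
#>      0.44 0.945 0.320       2.08         45.0   35.3   56.0              0.000
#>      0.55 0.914 0.399       1.40         43.8   35.3   53.2              0.000
```

Three items were screened out for high inter-item correlations; the
remaining bank recovers its generating discriminations at r = 0.977; and the
adaptive test at the tight SEM ≤ 0.33 stopping rule tracks the full-bank
score at r = 0.97 while asking 3.5 of 23 items on average. Tightening the
stopping rule monotonically trades item burden (mean items administered)
for precision (RMSE against the full-bank θ).

## Vignette

`vignettes/item-bank-engineering.Rmd` documents the statistical model, every
tunable parameter with its default and rationale, what the synthetic cohort
does and does not emulate, and the package's numerical choices and known
limitations.
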