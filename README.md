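# predictgrs

Do tumour gene-expression risk scores add prognostic value *beyond* the
clinicopathological model already used at the point of care — and if one is
grafted onto that model, does anything a clinician acts on actually change?

`predictgrs` implements that head-to-head evaluation for breast cancer as a
tested, configuration-driven R pipeline. It is aimed at biostatisticians and
methodologists evaluating genomic risk scores (GRSs — recurrence-score-style
weighted sums, risk-of-recurrence centroid correlations, good-prognosis
template correlations) against and within a PREDICT-style absolute-risk
model.

## The model at the core

For breast-cancer-specific survival in each ER stratum, the package fits

```
h_i(t) = h_0(t) · exp( PI_i + β·g_i )
```

where the clinical prognostic index `PI` enters the Cox partial likelihood
as an **offset** — coefficient fixed at one, so the validated clinical model
is not re-fitted — and the GRS `g` gets the single free coefficient `β`
(Efron ties; likelihood-ratio test on 1 df against the offset-only model).
Before the fitted term is grafted into the absolute-risk model, it is
recentred by `c = log mean(exp(β·g_i))` so the cohort-average hazard ratio
is exactly one and the tabulated baseline `S0(t)` stays valid; absolute
survival is `S(t) = S0(t)^exp(PI + treatment terms)` with complementary
log-log interpolation between baseline knots. The modified model is then
assessed by:

* **calibration** — mean predicted 10-year survival minus the observed
  Kaplan–Meier value, in percentage points;
* **discrimination** — Harrell's c with its asymptotic CI, plus out-of-bag
  bootstrap optimism (refit on each resample, apparent-minus-out-of-bag
  performance averaged over replicates);
* **reclassification** — movement between the chemotherapy-benefit bands
  < 3, 3–5 and > 5 percentage points of absolute 10-year benefit.

A synthetic-cohort generator with known proportional-hazards truth
(confounded, z-scored expression; realistic clinical marginals; exponential
or Weibull baseline) makes every stage testable without patient-level data.

## Worked example

```r
library(predictgrs)
library(dplyr)

sim <- generate_cohort(generator_config(n = 1500, seed = 42))
res <- run_pipeline(
  cohort     = sim$cohort,
  signatures = list(sim$truth$signature),
  spec_er_pos = read_predict_spec(
    system.file("extdata/configs/predict/er_positive.yaml", package = "predictgrs")),
  spec_er_neg = read_predict_spec(
    system.file("extdata/configs/predict/er_negative.yaml", package = "predictgrs")),
  outdir = "results/run", seed = 1
)

res$fits |> filter(er_stratum == "positive") |>
  select(signature, model, hr, ci_lo, ci_hi, lr_p)
#> 1 truth_linear (univariable) univariable    2.39  2.00  2.86 1.23e-22
#> 2 truth_linear               multivariable  1.58  1.32  1.90 4.22e- 7
```

The univariable hazard ratio (2.39 per score unit) collapses to 1.58 after
adjusting for the clinical index — the score's information overlaps the
clinical covariates, but the likelihood-ratio p of 4×10⁻⁷ says real
independent signal remains (the generator plants a true effect).

```r
res$evaluation |> filter(er_stratum == "positive") |>
  select(model, predicted_mean_s10, observed_s10, calibration_diff, c_index)
#> 1 PREDICT                      85.2     75.8     9.40   0.706
#> 2 PREDICT + truth_linear       84.4     75.8     8.60   0.719

res$reclass_summary |>
  select(signature, n_total, n_reclassified, pct_rounded)
#> 1 truth_linear    1115    194    17
```

Read: the (deliberately illustrative) clinical spec over-estimates 10-year
survival by 9.4 points; adding the score improves calibration by under one
point and the c-index by ~0.013, while 17% of ER-positive patients change
chemotherapy-benefit band. Calibration/discrimination barely move even when
treatment advice does — exactly the tension this pipeline exists to
quantify. `run_pipeline()` writes the per-stage tables (`scores.csv`,
`table2.csv`, `table3.csv`, `table4_<signature>.csv`, `summary.json`) under
`outdir`.

Lower-level entry points (`score_signature()`, `fit_offset_cox()`,
`rescale_grs_term()`, `chemo_benefit()`, `harrell_c()`,
`bootstrap_optimism()`, `build_reclass_table()`, …) are data-frame-in /
tibble-out and compose with the pipe; fitted objects have `tidy()` /
`glance()` methods and result types have `autoplot()`.

Bundled model specs and signature definitions under
`inst/extdata/configs/` are **illustrative synthetic defaults**: they carry
the right structure for the engine, not the published commercial constants.
Faithful runs supply real coefficient sets through the same YAML surface.
See `vignettes/grs-into-predict.Rmd` for the full methods account.

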