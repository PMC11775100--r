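# egfrtraj

Kidney-function decline is studied from longitudinal estimated glomerular
filtration rate (eGFR), but long creatinine series usually exist only in
routine electronic medical records (eMR). Creatinine assayed before
manufacturers improved standardization (around 2009) reads systematically
high, so naively mixing old eMR values with modern gold-standard measurements
makes trajectories look almost flat. `egfrtraj` is an R package for
epidemiologists who need to integrate the two sources: it quality-controls
raw eMR creatinine, estimates and removes the per-calendar-year assay bias
against same-year gold-standard values, derives eGFR, assembles event-aware
trajectories, and estimates annual decline with risk-factor regressions. A
synthetic cohort generator with known ground truth makes every stage testable
without access to restricted data.

## The model

Let `X = ln(crea_SC)` (study-center, gold standard) and `X* = ln(crea_eMR)`.
The error model is additive on the log scale,

    X* = X + s + E*,   E* ~ N(0, σ*²),

so the systematic bias in a calendar year is `s_year = μ̂*_year − μ̂_year`,
estimated on persons with both measurements in the same year (the eMR value
closest in time to the blood draw). On the original scale the correction
factor is the ratio of geometric means,

    factor_year = GM(crea_SC) / GM(crea_eMR) = exp(−s_year),

and corrected eMR creatinine is `crea_eMR × factor_year`. Years without
same-year overlap get proxy factors: interior gaps take the exponential of
the mean of the adjacent years' log biases, earlier years carry the first
estimated factor, and later years get 1.0 (no correction) once the last
estimate is close to unity.

eGFR comes from the race-free CKD-EPI 2021 creatinine equation; CKD is
flagged at eGFR < 60 mL/min/1.73m². Assessments after severe kidney events
(AKI, ESKD, dialysis, transplant, nephrectomy) or after a first eGFR < 15
are censored, values within ±6 months of a pregnancy are excluded, and
person-specific annual decline is the annualized first-to-last difference
(positive = declining), summarised as mean ± 1.96·SE and regressed on risk
factors by OLS.

## Worked example

```r
library(egfrtraj)

res <- run_pipeline(synthetic_config(n_persons = 2000, seed = 7))
res$bias_estimates[, 1:4]
#>    year n_pairs factor log_bias
#>    2007     158  0.833   0.182
#>    2008     201  0.834   0.182
#>    2009     203  0.897   0.109
#>    2010     173  0.904   0.101
#>    2012     166  0.949   0.0522
#>    2013     170  0.975   0.0256
res$decline_summary
#>   mean_decline ci_low ci_high n_persons m_assessments
#>           1.02  0.998    1.04      1958         21775

# the uncorrected contrast
run_pipeline(synthetic_config(n_persons = 2000, seed = 7),
             bias_correction = FALSE)$decline_summary
#>   mean_decline ci_low ci_high n_persons m_assessments
#>          0.279  0.244   0.314      1958         21775
```

The generator injected the bias schedule 0.84…0.97 over 2007–2013 and a true
mean decline of 1.0 mL/min/1.73m² per year. The pipeline recovers the
factors (0.833…0.975), and the corrected cohort mean (1.02, CI 0.998–1.04)
sits at the truth while the uncorrected estimate (0.28) is attenuated
several-fold — old assays reading high depress early eGFR and flatten the
apparent decline. `res$regressions` holds the risk-factor coefficient
tables, `res$peri_aki` the mean decline around incident acute kidney injury
(3.49 for this seed, several times the overall mean), and
`autoplot(res$bias_table)` / `plot_trajectory()` draw the standard figures.

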