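# benzrisk

Quantitative leukemia risk assessment for workers exposed to low levels of
benzene, built on the linearized multistage (LMS) dose-response model.

Occupational hygienists and epidemiologists measure benzene exposure two
ways: personal air monitors (a time-weighted average concentration,
`C_TWA`, in mg/m³) and urinary metabolites — S-phenylmercapturic acid
(S-PMA) and trans,trans-muconic acid (t,t-MA), in µg/g creatinine. This
package turns either measurement into an estimated lifetime leukemia risk,
and cross-checks the answer against two independent frameworks: the EPA
inhalation-unit-risk model and the Singapore semi-quantitative risk matrix.

## The model

The multistage quantal model for lifetime cancer incidence at dose *d* is

    P(d) = r + (1 − r) (1 − exp(−Σᵢ aᵢ dⁱ)),   0 ≤ r < 1,  aᵢ ≥ 0,

with background response *r* and stage coefficients *aᵢ*.
`fit_multistage()` estimates the parameters by constrained binomial maximum
likelihood on grouped incidence data (the benchmark-dose-software
convention), with multi-start optimization, exact boundary handling
(*aᵢ* = 0 is a valid MLE) and a chi-square goodness-of-fit test (deviance
and Pearson). The dose metric is cumulative exposure
`Dc = C_TWA × T` (mg/m³·year) over the working duration *T* years.

Fitted to the bundled grouped incidence table of a large Chinese
occupational cohort (`chinese_benzene_cohort()`: 35,804 unexposed /
56,528 exposed workers, strata at 0, 65 and 388 mg/m³·year), the degree-1
model is

    P(Dc) = 4.32e-4 + (1 − 4.32e-4) (1 − exp(−1.38e-6 · C_TWA · T)),

available with frozen coefficients as `benzene_cohort_lms()`.

Urinary metabolites reach the same model through ln-ln calibration
regressions with a smoking covariate
(`ln S-PMA = 0.77 ln C_TWA + 0.12 SMO + 0.54`;
`ln t,t-MA = 0.68 ln C_TWA + 0.08 SMO + 4.73`), inverted by
`invert_to_air()` — so a worker whose air reading is below the 0.05 mg/m³
detection limit can still be assessed from a urine sample.

## Worked example

Fit the dose-response model to the bundled cohort:

```r
library(benzrisk)
fit <- fit_multistage(chinese_benzene_cohort(), degree = 1)
fit
#> Multistage quantal dose-response model (degree 1)
#>   P(d) = r + (1 - r) * (1 - exp(-(a1*d^1)))
#>         r        a1
#> 4.321e-04 1.386e-06
#> log-likelihood: -7.7681  converged: TRUE
goodness_of_fit(fit)
#> Goodness of fit (deviance): chi-square = 1.3216, df = 1, p = 0.2503
#>   [pearson 1.2764 (p = 0.2586); deviance 1.3216 (p = 0.2503)]
```

The background leukemia risk is 4.32 × 10⁻⁴; each additional mg/m³·year of
cumulative benzene exposure adds ≈ 1.38 × 10⁻⁶ (risks are effectively
linear at occupational doses), and the 3-group fit leaves 1 degree of
freedom with an acceptable fit (p = 0.25).

Assess a (synthetic) worker population end-to-end — QC, aggregation,
quartile grouping, risks by air and by both biomarkers, trend test:

```r
sim <- generate_workers(synthetic_config(seed = 42))
tab <- run_assess(sim$samples, sim$workers)
tab[, c("group", "n", "mean_ce", "risk_air_1e4", "risk_spma_1e4", "risk_ttma_1e4")]
#>   group  n mean_ce risk_air_1e4 risk_spma_1e4 risk_ttma_1e4
#> 1    <3 31    1.69         4.34          4.36          4.37
#> 2   3-5 13    4.01         4.38          4.41          4.45
#> 3  5-12 23    8.11         4.43          4.48          4.54
#> 4  >=12 31   74.06         5.34          6.72          7.25
#> 5 Total 98   26.40         4.68          5.14          5.33
attr(tab, "trend")$air
#> ANOVA linear trend: t = 4.6729 (df = 94), p = 9.89e-06
```

Risk rises monotonically across exposure groups (reported in 10⁻⁴ units,
2 decimals), biomarker-based estimates track the air-based ones, and the
trend is highly significant. Workers below the detection limit are
assessed from t,t-MA via `attr(tab, "below_lod")`. Compare the three
frameworks per group:

```r
cmp <- run_compare(sim$samples, sim$workers)
cmp[, c("group", "c_twa", "risk_lms_1e4", "epa_low_1e4", "epa_high_1e4",
        "singapore_value", "singapore_label")]
#>   group c_twa risk_lms_1e4 epa_low_1e4 epa_high_1e4 singapore_value singapore_label
#> 1    <3  1.87         4.34         0.1          0.4            3.87       High risk
#> 2   3-5  3.29         4.38         0.3          1.0            4.47       High risk
#> 3  5-12  4.47         4.43         0.6          2.2            4.47       High risk
#> 4  >=12 23.27         5.34         4.7         16.6            5.00  Very high risk
```

All three models agree that even the lowest group (< 3 mg/m³·year) sits
above the EPA's 1 × 10⁻⁶ acceptable-risk floor; the LMS estimate exceeds
the EPA range at low exposures because it carries the cohort's background
response.

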