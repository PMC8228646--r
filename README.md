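# pneumolag

Distributed lag non-linear modelling of daily meteorology and low-count
hospital admission series, built for studies of suspected-pneumonia
admissions in settings where the raw data are free-text paper registers
with substantial missingness.

## The problem and who this is for

Ambient temperature and humidity influence respiratory infections with a
delay: a cold or dry spell can change hospital admissions days to weeks
later. Quantifying this requires three things at once, and this package
provides them as one tidyverse-native pipeline for epidemiologists and
health-climate researchers:

1. **Cleaning real admission registers** — identifying suspected-pneumonia
   admissions from free-text reasons with keyword screening, reconstructing
   missing admission dates from discharge date minus length of stay, and
   multiply imputing missing lengths of stay by predictive mean matching
   (PMM) with Rubin's-rules pooling of downstream estimates.
2. **A distributed lag non-linear model (DLNM)** for the daily counts. Each
   exposure's effect is a smooth surface f(x, l) over exposure value x and
   lag l, represented by the tensor product of two natural cubic spline
   bases and embedded in the linear predictor through a *crossbasis*
   matrix with row t, column (i, j) equal to
   Σ_{l=0..L} B_{x,i}(x_{t−l}) B_{l,j}(l), L = 21 days.
   Because daily counts are low (≈1.3/day), overdispersed and have excess
   zero days, the likelihood is a **zero-inflated negative binomial**
   (ZINB): with π_t = logistic(z_t'γ) and μ_t = exp(x_t'θ),
   a zero day contributes log[π_t + (1−π_t) NB(0; μ_t, α)] and a positive
   count log(1−π_t) + log NB(y_t; μ_t, α), Var = μ + αμ². The rate
   component holds lagged crossbases for mean temperature and relative
   humidity, an unlagged spline for diurnal temperature range (DTR),
   day-of-week indicators, a 6-month Fourier seasonal pair and a long-term
   trend spline; the zero component holds day-of-week, the previous three
   days' counts, and the seasonal pair.
3. **Interpretation**: centered relative rates RR(x, l) =
   exp([b_x(x) − b_x(c)] ⊗ b_l(l) · θ) with delta-method intervals
   (reference values c: 21 °C, 67 %, 1.3 °C), cumulative 21-day
   associations, and backward-perspective attributable fractions
   AF_t = 1 − exp(−Σ_l η(x_{t−l}, l)) with Monte-Carlo empirical
   intervals and climate-shift scenarios (e.g. the whole temperature
   distribution +2 °C).

A synthetic-data module generates meteorology, admission counts and raw
records from a known ground-truth model, so every stage can be validated
against closed-form truth.

## Worked example

```r
library(pneumolag)

# a synthetic 8-year study with known truth
met    <- simulate_meteorology(3021, seed = 11)
daily  <- simulate_admissions(met, truth_model(), seed = 12)

fit <- fit_zinb_dlnm(build_design(daily))
glance(fit)
#> # A tibble: 1 x 5
#>   logLik    df alpha n_used converged
#>    <dbl> <int> <dbl>  <int> <lgl>
#> 1 -4430.    63 0.686   2979 TRUE

cumulative_rr(fit, "mean_temp", exposure_grid = c(12, 30))
#> # A tibble: 2 x 5
#>   term      exposure    rr rr_low rr_high
#>   <chr>        <dbl> <dbl>  <dbl>   <dbl>
#> 1 mean_temp       12 0.863  0.376    1.98
#> 2 mean_temp       30 0.224  0.0968   0.516
```

The fitted cumulative rate ratios at the probe temperatures bracket the
generating truth (RR 1.27 at 12 °C and 0.34 at 30 °C vs the 21 °C
reference): a 3000-day series identifies the protective high-temperature
association clearly, while the weaker cold effect carries a wide interval,
exactly the behaviour expected at ~1.3 admissions/day. Attributable
fractions and scenarios:

```r
af_table(fit, daily, n_mc = 1000, seed = 1)   # Table of AF% with 95% CIs
autoplot(predict_rr(fit, "mean_temp"), lags = c(0, 7, 14))
```

With raw records instead of a ready-made series, `run_pipeline()` drives
filtering → date reconstruction → PMM imputation → per-imputation fits →
Rubin pooling → predictions → attribution from one `pipeline_config()`.

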