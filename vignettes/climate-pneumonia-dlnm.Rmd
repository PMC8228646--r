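---
title: "Methods: distributed lag non-linear modelling of climate and pneumonia admissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distributed lag non-linear modelling of climate and pneumonia admissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pneumolag)
```

## The model

Daily counts of suspected-pneumonia admissions are linked to daily
meteorology through a two-component count model. Writing $y_t$ for the
count on day $t$, $x_t$ for the rate-component design row and $z_t$ for
the zero-component row,

$$y_t \sim \pi_t\,\delta_0 + (1-\pi_t)\,\mathrm{NB}(\mu_t, \alpha),
\qquad \mu_t = e^{x_t'\theta},\quad \pi_t = \mathrm{logit}^{-1}(z_t'\gamma),$$

with the negative binomial parameterised so that
$\mathrm{Var}(y) = \mu + \alpha\mu^2$. The zero-inflation component
absorbs the excess of zero-admission days beyond what overdispersion
alone explains — in registers transcribed from paper admission books,
many calendar days record no admission at all, partly for structural
reasons (recording practice, weekends) that a pure rate model mis-fits.

The rate component contains, besides an intercept:

* **Crossbases** for mean temperature and relative humidity over lags
  0–21 days. A crossbasis is the tensor product of a natural cubic
  spline basis in the exposure and one in the lag, summed over the lag
  window: entry $(t, (i,j))$ is
  $\sum_{l=0}^{21} B_{x,i}(x_{t-l})\,B_{l,j}(l)$. This lets the data
  choose a smooth exposure–lag surface $f(x, l)$ within the spline
  span. Lags are summed at integer days, the resolution of the data.
* An **unlagged natural spline** for diurnal temperature range (DTR).
  Internally this is the same crossbasis code with maximum lag 0 and an
  intercept-only lag basis, so one code path serves both cases.
* **Day-of-week** indicators with Sunday as the reference category.
* One **Fourier pair** $\sin(2\pi t/P), \cos(2\pi t/P)$ with
  $P = 182.625$ days (six months), capturing the twice-yearly seasonal
  pattern of respiratory admissions; further harmonics can be added by
  configuration.
* A **long-term trend** natural spline over the day index with 5 degrees
  of freedom by default.

The zero component contains day-of-week, the admission counts of the
three preceding days as separate linear terms (admissions cluster in
time — an infectious-disease feature — and these terms also drain serial
autocorrelation from the residuals), and, by default, the same Fourier
pair: seasonality demonstrably affects the *odds of any admission*, not
only the rate, so the pair is included in both components unless
disabled (`fourier_in_zero = FALSE`).

## Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `max_lag` | 21 | days of delayed effect for temperature and humidity |
| exposure knots | 25/50/75th percentiles | boundary knots at the observed range |
| lag knots | 2 internal, log(1+lag)-spaced | flexibility concentrated at short lags |
| `fourier_period` | 182.625 d | six-month seasonal wavelength |
| `trend_df` | 5 | trend spline degrees of freedom |
| centers | 21 °C, 67 %, 1.3 °C | reference exposures where RR ≡ 1 |
| `m` | 20 | imputed datasets |
| `k_donors` | 5 | PMM donor-pool size |
| `n_mc` | 1000 | Monte Carlo repetitions for AF intervals |

The centering values are the observed medians for temperature and
humidity and the lowest observed value for DTR; predictions and
attributable fractions are relative to them. Knot positions for the
exposure dimension follow the percentile convention of the DLNM
literature and are fully configurable through `spline_spec()`; the
package makes no attempt at automatic knot selection, which in this
problem class is done by residual inspection and sensitivity analysis.

## Estimation

The likelihood is maximised in three equivariant stages:

1. **EM** (100 iterations by default): the E-step computes each zero
   day's posterior probability of being structural; the M-step fits a
   weighted binomial GLM for $\gamma$, a weighted negative binomial GLM
   for $\theta$ at the current dispersion, and a one-dimensional update
   of $\log\alpha$. EM is monotone and selects a likelihood basin
   stably, but converges linearly and can creep along ridges.
2. **BFGS** with the analytic gradient, to accelerate out of the EM
   tail.
3. **Newton polish** with the observed information until the scaled
   gradient is at machine-precision level.

The EM map and Newton steps are equivariant under affine
reparameterisation of design columns, and stages 2–3 converge tightly
enough that the fitted optimum — which is itself equivariant — is
reproduced to ~1e-8 whatever the column scaling. This matters in
practice: plain quasi-Newton optimisation from a distant start was
observed to land in different local optima of this non-concave
likelihood depending on innocuous column rescalings. The whole
likelihood and gradient are computed on the log scale
($\log(a+\mu)$ via log-sum-exp), so no finite parameter value produces
overflow. The covariance is the inverse observed information, projected
onto the positive semi-definite cone (eigenvalue flooring) because near
zero-component ridges the numerically inverted information can acquire
tiny negative eigenvalues. Dispersion is fitted as $\log\alpha$, keeping
the optimisation unconstrained. Initialisation: Poisson GLM for
$\theta$, zeros for $\gamma$, $\alpha = 0.5$.

The convergence flag requires the scaled gradient norm below `1e-4`.
Rank-deficient designs are rejected with the offending columns named,
rather than silently dropped.

## Missing data

Admission dates missing from the register are reconstructed as
discharge date minus length of stay (whole days; length 0 is a same-day
admission). Records with discharge but no length of stay enter
predictive mean matching: for each of `m` imputations, regression
parameters of a linear model of length of stay on calendar and weather
covariates are drawn from their approximate posterior, every record gets
a predictive mean, and each missing record copies the observed value of
one of its `k = 5` nearest complete-case donors (type-1 matching: donor
predictions from the maximum-likelihood fit, target predictions from the
posterior draw). PMM only ever imputes values that were actually
observed, which suits a discrete, skewed quantity like length of stay.
Records missing both dates cannot be placed in time and are excluded.
Each imputation consumes its own RNG stream derived from the master
seed, so `m` can be extended without reshuffling earlier imputations.

Downstream, each completed dataset is aggregated and fitted
independently; coefficient vectors and covariance matrices are pooled by
Rubin's rules (between-imputation covariance inflated by $1 + 1/m$) on
the log-rate scale, where the estimates are closest to normal, and
predictions and attributable fractions are computed from the pooled
quantities. Age and sex are deliberately *not* imputed: their
missingness in registers of this kind is not plausibly missing-at-random
and there is little predictive information to impute from.

## Predictions and attribution

Relative rates against the centering value $c$ are
$\log \mathrm{RR}(x, l) = [b_x(x) - b_x(c)] \otimes b_l(l) \cdot
\theta_{cb}$, with delta-method normal intervals on the log scale; the
cumulative association sums the log relative rates over lags 0–21. At
$x = c$ the contrast vanishes, so RR is exactly 1 with a zero-width
interval.

The backward-perspective attributable fraction asks, for each admission
day, what share of that day's cases is attributable to the exposures of
the preceding three weeks:
$\mathrm{AF}_t = 1 - \exp(-\sum_{l} \eta(x_{t-l}, l))$, attributable
number $\mathrm{AN}_t = \mathrm{AF}_t\,n_t$, total AF
$= \sum \mathrm{AN}_t / \sum n_t$. Negative values are admissions
averted. Three design choices deserve note:

* Only rate-component coefficients enter; the zero component is held
  fixed, consistent with the relative-rate definition of AF.
* Subrange membership (e.g. "cold" < 14 °C, "hot" > 26 °C) is judged on
  the exposure at the lagged source day. A day's attributable number is
  allocated across subranges in proportion to each subrange's share of
  the day's summed log-relative-rate exponent. This makes subranges
  that partition the exposure axis sum *exactly* to the total — an
  additivity that a per-subrange recomputation of $1 - e^{-s}$ cannot
  provide, since the exponential is not additive. DTR has no "low"
  subrange: its reference is the dataset minimum.
* Distribution-shift scenarios displace the whole exposure series by a
  constant and recompute with unchanged coefficients; natural splines
  extrapolate linearly beyond their boundary knots, which is the
  best-behaved default for modest shifts (±2 °C, ±5 %). Membership is
  judged on the shifted values.

Empirical 95% intervals come from `n_mc` multivariate-normal draws of
the crossbasis coefficients around the estimates with the fitted
covariance; the 2.5th/97.5th percentile interval is reported
(percentile, not bias-corrected — adequate for these near-symmetric
sampling distributions). The interval is seed-deterministic, and with a
zero covariance it collapses onto the point estimate.

## The synthetic-data generator

`simulate_meteorology()` emulates southern-hemisphere conditions: an
annual temperature sinusoid peaking in mid-January (mean 21 °C,
amplitude 5 °C) with AR(1) noise, relative humidity seasonally in phase
with temperature but with residuals negatively correlated with the
temperature residuals (clipped to [5, 100] %), and a positive seasonal
DTR averaging ~13 °C that exceeds 21 °C a handful of days per year.
`simulate_admissions()` draws counts day by day from the generative twin
of the fitted model; the truth's exposure–lag surfaces are quadratics in
the centered exposure times an exponentially decaying lag kernel
normalised to sum to one, so the true cumulative log relative rate at
any exposure is available in closed form
(`true_cumulative_logrr()`). Default effect sizes were set once to the
magnitudes a study of this kind reports — cumulative RR ≈ 0.34 at 30 °C
and ≈ 1.27 at 12 °C versus 21 °C, protective high humidity, a small
positive DTR slope, a Monday peak, six-month seasonality, a slow upward
trend — and the baseline is calibrated so the realised mean is
≈ 1.3 admissions/day (≈ 4000 admissions over eight years) with roughly
half of days at zero. `make_records()` then explodes counts into
free-text records with decoy diagnoses the keyword filter must reject,
and masks admission dates (34.3 %), both dates (4.5 %) and lengths of
stay (15 %, missing-at-random on temperature) at the rates such
registers exhibit.

What the generator does *not* emulate: epidemic outbreaks beyond the
autoregressive zero component, reporting gaps longer than a day,
exposure measurement error (the weather station stands in for the
community exposure), and any demographic structure. Passing tests on
synthetic data therefore demonstrate that the estimation machinery
recovers known truth under the model's own assumptions — not that those
assumptions hold in any particular register.

## Numerical choices and degenerate inputs

* Crossbasis rows with incomplete lag history are `NA` and excluded
  from the likelihood; zero-padding them would bias early-period
  estimates. The first usable day is `max(max_lag, 3) + 1`.
* The quadratic truth surfaces of the generator do not lie exactly in
  the fitted spline span; this mild misspecification is intentional and
  representative. At 3000 days the induced bias is well inside sampling
  error (verified by the recovery tests).
* Keyword screening is case-insensitive raw substring matching (the
  register's wildcard conventions imply substrings, not whole words);
  exclusion beats inclusion. The duplicate listing of one inclusion
  term in the source vocabulary is treated as a single term.
* An all-zero response, a rank-deficient design, meteorology gaps, and
  series shorter than the lag window are all hard errors with the
  offending columns, dates or lengths named.
* Problem sizes used by the validation suite — a 1000-day shared
  pilot fit, one 3000-day recovery fit, 200 replicates of 800 days for
  interval coverage, 100 replicates for imputation coverage — were
  chosen as the smallest sizes at which the corresponding Monte Carlo
  error bands are meaningfully tight.

## Known limitations

Estimation assumes a correctly specified lag window; effects beyond 21
days alias into the seasonal terms. The zero-inflation likelihood is
not concave, and with short series or rich zero-component designs the
zero component can sit on a ridge (quasi-separation); the fitter
converges and flags this only through wide intervals. AF intervals
ignore imputation noise beyond what Rubin pooling propagates into the
coefficient covariance. Minimum/maximum-temperature variants of the
model are a configuration change (swap the exposure column), not a
separate code path.
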