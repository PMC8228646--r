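#' Ground-truth generative model for synthetic admission series
#'
#' Parametric exposure-lag log-relative-rate surfaces with closed-form
#' cumulative associations, so every downstream estimate can be checked
#' against truth. Each lagged surface is a quadratic in the centered
#' exposure multiplied by an exponentially decaying lag kernel normalised
#' to sum to one over the lag window, so the cumulative log relative
#' rate at exposure `x` is exactly the quadratic
#' `lin * (x - center) + quad * (x - center)^2`. All surfaces are zero at
#' their centering value (true RR(center) = 1).
#'
#' Default effect sizes emulate a mid-sized climate-admissions study:
#' cumulative RR about 0.34 at 30 vs 21 deg C and about 1.27 at 12 deg C
#' for mean temperature; protective high humidity, harmful low humidity;
#' a small positive unlagged diurnal-temperature-range slope; a Monday
#' admission peak; six-month seasonality; a slow upward trend; strong
#' overdispersion and a zero component with negative dependence on the
#' preceding three days' counts. The baseline gives roughly 1.3
#' admissions/day with many zero days.
#'
#' @param temp,rh Lists with `lin`, `quad` (per-unit log-RR terms of the
#'   cumulative quadratic), `center`, and `decay` (lag-kernel e-folding
#'   in days).
#' @param dtr List with `lin` and `center` (unlagged linear effect).
#' @param dow_log_rr Length-7 log rate ratios, Sunday first (Sunday 0).
#' @param fourier_amp Length-2 sine/cosine amplitudes at period
#'   `fourier_period` days.
#' @param fourier_period Seasonal wavelength in days.
#' @param trend_slope Log-rate change per day.
#' @param baseline Baseline log rate.
#' @param alpha Negative binomial dispersion (variance `mu + alpha mu^2`).
#' @param zero List: `intercept`, `prev` (length-3 coefficients on the
#'   preceding three days' counts), `fourier_amp` (length-2).
#' @param max_lag Lag window length in days.
#'
#' @return An object of class `truth_model`.
#' @export
truth_model <- function(
    temp = list(lin = -0.0733, quad = -0.00519, center = 21, decay = 6),
    rh = list(lin = -0.0233, quad = -3.35e-4, center = 67, decay = 10),
    dtr = list(lin = 0.015, center = 1.3),
    dow_log_rr = c(0, 0.18, 0.08, 0.05, 0.05, 0.08, 0.02),
    fourier_amp = c(0.15, 0.10),
    fourier_period = 182.625,
    trend_slope = 1.4e-4,
    baseline = -0.026,
    alpha = 0.8,
    zero = list(intercept = -1.2, prev = c(-0.3, -0.2, -0.1),
                fourier_amp = c(0.3, 0)),
    max_lag = 21L) {
  structure(list(temp = temp, rh = rh, dtr = dtr, dow_log_rr = dow_log_rr,
                 fourier_amp = fourier_amp, fourier_period = fourier_period,
                 trend_slope = trend_slope, baseline = baseline,
                 alpha = alpha, zero = zero, max_lag = as.integer(max_lag)),
            class = "truth_model")
}

#' Null truth model (no covariate effects, no zero inflation)
#' @param baseline Baseline log rate.
#' @param alpha Dispersion.
#' @return A [truth_model()] whose only nonzero ingredient is the
#'   baseline (and dispersion).
#' @export
truth_model_null <- function(baseline = log(1.3), alpha = 0.8) {
  truth_model(temp = list(lin = 0, quad = 0, center = 21, decay = 6),
              rh = list(lin = 0, quad = 0, center = 67, decay = 10),
              dtr = list(lin = 0, center = 1.3),
              dow_log_rr = rep(0, 7), fourier_amp = c(0, 0),
              trend_slope = 0, baseline = baseline, alpha = alpha,
              zero = list(intercept = -Inf, prev = c(0, 0, 0),
                          fourier_amp = c(0, 0)))
}

# Normalised exponential lag kernel over 0..max_lag.
lag_kernel <- function(decay, max_lag) {
  w <- exp(-(0:max_lag) / decay)
  w / sum(w)
}

#' True cumulative log relative rate at an exposure value
#'
#' Closed form implied by the truth model's quadratic-times-kernel
#' surfaces (the kernel sums to one over the lag window).
#'
#' @param truth A [truth_model()].
#' @param term `"mean_temp"`, `"rh"` or `"dtr"`.
#' @param x Exposure values.
#' @return Numeric vector of cumulative log relative rates vs the term's
#'   center.
#' @export
true_cumulative_logrr <- function(truth, term, x) {
  p <- switch(term, mean_temp = truth$temp, rh = truth$rh,
              dtr = c(truth$dtr, quad = 0),
              stop("unknown term `", term, "`", call. = FALSE))
  d <- x - p$center
  p$lin * d + p$quad * d^2
}

#' Simulate southern-hemisphere daily meteorology
#'
#' Mean temperature follows an annual sinusoid peaking in mid-January
#' plus AR(1) noise; relative humidity follows its own seasonal sinusoid
#' plus noise negatively correlated with the temperature residuals,
#' clipped to `[5, 100]`; the diurnal temperature range is a positive
#' seasonal signal plus noise (floored just above zero), and min/max
#' temperatures are the mean -/+ half the range. Deterministic given
#' `seed`.
#'
#' @param n_days Number of days (>= 22).
#' @param start_date First date.
#' @param params List overriding any of: `temp_mean` 21, `temp_amp` 5,
#'   `temp_ar` 0.7, `temp_sd` 1.6 (innovation SD), `rh_mean` 67,
#'   `rh_amp` 8, `rh_sd` 7, `rh_temp_cor` -0.6, `dtr_mean` 13,
#'   `dtr_amp` 2, `dtr_sd` 3.5, `peak_doy` 15 (January peak).
#' @param seed RNG seed.
#' @return Tibble: `date`, `mean_temp`, `min_temp`, `max_temp`, `rh`,
#'   `dtr`, `dow`.
#' @export
simulate_meteorology <- function(n_days, start_date = as.Date("2007-10-10"),
                                 params = list(), seed = 1L) {
  stopifnot(n_days >= 22)
  p <- utils::modifyList(
    list(temp_mean = 21, temp_amp = 5, temp_ar = 0.7, temp_sd = 1.6,
         rh_mean = 67, rh_amp = 8, rh_sd = 7, rh_temp_cor = -0.6,
         dtr_mean = 13, dtr_amp = 2, dtr_sd = 3.5, peak_doy = 15),
    params)
  if (p$temp_sd < 0 || p$rh_sd < 0 || p$dtr_sd < 0) {
    stop("noise standard deviations must be non-negative", call. = FALSE)
  }
  set.seed(as.integer(seed))
  dates <- seq(as.Date(start_date), by = "day", length.out = n_days)
  doy <- as.numeric(format(dates, "%j"))
  phase <- 2 * pi * (doy - p$peak_doy) / 365.25

  eps <- stats::rnorm(n_days, 0, p$temp_sd)
  ar <- stats::filter(eps, p$temp_ar, method = "recursive")
  temp <- p$temp_mean + p$temp_amp * cos(phase) + as.numeric(ar)

  rh_noise <- p$rh_temp_cor * (p$rh_sd / p$temp_sd) *
    sqrt(1 - p$temp_ar^2) * as.numeric(ar) +
    sqrt(max(0, 1 - p$rh_temp_cor^2)) * stats::rnorm(n_days, 0, p$rh_sd)
  rh <- pmin(100, pmax(5, p$rh_mean + p$rh_amp * cos(phase) + rh_noise))

  dtr <- pmax(0.2, p$dtr_mean + p$dtr_amp * cos(phase) +
                stats::rnorm(n_days, 0, p$dtr_sd))

  tibble::tibble(date = dates,
                 mean_temp = temp,
                 min_temp = temp - dtr / 2,
                 max_temp = temp + dtr / 2,
                 rh = rh,
                 dtr = dtr,
                 dow = dow_factor(dates))
}

#' Simulate a daily admission series from a truth model
#'
#' Sequential day-by-day draw from the generative twin of the fitted
#' model: the rate is `exp(baseline + lagged temperature and humidity
#' contributions + unlagged DTR + day-of-week + Fourier + trend)`, the
#' structural-zero probability comes from the zero component (using the
#' already-drawn counts of the preceding three days), and the count is a
#' zero-inflated negative binomial draw. The first `max_lag` days are
#' burn-in and excluded from the output.
#'
#' @param met Meteorology tibble from [simulate_meteorology()].
#' @param truth A [truth_model()].
#' @param seed RNG seed.
#' @return Daily series tibble: `date`, `count`, `mean_temp`, `rh`,
#'   `dtr`, `dow`, with attribute `truth`.
#' @export
simulate_admissions <- function(met, truth = truth_model(), seed = 1L) {
  stopifnot(inherits(truth, "truth_model"))
  n <- nrow(met)
  L <- truth$max_lag
  if (n <= L) stop("meteorology must be longer than the lag window",
                   call. = FALSE)
  set.seed(as.integer(seed))

  kT <- lag_kernel(truth$temp$decay, L)
  kH <- lag_kernel(truth$rh$decay, L)
  fT <- function(x) truth$temp$lin * (x - truth$temp$center) +
    truth$temp$quad * (x - truth$temp$center)^2
  fH <- function(x) truth$rh$lin * (x - truth$rh$center) +
    truth$rh$quad * (x - truth$rh$center)^2
  gD <- function(d) truth$dtr$lin * (d - truth$dtr$center)

  t_idx <- seq_len(n)
  four <- truth$fourier_amp[1] * sin(2 * pi * t_idx / truth$fourier_period) +
    truth$fourier_amp[2] * cos(2 * pi * t_idx / truth$fourier_period)
  four_z <- truth$zero$fourier_amp[1] *
    sin(2 * pi * t_idx / truth$fourier_period) +
    truth$zero$fourier_amp[2] * cos(2 * pi * t_idx / truth$fourier_period)
  dow_i <- as.integer(met$dow)

  lagged_T <- fT(met$mean_temp)
  lagged_H <- fH(met$rh)
  y <- integer(n)
  size <- 1 / truth$alpha
  for (t in t_idx) {
    if (t <= L) { y[t] <- 0L; next }                # burn-in
    sT <- sum(kT * lagged_T[t - (0:L)])
    sH <- sum(kH * lagged_H[t - (0:L)])
    eta <- truth$baseline + sT + sH + gD(met$dtr[t]) +
      truth$dow_log_rr[dow_i[t]] + four[t] + truth$trend_slope * t
    z <- truth$zero$intercept + sum(truth$zero$prev * y[t - (1:3)]) + four_z[t]
    pi_t <- stats::plogis(z)
    y[t] <- if (stats::runif(1) < pi_t) 0L else
      stats::rnbinom(1, size = size, mu = exp(eta))
  }

  out <- tibble::tibble(date = met$date, count = y,
                        mean_temp = met$mean_temp, rh = met$rh,
                        dtr = met$dtr, dow = met$dow)[-seq_len(L), ]
  attr(out, "truth") <- truth
  out
}

#' Missingness configuration for synthetic raw records
#'
#' Rates emulate the observed record quality of paper-based admission
#' registers: about a third of records lack an admission date (but have
#' discharge and usually length of stay), a small fraction lack both
#' dates and are unusable, and length of stay is missing at random with
#' probability depending (on the logit scale) on the day's mean
#' temperature.
#'
#' @param date_missing Fraction of records with admission date masked
#'   (default 0.343).
#' @param both_missing Fraction with both admission and discharge masked
#'   (default 0.045).
#' @param los_missing Baseline fraction with length of stay masked
#'   (default 0.15).
#' @param los_mar_slope Logit slope of length-of-stay missingness on the
#'   standardised mean temperature (default 0.5; MAR mechanism).
#' @param decoy_rate Decoy (non-pneumonia) records added per true record
#'   (default 0.3).
#' @return A list of class `missingness_config`.
#' @export
missingness_config <- function(date_missing = 0.343, both_missing = 0.045,
                               los_missing = 0.15, los_mar_slope = 0.5,
                               decoy_rate = 0.3) {
  vals <- c(date_missing, both_missing, los_missing)
  if (any(vals < 0 | vals > 1)) stop("fractions must lie in [0, 1]",
                                     call. = FALSE)
  structure(list(date_missing = date_missing, both_missing = both_missing,
                 los_missing = los_missing, los_mar_slope = los_mar_slope,
                 decoy_rate = decoy_rate),
            class = "missingness_config")
}

pneumonia_reason_pool <- function() {
  c("Pneumonia", "Bronchopneumonia", "BRPN", "bpn", "PCP pneumonia",
    "severe pneumonia", "lobar pneumonia")
}

decoy_reason_pool <- function() {
  c("pneumothorax", "aspiration pneumonia", "chemical pneumonitis",
    "asthma", "gastroenteritis", "tuberculosis", "fracture")
}

#' Explode a daily series into raw admission records with missingness
#'
#' Each day's count becomes that many records with plausible pneumonia
#' reason texts; decoy records with reasons the keyword filter must drop
#' are interleaved. Length of stay is drawn from a shifted negative
#' binomial, discharge = admission + length of stay, and auxiliary
#' covariates (calendar fields and the discharge day's meteorology) are
#' attached for the imputation model. Admission dates, both dates, or
#' lengths of stay are then masked per `missingness`.
#'
#' @param daily Daily series (from [simulate_admissions()] or
#'   [aggregate_daily()]).
#' @param missingness A [missingness_config()].
#' @param seed RNG seed.
#' @return Tibble of admission records: `reason_text`, `admission_date`,
#'   `discharge_date`, `length_of_stay`, auxiliary covariates, and the
#'   bookkeeping columns `true_admission_date`, `is_decoy`.
#' @export
make_records <- function(daily, missingness = missingness_config(),
                         seed = 1L) {
  set.seed(as.integer(seed))
  n_true <- sum(daily$count)
  true_dates <- rep(as.Date(daily$date), daily$count)
  reasons <- sample(pneumonia_reason_pool(), n_true, replace = TRUE)

  n_decoy <- stats::rpois(1, missingness$decoy_rate * n_true)
  decoy_dates <- sample(as.Date(daily$date), n_decoy, replace = TRUE)
  decoy_reasons <- sample(decoy_reason_pool(), n_decoy, replace = TRUE)

  adm <- c(true_dates, decoy_dates)
  rec <- tibble::tibble(
    reason_text = c(reasons, decoy_reasons),
    is_decoy = rep(c(FALSE, TRUE), c(n_true, n_decoy)),
    true_admission_date = adm,
    admission_date = adm,
    length_of_stay = 1 + stats::rnbinom(length(adm), size = 2, mu = 3))
  rec$discharge_date <- rec$admission_date + rec$length_of_stay

  # auxiliary covariates from the discharge day (always recorded)
  met_idx <- match(pmin(rec$discharge_date, max(daily$date)), daily$date)
  met_idx[is.na(met_idx)] <- nrow(daily)
  rec <- dplyr::mutate(
    rec,
    day_of_year = as.numeric(format(.data$discharge_date, "%j")),
    dow = dow_factor(.data$discharge_date),
    month = as.integer(format(.data$discharge_date, "%m")),
    year = as.integer(format(.data$discharge_date, "%Y")),
    season = factor(c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA", "JJA", "JJA",
                      "SON", "SON", "SON", "DJF")[.data$month],
                    levels = c("DJF", "MAM", "JJA", "SON")),
    mean_temp = daily$mean_temp[met_idx],
    rh = daily$rh[met_idx])

  n <- nrow(rec)
  u <- stats::runif(n)
  mask_both <- u < missingness$both_missing
  mask_date <- !mask_both & u < missingness$both_missing +
    missingness$date_missing
  z_los <- stats::qlogis(max(1e-6, missingness$los_missing)) +
    missingness$los_mar_slope * scale(rec$mean_temp)[, 1]
  mask_los <- stats::runif(n) < stats::plogis(z_los)

  rec$admission_date[mask_date | mask_both] <- NA
  rec$discharge_date[mask_both] <- NA
  rec$length_of_stay[mask_los] <- NA
  rec
}
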