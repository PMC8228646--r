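#' Backward-perspective attributable fraction of one exposure
#'
#' For each admission day \eqn{t} with a complete lag history, the
#' backward attributable fraction is
#' \eqn{\mathrm{AF}_t = 1 - \exp(-\sum_{l=0}^{L} \eta(x_{t-l}, l))},
#' where \eqn{\eta(x, l)} is the lag-specific log relative rate of
#' exposure \eqn{x} relative to the centering value. The attributable
#' number is \eqn{\mathrm{AN}_t = \mathrm{AF}_t\, n_t}, and the total AF
#' is \eqn{\sum_t \mathrm{AN}_t / \sum_t n_t}. Negative values denote
#' admissions averted by exposures with protective relative rates.
#'
#' Exposure subranges decompose the total: each lagged source-day
#' contribution belongs to the subrange containing the exposure on the
#' day it occurred, and a day's attributable number is allocated across
#' subranges in proportion to each subrange's share of the day's summed
#' log-relative-rate exponent. Subranges that partition the exposure
#' axis therefore sum exactly to the total.
#'
#' Only the rate-component coefficients enter the computation (the AF is
#' defined on the relative-rate scale); empirical 95% intervals come from
#' Monte Carlo draws of those coefficients from their estimated
#' multivariate normal sampling distribution.
#'
#' @param fit A [fit_zinb_dlnm()] object fitted from a [build_design()]
#'   design.
#' @param term Term name (`"mean_temp"`, `"rh"`, `"dtr"`).
#' @param daily Daily series with the exposure column and `count`; the
#'   exposure series must cover the counts' dates plus `max_lag` days of
#'   history (the first `max_lag` days seed the history and their counts
#'   are excluded from the denominator).
#' @param center Reference exposure; defaults to the design's stored
#'   center.
#' @param subranges Named list of exposure intervals `c(lo, hi)`
#'   (membership `lo <= x < hi`); e.g.
#'   `list(low = c(-Inf, 14), high = c(26, Inf))`.
#' @param shift Exposure displacement added to the whole series before
#'   computation (climate-shift scenario); the natural spline
#'   extrapolates linearly beyond its boundary knots. Subrange
#'   membership is judged on the shifted exposures.
#' @param n_mc Monte Carlo repetitions for the empirical interval
#'   (default 1000); set to 0 to skip.
#' @param seed Seed for the Monte Carlo draws.
#'
#' @return Object of class `af_result`: tibble with one row per
#'   component (`total` plus any subranges): `term`, `component`,
#'   `shift`, `af`, `ci_low`, `ci_high`, `attributable_number`;
#'   attributes `center`, `n_mc`, `seed`, `n_admissions`.
#' @export
backward_af <- function(fit, term = "mean_temp", daily, center = NULL,
                        subranges = NULL, shift = 0, n_mc = 1000L,
                        seed = 1L) {
  pb <- term_block(fit, term)
  center <- center %||% fit$design_meta$centers[[term]]
  if (is.null(center)) stop("no centering value for term `", term, "`",
                            call. = FALSE)
  x <- as.numeric(daily[[term]])
  counts <- as.numeric(daily$count)
  L <- pb$meta$max_lag
  if (length(x) <= L) stop("exposure series shorter than the lag window",
                           call. = FALSE)

  point <- af_components(pb$meta, pb$theta, x, counts, center, subranges,
                         shift)

  ci <- NULL
  if (n_mc >= 2) {
    draws <- mc_af_draws(pb, x, counts, center, subranges, shift, n_mc, seed)
    ci <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE)
  } else if (n_mc != 0) {
    stop("n_mc must be 0 or >= 2", call. = FALSE)
  }

  comp <- names(point$af)
  out <- tibble::tibble(
    term = term, component = comp, shift = shift,
    af = unname(point$af),
    ci_low = if (is.null(ci)) NA_real_ else ci[1, ],
    ci_high = if (is.null(ci)) NA_real_ else ci[2, ],
    attributable_number = unname(point$an))
  structure(out, center = center, n_mc = n_mc, seed = seed,
            n_admissions = point$n_total,
            class = c("af_result", class(out)))
}

#' Attributable fraction under a shifted exposure distribution
#'
#' Recomputes [backward_af()] after displacing the whole exposure series
#' by `shift`, holding the fitted coefficients fixed — the impact a
#' long-term climate shift of that size would have had on the observed
#' admission series. `shift = 0` reproduces [backward_af()] exactly.
#'
#' @inheritParams backward_af
#' @return An `af_result`, as [backward_af()].
#' @export
scenario_af <- function(fit, term = "mean_temp", daily, shift, center = NULL,
                        subranges = NULL, n_mc = 1000L, seed = 1L) {
  backward_af(fit, term, daily, center = center, subranges = subranges,
              shift = shift, n_mc = n_mc, seed = seed)
}

# Point computation of total + subrange AF/AN for one coefficient vector.
af_components <- function(meta, theta, x, counts, center, subranges, shift) {
  L <- meta$max_lag
  n <- length(x)
  xs <- x + shift
  vx <- basis_dim(meta$exposure_spec)
  vl <- basis_dim(meta$lag_spec)
  A <- ns_basis(xs, meta$exposure_spec) -
    ns_basis(rep(center, n), meta$exposure_spec)
  Bl <- ns_basis(0:L, meta$lag_spec)
  Th <- t(matrix(theta, nrow = vl, ncol = vx))      # [i, j] = theta_(i,j)
  G <- A %*% Th %*% t(Bl)                            # G[s, l+1] = eta(x_s, l)

  tt <- (L + 1L):n
  s_tot <- numeric(length(tt))
  for (l in 0:L) s_tot <- s_tot + G[tt - l, l + 1L]
  n_t <- counts[tt]
  an_t <- (1 - exp(-s_tot)) * n_t
  n_total <- sum(n_t)
  af <- c(total = sum(an_t) / n_total)
  an <- c(total = sum(an_t))

  if (!is.null(subranges)) {
    for (nm in names(subranges)) {
      rg <- subranges[[nm]]
      ind <- as.numeric(xs >= rg[1] & xs < rg[2])
      s_sub <- numeric(length(tt))
      for (l in 0:L) s_sub <- s_sub + G[tt - l, l + 1L] * ind[tt - l]
      share <- ifelse(s_tot == 0, 0, s_sub / s_tot)
      an_sub <- sum(an_t * share)
      af[nm] <- an_sub / n_total
      an[nm] <- an_sub
    }
  }
  list(af = af, an = an, n_total = n_total)
}

mc_af_draws <- function(pb, x, counts, center, subranges, shift, n_mc, seed) {
  set.seed(as.integer(seed))
  th <- MASS::mvrnorm(n_mc, pb$theta, psd_project(pb$vcov))
  if (is.null(dim(th))) th <- matrix(th, nrow = n_mc)
  res <- apply(th, 1, function(b)
    af_components(pb$meta, b, x, counts, center, subranges, shift)$af)
  if (is.null(dim(res))) matrix(res, ncol = 1) else t(res)
}

#' Monte Carlo empirical interval for an attributable-fraction statistic
#'
#' Draws `n_mc` coefficient vectors from the multivariate normal centered
#' at the fitted estimates with the fit covariance, recomputes the
#' statistic for each draw, and returns the 2.5th/97.5th percentiles.
#' With a zero covariance the interval collapses to the point estimate;
#' the same seed reproduces the interval bit-exactly.
#'
#' @param fit A [fit_zinb_dlnm()] object (or any list with
#'   `coefficients` and `vcov`).
#' @param af_fun Function taking one coefficient vector (same order as
#'   `fit$coefficients`) and returning a scalar statistic.
#' @param n_mc Number of draws (>= 2).
#' @param seed RNG seed.
#' @return Named numeric `c(ci_low, ci_high)`.
#' @export
mc_ci <- function(fit, af_fun, n_mc = 1000L, seed = 1L) {
  if (n_mc < 2) stop("n_mc must be >= 2", call. = FALSE)
  V <- psd_project(fit$vcov)
  set.seed(as.integer(seed))
  draws <- MASS::mvrnorm(n_mc, fit$coefficients, V)
  vals <- apply(draws, 1, af_fun)
  q <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
  c(ci_low = q[1], ci_high = q[2])
}

#' Attributable-fraction summary table across exposures and scenarios
#'
#' Builds a table shaped like the study's headline AF table: for each
#' exposure, the total AF and the AFs attributable to low and high
#' exposure subranges, unshifted and under positive/negative
#' distribution shifts, all as percentages with empirical 95% intervals.
#' The diurnal-temperature-range term has no low subrange because its
#' reference is the dataset minimum.
#'
#' @param fit A [fit_zinb_dlnm()] object.
#' @param daily The daily series used for the fit.
#' @param shifts Named list of shift magnitudes per term (default
#'   `mean_temp` 2 deg C, `rh` 5 %, `dtr` 2 deg C; each applied as + and -).
#' @param subranges Named list of per-term subrange lists; defaults:
#'   temperature low < 14, high > 26 deg C; humidity low < 40, high > 80 %;
#'   DTR high > 20 deg C.
#' @param n_mc,seed Monte Carlo settings per [backward_af()].
#' @return A tibble: `exposure`, `scenario`, then `<component>_af`,
#'   `<component>_low`, `<component>_high` columns in percent.
#' @export
af_table <- function(fit, daily,
                     shifts = list(mean_temp = 2, rh = 5, dtr = 2),
                     subranges = list(
                       mean_temp = list(low = c(-Inf, 14), high = c(26, Inf)),
                       rh = list(low = c(-Inf, 40), high = c(80, Inf)),
                       dtr = list(high = c(20, Inf))),
                     n_mc = 1000L, seed = 1L) {
  purrr::map_dfr(names(shifts), function(term) {
    delta <- shifts[[term]]
    purrr::map_dfr(c(0, delta, -delta), function(sh) {
      res <- backward_af(fit, term, daily, subranges = subranges[[term]],
                         shift = sh, n_mc = n_mc, seed = seed)
      wide <- res |>
        dplyr::mutate(dplyr::across(c("af", "ci_low", "ci_high"),
                                    ~ 100 * .x)) |>
        dplyr::select("component", "af", "ci_low", "ci_high") |>
        tidyr::pivot_wider(names_from = "component",
                           values_from = c("af", "ci_low", "ci_high"),
                           names_glue = "{component}_{.value}")
      dplyr::bind_cols(
        tibble::tibble(exposure = term,
                       scenario = if (sh == 0) "none"
                                  else sprintf("%+g", sh)),
        wide)
    })
  })
}

#' @rdname tidy.zinb_dlnm
#' @export
tidy.af_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
print.af_result <- function(x, ...) {
  cat("<af_result> term ", x$term[1], "; shift ", x$shift[1],
      "; reference ", attr(x, "center"), "; ", attr(x, "n_admissions"),
      " admissions; n_mc ", attr(x, "n_mc"), "\n", sep = "")
  print(tibble::as_tibble(x))
  invisible(x)
}
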