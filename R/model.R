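#' Model specification for the zero-inflated negative binomial DLNM
#'
#' Collects the tunable structure of the two-component model. The rate
#' (negative binomial) component holds the lagged crossbases for mean
#' temperature and relative humidity, an unlagged natural spline for
#' diurnal temperature range, day-of-week indicators (Sunday reference),
#' Fourier seasonal terms and a long-term trend spline. The zero
#' (binomial) component holds day-of-week indicators, linear terms for
#' the admission counts of the preceding three days, and (by default)
#' the same Fourier terms — seasonality measurably affects the odds of
#' any admission occurring, not only the rate.
#'
#' @param max_lag Maximum lag in days for temperature and humidity
#'   crossbases (default 21).
#' @param temp_spec,rh_spec,dtr_spec Optional [spline_spec()]s for the
#'   exposure dimensions; quantile-based defaults from the data when
#'   `NULL`.
#' @param lag_spec Optional [spline_spec()] for the lag dimension;
#'   default [lag_spec_default()].
#' @param fourier_period Seasonal wavelength in days (default 182.625,
#'   i.e. six months).
#' @param fourier_pairs Number of sine/cosine pairs at harmonics of the
#'   base period (default 1).
#' @param fourier_in_zero Include the Fourier terms in the zero component
#'   too (default `TRUE`).
#' @param trend_df Degrees of freedom of the long-term trend spline over
#'   the day index (default 5).
#' @param centers Named list of centering values used downstream for
#'   predictions and attribution: `mean_temp` 21 deg C, `rh` 67 %, `dtr`
#'   1.3 deg C (the dataset-optimal low value).
#'
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(max_lag = 21L,
                       temp_spec = NULL, rh_spec = NULL, dtr_spec = NULL,
                       lag_spec = NULL,
                       fourier_period = 182.625, fourier_pairs = 1L,
                       fourier_in_zero = TRUE,
                       trend_df = 5L,
                       centers = list(mean_temp = 21, rh = 67, dtr = 1.3)) {
  structure(list(max_lag = as.integer(max_lag),
                 temp_spec = temp_spec, rh_spec = rh_spec,
                 dtr_spec = dtr_spec, lag_spec = lag_spec,
                 fourier_period = fourier_period,
                 fourier_pairs = as.integer(fourier_pairs),
                 fourier_in_zero = isTRUE(fourier_in_zero),
                 trend_df = as.integer(trend_df),
                 centers = centers),
            class = "model_spec")
}

fourier_terms <- function(t_idx, period, pairs) {
  out <- lapply(seq_len(pairs), function(h) {
    m <- cbind(sin(2 * pi * h * t_idx / period),
               cos(2 * pi * h * t_idx / period))
    colnames(m) <- paste0(c("fourier.sin", "fourier.cos"), h)
    m
  })
  do.call(cbind, out)
}

dow_dummies <- function(dow) {
  m <- stats::model.matrix(~ dow)[, -1, drop = FALSE]
  colnames(m) <- sub("^dow", "dow.", colnames(m))
  m
}

#' Assemble the two-component design matrices
#'
#' Builds the rate-component and zero-component design matrices from a
#' daily series. Usable rows are those with a complete `max_lag`-day
#' exposure history and a 3-day count history, i.e. rows
#' `max(max_lag, 3) + 1` onward.
#'
#' @param daily Daily series tibble (`date`, `count`, `mean_temp`, `rh`,
#'   `dtr`, `dow`), e.g. from [aggregate_daily()] or
#'   [simulate_admissions()].
#' @param spec A [model_spec()].
#'
#' @return An object of class `dlnm_design`: list with `count_design`,
#'   `zero_design`, `response`, `valid_rows` (indices into `daily`),
#'   `cb_meta` (crossbasis metadata per lagged/unlagged exposure term,
#'   keyed by term name), `centers`, `spec` and `daily`.
#' @export
build_design <- function(daily, spec = model_spec()) {
  daily <- tibble::as_tibble(daily)
  need <- c("date", "count", "mean_temp", "rh", "dtr")
  stopifnot(all(need %in% names(daily)))
  if (!"dow" %in% names(daily)) daily$dow <- dow_factor(as.Date(daily$date))
  n <- nrow(daily)
  first <- max(spec$max_lag, 3L) + 1L
  if (n <= first + 1L) {
    stop("daily series too short (", n, " rows) for max_lag ", spec$max_lag,
         " plus the 3-day count history", call. = FALSE)
  }

  cb_temp <- crossbasis(daily$mean_temp, spec$max_lag,
                        exposure_spec = spec$temp_spec,
                        lag_spec = spec$lag_spec, source_name = "mean_temp")
  cb_rh <- crossbasis(daily$rh, spec$max_lag,
                      exposure_spec = spec$rh_spec,
                      lag_spec = spec$lag_spec, source_name = "rh")
  cb_dtr <- crossbasis(daily$dtr, 0L,
                       exposure_spec = spec$dtr_spec %||%
                         spline_spec_quantile(daily$dtr),
                       lag_spec = intercept_spec(), source_name = "dtr")

  rows <- first:n
  t_idx <- seq_len(n)
  four <- fourier_terms(t_idx, spec$fourier_period, spec$fourier_pairs)
  trend <- ns_basis(t_idx, spline_spec(
    stats::quantile(t_idx, seq_len(spec$trend_df - 1L) / spec$trend_df),
    range(t_idx)))
  colnames(trend) <- paste0("trend.b", seq_len(ncol(trend)))
  dowm <- dow_dummies(daily$dow)

  count_design <- cbind(
    `(Intercept)` = 1,
    cb_temp[rows, , drop = FALSE],
    cb_rh[rows, , drop = FALSE],
    cb_dtr[rows, , drop = FALSE],
    dowm[rows, , drop = FALSE],
    four[rows, , drop = FALSE],
    trend[rows, , drop = FALSE])

  prev <- sapply(1:3, function(k) daily$count[rows - k])
  colnames(prev) <- paste0("prev.count", 1:3)
  zero_design <- cbind(
    `(Intercept)` = 1,
    dowm[rows, , drop = FALSE],
    prev,
    if (spec$fourier_in_zero) four[rows, , drop = FALSE])

  structure(list(count_design = count_design,
                 zero_design = zero_design,
                 response = as.numeric(daily$count[rows]),
                 valid_rows = rows,
                 cb_meta = list(mean_temp = cb_meta(cb_temp),
                                rh = cb_meta(cb_rh),
                                dtr = cb_meta(cb_dtr)),
                 centers = spec$centers,
                 spec = spec,
                 daily = daily),
            class = "dlnm_design")
}

#' @export
print.dlnm_design <- function(x, ...) {
  cat("<dlnm_design>", length(x$response), "usable days;",
      ncol(x$count_design), "rate columns,", ncol(x$zero_design),
      "zero columns\n")
  invisible(x)
}

# Project a covariance matrix onto the positive semi-definite cone
# (eigenvalue flooring); guards against tiny negative eigenvalues from
# numerically inverted information matrices near likelihood ridges.
psd_project <- function(V) {
  V <- (V + t(V)) / 2
  e <- eigen(V, symmetric = TRUE)
  if (all(e$values >= 0)) return(V)
  out <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  dimnames(out) <- dimnames(V)
  out <- (out + t(out)) / 2
  diag(out) <- pmax(diag(out), 0)   # rounding can leave diag at -1e-17
  out
}

# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  mid <- x > 18 & x <= 33
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

# Split a packed parameter vector into theta (rate), gamma (zero), log_alpha.
split_params <- function(params, p1, p2) {
  list(theta = params[seq_len(p1)],
       gamma = params[p1 + seq_len(p2)],
       log_alpha = params[p1 + p2 + 1L])
}

#' Zero-inflated negative binomial log-likelihood
#'
#' Mixture log-likelihood of the two-component model. With
#' \eqn{\pi_t = \mathrm{logistic}(z_t'\gamma)} and
#' \eqn{\mu_t = \exp(x_t'\theta)}, a zero count contributes
#' \eqn{\log[\pi_t + (1-\pi_t)\,\mathrm{NB}(0;\mu_t,\alpha)]} and a
#' positive count \eqn{\log(1-\pi_t) + \log \mathrm{NB}(y_t;\mu_t,\alpha)},
#' where the negative binomial is parameterised so that
#' \eqn{\mathrm{Var} = \mu + \alpha\mu^2} (size \eqn{1/\alpha}). The
#' dispersion enters `params` as its logarithm, keeping the optimisation
#' unconstrained.
#'
#' @param params Numeric vector `c(theta, gamma, log_alpha)`.
#' @param count_design,zero_design Design matrices (rate and zero
#'   components).
#' @param y Non-negative integer response.
#' @return The log-likelihood (scalar).
#' @export
zinb_loglik <- function(params, count_design, zero_design, y) {
  p1 <- ncol(count_design); p2 <- ncol(zero_design)
  stopifnot(length(params) == p1 + p2 + 1L,
            nrow(count_design) == length(y),
            nrow(zero_design) == length(y))
  pr <- split_params(params, p1, p2)
  eta <- drop(count_design %*% pr$theta)
  z <- drop(zero_design %*% pr$gamma)
  log_a <- -pr$log_alpha                    # log size = -log alpha

  # everything on the log scale: log(a + mu) = logsumexp(log a, eta),
  # so the likelihood stays finite for any finite parameter value
  lse <- pmax(log_a, eta) + log1p(exp(-abs(eta - log_a)))
  a <- exp(log_a)
  logp0 <- a * (log_a - lse)

  ll <- numeric(length(y))
  zero <- y == 0
  ll[zero] <- log1pexp(logp0[zero] - z[zero]) - log1pexp(-z[zero])
  yp <- y[!zero]
  ll[!zero] <- -log1pexp(z[!zero]) +        # log(1 - pi)
    lgamma(yp + a) - lgamma(a) - lgamma(yp + 1) +
    a * (log_a - lse[!zero]) + yp * (eta[!zero] - lse[!zero])
  out <- sum(ll)
  if (!is.finite(out)) {
    bad <- which(!is.finite(ll))[1]
    stop("non-finite log-likelihood contribution at row ", bad, call. = FALSE)
  }
  out
}

# Analytic gradient of zinb_loglik with respect to c(theta, gamma, log_alpha).
zinb_grad <- function(params, count_design, zero_design, y) {
  p1 <- ncol(count_design); p2 <- ncol(zero_design)
  pr <- split_params(params, p1, p2)
  eta <- drop(count_design %*% pr$theta)
  z <- drop(zero_design %*% pr$gamma)
  log_a <- -pr$log_alpha
  a <- exp(log_a)
  lse <- pmax(log_a, eta) + log1p(exp(-abs(eta - log_a)))  # log(a + mu)
  r_mu <- stats::plogis(eta - log_a)         # mu / (a + mu)
  r_a <- stats::plogis(log_a - eta)          # a / (a + mu)
  pi_ <- stats::plogis(z)
  zero <- y == 0

  du <- numeric(length(y))                   # d ll / d eta
  dv <- numeric(length(y))                   # d ll / d z
  da <- numeric(length(y))                   # d ll / d size

  # positive counts: (y - mu) a / (a + mu) = y r_a - a r_mu, overflow-free
  yp <- y[!zero]
  du[!zero] <- yp * r_a[!zero] - a * r_mu[!zero]
  dv[!zero] <- -pi_[!zero]
  da[!zero] <- digamma(yp + a) - digamma(a) + log_a + 1 -
    lse[!zero] - r_a[!zero] * (1 + yp / a)

  # zeros: D = pi + (1-pi) p0, ratios formed on the log scale
  logp0 <- a * (log_a - lse[zero])
  logD <- log1pexp(logp0 - z[zero]) - log1pexp(-z[zero])
  log1mPi <- -log1pexp(z[zero])
  w <- exp(log1mPi + logp0 - logD)           # (1-pi) p0 / D
  du[zero] <- -w * a * r_mu[zero]
  dv[zero] <- exp(-log1pexp(-z[zero]) + log1mPi - logD) * (1 - exp(logp0))
  da[zero] <- w * (log_a - lse[zero] + r_mu[zero])

  c(drop(crossprod(count_design, du)),
    drop(crossprod(zero_design, dv)),
    -a * sum(da))                            # chain rule: d size/d log_alpha = -size
}

#' Fit the zero-inflated negative binomial DLNM by maximum likelihood
#'
#' Maximises [zinb_loglik()] by expectation-maximisation followed by a
#' Newton polish on the full parameter vector. The E-step computes each
#' zero day's posterior probability of being structural; the M-step fits
#' a weighted binomial GLM for the zero component, a weighted negative
#' binomial GLM for the rate component, and a one-dimensional dispersion
#' update. Both the EM map and the Newton steps are equivariant under
#' affine reparameterisation of design columns, so fits are invariant
#' (up to reparameterisation) to column rescaling. Initialisation:
#' Poisson GLM for the rate coefficients, zeros for the zero-component
#' coefficients, dispersion 0.5. The covariance is the inverse observed
#' information at the optimum; convergence requires a scaled
#' gradient-norm check.
#'
#' @param design A [build_design()] result, or a count design matrix if
#'   `zero_design` and `y` are given separately.
#' @param zero_design,y Optional explicit zero-component design and
#'   response (when `design` is a plain matrix).
#' @param options List: `em_maxit` (default 200), `em_tol` relative
#'   log-likelihood change stopping the EM loop (default 1e-8),
#'   `newton_maxit` (default 25), `grad_tol` scaled-gradient threshold
#'   for the convergence flag (default 1e-4), `init_alpha` (default
#'   0.5).
#'
#' @return Object of class `zinb_dlnm`: `coefficients` (named,
#'   `count.`/`zero.` prefixes), `count_coefficients`,
#'   `zero_coefficients`, `alpha`, `log_alpha`, `vcov` (all free
#'   parameters incl. `log_alpha`), `logLik`, `converged`, `n_used`,
#'   `design_meta` (crossbasis metadata and centers when fitted from a
#'   `dlnm_design`), `fitted_mu`, `fitted_pi`.
#' @export
fit_zinb_dlnm <- function(design, zero_design = NULL, y = NULL,
                          options = list()) {
  opt <- utils::modifyList(
    list(em_maxit = 100L, em_tol = 1e-8, bfgs_maxit = 2000L,
         newton_maxit = 25L, grad_tol = 1e-4, init_alpha = 0.5),
    options)
  if (inherits(design, "dlnm_design")) {
    X <- design$count_design; Z <- design$zero_design; y <- design$response
    meta <- list(cb_meta = design$cb_meta, centers = design$centers,
                 valid_rows = design$valid_rows)
  } else {
    X <- design; Z <- zero_design
    stopifnot(!is.null(Z), !is.null(y))
    meta <- NULL
  }
  y <- as.numeric(y)
  if (all(y == 0)) stop("response is all zeros; the rate component is not ",
                        "identifiable", call. = FALSE)
  for (nm in c("X", "Z")) {
    M <- get(nm)
    r <- qr(M)
    if (r$rank < ncol(M)) {
      drop_cols <- colnames(M)[r$pivot[(r$rank + 1):ncol(M)]]
      stop("design is rank-deficient; collinear column(s): ",
           paste(drop_cols, collapse = ", "), call. = FALSE)
    }
  }
  p1 <- ncol(X); p2 <- ncol(Z)

  theta0 <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::poisson())$coefficients)
  theta0[is.na(theta0)] <- 0

  negll <- function(p) -zinb_loglik(p, X, Z, y)
  neggr <- function(p) -zinb_grad(p, X, Z, y)

  # --- EM ---------------------------------------------------------------
  theta <- theta0
  gamma <- rep(0, p2)
  log_alpha <- log(opt$init_alpha)
  zero <- y == 0
  ll_old <- -Inf
  for (iter in seq_len(opt$em_maxit)) {
    eta <- drop(X %*% theta)
    z <- drop(Z %*% gamma)
    a <- exp(-log_alpha)
    lse <- pmax(log(a), eta) + log1p(exp(-abs(eta - log(a))))
    logp0 <- a * (log(a) - lse)
    # E-step: posterior probability a zero is structural
    w <- numeric(length(y))
    w[zero] <- stats::plogis(z[zero] - logp0[zero])
    # M-step, zero component: weighted binomial GLM on the responsibilities
    gamma <- suppressWarnings(stats::glm.fit(
      Z, w, family = stats::quasibinomial(), start = gamma)$coefficients)
    gamma[is.na(gamma)] <- 0
    # M-step, rate component: weighted NB GLM at the current dispersion
    theta <- suppressWarnings(stats::glm.fit(
      X, y, weights = 1 - w, family = MASS::negative.binomial(a),
      etastart = eta)$coefficients)
    theta[is.na(theta)] <- 0
    # M-step, dispersion: one-dimensional weighted profile update
    mu_new <- exp(drop(X %*% theta))
    log_alpha <- stats::optimize(function(la)
      -sum((1 - w) * stats::dnbinom(y, size = exp(-la), mu = mu_new,
                                    log = TRUE)),
      c(-12, 6))$minimum
    ll <- zinb_loglik(c(theta, gamma, log_alpha), X, Z, y)
    if (is.finite(ll_old) && abs(ll - ll_old) <
          opt$em_tol * (1 + abs(ll))) break
    ll_old <- ll
  }

  # --- quasi-Newton acceleration from the EM solution --------------------
  fit <- stats::optim(c(theta, gamma, log_alpha), negll, neggr,
                      method = "BFGS",
                      control = list(maxit = opt$bfgs_maxit,
                                     reltol = 1e-14))

  # --- Newton polish with the observed information ------------------------
  for (k in seq_len(opt$newton_maxit)) {
    g <- neggr(fit$par)
    if (max(abs(g)) < 1e-10 * max(1, abs(fit$value))) break
    Hk <- tryCatch(stats::optimHess(fit$par, negll, neggr),
                   error = function(e) NULL)
    step <- if (is.null(Hk)) NULL else
      tryCatch(solve(Hk, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    lam <- 1
    improved <- FALSE
    while (lam >= 1e-6) {
      cand <- fit$par - lam * step
      v <- tryCatch(negll(cand), error = function(e) Inf)
      if (is.finite(v) && v <= fit$value) {
        improved <- v < fit$value
        fit$par <- cand; fit$value <- v
        break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }

  grad <- neggr(fit$par)
  grad_scale <- max(abs(grad)) / max(1, abs(fit$value))
  converged <- grad_scale < opt$grad_tol
  if (!converged) {
    warning("ZINB fit did not fully converge (scaled gradient ",
            signif(grad_scale, 3), ")", call. = FALSE)
  }

  H <- stats::optimHess(fit$par, negll, neggr)
  V <- tryCatch(solve(H), error = function(e) MASS::ginv(H))
  V <- psd_project(V)
  par_names <- c(paste0("count.", colnames(X)), paste0("zero.", colnames(Z)),
                 "log_alpha")
  names(fit$par) <- par_names
  dimnames(V) <- list(par_names, par_names)

  pr <- split_params(fit$par, p1, p2)
  structure(list(
    coefficients = fit$par,
    count_coefficients = rlang::set_names(pr$theta, colnames(X)),
    zero_coefficients = rlang::set_names(pr$gamma, colnames(Z)),
    alpha = exp(pr$log_alpha),
    log_alpha = unname(pr$log_alpha),
    vcov = V,
    logLik = -fit$value,
    converged = converged,
    grad_scale = grad_scale,
    n_used = length(y),
    design_meta = meta,
    fitted_mu = exp(drop(X %*% pr$theta)),
    fitted_pi = stats::plogis(drop(Z %*% pr$gamma)),
    response = y),
    class = "zinb_dlnm")
}

#' @export
print.zinb_dlnm <- function(x, ...) {
  cat("<zinb_dlnm> ", x$n_used, " days; logLik ", round(x$logLik, 2),
      "; dispersion alpha ", signif(x$alpha, 4),
      "; converged: ", x$converged, "\n", sep = "")
  cat("  rate terms: ", length(x$count_coefficients),
      "; zero terms: ", length(x$zero_coefficients), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy coefficient table of a fitted ZINB DLNM
#'
#' One row per free parameter: `component` (`count`, `zero` or
#' `dispersion`), `term`, `estimate`, `std.error`, and `rr`
#' (`exp(estimate)`) for rate-component terms, mirroring the shape of a
#' coefficient appendix table.
#'
#' @param x A [fit_zinb_dlnm()] object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.zinb_dlnm <- function(x, ...) {
  nm <- names(x$coefficients)
  comp <- dplyr::case_when(grepl("^count\\.", nm) ~ "count",
                           grepl("^zero\\.", nm) ~ "zero",
                           .default = "dispersion")
  est <- unname(x$coefficients)
  se <- sqrt(pmax(diag(x$vcov), 0))
  tibble::tibble(
    component = comp,
    term = sub("^(count|zero)\\.", "", nm),
    estimate = est,
    std.error = unname(se),
    rr = ifelse(comp == "count", exp(est), NA_real_),
    rr_low = ifelse(comp == "count", exp(est - 1.96 * se), NA_real_),
    rr_high = ifelse(comp == "count", exp(est + 1.96 * se), NA_real_))
}

#' @rdname tidy.zinb_dlnm
#' @return `glance()`: a one-row tibble with `logLik`, `df`, `alpha`,
#'   `n_used`, `converged`.
#' @export
glance.zinb_dlnm <- function(x, ...) {
  tibble::tibble(logLik = x$logLik,
                 df = length(x$coefficients),
                 alpha = x$alpha,
                 n_used = x$n_used,
                 converged = x$converged)
}

#' Randomised-quantile style residuals and their autocorrelation
#'
#' Exports deviance-style (Pearson, on the mixture mean/variance)
#' residuals of the fitted model together with their autocorrelation
#' function, supporting residual diagnostics.
#'
#' @param fit A [fit_zinb_dlnm()] object.
#' @param lag_max Maximum ACF lag (default 30).
#' @return List with `residuals` (tibble: index, observed, fitted_mean,
#'   pearson) and `acf` (tibble: lag, acf).
#' @export
residual_diagnostics <- function(fit, lag_max = 30L) {
  mu <- fit$fitted_mu; pi_ <- fit$fitted_pi; y <- fit$response
  mean_y <- (1 - pi_) * mu
  var_y <- (1 - pi_) * mu * (1 + mu * (fit$alpha + pi_))
  pearson <- (y - mean_y) / sqrt(var_y)
  ac <- stats::acf(pearson, lag.max = lag_max, plot = FALSE)
  list(residuals = tibble::tibble(index = seq_along(y), observed = y,
                                  fitted_mean = mean_y, pearson = pearson),
       acf = tibble::tibble(lag = drop(ac$lag), acf = drop(ac$acf)))
}
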