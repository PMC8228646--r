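# Shared synthetic fixtures, generated in code. The pilot fit is computed
# lazily once per test run and reused across files.

sim_small_study <- function(n_days = 1000, seed = 42, truth = truth_model()) {
  met <- simulate_meteorology(n_days + truth$max_lag, seed = seed)
  simulate_admissions(met, truth, seed = seed + 1)
}

# Reduced-knot spec for fast fits in tests.
small_model_spec <- function(daily) {
  model_spec(
    temp_spec = spline_spec(stats::median(daily$mean_temp),
                            range(daily$mean_temp)),
    rh_spec = spline_spec(stats::median(daily$rh), range(daily$rh)),
    lag_spec = lag_spec_default(21, n_knots = 1),
    trend_df = 3)
}

.pilot <- new.env()

pilot <- function() {
  if (is.null(.pilot$fit)) {
    .pilot$daily <- sim_small_study(1000, seed = 42)
    .pilot$design <- build_design(.pilot$daily)
    .pilot$fit <- fit_zinb_dlnm(.pilot$design)
  }
  .pilot
}

# Independent per-observation ZINB log-likelihood: naive loop over rows
# using stats::dnbinom and the mixture definition directly.
zinb_loglik_naive <- function(params, X, Z, y) {
  p1 <- ncol(X); p2 <- ncol(Z)
  theta <- params[1:p1]; gamma <- params[p1 + 1:p2]
  alpha <- exp(params[p1 + p2 + 1])
  total <- 0
  for (i in seq_along(y)) {
    mu <- exp(sum(X[i, ] * theta))
    pi_ <- 1 / (1 + exp(-sum(Z[i, ] * gamma)))
    if (y[i] == 0) {
      total <- total + log(pi_ + (1 - pi_) *
                             stats::dnbinom(0, size = 1 / alpha, mu = mu))
    } else {
      total <- total + log(1 - pi_) +
        stats::dnbinom(y[i], size = 1 / alpha, mu = mu, log = TRUE)
    }
  }
  total
}

# Brute-force crossbasis: explicit double loop over days and lags.
crossbasis_naive <- function(x, max_lag, exposure_spec, lag_spec) {
  Bx <- ns_basis(x, exposure_spec)
  Bl <- ns_basis(0:max_lag, lag_spec)
  n <- length(x); vx <- ncol(Bx); vl <- ncol(Bl)
  M <- matrix(NA_real_, n, vx * vl)
  for (t in (max_lag + 1):n) {
    for (i in 1:vx) {
      for (j in 1:vl) {
        s <- 0
        for (l in 0:max_lag) s <- s + Bx[t - l, i] * Bl[l + 1, j]
        M[t, (i - 1) * vl + j] <- s
      }
    }
  }
  M
}

finite_diff_2nd <- function(f, x, eps = 1e-4) {
  (f(x + eps) - 2 * f(x) + f(x - eps)) / eps^2
}
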