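test_that("design matrices have the documented structure", {
  daily <- sim_small_study(200, seed = 3)
  spec <- small_model_spec(daily)
  des <- build_design(daily, spec)
  # first usable row: complete 21-day exposure history and 3-day count history
  expect_equal(des$valid_rows[1], max(21, 3) + 1L)
  expect_equal(length(des$response), nrow(daily) - 21)

  # column count equals the sum of the term dimensions
  vx <- basis_dim(spec$temp_spec); vl <- basis_dim(lag_spec_default(21, 1))
  expected_cols <- 1 +                      # intercept
    vx * vl +                               # temperature crossbasis
    basis_dim(spec$rh_spec) * vl +          # humidity crossbasis
    basis_dim(spline_spec_quantile(daily$dtr)) +  # unlagged DTR spline
    6 +                                     # day-of-week (Sunday reference)
    2 +                                     # one Fourier pair
    3                                       # trend spline
  expect_equal(ncol(des$count_design), expected_cols)
  expect_equal(ncol(des$zero_design), 1 + 6 + 3 + 2)

  # Fourier pair is a unit-amplitude harmonic: sin^2 + cos^2 = 1 rowwise
  f <- des$count_design[, c("fourier.sin1", "fourier.cos1")]
  expect_equal(unname(rowSums(f^2)), rep(1, nrow(f)), tolerance = 1e-12)

  # zero design carries the preceding three days' counts as separate columns
  expect_equal(unname(des$zero_design[, "prev.count1"]),
               as.numeric(daily$count[des$valid_rows - 1]))
  expect_equal(unname(des$zero_design[, "prev.count3"]),
               as.numeric(daily$count[des$valid_rows - 3]))
  expect_error(build_design(daily[1:20, ], spec), "too short")
})

test_that("ZINB log-likelihood matches a naive per-observation summation", {
  set.seed(41)
  n <- 50
  X <- cbind(1, rnorm(n), rnorm(n))
  Z <- cbind(1, rnorm(n))
  y <- rpois(n, 2) * rbinom(n, 1, 0.7)
  for (r in 1:5) {
    par <- c(rnorm(3, 0, 0.5), rnorm(2, 0, 0.5), rnorm(1, -0.5, 0.5))
    expect_equal(zinb_loglik(par, X, Z, y),
                 zinb_loglik_naive(par, X, Z, y), tolerance = 1e-10)
  }
})

test_that("likelihood degenerates correctly at the mixture edges", {
  set.seed(42)
  n <- 60
  X <- cbind(1, rnorm(n)); Z <- cbind(1)
  Z <- matrix(1, n, 1)
  y <- rpois(n, 1.5)
  theta <- c(0.3, 0.2); la <- log(0.6)
  # gamma -> -Inf (pi = 0) reduces to the plain negative binomial
  nb_ll <- sum(stats::dnbinom(y, size = exp(-la), mu = exp(drop(X %*% theta)),
                              log = TRUE))
  expect_equal(zinb_loglik(c(theta, -40, la), X, Z, y), nb_ll,
               tolerance = 1e-8)
  # alpha -> 0 approaches the Poisson likelihood on the same mu
  pois_ll <- sum(stats::dpois(y, exp(drop(X %*% theta)), log = TRUE))
  expect_equal(zinb_loglik(c(theta, -40, log(1e-8)), X, Z, y), pois_ll,
               tolerance = 1e-4)
})

test_that("analytic gradient agrees with central finite differences", {
  set.seed(43)
  n <- 40
  X <- cbind(1, rnorm(n), runif(n)); Z <- cbind(1, rnorm(n))
  y <- rpois(n, 1.2) * rbinom(n, 1, 0.8)
  par <- c(0.2, -0.3, 0.1, -0.5, 0.4, log(0.7))
  g <- pneumolag:::zinb_grad(par, X, Z, y)
  num <- vapply(seq_along(par), function(j) {
    h <- 1e-6; e <- rep(0, length(par)); e[j] <- h
    (zinb_loglik(par + e, X, Z, y) - zinb_loglik(par - e, X, Z, y)) / (2 * h)
  }, numeric(1))
  expect_equal(g, num, tolerance = 1e-6)
})

test_that("the fitted optimum satisfies the first-order condition and beats the NB start", {
  p <- pilot()
  fit <- p$fit
  expect_true(fit$converged)
  expect_lt(fit$grad_scale, 1e-4)
  # improvement over the Poisson-start / no-zero-inflation configuration
  X <- p$design$count_design; Z <- p$design$zero_design; y <- p$design$response
  theta0 <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::poisson())$coefficients)
  ll_start <- zinb_loglik(c(theta0, rep(0, ncol(Z)), log(0.5)), X, Z, y)
  ll_nb <- zinb_loglik(c(theta0, c(-40, rep(0, ncol(Z) - 1)), log(0.5)),
                       X, Z, y)
  expect_gt(fit$logLik, ll_start)
  expect_gt(fit$logLik, ll_nb)
  # covariance is symmetric with positive diagonal
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(diag(fit$vcov) > 0))
})

test_that("fit errors are informative for degenerate inputs", {
  daily <- sim_small_study(200, seed = 6)
  des <- build_design(daily, small_model_spec(daily))
  X <- des$count_design
  Xbad <- cbind(X, dup = X[, 2] * 2)
  expect_error(fit_zinb_dlnm(Xbad, des$zero_design, des$response),
               "collinear")
  expect_error(fit_zinb_dlnm(X, des$zero_design, rep(0, nrow(X))),
               "all zeros")
})

test_that("fit is invariant to affine rescaling of a design column", {
  daily <- sim_small_study(400, seed = 8)
  des <- build_design(daily, small_model_spec(daily))
  X <- des$count_design; Z <- des$zero_design; y <- des$response
  f1 <- fit_zinb_dlnm(X, Z, y)
  X2 <- X
  X2[, "fourier.sin1"] <- 3 * X2[, "fourier.sin1"] + 1  # affine, intercept present
  f2 <- fit_zinb_dlnm(X2, Z, y)
  expect_equal(f2$fitted_mu, f1$fitted_mu, tolerance = 1e-6)
  expect_equal(f2$logLik, f1$logLik, tolerance = 1e-8)
})

test_that("simulated-truth coefficients are recovered within Monte Carlo error", {
  # data simulated from a known (theta, gamma, alpha) on a real design
  met <- simulate_meteorology(550, seed = 14)
  daily <- simulate_admissions(met, truth_model_null(), seed = 15)
  des <- build_design(daily, small_model_spec(daily))
  X <- des$count_design; Z <- des$zero_design
  set.seed(16)
  theta <- c(log(1.4), rnorm(ncol(X) - 1, 0, 0.05))
  gamma <- c(-1.1, rep(0, ncol(Z) - 1))
  mu <- exp(drop(X %*% theta)); pi_ <- plogis(drop(Z %*% gamma))
  y <- ifelse(runif(length(mu)) < pi_, 0,
              rnbinom(length(mu), size = 1 / 0.8, mu = mu))
  fit <- suppressWarnings(fit_zinb_dlnm(X, Z, y))
  z <- (fit$coefficients[seq_len(ncol(X))] - theta) /
    sqrt(diag(fit$vcov)[seq_len(ncol(X))])
  expect_lt(max(abs(z)), 4)     # every component within sampling error
})

test_that("the fit agrees with an independent ZINB implementation", {
  skip_if_not_installed("glmmTMB")
  set.seed(51)
  n <- 800
  x <- rnorm(n)
  z <- rnorm(n)
  mu <- exp(1.2 + 0.3 * x)
  pi_ <- plogis(-0.5 + 0.8 * z)
  y <- ifelse(runif(n) < pi_, 0, rnbinom(n, size = 1 / 0.5, mu = mu))
  ours <- fit_zinb_dlnm(cbind(`(Intercept)` = 1, x = x),
                        cbind(`(Intercept)` = 1, z = z), y)
  ref <- glmmTMB::glmmTMB(y ~ x, ziformula = ~z,
                          family = glmmTMB::nbinom2,
                          data = data.frame(y = y, x = x, z = z))
  expect_equal(unname(ours$count_coefficients),
               unname(glmmTMB::fixef(ref)$cond), tolerance = 1e-4)
  expect_equal(unname(ours$zero_coefficients),
               unname(glmmTMB::fixef(ref)$zi), tolerance = 1e-3)
  expect_equal(unname(ours$alpha), 1 / glmmTMB::sigma(ref), tolerance = 1e-3)
  expect_equal(ours$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
})

test_that("tidy/glance and residual diagnostics expose the fit", {
  fit <- pilot()$fit
  td <- tidy(fit)
  expect_setequal(unique(td$component), c("count", "zero", "dispersion"))
  expect_equal(nrow(td), length(fit$coefficients))
  expect_true(all(is.finite(td$std.error)))
  expect_equal(td$rr[td$component == "count"],
               exp(td$estimate[td$component == "count"]))
  gl <- glance(fit)
  expect_equal(gl$n_used, fit$n_used)
  diag_ <- residual_diagnostics(fit)
  expect_equal(nrow(diag_$residuals), fit$n_used)
  expect_equal(diag_$acf$acf[1], 1)
  expect_true(all(abs(diag_$acf$acf) <= 1))
})
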