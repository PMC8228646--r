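test_that("null coefficients and centered exposures give AF exactly 0", {
  p <- pilot()
  null_fit <- p$fit
  cb_cols <- grep("^count\\.mean_temp\\.", names(p$fit$coefficients))
  null_fit$coefficients[cb_cols] <- 0
  af <- backward_af(null_fit, "mean_temp", p$daily, n_mc = 0)
  expect_equal(af$af, 0)
  expect_equal(af$attributable_number, 0)

  # exposures identically at the center: AF 0 even with real coefficients
  flat <- p$daily
  flat$mean_temp <- 21
  af2 <- backward_af(p$fit, "mean_temp", flat, n_mc = 0)
  expect_equal(af2$af, 0, tolerance = 1e-12)

  # shifting a null-coefficient model changes nothing
  af3 <- scenario_af(null_fit, "mean_temp", p$daily, shift = 2, n_mc = 0)
  expect_equal(af3$af, 0)
})

test_that("single-day toy reproduces the closed form 1 - exp(-s)", {
  p <- pilot()
  pb <- pneumolag:::term_block(p$fit, "mean_temp")
  daily <- p$daily[1:60, ]
  daily$count <- c(rep(0, 59), 1L)             # one admission on the last day
  af <- backward_af(p$fit, "mean_temp", daily, n_mc = 0)
  # hand-computed eta sum over the 21 lagged source days
  s <- 0
  for (l in 0:21) {
    s <- s + drop(pneumolag:::cb_contrast(pb$meta, daily$mean_temp[60 - l],
                                          l, 21) %*% pb$theta)
  }
  expect_equal(af$af[af$component == "total"], 1 - exp(-s),
               tolerance = 1e-12)
})

test_that("an exposure with protective cumulative RR yields negative AF", {
  p <- pilot()
  # constant exposure above center where the fitted temperature curve is
  # protective: backward AF equals the single-day closed form and is < 0
  daily <- p$daily
  daily$mean_temp <- 28
  cum <- cumulative_rr(p$fit, "mean_temp", exposure_grid = 28)
  af <- backward_af(p$fit, "mean_temp", daily, n_mc = 0)
  expect_equal(af$af[1], 1 - exp(-log(cum$rr)), tolerance = 1e-10)
  if (cum$rr < 1) expect_lt(af$af[1], 0) else expect_gt(af$af[1], 0)
})

test_that("subranges partitioning the exposure axis sum to the total AF", {
  p <- pilot()
  parts <- list(below = c(-Inf, 21), mid = c(21, 24), above = c(24, Inf))
  af <- backward_af(p$fit, "mean_temp", p$daily, subranges = parts, n_mc = 0)
  tot <- af$af[af$component == "total"]
  expect_equal(sum(af$af[af$component != "total"]), tot, tolerance = 1e-10)
  expect_equal(sum(af$attributable_number[af$component != "total"]),
               af$attributable_number[af$component == "total"],
               tolerance = 1e-8)
  expect_lt(tot, 1)
})

test_that("AF is invariant to scaling all counts by a positive constant", {
  p <- pilot()
  daily3 <- p$daily
  daily3$count <- daily3$count * 3L
  af1 <- backward_af(p$fit, "mean_temp", p$daily, n_mc = 0)
  af3 <- backward_af(p$fit, "mean_temp", daily3, n_mc = 0)
  expect_equal(af3$af, af1$af, tolerance = 1e-12)
  expect_equal(af3$attributable_number, 3 * af1$attributable_number,
               tolerance = 1e-9)
})

test_that("shift = 0 scenario is identical to the unshifted computation", {
  p <- pilot()
  af0 <- backward_af(p$fit, "rh", p$daily, n_mc = 50, seed = 9)
  afs <- scenario_af(p$fit, "rh", p$daily, shift = 0, n_mc = 50, seed = 9)
  expect_identical(af0$af, afs$af)
  expect_identical(af0$ci_low, afs$ci_low)
})

test_that("a toy log-linear unlagged effect obeys the closed-form shift response", {
  # exposure basis spanning a line, theta giving log-RR = beta * (x - c):
  # per-day AF under shift delta on a constant series x = c is 1 - e^(-beta*delta)
  p <- pilot()
  fit <- p$fit
  pb <- pneumolag:::term_block(fit, "dtr")
  meta <- pb$meta
  # solve for theta reproducing a straight line on the dtr basis
  xg <- seq(meta$exposure_spec$boundary_knots[1],
            meta$exposure_spec$boundary_knots[2], length.out = 50)
  beta <- 0.05
  B <- ns_basis(xg, meta$exposure_spec)
  theta_line <- qr.coef(qr(cbind(1, B)), beta * xg)[-1]
  lin_fit <- fit
  idx <- match(paste0("count.", meta$colnames), names(fit$coefficients))
  lin_fit$coefficients[idx] <- theta_line
  daily <- p$daily
  daily$dtr <- 10                               # constant, inside boundaries
  base <- backward_af(lin_fit, "dtr", daily, center = 10, n_mc = 0)
  expect_equal(base$af[1], 0, tolerance = 1e-10)
  delta <- 3
  shifted <- scenario_af(lin_fit, "dtr", daily, shift = delta, center = 10,
                         n_mc = 0)
  expect_equal(shifted$af[1], 1 - exp(-beta * delta), tolerance = 1e-8)
})

test_that("Monte Carlo intervals are seed-deterministic and collapse under zero covariance", {
  p <- pilot()
  af1 <- backward_af(p$fit, "mean_temp", p$daily, n_mc = 200, seed = 4)
  af2 <- backward_af(p$fit, "mean_temp", p$daily, n_mc = 200, seed = 4)
  expect_identical(af1$ci_low, af2$ci_low)
  expect_identical(af1$ci_high, af2$ci_high)

  frozen <- p$fit
  frozen$vcov[] <- 0
  af0 <- backward_af(frozen, "mean_temp", p$daily, n_mc = 100, seed = 4)
  expect_equal(af0$ci_low, af0$af, tolerance = 1e-12)
  expect_equal(af0$ci_high, af0$af, tolerance = 1e-12)

  expect_error(backward_af(p$fit, "mean_temp", p$daily, n_mc = 1), "n_mc")
})

test_that("mc_ci percentiles match analytic normal quantiles on a scalar toy", {
  # statistic = the coefficient itself: draws are N(mu, s2), so the
  # empirical 2.5/97.5 percentiles estimate mu -/+ 1.96 s
  toy <- list(coefficients = c(a = 0.4), vcov = matrix(0.09, 1, 1))
  ci <- mc_ci(toy, function(b) b[1], n_mc = 4000, seed = 12)
  expect_equal(unname(ci[1]), 0.4 - 1.96 * 0.3, tolerance = 0.04)
  expect_equal(unname(ci[2]), 0.4 + 1.96 * 0.3, tolerance = 0.04)
  expect_identical(ci, mc_ci(toy, function(b) b[1], n_mc = 4000, seed = 12))
  expect_error(mc_ci(toy, identity, n_mc = 1), "n_mc")
})

test_that("the AF summary table has the study's shape", {
  p <- pilot()
  tab <- af_table(p$fit, p$daily, n_mc = 20, seed = 3)
  expect_equal(nrow(tab), 9)                    # 3 exposures x 3 scenarios
  expect_setequal(unique(tab$exposure), c("mean_temp", "rh", "dtr"))
  expect_setequal(unique(tab$scenario), c("none", "+2", "-2", "+5", "-5"))
  expect_true(all(c("total_af", "low_af", "high_af") %in% names(tab)))
  # DTR has no low-range component: its reference is the dataset minimum
  expect_true(all(is.na(tab$low_af[tab$exposure == "dtr"])))
  expect_true(all(!is.na(tab$total_af)))
})
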