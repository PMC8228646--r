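#' Pipeline configuration
#'
#' One configuration object driving the full analysis: record filtering,
#' date reconstruction, multiple imputation, per-imputation model
#' fitting, Rubin pooling, centered predictions and attributable
#' fractions. Defaults reproduce the study's stated settings: 21-day
#' maximum lag, 20 imputations, 1000 Monte Carlo repetitions, centering
#' at 21 deg C / 67 % / 1.3 deg C, shifts of +/-2 deg C and +/-5 %, and
#' subrange bounds at 14/26 deg C, 40/80 % and 20 deg C.
#'
#' @param start_date,end_date Study window (defaults 2007-10-10 to
#'   2015-12-31).
#' @param m Number of imputations (default 20).
#' @param k_donors Predictive-mean-matching donors (default 5).
#' @param imputation_predictors Predictor columns for the
#'   length-of-stay imputation model.
#' @param imputation_seed,mc_seed Seeds for the stochastic stages.
#' @param model A [model_spec()].
#' @param prediction_grid_n Points per exposure grid (default 50).
#' @param shifts,subranges Scenario shifts and subrange bounds per term
#'   (see [af_table()]).
#' @param n_mc Monte Carlo repetitions for AF intervals (default 1000).
#' @param pool Set `FALSE` (with `m = 1`) to bypass Rubin pooling and fit
#'   once; useful when there is no missingness.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(start_date = as.Date("2007-10-10"),
                            end_date = as.Date("2015-12-31"),
                            m = 20L, k_donors = 5L,
                            imputation_predictors =
                              c("day_of_year", "dow", "month", "year",
                                "mean_temp", "rh"),
                            imputation_seed = 1L, mc_seed = 1L,
                            model = model_spec(),
                            prediction_grid_n = 50L,
                            shifts = list(mean_temp = 2, rh = 5, dtr = 2),
                            subranges = list(
                              mean_temp = list(low = c(-Inf, 14),
                                               high = c(26, Inf)),
                              rh = list(low = c(-Inf, 40),
                                        high = c(80, Inf)),
                              dtr = list(high = c(20, Inf))),
                            n_mc = 1000L, pool = TRUE) {
  if (!pool && m != 1L) stop("pooling can only be bypassed with m = 1",
                             call. = FALSE)
  if (pool && m < 2L) stop("Rubin pooling needs m >= 2; set pool = FALSE ",
                           "for a single fit", call. = FALSE)
  structure(list(start_date = as.Date(start_date),
                 end_date = as.Date(end_date),
                 m = as.integer(m), k_donors = as.integer(k_donors),
                 imputation_predictors = imputation_predictors,
                 imputation_seed = imputation_seed, mc_seed = mc_seed,
                 model = model, prediction_grid_n = prediction_grid_n,
                 shifts = shifts, subranges = subranges,
                 n_mc = as.integer(n_mc), pool = isTRUE(pool)),
            class = "pipeline_config")
}

#' Run the full records-to-attribution pipeline
#'
#' Executes: keyword filtering -> admission-date reconstruction ->
#' multiple imputation of missing lengths of stay -> per-imputation daily
#' aggregation, design construction and zero-inflated negative binomial
#' fit -> Rubin pooling of coefficients and covariances -> centered
#' relative-rate predictions -> attributable-fraction table. Any stage
#' error aborts with the stage name.
#'
#' @param records Raw admission-record tibble (free-text reason,
#'   admission/discharge dates, length of stay, auxiliary covariates).
#' @param meteorology Daily meteorology tibble covering the study window.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, all result tables are
#'   written as tab-separated text together with a run manifest.
#'
#' @return List of class `pipeline_result`: `coefficients` (pooled tidy
#'   table), `predictions` (named list of [predict_rr()] objects),
#'   `rr_table` (bound tidy cumulative RRs), `af` (the [af_table()]),
#'   `diagnostics` (residuals/ACF of the first fit), `fits`
#'   (per-imputation fits), `pooled_fit`, `daily` (first completed daily
#'   series), `manifest`.
#' @export
run_pipeline <- function(records, meteorology, config = pipeline_config(),
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  filtered <- stage("filter", filter_pneumonia(records))
  resolved <- stage("reconstruct", reconstruct_admission_dates(filtered))
  usable <- dplyr::filter(resolved, .data$date_status != "excluded")

  needs <- any(is.na(usable$length_of_stay) &
                 usable$date_status == "needs_imputation")
  if (config$pool) {
    imp <- stage("impute", pmm_impute(
      usable, predictors = config$imputation_predictors, m = config$m,
      k_donors = config$k_donors, seed = config$imputation_seed))
    datasets <- imp$datasets
  } else {
    if (needs) stop("pipeline stage [impute] failed: records need ",
                    "imputation but pooling is bypassed (m = 1)",
                    call. = FALSE)
    imp <- NULL
    datasets <- list(usable)
  }

  fits <- vector("list", length(datasets))
  dailies <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    d$admission_date[is.na(d$admission_date) & !is.na(d$discharge_date)] <-
      (d$discharge_date - d$length_of_stay)[
        is.na(d$admission_date) & !is.na(d$discharge_date)]
    daily <- stage("aggregate", aggregate_daily(
      d, meteorology, config$start_date, config$end_date))
    design <- stage("design", build_design(daily, config$model))
    fits[[i]] <- stage("fit", fit_zinb_dlnm(design))
    dailies[[i]] <- daily
  }

  pooled_fit <- if (length(fits) == 1) fits[[1]] else
    stage("pool", pool_zinb_fits(fits))

  preds <- stage("predict", rlang::set_names(
    lapply(c("mean_temp", "rh", "dtr"), function(tm)
      predict_rr(pooled_fit, tm)),
    c("mean_temp", "rh", "dtr")))
  rr_table <- dplyr::bind_rows(lapply(preds, tidy, which = "both"))

  af <- stage("attribution", af_table(
    pooled_fit, dailies[[1]], shifts = config$shifts,
    subranges = config$subranges, n_mc = config$n_mc,
    seed = config$mc_seed))

  diag <- stage("diagnostics", residual_diagnostics(fits[[1]]))

  manifest <- tibble::tibble(
    key = c("n_records_in", "n_filtered", "n_excluded", "n_imputations",
            "imputation_seed", "mc_seed", "max_lag", "n_mc",
            "start_date", "end_date", "r_version"),
    value = as.character(c(nrow(records), nrow(filtered),
                           sum(resolved$date_status == "excluded"),
                           length(datasets), config$imputation_seed,
                           config$mc_seed, config$model$max_lag,
                           config$n_mc, config$start_date, config$end_date,
                           as.character(getRversion()))))

  res <- structure(list(coefficients = pooled_coef_table(fits, pooled_fit),
                        predictions = preds,
                        rr_table = rr_table,
                        af = af,
                        diagnostics = diag,
                        fits = fits,
                        pooled_fit = pooled_fit,
                        daily = dailies[[1]],
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

# Rubin-pool per-imputation ZINB fits into one fit-like object usable by
# predict_rr()/backward_af(): pooled coefficients + pooled covariance.
pool_zinb_fits <- function(fits) {
  pooled <- pool_coef_vcov(lapply(fits, `[[`, "coefficients"),
                           lapply(fits, `[[`, "vcov"))
  base <- fits[[1]]
  p1 <- length(base$count_coefficients)
  p2 <- length(base$zero_coefficients)
  pr <- split_params(pooled$coefficients, p1, p2)
  out <- base
  out$coefficients <- pooled$coefficients
  out$count_coefficients <- rlang::set_names(
    pr$theta, names(base$count_coefficients))
  out$zero_coefficients <- rlang::set_names(
    pr$gamma, names(base$zero_coefficients))
  out$log_alpha <- unname(pr$log_alpha)
  out$alpha <- exp(pr$log_alpha)
  out$vcov <- pooled$vcov
  out$logLik <- mean(vapply(fits, `[[`, numeric(1), "logLik"))
  out$converged <- all(vapply(fits, `[[`, logical(1), "converged"))
  out$pooled_m <- length(fits)
  out
}

pooled_coef_table <- function(fits, pooled_fit) {
  if (length(fits) == 1) return(tidy(pooled_fit))
  est <- do.call(rbind, lapply(fits, `[[`, "coefficients"))
  vars <- do.call(rbind, lapply(fits, function(f) pmax(diag(f$vcov), 0)))
  pooled <- pool_rubin(est, vars)
  comp <- dplyr::case_when(grepl("^count\\.", pooled$term) ~ "count",
                           grepl("^zero\\.", pooled$term) ~ "zero",
                           .default = "dispersion")
  tibble::tibble(component = comp,
                 term = sub("^(count|zero)\\.", "", pooled$term),
                 estimate = pooled$point,
                 std.error = sqrt(pooled$total_var),
                 dof = pooled$dof,
                 rr = ifelse(comp == "count", exp(pooled$point), NA_real_))
}

write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(res$coefficients, file.path(out_dir, "coefficients.tsv"))
  readr::write_tsv(res$rr_table, file.path(out_dir, "rr_table.tsv"))
  readr::write_tsv(res$af, file.path(out_dir, "af_table.tsv"))
  readr::write_tsv(res$diagnostics$residuals,
                   file.path(out_dir, "residuals.tsv"))
  readr::write_tsv(res$diagnostics$acf, file.path(out_dir, "acf.tsv"))
  readr::write_tsv(res$manifest, file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$manifest)
  invisible(x)
}
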