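#' Multiple imputation of length of stay by predictive mean matching
#'
#' Proper (Bayesian-draw) predictive mean matching. For each of `m`
#' imputations: a linear model of length of stay on the predictors is fit
#' to the complete cases; regression parameters are drawn from their
#' approximate posterior (sigma^2 from the scaled inverse chi-square,
#' beta from its normal conditional); predictive means are computed for
#' every record; each missing record is matched to the `k_donors`
#' complete cases whose (maximum-likelihood) predictive means are closest
#' to its posterior-draw predictive mean, and the observed length of stay
#' of one donor, chosen uniformly at random, is copied. Every imputed
#' value is therefore a value actually observed in the donor pool.
#'
#' Each imputation uses its own RNG stream seeded from
#' `seed + imputation index`, so increasing `m` extends the set of
#' completed datasets without reshuffling earlier ones.
#'
#' @param records Data frame with a `length_of_stay` column (NA where
#'   missing) and the predictor columns.
#' @param predictors Character vector of predictor column names; must be
#'   complete (non-NA) for every record needing imputation. Constant
#'   columns are dropped with a warning.
#' @param m Number of imputations (default 20).
#' @param k_donors Donor-pool size per missing record (default 5).
#' @param seed Master seed (integer).
#'
#' @return An object of class `pmm_imputation`: a list with
#'   `datasets` (list of `m` completed tibbles), `m`, `k_donors`,
#'   `predictors`, `seed`, and `missing_idx`.
#' @export
pmm_impute <- function(records, predictors, m = 20L, k_donors = 5L, seed) {
  records <- tibble::as_tibble(records)
  stopifnot("length_of_stay" %in% names(records), m >= 1, k_donors >= 1)
  if (missing(seed)) stop("`seed` is required for reproducibility",
                          call. = FALSE)

  miss <- is.na(records$length_of_stay)
  if (!any(miss)) {
    return(structure(list(datasets = replicate(m, records, simplify = FALSE),
                          m = as.integer(m), k_donors = as.integer(k_donors),
                          predictors = predictors, seed = seed,
                          missing_idx = integer(0)),
                     class = "pmm_imputation"))
  }

  X <- stats::model.matrix(
    ~ ., data = as.data.frame(records[, predictors, drop = FALSE]))
  const <- apply(X[, -1, drop = FALSE], 2, function(col) length(unique(col)) == 1)
  if (any(const)) {
    warning("dropping constant predictor column(s): ",
            paste(colnames(X[, -1, drop = FALSE])[const], collapse = ", "),
            call. = FALSE)
    X <- X[, c(TRUE, !const), drop = FALSE]
  }
  if (any(is.na(X[miss, ]))) {
    stop("predictors contain missing values for records needing imputation",
         call. = FALSE)
  }
  obs <- which(!miss & stats::complete.cases(X))
  if (length(obs) == 0) stop("no complete cases to fit the imputation model",
                             call. = FALSE)
  if (length(obs) < k_donors) {
    stop("fewer complete cases (", length(obs), ") than k_donors (",
         k_donors, ")", call. = FALSE)
  }

  y_obs <- records$length_of_stay[obs]
  X_obs <- X[obs, , drop = FALSE]
  qr_obs <- qr(X_obs)
  beta_hat <- qr.coef(qr_obs, y_obs)
  beta_hat[is.na(beta_hat)] <- 0
  resid <- y_obs - drop(X_obs %*% beta_hat)
  df_res <- max(length(obs) - qr_obs$rank, 1L)
  s2 <- sum(resid^2) / df_res
  XtX_inv <- chol2inv(qr.R(qr_obs)[seq_len(ncol(X_obs)), , drop = FALSE])
  yhat_obs <- drop(X_obs %*% beta_hat)            # donors matched on ML fit

  datasets <- vector("list", m)
  for (i in seq_len(m)) {
    set.seed(as.integer(seed) + i)
    sigma2_star <- s2 * df_res / stats::rchisq(1, df_res)
    beta_star <- beta_hat + drop(chol(sigma2_star * XtX_inv) %*%
                                   stats::rnorm(ncol(X_obs)))
    yhat_mis <- drop(X[miss, , drop = FALSE] %*% beta_star)
    donor_los <- vapply(yhat_mis, function(mu) {
      pool <- order(abs(yhat_obs - mu))[seq_len(k_donors)]
      y_obs[pool[sample.int(k_donors, 1)]]
    }, numeric(1))
    filled <- records
    filled$length_of_stay[miss] <- donor_los
    datasets[[i]] <- filled
  }
  structure(list(datasets = datasets, m = as.integer(m),
                 k_donors = as.integer(k_donors),
                 predictors = colnames(X)[-1], seed = seed,
                 missing_idx = which(miss)),
            class = "pmm_imputation")
}

#' @export
print.pmm_imputation <- function(x, ...) {
  cat("<pmm_imputation> m =", x$m, "datasets;", length(x$missing_idx),
      "record(s) imputed; k =", x$k_donors, "donors; seed", x$seed, "\n")
  invisible(x)
}

#' Stack completed datasets into one long tibble
#' @param imp A [pmm_impute()] result.
#' @return Tibble with an `.imp` column identifying the imputation.
#' @export
complete_datasets <- function(imp) {
  stopifnot(inherits(imp, "pmm_imputation"))
  dplyr::bind_rows(imp$datasets, .id = ".imp") |>
    dplyr::mutate(.imp = as.integer(.data$.imp))
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines `m` per-imputation point estimates and variances: the pooled
#' point is the mean of the estimates, the within-imputation variance is
#' the mean of the variances, the between-imputation variance is the
#' sample variance of the estimates, and the total variance is
#' `within + (1 + 1/m) * between`. Degrees of freedom follow the
#' large-sample formula `(m - 1) * (1 + within / ((1 + 1/m) * between))^2`
#' (infinite when the between-variance is zero).
#'
#' Estimates should be pooled on a scale where they are approximately
#' normal (for rate models, the log scale) and transformed afterwards.
#'
#' @param estimates Numeric vector of `m` point estimates, or an
#'   `m x p` matrix (one column per parameter).
#' @param variances Numeric vector or `m x p` matrix of the matching
#'   variances (all non-negative).
#'
#' @return A tibble with columns `point`, `within_var`, `between_var`,
#'   `total_var`, `dof` (one row per parameter).
#' @export
#' @examples
#' pool_rubin(c(1, 3), c(1, 1))  # point 2, total variance 4
pool_rubin <- function(estimates, variances) {
  estimates <- as.matrix(estimates)
  variances <- as.matrix(variances)
  if (ncol(estimates) == 1 && nrow(estimates) < nrow(variances)) {
    stop("estimates and variances must have matching dimensions", call. = FALSE)
  }
  stopifnot(identical(dim(estimates), dim(variances)),
            all(variances >= 0))
  m <- nrow(estimates)
  if (m < 2) stop("Rubin pooling needs m >= 2 (between-imputation variance ",
                  "is undefined for m = 1)", call. = FALSE)
  point <- colMeans(estimates)
  within <- colMeans(variances)
  between <- apply(estimates, 2, stats::var)
  total <- within + (1 + 1 / m) * between
  dof <- ifelse(between > 0,
                (m - 1) * (1 + within / ((1 + 1 / m) * between))^2,
                Inf)
  tibble::tibble(
    term = colnames(estimates) %||% as.character(seq_along(point)),
    point = unname(point), within_var = unname(within),
    between_var = unname(between), total_var = unname(total),
    dof = unname(dof))
}

# Rubin pooling of full coefficient vectors + covariance matrices, for
# downstream prediction/attribution: pooled vcov = W-bar + (1+1/m) B with
# B the between-imputation covariance of the coefficient vectors.
pool_coef_vcov <- function(coefs, vcovs) {
  m <- length(coefs)
  stopifnot(m >= 2, length(vcovs) == m)
  cmat <- do.call(rbind, coefs)
  point <- colMeans(cmat)
  W <- Reduce(`+`, vcovs) / m
  dev <- sweep(cmat, 2, point)
  B <- crossprod(dev) / (m - 1)
  V <- W + (1 + 1 / m) * B
  list(coefficients = point, vcov = (V + t(V)) / 2)
}
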