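#' Centered relative-rate predictions from a fitted crossbasis term
#'
#' Converts the fitted coefficients of one crossbasis term into relative
#' rates against a centering (reference) exposure. The log relative rate
#' at exposure \eqn{x} and lag \eqn{l} is the contrast
#' \eqn{[b_x(x) - b_x(c)] \otimes b_l(l) \cdot \theta}; 95% intervals are
#' delta-method normal intervals on the log scale using the matching
#' block of the fit covariance. At the centering value the relative rate
#' is exactly 1 with a zero-width interval.
#'
#' @param fit A [fit_zinb_dlnm()] object fitted from a [build_design()]
#'   design (so crossbasis metadata is available).
#' @param term Term name: `"mean_temp"`, `"rh"` or `"dtr"`.
#' @param exposure_grid Numeric exposures at which to predict; default 50
#'   equally spaced points over the basis boundary range, plus the
#'   center.
#' @param center Reference exposure; defaults to the center stored in the
#'   design (21 deg C, 67 %, 1.3 deg C).
#' @param conf_level Confidence level (default 0.95).
#'
#' @return An object of class `cross_pred`: list with `surface` (tibble:
#'   term, exposure, lag, rr, rr_low, rr_high over integer lags),
#'   `cumulative` (tibble: term, exposure, rr, rr_low, rr_high),
#'   `center`, `term`, `max_lag`.
#' @export
predict_rr <- function(fit, term = "mean_temp", exposure_grid = NULL,
                       center = NULL, conf_level = 0.95) {
  pb <- term_block(fit, term)
  center <- center %||% fit$design_meta$centers[[term]]
  if (is.null(center)) stop("no centering value available for term `", term,
                            "`", call. = FALSE)
  if (is.null(exposure_grid)) {
    rng <- pb$meta$exposure_spec$boundary_knots
    exposure_grid <- sort(unique(c(seq(rng[1], rng[2], length.out = 50),
                                   center)))
  }
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  lags <- 0:pb$meta$max_lag

  surf <- purrr::map_dfr(lags, function(l) {
    C <- cb_contrast(pb$meta, exposure_grid, l, center)
    lr <- drop(C %*% pb$theta)
    se <- sqrt(pmax(rowSums((C %*% pb$vcov) * C), 0))
    tibble::tibble(term = term, exposure = exposure_grid, lag = l,
                   rr = exp(lr), rr_low = exp(lr - zq * se),
                   rr_high = exp(lr + zq * se))
  })

  # cumulative contrast: bx-diff (x) colSums of the lag basis over all lags
  Csum <- Reduce(`+`, lapply(lags, function(l)
    cb_contrast(pb$meta, exposure_grid, l, center)))
  lr <- drop(Csum %*% pb$theta)
  se <- sqrt(pmax(rowSums((Csum %*% pb$vcov) * Csum), 0))
  cum <- tibble::tibble(term = term, exposure = exposure_grid,
                        rr = exp(lr), rr_low = exp(lr - zq * se),
                        rr_high = exp(lr + zq * se))

  structure(list(surface = surf, cumulative = cum, center = center,
                 term = term, max_lag = pb$meta$max_lag,
                 conf_level = conf_level),
            class = "cross_pred")
}

#' Cumulative (whole-lag-window) relative rates
#'
#' The cumulative association at exposure `x` is the exponential of the
#' sum of lag-specific log relative rates over lags `0..max_lag` — the
#' net multi-day effect of a single day's exposure. For an unlagged term
#' (max lag 0) this is the single-day association.
#'
#' @inheritParams predict_rr
#' @return A tibble: `term`, `exposure`, `rr`, `rr_low`, `rr_high`.
#' @export
cumulative_rr <- function(fit, term = "mean_temp", exposure_grid = NULL,
                          center = NULL, conf_level = 0.95) {
  predict_rr(fit, term, exposure_grid, center, conf_level)$cumulative
}

# Extract one crossbasis term's coefficients, covariance block and metadata.
term_block <- function(fit, term) {
  stopifnot(inherits(fit, "zinb_dlnm"))
  meta <- fit$design_meta$cb_meta[[term]]
  if (is.null(meta)) {
    stop("term `", term, "` not found; available: ",
         paste(names(fit$design_meta$cb_meta), collapse = ", "),
         call. = FALSE)
  }
  idx <- match(paste0("count.", meta$colnames), names(fit$coefficients))
  if (anyNA(idx)) stop("crossbasis columns of `", term,
                       "` do not match the fitted coefficients", call. = FALSE)
  list(meta = meta,
       theta = unname(fit$coefficients[idx]),
       vcov = fit$vcov[idx, idx, drop = FALSE],
       idx = idx)
}

#' @export
print.cross_pred <- function(x, ...) {
  cat("<cross_pred> ", x$term, ": ", nrow(x$cumulative),
      " exposures x lags 0..", x$max_lag, "; centered at ", x$center,
      "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.zinb_dlnm
#' @param which For `cross_pred` objects: `"cumulative"` (default) or
#'   `"surface"` (lag-specific rows, lag column holds the lag; cumulative
#'   rows are labelled `"cumulative"` when both are bound).
#' @export
tidy.cross_pred <- function(x, which = c("cumulative", "surface", "both"),
                            ...) {
  which <- match.arg(which)
  cum <- dplyr::mutate(x$cumulative, lag = "cumulative", .after = "exposure")
  surf <- dplyr::mutate(x$surface, lag = as.character(.data$lag))
  switch(which,
         cumulative = cum,
         surface = surf,
         both = dplyr::bind_rows(surf, cum))
}

#' Plot a centered relative-rate prediction
#'
#' The cumulative exposure-response curve with its confidence ribbon,
#' plus (optionally) lag-specific curves at selected lags.
#'
#' @param object A [predict_rr()] result.
#' @param lags Integer lags to facet (default none: cumulative only).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cross_pred <- function(object, lags = NULL, ...) {
  df <- if (is.null(lags)) {
    dplyr::mutate(object$cumulative, panel = "cumulative")
  } else {
    dplyr::bind_rows(
      dplyr::mutate(object$cumulative, panel = "cumulative"),
      object$surface |>
        dplyr::filter(.data$lag %in% lags) |>
        dplyr::mutate(panel = paste("lag", .data$lag)))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$exposure, y = .data$rr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rr_low,
                                      ymax = .data$rr_high),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$center, linetype = 3) +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = object$term, y = "relative rate (RR)",
                  title = paste("Association of", object$term,
                                "with admissions"),
                  subtitle = paste0("reference ", object$center,
                                    "; lags 0-", object$max_lag)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
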