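#' Natural cubic spline specification
#'
#' A `spline_spec` fixes the knots of a natural cubic spline basis so the
#' basis can be re-evaluated reproducibly at arbitrary values (including
#' values beyond the boundary knots, where natural splines extrapolate
#' linearly). The basis dimension is
#' `length(internal_knots) + 1 + intercept`.
#'
#' @param internal_knots Numeric vector of internal knots (sorted
#'   internally). May be empty.
#' @param boundary_knots Length-2 numeric vector strictly bracketing the
#'   internal knots.
#' @param intercept Logical; if `TRUE` the basis spans the constant
#'   function (one extra column).
#'
#' @return An object of class `spline_spec`.
#' @seealso [ns_basis()], [spline_spec_quantile()]
#' @export
#' @examples
#' sp <- spline_spec(c(15, 21, 25), c(8, 33))
#' dim(ns_basis(seq(8, 33, length.out = 10), sp))
spline_spec <- function(internal_knots, boundary_knots, intercept = FALSE) {
  internal_knots <- sort(as.numeric(internal_knots))
  boundary_knots <- as.numeric(boundary_knots)
  stopifnot(length(boundary_knots) == 2, boundary_knots[1] < boundary_knots[2])
  if (length(internal_knots) > 0 &&
      (min(internal_knots) <= boundary_knots[1] ||
       max(internal_knots) >= boundary_knots[2])) {
    stop("boundary knots must strictly bracket the internal knots",
         call. = FALSE)
  }
  structure(
    list(internal_knots = internal_knots,
         boundary_knots = boundary_knots,
         intercept = isTRUE(intercept)),
    class = "spline_spec"
  )
}

#' Intercept-only basis specification
#'
#' Degenerate basis consisting of the constant function 1. Used as the lag
#' basis of an unlagged exposure (maximum lag 0), so a single code path
#' serves both lagged and unlagged crossbases.
#'
#' @return An object of class `c("intercept_spec", "spline_spec")`.
#' @export
intercept_spec <- function() {
  structure(list(internal_knots = numeric(0), boundary_knots = NULL,
                 intercept = TRUE),
            class = c("intercept_spec", "spline_spec"))
}

#' @export
print.spline_spec <- function(x, ...) {
  if (inherits(x, "intercept_spec")) {
    cat("<spline_spec> intercept-only (1 column)\n")
  } else {
    cat("<spline_spec>", basis_dim(x), "columns; internal knots:",
        paste(signif(x$internal_knots, 4), collapse = ", "),
        "; boundary:", paste(signif(x$boundary_knots, 4), collapse = ", "),
        if (x$intercept) "; with intercept" else "", "\n")
  }
  invisible(x)
}

#' Basis dimension of a spline specification
#' @param spec A [spline_spec()].
#' @return Integer number of basis columns.
#' @export
basis_dim <- function(spec) {
  if (inherits(spec, "intercept_spec")) return(1L)
  length(spec$internal_knots) + 1L + as.integer(spec$intercept)
}

#' Quantile-based spline specification for an exposure
#'
#' Places internal knots at quantiles of the observed exposure (default
#' 25th/50th/75th percentiles) and boundary knots at the observed range —
#' the conventional default for the exposure dimension of a distributed
#' lag non-linear model.
#'
#' @param x Observed exposure values.
#' @param probs Quantile probabilities for the internal knots.
#' @param intercept Passed to [spline_spec()].
#' @return A [spline_spec()].
#' @export
spline_spec_quantile <- function(x, probs = c(0.25, 0.50, 0.75),
                                 intercept = FALSE) {
  x <- x[is.finite(x)]
  kn <- unique(unname(stats::quantile(x, probs)))
  spline_spec(kn, range(x), intercept = intercept)
}

#' Default lag-dimension specification
#'
#' Natural cubic spline with intercept over integer lags `0..max_lag`,
#' internal knots equally spaced on the log(1 + lag) scale — the standard
#' choice that concentrates flexibility at short lags, where delayed
#' effects change fastest.
#'
#' @param max_lag Maximum lag in days.
#' @param n_knots Number of internal knots (default 2).
#' @return A [spline_spec()]; an [intercept_spec()] when `max_lag` is 0.
#' @export
lag_spec_default <- function(max_lag, n_knots = 2L) {
  if (max_lag == 0) return(intercept_spec())
  kn <- exp(seq(log(1), log(1 + max_lag), length.out = n_knots + 2L)) - 1
  kn <- kn[-c(1L, length(kn))]
  spline_spec(kn, c(0, max_lag), intercept = TRUE)
}

#' Evaluate a natural cubic spline basis
#'
#' Evaluates the basis fixed by `spec` at `x`: piecewise cubic between the
#' boundary knots with zero second derivative at and beyond them, hence
#' linear extrapolation outside the boundaries.
#'
#' @param x Numeric vector (all finite).
#' @param spec A [spline_spec()] or [intercept_spec()].
#' @return Numeric matrix, `length(x)` rows and [basis_dim()] columns.
#' @export
ns_basis <- function(x, spec) {
  if (length(x) == 0) stop("`x` is empty", call. = FALSE)
  if (!all(is.finite(x))) stop("`x` contains non-finite values", call. = FALSE)
  if (inherits(spec, "intercept_spec")) {
    return(matrix(1, nrow = length(x), ncol = 1L))
  }
  m <- if (length(spec$internal_knots) > 0) {
    splines::ns(x, knots = spec$internal_knots,
                Boundary.knots = spec$boundary_knots,
                intercept = spec$intercept)
  } else {
    splines::ns(x, Boundary.knots = spec$boundary_knots,
                intercept = spec$intercept)
  }
  m <- unclass(m)
  attributes(m)[setdiff(names(attributes(m)), "dim")] <- NULL
  m
}

#' Exposure-lag crossbasis
#'
#' Builds the tensor-product design matrix of an exposure basis and a lag
#' basis, summed over the lag window: row \eqn{t}, column \eqn{(i,j)}
#' holds \eqn{\sum_{l=0}^{L} B_{x,i}(x_{t-l})\, B_{l,j}(l)}. This embeds a
#' distributed lag non-linear model in the linear predictor of any
#' regression. Rows with incomplete lag history (the first `max_lag` days)
#' are set to `NA` and flagged by the `valid_from` attribute; they are
#' excluded from any likelihood rather than zero-padded.
#'
#' @param x Daily exposure series (numeric, all finite).
#' @param max_lag Maximum lag in days (21 for the lagged exposures; 0
#'   yields the unlagged, single-day basis).
#' @param exposure_spec [spline_spec()] for the exposure dimension;
#'   default: internal knots at the 25th/50th/75th percentiles of `x`,
#'   boundaries at its range.
#' @param lag_spec [spline_spec()] for the lag dimension evaluated at
#'   integer lags `0..max_lag`; default [lag_spec_default()].
#' @param source_name Label naming the exposure (used as column prefix).
#'
#' @return A numeric matrix of class `crossbasis` with attributes
#'   `exposure_spec`, `lag_spec`, `max_lag`, `valid_from` (first usable
#'   row, 1-based) and `source_name`. Columns are named
#'   `<source>.x<i>.l<j>` with the lag index varying fastest.
#' @export
#' @examples
#' x <- sin(seq_len(120) / 10) * 5 + 21
#' cb <- crossbasis(x, max_lag = 21, source_name = "mean_temp")
#' dim(cb); attr(cb, "valid_from")
crossbasis <- function(x, max_lag = 21L,
                       exposure_spec = NULL, lag_spec = NULL,
                       source_name = "exposure") {
  x <- as.numeric(x)
  max_lag <- as.integer(max_lag)
  if (length(x) <= max_lag) {
    stop("series length (", length(x), ") must exceed max_lag (",
         max_lag, ")", call. = FALSE)
  }
  if (!all(is.finite(x))) stop("exposure series contains non-finite values",
                               call. = FALSE)
  if (is.null(exposure_spec)) exposure_spec <- spline_spec_quantile(x)
  if (is.null(lag_spec)) lag_spec <- lag_spec_default(max_lag)

  Bx <- ns_basis(x, exposure_spec)                 # n x vx
  Bl <- ns_basis(0:max_lag, lag_spec)              # (L+1) x vl
  n <- length(x); vx <- ncol(Bx); vl <- ncol(Bl)

  M <- matrix(0, n, vx * vl)
  xi <- rep(seq_len(vx), each = vl)                # exposure index per column
  for (l in 0:max_lag) {
    rows <- (l + 1L):n
    M[rows, ] <- M[rows, ] +
      Bx[rows - l, xi, drop = FALSE] *
      matrix(rep(Bl[l + 1L, ], times = vx), nrow = length(rows),
             ncol = vx * vl, byrow = TRUE)
  }
  if (max_lag > 0) M[seq_len(max_lag), ] <- NA_real_
  colnames(M) <- paste0(source_name, ".x", xi, ".l", rep(seq_len(vl), vx))
  structure(M,
            exposure_spec = exposure_spec,
            lag_spec = lag_spec,
            max_lag = max_lag,
            valid_from = max_lag + 1L,
            source_name = source_name,
            class = c("crossbasis", "matrix", "array"))
}

#' @export
print.crossbasis <- function(x, ...) {
  cat("<crossbasis> ", attr(x, "source_name"), ": ", nrow(x), " days x ",
      ncol(x), " columns; max lag ", attr(x, "max_lag"),
      "; valid from row ", attr(x, "valid_from"), "\n", sep = "")
  invisible(x)
}

# Contrast row for one (exposure, lag) pair relative to the centering value:
# (Bx(x) - Bx(center)) (x) Bl(lag), flattened to match crossbasis columns.
cb_contrast <- function(cb_meta, x, lag, center) {
  bx <- ns_basis(x, cb_meta$exposure_spec) -
    ns_basis(rep(center, length(x)), cb_meta$exposure_spec)
  bl <- ns_basis(lag, cb_meta$lag_spec)
  vx <- ncol(bx); vl <- ncol(bl)
  bx[, rep(seq_len(vx), each = vl), drop = FALSE] *
    bl[rep(1L, nrow(bx)), rep(seq_len(vl), vx), drop = FALSE]
}

# Metadata bundle for a fitted crossbasis term (specs + column names).
cb_meta <- function(cb) {
  list(exposure_spec = attr(cb, "exposure_spec"),
       lag_spec = attr(cb, "lag_spec"),
       max_lag = attr(cb, "max_lag"),
       source_name = attr(cb, "source_name"),
       colnames = colnames(cb))
}
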