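#' Geometrically decaying observation weights
#'
#' Builds the weight scheme w_t = kappa * (1 - kappa)^(T - t) used by the
#' weighted FPCA estimators, normalised to sum to one so the weighted mean is
#' a proper average (the raw weights sum to 1 - (1-kappa)^T).  The most
#' recent year always receives the largest weight; `kappa = 0` is the uniform
#' sentinel giving every year weight 1/T (the unweighted estimators).
#'
#' @param n_years number of observation years T (>= 2).
#' @param kappa decay parameter in `[0, 1)`; larger values discount the past
#'   faster.  0 means uniform weights.
#' @return An object of class `weight_scheme`: a list with elements `kappa`,
#'   `n_years`, `raw` (unnormalised weights) and `weights` (summing to 1).
#' @export
#' @examples
#' geometric_weights(3, 0.5)$weights  # 1/7, 2/7, 4/7
geometric_weights <- function(n_years, kappa = 0) {
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa < 0 || kappa >= 1) {
    abort("kappa must be a single value in [0, 1)")
  }
  n_years <- as.integer(n_years)
  if (n_years < 2L) abort("need at least 2 years")
  t <- seq_len(n_years)
  raw <- if (kappa == 0) rep(1 / n_years, n_years) else kappa * (1 - kappa)^(n_years - t)
  structure(
    list(kappa = kappa, n_years = n_years, raw = raw, weights = raw / sum(raw)),
    class = "weight_scheme"
  )
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("<weight_scheme> T =", x$n_years, "kappa =", x$kappa, "\n")
  invisible(x)
}

#' Weighted mean curve
#'
#' @param curves T x J matrix, years in rows.
#' @param scheme a [geometric_weights()] scheme with `n_years == nrow(curves)`.
#' @return J-vector of weighted column means.
#' @export
weighted_mean_curve <- function(curves, scheme) {
  curves <- as.matrix(curves)
  stopifnot(inherits(scheme, "weight_scheme"), nrow(curves) == scheme$n_years)
  drop(crossprod(curves, scheme$weights))
}

#' Scale centred curves for weighted eigen-estimation
#'
#' Multiplies row t of an already-centred curve matrix by `sqrt(w_t)` so that
#' the Gram matrix of the result equals the weighted covariance
#' `sum_t w_t f*_t f*_t'`.  (Scaling by `w_t` itself, the literal diagonal-W
#' product, would square the weights inside the covariance; set
#' `literal_w = TRUE` for that reading.)
#'
#' @param centred T x J matrix of curves already centred by the weighted mean.
#' @inheritParams weighted_mean_curve
#' @param literal_w scale rows by `w_t` instead of `sqrt(w_t)`.
#' @return T x J matrix.
#' @export
weight_rows_for_eigen <- function(centred, scheme, literal_w = FALSE) {
  centred <- as.matrix(centred)
  stopifnot(inherits(scheme, "weight_scheme"), nrow(centred) == scheme$n_years)
  s <- if (literal_w) scheme$weights else sqrt(scheme$weights)
  centred * s
}

# Unbiased normalisation constant for the weighted covariance: for uniform
# weights 1/(1 - sum(w^2)) * sum_t w_t x_t x_t' reduces to the usual 1/(T-1)
# sample covariance.
weighted_cov_denom <- function(scheme) 1 - sum(scheme$weights^2)
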