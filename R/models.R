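#' Fit the weighted multivariate FPCA mortality model
#'
#' Smooths each population's log rates (unless already-smoothed curves are
#' supplied), estimates the geometrically weighted mean and weighted
#' univariate FPCA per population, and joins the per-population score
#' blocks with a multivariate FPCA, giving each population its own mean
#' and eigenfunctions but a single set of shared, uncorrelated scores.
#' `kappa = 0` gives the unweighted MFPCA baseline; a single population
#' reduces to the independent FPCA fit.
#'
#' @param data tidy surface tibble (columns population, year, age, log_mx)
#'   or a [smooth_surface()] result.
#' @param kappa geometric weight decay in `[0, 1)`; 0 = uniform.
#' @param P cumulative-variance threshold for both truncation stages.
#' @param pivot_age,smoothness passed to [smooth_surface()] when `data` is
#'   a raw surface tibble.
#' @param n_components,n_joint optional overrides of the univariate and
#'   joint truncations (`"all"` retains every nonzero component).
#' @return An object of class `wmfpca_fit`.
#' @export
#' @examples
#' sim <- generate_mortality(synthetic_spec(n_years = 40, ages = 0:20, seed = 1))
#' fit <- fit_wmfpca(sim$data, kappa = 0.05)
#' fc <- forecast(fit, h = 10)
fit_wmfpca <- function(data, kappa = 0, P = 0.9, pivot_age = 65,
                       smoothness = "auto", n_components = NULL,
                       n_joint = NULL) {
  curves <- as_smooth_curves(data, pivot_age, smoothness)
  scheme <- geometric_weights(length(curves$years), kappa)
  fits <- lapply(curves$populations, function(p) {
    ufpca(curves$curves[[p]], scheme, P = P, n_components = n_components,
          ages = curves$ages, population = p)
  })
  joint <- mfpca_from_ufpca(fits, P = P, n_components = n_joint)
  structure(
    list(
      curves = curves, scheme = scheme, kappa = kappa, P = P,
      populations = curves$populations,
      means = lapply(fits, `[[`, "mean") |> setNames(curves$populations),
      mfpca = joint,
      sigma2 = curves$sigma2,
      tau2 = lapply(curves$sigma2, function(s2) sum(scheme$weights^2) * s2)
    ),
    class = "wmfpca_fit"
  )
}

#' Fit independent per-population FPCA models
#'
#' The single-population baseline: each population gets its own weighted
#' univariate FPCA and its scores are extrapolated separately, with no
#' information shared between populations.
#'
#' @inheritParams fit_wmfpca
#' @return An object of class `independent_fit`.
#' @export
fit_independent <- function(data, kappa = 0, P = 0.9, pivot_age = 65,
                            smoothness = "auto", n_components = NULL) {
  curves <- as_smooth_curves(data, pivot_age, smoothness)
  scheme <- geometric_weights(length(curves$years), kappa)
  fits <- lapply(curves$populations, function(p) {
    ufpca(curves$curves[[p]], scheme, P = P, n_components = n_components,
          ages = curves$ages, population = p)
  }) |> setNames(curves$populations)
  structure(
    list(
      curves = curves, scheme = scheme, kappa = kappa, P = P,
      populations = curves$populations,
      means = lapply(fits, `[[`, "mean"),
      fits = fits,
      sigma2 = curves$sigma2,
      tau2 = lapply(curves$sigma2, function(s2) sum(scheme$weights^2) * s2)
    ),
    class = "independent_fit"
  )
}

#' Fit the coherent weighted multivariate FPCA model
#'
#' Decomposes the smoothed log-rate curves into a cross-population average
#' and population-specific deviations, in six steps: (1) the total
#' mortality function `g_t = mean_i f_t^(i)` and its weighted mean `mu`;
#' (2-3) weighted univariate FPCA of the centred total function, retaining
#' K common components with scores `beta`; (4) deviations
#' `d_t^(i) = f_t^(i) - g~_t` from the fitted total function and their
#' weighted means `eta^(i)`; (5-6) weighted multivariate FPCA of the
#' centred deviations, retaining L components with shared scores `gamma`.
#' Forecasting extrapolates `beta` with (possibly non-stationary) ARIMA and
#' `gamma` with stationarity-restricted ARMA converging to zero, so
#' between-population forecast gaps converge to the fixed mean gaps
#' `eta^(i) - eta^(j)`.
#'
#' @inheritParams fit_wmfpca
#' @param n_common,n_deviation optional overrides of the common (K) and
#'   deviation (L) truncations.
#' @return An object of class `coherent_fit`.
#' @export
fit_coherent <- function(data, kappa = 0, P = 0.9, pivot_age = 65,
                         smoothness = "auto", n_common = NULL,
                         n_deviation = NULL) {
  curves <- as_smooth_curves(data, pivot_age, smoothness)
  pops <- curves$populations
  p <- length(pops)
  scheme <- geometric_weights(length(curves$years), kappa)

  # (1)-(3): total mortality function and its weighted FPCA.
  g <- Reduce(`+`, curves$curves) / p
  common <- ufpca(g, scheme, P = P, n_components = n_common,
                  ages = curves$ages, population = "total")
  mu <- common$mean
  g_fitted <- sweep(reconstruct(common), 2L, mu, `+`)

  # (4)-(6): deviations from the fitted total function, weighted MFPCA.
  eta <- vector("list", p); names(eta) <- pops
  dev_fits <- vector("list", p)
  for (i in seq_len(p)) {
    d <- curves$curves[[pops[i]]] - g_fitted
    eta[[i]] <- weighted_mean_curve(d, scheme)
    dev_fits[[i]] <- ufpca(d, scheme, P = P, n_components = "all",
                           ages = curves$ages, population = pops[i])
  }
  deviation <- mfpca_from_ufpca(dev_fits, P = P, n_components = n_deviation)

  structure(
    list(
      curves = curves, scheme = scheme, kappa = kappa, P = P,
      populations = pops,
      mu = mu, eta = eta,
      means = lapply(eta, function(e) mu + e),
      common = common, deviation = deviation, g_fitted = g_fitted,
      K = common$N, L = deviation$N,
      sigma2 = curves$sigma2,
      tau2 = lapply(curves$sigma2, function(s2) sum(scheme$weights^2) * s2)
    ),
    class = "coherent_fit"
  )
}

as_smooth_curves <- function(data, pivot_age, smoothness) {
  if (inherits(data, "smooth_curves")) return(data)
  smooth_surface(data, pivot_age = pivot_age, smoothness = smoothness)
}

#' @export
print.wmfpca_fit <- function(x, ...) {
  cat("<wmfpca_fit> ", length(x$populations), " population(s), kappa = ",
      x$kappa, "; ", x$mfpca$N, " shared component(s)\n", sep = "")
  invisible(x)
}

#' @export
print.independent_fit <- function(x, ...) {
  cat("<independent_fit> ", length(x$populations),
      " population(s), kappa = ", x$kappa, "\n", sep = "")
  invisible(x)
}

#' @export
print.coherent_fit <- function(x, ...) {
  cat("<coherent_fit> ", length(x$populations), " population(s), kappa = ",
      x$kappa, "; K = ", x$K, " common + L = ", x$L,
      " deviation component(s)\n", sep = "")
  invisible(x)
}

#' In-sample fitted log-rate surfaces
#'
#' @param object a fitted mortality model.
#' @param population population label.
#' @param ... unused.
#' @return T x J matrix of fitted log rates.
#' @export
fitted_surface <- function(object, population, ...) UseMethod("fitted_surface")

#' @export
fitted_surface.wmfpca_fit <- function(object, population, ...) {
  sweep(reconstruct(object$mfpca, population = population), 2L,
        object$means[[population]], `+`)
}

#' @export
fitted_surface.independent_fit <- function(object, population, ...) {
  f <- object$fits[[population]]
  sweep(reconstruct(f), 2L, f$mean, `+`)
}

#' @export
fitted_surface.coherent_fit <- function(object, population, ...) {
  object$g_fitted +
    matrix(object$eta[[population]], nrow(object$g_fitted),
           length(object$eta[[population]]), byrow = TRUE) +
    reconstruct(object$deviation, population = population)
}
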