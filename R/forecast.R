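#' Forecast mortality from a fitted model
#'
#' Extrapolates every principal-component score series independently (they
#' are uncorrelated by construction, so no vector model is needed) and
#' assembles h-step point forecasts, component-wise forecast variances and
#' symmetric normal prediction intervals:
#' `Var(Y_{t+h}(x)) = tau^2(x) + sum_n v_{t+h,n} psi_n(x)^2 + sigma^2(x)`,
#' where `tau^2` is the sampling variance of the estimated mean curve,
#' `v_{t+h,n}` the score-forecast variances and `sigma^2` the pooled
#' observation-noise variance.  For the coherent model the common scores
#' use (possibly non-stationary) ARIMA while the deviation scores use
#' stationarity-restricted ARMA fitted to the demeaned series, forcing
#' their forecasts — and hence between-population gaps net of the mean
#' offsets — to converge.
#'
#' @param object a `wmfpca_fit`, `coherent_fit` or `independent_fit`.
#' @param h forecast horizon in years (positive integer).
#' @param alpha 1 - coverage of the prediction intervals (default 0.05).
#' @param criterion ARIMA order-selection criterion, `"aic"` or `"bic"`.
#' @param max_order search caps `c(p, d, q)` for the trend scores.
#' @param max_order_stationary search caps `c(p, q)` for deviation scores
#'   (coherent model only).
#' @param order,order_stationary optional fixed orders bypassing the search.
#' @param drift include a drift regressor with a fixed `order` (d = 1).
#' @param ... unused.
#' @return An object of class `mortality_forecast`; `tidy()` returns a
#'   tibble with columns population, year, horizon, age, point, variance,
#'   lower, upper.
#' @export
forecast <- function(object, h, ...) UseMethod("forecast")

#' @rdname forecast
#' @export
forecast.wmfpca_fit <- function(object, h, alpha = 0.05,
                                criterion = "aic", max_order = c(5, 2, 5),
                                order = NULL, drift = FALSE, ...) {
  h <- check_h(h)
  sf <- lapply(seq_len(object$mfpca$N), function(n) {
    forecast_score_arima(object$mfpca$scores[, n], h, criterion = criterion,
                         max_order = max_order, order = order, drift = drift)
  })
  assemble_forecast(
    object, h, alpha,
    components = lapply(object$populations, function(p) {
      object$mfpca$eigenfunctions[[p]]
    }) |> setNames(object$populations),
    score_fc = sf, score_fc2 = NULL, components2 = NULL,
    score_forecasts = list(shared = sf)
  )
}

#' @rdname forecast
#' @export
forecast.independent_fit <- function(object, h, alpha = 0.05,
                                     criterion = "aic", max_order = c(5, 2, 5),
                                     order = NULL, drift = FALSE, ...) {
  h <- check_h(h)
  out <- lapply(object$populations, function(p) {
    f <- object$fits[[p]]
    sf <- lapply(seq_len(f$N), function(n) {
      forecast_score_arima(f$scores[, n], h, criterion = criterion,
                           max_order = max_order, order = order, drift = drift)
    })
    list(psi = f$eigenfunctions, sf = sf)
  }) |> setNames(object$populations)
  assemble_forecast(
    object, h, alpha,
    components = lapply(out, `[[`, "psi"),
    score_fc = NULL, per_pop_fc = lapply(out, `[[`, "sf"),
    score_forecasts = lapply(out, `[[`, "sf")
  )
}

#' @rdname forecast
#' @export
forecast.coherent_fit <- function(object, h, alpha = 0.05,
                                  criterion = "aic", max_order = c(5, 2, 5),
                                  max_order_stationary = c(5, 5),
                                  order = NULL, order_stationary = NULL,
                                  drift = FALSE, ...) {
  h <- check_h(h)
  beta_fc <- lapply(seq_len(object$K), function(k) {
    forecast_score_arima(object$common$scores[, k], h, criterion = criterion,
                         max_order = max_order, order = order, drift = drift)
  })
  gamma_fc <- lapply(seq_len(object$L), function(l) {
    g <- object$deviation$scores[, l]
    forecast_score_stationary(g - mean(g), h, criterion = criterion,
                              max_order = max_order_stationary,
                              order = order_stationary, include_mean = FALSE)
  })
  assemble_forecast(
    object, h, alpha,
    components = replicate(length(object$populations),
                           object$common$eigenfunctions, simplify = FALSE) |>
      setNames(object$populations),
    score_fc = beta_fc,
    components2 = lapply(object$populations, function(p) {
      object$deviation$eigenfunctions[[p]]
    }) |> setNames(object$populations),
    score_fc2 = gamma_fc,
    score_forecasts = list(common = beta_fc, deviation = gamma_fc)
  )
}

check_h <- function(h) {
  h <- as.integer(h)
  if (length(h) != 1L || is.na(h) || h < 1L) abort("h must be a positive integer")
  h
}

# Shared assembly of point forecasts, variance addends and intervals.
# components / score_fc: first component set (per-population N x J matrices
# and h-step score forecasts shared across populations); components2 /
# score_fc2: optional second set (coherent deviations); per_pop_fc: used by
# the independent model instead of shared score forecasts.
assemble_forecast <- function(object, h, alpha, components, score_fc,
                              components2 = NULL, score_fc2 = NULL,
                              per_pop_fc = NULL, score_forecasts = NULL) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("alpha must be in (0, 1)")
  }
  z <- qnorm(1 - alpha / 2)
  ages <- object$curves$ages
  years <- max(object$curves$years) + seq_len(h)
  pops <- object$populations

  comp_contrib <- function(psi, fcs) {
    # psi: N x J; fcs: list of h-step score forecasts
    pt <- matrix(0, h, length(ages)); vr <- matrix(0, h, length(ages))
    for (n in seq_along(fcs)) {
      pt <- pt + fcs[[n]]$point %o% psi[n, ]
      vr <- vr + fcs[[n]]$variance %o% (psi[n, ]^2)
    }
    list(pt = pt, vr = vr)
  }

  res <- lapply(pops, function(p) {
    fcs <- if (is.null(per_pop_fc)) score_fc else per_pop_fc[[p]]
    cc <- comp_contrib(components[[p]], fcs)
    pt <- sweep(cc$pt, 2L, object$means[[p]], `+`)
    vr_comp <- cc$vr
    if (!is.null(components2)) {
      cc2 <- comp_contrib(components2[[p]], score_fc2)
      pt <- pt + cc2$pt
      vr_comp <- vr_comp + cc2$vr
    }
    tau2 <- matrix(object$tau2[[p]], h, length(ages), byrow = TRUE)
    sig2 <- matrix(object$sigma2[[p]], h, length(ages), byrow = TRUE)
    vr <- tau2 + vr_comp + sig2
    list(point = pt, variance = vr,
         addends = list(tau2 = tau2, component = vr_comp, sigma2 = sig2),
         lower = pt - z * sqrt(vr), upper = pt + z * sqrt(vr))
  }) |> setNames(pops)

  structure(
    list(populations = pops, ages = ages, years = years, h = h,
         alpha = alpha, z = z, results = res,
         score_forecasts = score_forecasts,
         model = class(object)[1]),
    class = "mortality_forecast"
  )
}

#' @export
print.mortality_forecast <- function(x, ...) {
  cat("<mortality_forecast> ", x$model, "; ", length(x$populations),
      " population(s); h = ", x$h, "; years ", min(x$years), "-",
      max(x$years), "; ", 100 * (1 - x$alpha), "% intervals\n", sep = "")
  invisible(x)
}

#' @export
tidy.mortality_forecast <- function(x, ...) {
  purrr::map_dfr(x$populations, function(p) {
    r <- x$results[[p]]
    tibble::tibble(
      population = p,
      year    = rep(x$years, times = length(x$ages)),
      horizon = rep(seq_len(x$h), times = length(x$ages)),
      age     = rep(x$ages, each = x$h),
      point    = as.vector(r$point),
      variance = as.vector(r$variance),
      lower    = as.vector(r$lower),
      upper    = as.vector(r$upper)
    )
  })
}

#' @export
glance.mortality_forecast <- function(x, ...) {
  tibble::tibble(
    model = x$model, populations = length(x$populations),
    h = x$h, alpha = x$alpha,
    n_scores = length(unlist(x$score_forecasts, recursive = FALSE))
  )
}
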