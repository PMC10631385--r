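#' Extrapolate a principal-component score series with ARIMA
#'
#' Exhaustive order search over (p <= max_order[1], d <= max_order[2],
#' q <= max_order[3]) maximum-likelihood ARIMA fits, minimising AIC (or
#' BIC).  For d = 1 a drift term is included via a linear regressor, so a
#' random walk with drift — the typical behaviour of the leading mortality
#' score — is in the candidate set.  Returns analytic h-step point
#' forecasts and forecast variances.
#'
#' Series that are deterministic after differencing (constants, exact
#' linear or quadratic trends) are extrapolated exactly with zero variance
#' rather than handed to the likelihood optimiser.
#'
#' @param series numeric score series (length >= 10 for the automatic
#'   search).
#' @param h forecast horizon (positive integer).
#' @param criterion `"aic"` or `"bic"`.
#' @param max_order `c(p_max, d_max, q_max)` search caps.
#' @param order optional fixed `c(p, d, q)` order, skipping the search.
#' @param drift with a fixed `order`, include the drift regressor
#'   (requires `d == 1`; default `FALSE`).
#' @return An object of class `score_forecast`: `point` and `variance`
#'   (h-vectors), selected `order`, `drift` flag, criterion value and a
#'   `stationary` contract flag.
#' @export
forecast_score_arima <- function(series, h, criterion = c("aic", "bic"),
                                 max_order = c(5, 2, 5), order = NULL,
                                 drift = FALSE) {
  criterion <- match.arg(criterion)
  series <- as.numeric(series)
  if (!all(is.finite(series))) abort("score series must be finite")
  h <- as.integer(h)
  if (h < 1L) abort("forecast horizon must be at least 1")

  det <- deterministic_forecast(series, h, max_d = max_order[2])
  if (!is.null(det)) return(det)

  cands <- if (!is.null(order)) {
    if (drift && order[2] != 1L) abort("drift requires d = 1")
    list(list(order = as.integer(order), drift = drift))
  } else {
    if (length(series) < 10L) abort("need at least 10 observations for the order search")
    grid <- expand.grid(p = 0:max_order[1], d = 0:max_order[2], q = 0:max_order[3])
    out <- list()
    for (r in seq_len(nrow(grid))) {
      o <- as.integer(unlist(grid[r, ]))
      out[[length(out) + 1L]] <- list(order = o, drift = FALSE)
      if (o[2] == 1L) out[[length(out) + 1L]] <- list(order = o, drift = TRUE)
    }
    out
  }

  best <- NULL
  for (cand in cands) {
    fit <- fit_arima_candidate(series, cand$order, cand$drift)
    if (is.null(fit)) next
    crit <- arima_criterion(fit, criterion)
    if (is.null(best) || crit < best$crit - 1e-9) {
      best <- list(fit = fit, crit = crit, order = cand$order, drift = cand$drift)
    }
  }
  if (is.null(best)) abort("no ARIMA candidate could be fitted")

  n <- length(series)
  newxreg <- if (best$drift) matrix(n + seq_len(h), ncol = 1) else NULL
  pr <- predict(best$fit, n.ahead = h, newxreg = newxreg)
  new_score_forecast(
    point = as.numeric(pr$pred), variance = as.numeric(pr$se)^2,
    order = best$order, drift = best$drift,
    criterion = criterion, criterion_value = best$crit,
    stationary = best$order[2] == 0L && ar_roots_stationary(best$fit),
    mean_forecast = NULL, fit = best$fit
  )
}

#' Extrapolate a score series with a stationarity-restricted ARMA model
#'
#' As [forecast_score_arima()], but the search is restricted to d = 0
#' ARMA(p, q) fits with the autoregressive roots constrained outside the
#' unit circle, so point forecasts converge to the process mean as the
#' horizon grows.  This is the mechanism that keeps the deviation
#' components of the coherent model — and hence between-population gaps —
#' from diverging: fit to the *demeaned* deviation scores with
#' `include_mean = FALSE` and the forecasts converge to exactly zero.
#'
#' @inheritParams forecast_score_arima
#' @param max_order `c(p_max, q_max)` search caps.
#' @param order optional fixed `c(p, q)`.
#' @param include_mean estimate and revert to a nonzero process mean
#'   (default `TRUE`); `FALSE` forces convergence to zero.
#' @return A `score_forecast` with `stationary = TRUE`.
#' @export
forecast_score_stationary <- function(series, h, criterion = c("aic", "bic"),
                                      max_order = c(5, 5), order = NULL,
                                      include_mean = TRUE) {
  criterion <- match.arg(criterion)
  series <- as.numeric(series)
  if (!all(is.finite(series))) abort("score series must be finite")
  h <- as.integer(h)
  if (h < 1L) abort("forecast horizon must be at least 1")

  if (sd(series) < 1e-12) {
    m <- if (include_mean) series[1] else 0
    return(new_score_forecast(rep(m, h), rep(0, h), c(0L, 0L, 0L), FALSE,
                              criterion, NA_real_, TRUE, m, NULL))
  }

  cands <- if (!is.null(order)) {
    list(c(order[1], 0L, order[2]))
  } else {
    if (length(series) < 10L) abort("need at least 10 observations for the order search")
    grid <- expand.grid(p = 0:max_order[1], q = 0:max_order[2])
    lapply(seq_len(nrow(grid)), function(r) c(grid$p[r], 0L, grid$q[r]))
  }

  best <- NULL
  for (o in cands) {
    fit <- tryCatch(
      suppressWarnings(arima(series, order = o, include.mean = include_mean,
                             method = "ML", transform.pars = TRUE)),
      error = function(e) NULL
    )
    if (is.null(fit) || !ar_roots_stationary(fit)) next
    crit <- arima_criterion(fit, criterion)
    if (is.null(best) || crit < best$crit - 1e-9) {
      best <- list(fit = fit, crit = crit, order = o)
    }
  }
  if (is.null(best)) abort("no stationary ARMA candidate could be fitted")

  pr <- predict(best$fit, n.ahead = h)
  m <- if (include_mean && "intercept" %in% names(best$fit$coef)) {
    unname(best$fit$coef["intercept"])
  } else 0
  new_score_forecast(
    point = as.numeric(pr$pred), variance = as.numeric(pr$se)^2,
    order = best$order, drift = FALSE,
    criterion = criterion, criterion_value = best$crit,
    stationary = TRUE, mean_forecast = m, fit = best$fit
  )
}

new_score_forecast <- function(point, variance, order, drift, criterion,
                               criterion_value, stationary, mean_forecast, fit) {
  structure(
    list(point = point, variance = pmax(variance, 0), h = length(point),
         order = order, drift = drift, criterion = criterion,
         criterion_value = criterion_value, stationary = stationary,
         mean_forecast = mean_forecast, fit = fit),
    class = "score_forecast"
  )
}

#' @export
print.score_forecast <- function(x, ...) {
  cat("<score_forecast> ARIMA(", paste(x$order, collapse = ","), ")",
      if (x$drift) " + drift", "; h = ", x$h,
      if (x$stationary) "; stationary", "\n", sep = "")
  invisible(x)
}

# ---- internals ---------------------------------------------------------

fit_arima_candidate <- function(series, order, drift) {
  args <- list(series, order = order, include.mean = order[2] == 0L,
               method = "ML", transform.pars = TRUE)
  if (drift) {
    # do.call embeds the evaluated xreg in the stored call, so that
    # predict.Arima can recover it outside this frame
    args$xreg <- matrix(seq_along(series), ncol = 1,
                        dimnames = list(NULL, "drift"))
  }
  tryCatch(suppressWarnings(do.call(stats::arima, args)),
           error = function(e) NULL)
}

arima_criterion <- function(fit, criterion) {
  npar <- length(fit$coef) + 1
  ll <- fit$loglik
  if (criterion == "aic") -2 * ll + 2 * npar else -2 * ll + log(fit$nobs) * npar
}

ar_roots_stationary <- function(fit) {
  phi <- fit$model$phi
  if (!length(phi) || all(abs(phi) < 1e-12)) return(TRUE)
  all(Mod(polyroot(c(1, -phi))) > 1 + 1e-8)
}

# Exact extrapolation of series that are deterministic after differencing.
deterministic_forecast <- function(series, h, max_d = 2L) {
  n <- length(series)
  for (d in 0:min(max_d, n - 1L)) {
    z <- if (d == 0L) series else diff(series, differences = d)
    if (length(z) && max(z) - min(z) < 1e-10 * max(1, max(abs(series)))) {
      cst <- mean(z)
      pt <- series
      for (i in seq_len(h)) {
        nxt <- switch(as.character(d),
          "0" = cst,
          "1" = tail(pt, 1) + cst,
          "2" = 2 * tail(pt, 1) - tail(pt, 2)[1] + cst
        )
        pt <- c(pt, nxt)
      }
      return(new_score_forecast(tail(pt, h), rep(0, h),
                                c(0L, d, 0L), FALSE, "aic", NA_real_,
                                d == 0L, if (d == 0L) cst else NULL, NULL))
    }
  }
  NULL
}
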