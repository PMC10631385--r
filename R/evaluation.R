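#' Average root mean squared forecast error across populations
#'
#' The per-population root is taken before averaging:
#' `RMSE = (1/p) sum_i sqrt( (1/J) sum_j (Y_ij - Yhat_ij)^2 )`.
#'
#' @param actual,predicted numeric vectors (p = 1) or p x J matrices of
#'   log rates, populations in rows.
#' @return scalar RMSE.
#' @export
#' @examples
#' rmse_avg(c(3, 4), c(0, 0))  # sqrt(12.5)
rmse_avg <- function(actual, predicted) {
  if (is.null(dim(actual))) actual <- matrix(actual, nrow = 1)
  if (is.null(dim(predicted))) predicted <- matrix(predicted, nrow = 1)
  if (!all(dim(actual) == dim(predicted))) abort("shape mismatch")
  mean(sqrt(rowMeans((actual - predicted)^2)))
}

#' Rolling-window out-of-sample forecast accuracy
#'
#' Repeatedly truncates the sample, refits the model on years up to the
#' window end, forecasts `h` years ahead, and accumulates squared errors
#' against the observed log rates over all ages and windows.  The reported
#' per-population value is `sqrt( sum of squared errors / (n_windows * J) )`.
#' Smoothing is done once on the full sample and the window's years are
#' taken from it (the smoother is independent across years, so this equals
#' re-smoothing each window).
#'
#' @param data tidy surface tibble with all populations.
#' @param model `"coherent"`, `"wmfpca"` or `"independent"`.
#' @param h forecast horizon in years.
#' @param n_windows number of one-year-apart windows (default 10).
#' @param kappa,P model parameters; see [fit_wmfpca()].
#' @param pivot_age,smoothness smoothing parameters.
#' @param max_order,max_order_stationary ARIMA search caps (kept modest by
#'   default because the model is refitted in every window).
#' @param criterion order-selection criterion.
#' @return An object of class `evaluation_result` with tibbles
#'   `by_population` (population, horizon, rmse) and `windows`
#'   (per-window squared-error sums).
#' @export
rolling_rmse <- function(data, model = c("coherent", "wmfpca", "independent"),
                         h, n_windows = 10, kappa = 0, P = 0.9,
                         pivot_age = 65, smoothness = "auto",
                         max_order = c(2, 1, 2), max_order_stationary = c(2, 2),
                         criterion = "aic") {
  model <- match.arg(model)
  al <- aligned_matrices(data)
  Tall <- length(al$years)
  h <- check_h(h)
  t0 <- Tall - h - (n_windows - 1L)   # first training-window end (index)
  min_train <- 12L
  if (t0 < min_train) {
    abort(paste0("insufficient years: need at least ",
                 min_train + h + n_windows - 1L, " for h = ", h, " and ",
                 n_windows, " windows"))
  }
  curves_full <- smooth_surface(data, pivot_age = pivot_age,
                                smoothness = smoothness)
  pops <- curves_full$populations
  J <- length(al$ages)

  sq_err <- matrix(0, n_windows, length(pops), dimnames = list(NULL, pops))
  for (w in seq_len(n_windows)) {
    tr <- seq_len(t0 + w - 1L)
    cw <- window_curves(curves_full, tr)
    fit <- switch(model,
      coherent    = fit_coherent(cw, kappa = kappa, P = P),
      wmfpca      = fit_wmfpca(cw, kappa = kappa, P = P),
      independent = fit_independent(cw, kappa = kappa, P = P)
    )
    fc <- forecast(fit, h = h, criterion = criterion, max_order = max_order,
                   max_order_stationary = max_order_stationary)
    target <- t0 + w - 1L + h
    for (p in pops) {
      actual <- al$mats[[p]]$Y[target, ]
      pred <- fc$results[[p]]$point[h, ]
      ok <- !is.na(actual)
      sq_err[w, p] <- sum((actual[ok] - pred[ok])^2) * J / max(sum(ok), 1L)
    }
  }
  by_pop <- tibble::tibble(
    population = pops, horizon = h, kappa = kappa,
    rmse = unname(sqrt(colSums(sq_err) / (n_windows * J)))
  )
  structure(
    list(by_population = by_pop,
         windows = tibble::as_tibble(sq_err) |>
           dplyr::mutate(window = dplyr::row_number(), .before = 1),
         h = h, n_windows = n_windows, kappa = kappa, model = model,
         J = J, populations = pops),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("<evaluation_result> ", x$model, "; h = ", x$h, "; ",
      x$n_windows, " windows; kappa = ", x$kappa, "\n", sep = "")
  print(x$by_population)
  invisible(x)
}

#' @export
tidy.evaluation_result <- function(x, ...) x$by_population

# Truncate a smooth_curves object to the given year indices.
window_curves <- function(curves, idx) {
  out <- curves
  out$years <- curves$years[idx]
  out$curves <- lapply(curves$curves, function(m) m[idx, , drop = FALSE])
  out$lambda <- lapply(curves$lambda, function(l) l[idx])
  out$leverage <- lapply(curves$leverage, function(m) m[idx, , drop = FALSE])
  # pooled noise profile kept from the full sample; it enters interval
  # widths only, never the point forecasts scored by rolling RMSE
  out$sigma2 <- curves$sigma2
  out
}

#' Tune the weight decay parameter by rolling-window RMSE
#'
#' Evaluates [rolling_rmse()] on a grid of `kappa` values and returns the
#' minimiser of the population-averaged RMSE, with ties broken toward the
#' smaller (less aggressive) `kappa`.
#'
#' @inheritParams rolling_rmse
#' @param grid candidate `kappa` values in `[0, 1)`.
#' @return A list with `kappa` (the selected value) and `profile`, a tibble
#'   with one row per grid point (kappa, rmse).
#' @export
tune_kappa <- function(data, model = c("coherent", "wmfpca", "independent"),
                       h, grid = seq(0, 0.5, by = 0.1), n_windows = 10,
                       ...) {
  model <- match.arg(model)
  if (!length(grid)) abort("kappa grid must be non-empty")
  rmse <- vapply(grid, function(k) {
    mean(rolling_rmse(data, model = model, h = h, n_windows = n_windows,
                      kappa = k, ...)$by_population$rmse)
  }, 0)
  profile <- tibble::tibble(kappa = as.numeric(grid), rmse = rmse)
  best <- profile$kappa[order(profile$rmse, profile$kappa)][1]
  list(kappa = best, profile = profile)
}

#' Period life expectancy from a log-rate curve
#'
#' Standard period life table on single-year ages starting at age 0:
#' central rates `m_x = exp(log_mx)` are converted to death probabilities
#' `q_x = m_x / (1 + 0.5 m_x)` (midpoint a_x = 0.5, capped at 1), survivors
#' and person-years follow with an open-ended last age
#' (`L_A = l_A / m_A`), and `e_x = sum_{y >= x} L_y / l_x`.
#'
#' @param log_mx numeric vector of log central death rates on ages
#'   `0..A`, or a tidy surface tibble for one population-year.
#' @return A tibble with columns `age` and `ex` (remaining life
#'   expectancy in years).
#' @export
life_expectancy <- function(log_mx) {
  if (is.data.frame(log_mx)) {
    check_surface_df(log_mx)
    if (length(unique(log_mx$population)) != 1L ||
        length(unique(log_mx$year)) != 1L) {
      abort("supply a single population-year curve")
    }
    log_mx <- log_mx$log_mx[order(log_mx$age)]
  }
  m <- exp(as.numeric(log_mx))
  if (any(!is.finite(m) | m <= 0)) abort("all death rates must be positive and finite")
  A <- length(m)
  q <- pmin(m / (1 + 0.5 * m), 1)
  q[A] <- 1                      # open-ended last age
  l <- cumprod(c(1, 1 - q[-A]))  # survivors at exact age x
  d <- l * q
  L <- l - 0.5 * d
  L[A] <- l[A] / m[A]
  Tx <- rev(cumsum(rev(L)))
  tibble::tibble(age = seq_len(A) - 1L, ex = Tx / l)
}

#' Mortality rate ratio between two populations
#'
#' @param log_mx_a,log_mx_b log-rate curves on the same age grid.
#' @return numeric vector `exp(a - b)`, e.g. the male/female rate ratio.
#' @export
sex_ratio <- function(log_mx_a, log_mx_b) {
  a <- as.numeric(log_mx_a); b <- as.numeric(log_mx_b)
  if (length(a) != length(b)) abort("shape mismatch")
  exp(a - b)
}
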