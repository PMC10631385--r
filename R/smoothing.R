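#' Smooth mortality surfaces with partially monotone penalised splines
#'
#' Each year's log-rate curve is fitted with a penalised cubic B-spline
#' (interior knots every `knot_every` years of age, second-difference penalty
#' on the coefficients), and the fitted values at ages at or above
#' `pivot_age` are then projected onto the monotone non-decreasing cone by
#' pool-adjacent-violators, reflecting the demographic expectation that
#' mortality increases with age beyond midlife.  Masked (`NA`) cells are
#' predicted from the fit.  With `smoothness = "auto"` the penalty weight is
#' chosen per curve by generalised cross-validation over a log-spaced grid.
#'
#' @param data tidy surface tibble (one or more populations) as produced by
#'   [new_surface()], [read_hmd_mx()] or [generate_mortality()].
#' @param pivot_age fitted curves are constrained non-decreasing for ages at
#'   or above this age (default 65).
#' @param smoothness `"auto"` (GCV) or a fixed non-negative penalty weight.
#' @param knot_every interior knot spacing in years of age (default 5).
#' @return An object of class `smooth_curves` holding, per population, the
#'   T x J matrix of smoothed curves, the pooled per-age residual variance,
#'   and the selected penalty weights.  Use [tidy()] for a long tibble.
#' @export
smooth_surface <- function(data, pivot_age = 65, smoothness = "auto",
                           knot_every = 5) {
  al <- aligned_matrices(data)
  ages <- al$ages; years <- al$years
  bas <- pspline_basis(ages, knot_every)
  auto <- identical(smoothness, "auto")
  if (!auto && (!is.numeric(smoothness) || smoothness < 0)) {
    abort("smoothness must be \"auto\" or a non-negative number")
  }
  lambda_grid <- if (auto) 10^seq(-4, 6, length.out = 31) else as.numeric(smoothness)

  fits <- lapply(al$mats, function(m) {
    fit_pspline_surface(m, bas, lambda_grid, pivot_age)
  })

  out <- structure(
    list(
      populations = names(al$mats),
      years = years, ages = ages, pivot_age = pivot_age,
      knot_every = knot_every,
      curves = lapply(fits, `[[`, "fitted"),
      lambda = lapply(fits, `[[`, "lambda"),
      leverage = lapply(fits, `[[`, "leverage"),
      sigma2 = NULL
    ),
    class = "smooth_curves"
  )
  estimate_sigma(data, out)
}

#' Estimate the age-varying observation noise scale
#'
#' Pools squared smoothing residuals over years at each age to estimate the
#' observation-noise variance profile `sigma^2(x)` (log-rate units squared).
#' The profile enters the forecast variance as the irreducible
#' observation-error term and, scaled by the squared mean weights, as the
#' sampling variance of the estimated mean curve.
#'
#' @inheritParams smooth_surface
#' @param curves a `smooth_curves` object fitted to `data`.
#' @return The `smooth_curves` object with its `sigma2` field (a per-age
#'   variance vector per population) filled in.
#' @export
estimate_sigma <- function(data, curves) {
  stopifnot(inherits(curves, "smooth_curves"))
  al <- aligned_matrices(data)
  if (!identical(al$ages, curves$ages) || !identical(al$years, curves$years)) {
    abort("data grid does not match the smoothed curves")
  }
  curves$sigma2 <- lapply(curves$populations, function(p) {
    res <- al$mats[[p]]$Y - curves$curves[[p]]
    # centre the residuals over years at each age (removes the smoother's
    # systematic per-age bias profile), then divide by the per-cell
    # residual factor 1 - 2*A_jj + (AA')_jj so the noise scale is not
    # deflated by the degrees of freedom the fit absorbs
    lev <- curves$leverage[[p]]
    obs <- !is.na(res)
    n_obs <- pmax(colSums(obs), 1L)
    res_c <- sweep(res, 2L, colSums(res, na.rm = TRUE) / n_obs)
    num <- colSums(res_c^2 * obs, na.rm = TRUE)
    den <- colSums(pmax(lev, 1e-3) * obs, na.rm = TRUE) * (n_obs - 1L) / n_obs
    s2 <- num / pmax(den, 1e-12)
    s2[!is.finite(s2)] <- 0
    s2
  })
  names(curves$sigma2) <- curves$populations
  curves
}

#' @export
print.smooth_curves <- function(x, ...) {
  cat("<smooth_curves> ", length(x$populations), " population(s), ",
      length(x$years), " years x ", length(x$ages), " ages; pivot age ",
      x$pivot_age, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.smooth_curves <- function(x, ...) {
  purrr::map_dfr(x$populations, function(p) {
    tibble::tibble(
      population = p,
      year  = rep(x$years, times = length(x$ages)),
      age   = rep(x$ages, each = length(x$years)),
      smoothed = as.vector(x$curves[[p]]),
      sigma = rep(sqrt(x$sigma2[[p]]), each = length(x$years))
    )
  })
}

# ---- internals ---------------------------------------------------------

# Cubic B-spline basis on equally spaced knots (one per `knot_every` years,
# extended past the boundaries) with a second-difference coefficient
# penalty: uniform knots keep the penalty nullspace exactly linear, so
# linear-in-age curves are reproduced at any penalty weight.
pspline_basis <- function(ages, knot_every = 5) {
  a0 <- min(ages); a1 <- max(ages)
  n_span <- ceiling((a1 - a0) / knot_every)
  knots <- a0 + knot_every * seq(-3, n_span + 3)
  B <- splines::splineDesign(knots, ages, ord = 4, outer.ok = TRUE)
  K <- ncol(B)
  D <- diff(diag(K), differences = 2)
  list(B = B, P = crossprod(D), K = K, ages = ages)
}

# Demmler-Reinsch decomposition shared by every complete curve of a surface.
dr_decompose <- function(bas) {
  BtB <- crossprod(bas$B)
  R <- chol(BtB + diag(1e-10 * mean(diag(BtB)), bas$K))
  Rinv <- backsolve(R, diag(bas$K))
  E <- (t(Rinv) %*% bas$P %*% Rinv)
  eg <- eigen((E + t(E)) / 2, symmetric = TRUE)
  s <- pmax(eg$values, 0)
  M <- bas$B %*% (Rinv %*% eg$vectors)   # J x K, orthonormal columns
  list(M = M, s = s)
}

fit_pspline_surface <- function(m, bas, lambda_grid, pivot_age) {
  Tn <- nrow(m$Y); J <- ncol(m$Y); K <- bas$K
  usable <- rowSums(!m$mask)
  if (any(usable < K)) {
    yr <- m$years[which(usable < K)[1]]
    abort(paste0("year ", yr, " has ", usable[which(m$years == yr)],
                 " usable cells but the spline has ", K, " coefficients"))
  }
  fitted <- matrix(NA_real_, Tn, J, dimnames = dimnames(m$Y))
  leverage <- matrix(NA_real_, Tn, J, dimnames = dimnames(m$Y))
  lambda <- numeric(Tn)
  complete <- !apply(m$mask, 1L, any)

  if (any(complete)) {
    dr <- dr_decompose(bas)
    Yc <- m$Y[complete, , drop = FALSE]
    Z <- Yc %*% dr$M                      # T_c x K rotated coefficients
    yTy <- rowSums(Yc^2)
    best_rss <- rep(Inf, nrow(Z)); best_gcv <- rep(Inf, nrow(Z))
    best_l <- numeric(nrow(Z)); best_c <- matrix(1, nrow(Z), K)
    for (l in lambda_grid) {
      cc <- 1 / (1 + l * dr$s)            # shrinkage factors, length K
      trA <- sum(cc)
      Z2 <- Z^2
      rss <- pmax(yTy - Z2 %*% (2 * cc - cc^2), 0)
      gcv <- J * rss / (J - trA)^2
      upd <- gcv < best_gcv
      if (any(upd)) {
        best_gcv[upd] <- gcv[upd]
        best_l[upd] <- l
        best_c[upd, ] <- matrix(cc, sum(upd), K, byrow = TRUE)
      }
    }
    fitted[complete, ] <- (Z * best_c) %*% t(dr$M)
    lambda[complete] <- best_l
    # residual factor diag(I - A)^2-ish: 1 - 2 A_jj + (A A')_jj with
    # A = M diag(c) M'
    M2 <- dr$M^2
    leverage[complete, ] <- 1 - 2 * best_c %*% t(M2) + (best_c^2) %*% t(M2)
  }

  for (t in which(!complete)) {
    obs <- !m$mask[t, ]
    y <- m$Y[t, obs]
    Bo <- bas$B[obs, , drop = FALSE]
    BtB <- crossprod(Bo); Bty <- crossprod(Bo, y)
    best <- list(gcv = Inf)
    for (l in lambda_grid) {
      A <- BtB + l * bas$P
      a <- solve(A, Bty)
      H <- Bo %*% solve(A, t(Bo))     # hat matrix on the observed cells
      trA <- sum(diag(H))
      rss <- sum((y - Bo %*% a)^2)
      gcv <- length(y) * rss / (length(y) - trA)^2
      if (gcv < best$gcv) best <- list(gcv = gcv, a = a, l = l, H = H)
    }
    fitted[t, ] <- bas$B %*% best$a
    lambda[t] <- best$l
    leverage[t, obs] <- 1 - 2 * diag(best$H) + rowSums(best$H^2)
  }

  hi <- which(bas$ages >= pivot_age)
  if (length(hi) > 1L) {
    for (t in seq_len(Tn)) {
      fitted[t, hi] <- isoreg(bas$ages[hi], fitted[t, hi])$yf
    }
  }
  list(fitted = fitted, lambda = lambda, leverage = leverage)
}
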