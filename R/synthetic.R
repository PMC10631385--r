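#' Specify a synthetic multipopulation mortality model
#'
#' Builds a reproducible specification of the coherent decomposition
#' `f_t^(i)(x) = mu(x) + eta^(i)(x) + G_t(x) + Z_t^(i)(x)` from which
#' [generate_mortality()] simulates log-mortality surfaces with known ground
#' truth.  The common trend `G_t` is driven by `n_common` random-walk-with-
#' drift scores on orthonormal basis curves shared by all populations; the
#' population-specific deviations `Z_t^(i)` are driven by `n_deviation`
#' stationary AR(1) scores on multivariate-orthonormal, zero-sum-across-
#' population basis curves, so the simulated subpopulations share a
#' direction of travel while their gaps mean-revert.  Observation noise is
#' age-varying i.i.d. Gaussian.
#'
#' Defaults emulate two sex-specific populations on ages 0-100 over 70
#' years: a dominant declining common component plus a slow secondary one,
#' and one mean-reverting deviation component.
#'
#' @param n_pop number of subpopulations p (>= 2).
#' @param n_years number of calendar years T.
#' @param ages integer age grid (default `0:100`).
#' @param n_common number of common random-walk-with-drift components K.
#' @param n_deviation number of stationary deviation components L.
#' @param drift per-component drifts of the common scores (recycled).
#' @param common_sd innovation standard deviations of the common scores.
#' @param ar_coef AR(1) coefficients of the deviation scores, inside (-1, 1).
#' @param ar_sd innovation standard deviations of the deviation scores.
#' @param noise_sd observation noise scale: a single value, a J-vector, or
#'   `NULL` for the default age-varying profile (0.02 at midlife rising to
#'   0.08 at the extreme ages, where death counts are smallest).
#' @param eta_scale amplitude of the between-population mean offsets.
#' @param seed integer seed; the spec and all simulations from it are
#'   deterministic given the seed.
#' @return An object of class `synthetic_spec`.
#' @export
#' @examples
#' sp <- synthetic_spec(n_pop = 2, n_years = 50, ages = 0:20, seed = 7)
#' sim <- generate_mortality(sp)
#' dplyr::count(sim$data, population)
synthetic_spec <- function(n_pop = 2, n_years = 70, ages = 0:100,
                           n_common = 2, n_deviation = 1,
                           drift = c(-0.20, 0.03), common_sd = c(0.15, 0.08),
                           ar_coef = 0.6, ar_sd = 0.10,
                           noise_sd = NULL, eta_scale = 0.3, seed = 1L) {
  p <- as.integer(n_pop); K <- as.integer(n_common); L <- as.integer(n_deviation)
  J <- length(ages)
  if (p < 2L) abort("need at least 2 subpopulations")
  if (K < 1L || L < 1L) abort("need at least one common and one deviation component")
  if (J < K + L + 1L) abort("age grid too small to orthonormalise the bases")
  validate_grid(seq_len(n_years), ages)
  drift <- rep_len(drift, K); common_sd <- rep_len(common_sd, K)
  ar_coef <- rep_len(ar_coef, L); ar_sd <- rep_len(ar_sd, L)
  if (any(abs(ar_coef) >= 1)) abort("AR(1) coefficients must be strictly inside (-1, 1)")

  x <- (ages - min(ages)) / diff(range(ages))    # in [0, 1]
  mu <- base_log_mortality(x)

  # Smooth raw curves: low-order polynomials and sinusoids, then joint
  # Gram-Schmidt so common and deviation shapes are mutually orthonormal
  # under the unit-spacing quadrature.
  raw <- cbind(
    x, sin(pi * x), x^2, cos(pi * x), sin(2 * pi * x), x^3,
    cos(2 * pi * x), sin(3 * pi * x)
  )
  need <- K + L
  if (need > ncol(raw)) abort("too many components requested for the built-in shapes")
  Q <- gram_schmidt(cbind(1, raw)[, seq_len(need + 1L), drop = FALSE])
  Q <- Q[, -1L, drop = FALSE]                   # drop the constant direction
  common_basis <- Q[, seq_len(K), drop = FALSE]           # J x K
  dev_shapes <- Q[, K + seq_len(L), drop = FALSE]         # J x L

  # Zero-sum orthonormal population contrasts (Helmert rows, normalised).
  H <- stats::contr.helmert(p)                  # p x (p-1), columns zero-sum
  H <- sweep(H, 2L, sqrt(colSums(H^2)), "/")
  contrasts <- H[, ((seq_len(L) - 1L) %% (p - 1L)) + 1L, drop = FALSE]  # p x L

  # eta curves: smooth offsets that sum to zero across populations.
  eta_shape <- 0.5 + 0.5 * sin(pi * x)
  eta <- outer(H[, 1L], eta_shape * eta_scale)  # p x J, zero column sums

  if (is.null(noise_sd)) {
    noise_sd <- 0.02 + 0.06 * (2 * abs(x - 0.5))^2
  } else {
    noise_sd <- rep_len(noise_sd, J)
  }
  if (any(noise_sd < 0)) abort("noise_sd must be non-negative")

  structure(
    list(
      n_pop = p, n_years = as.integer(n_years), ages = as.integer(ages),
      n_common = K, n_deviation = L,
      mu = mu, eta = eta,
      common_basis = common_basis,
      deviation_shapes = dev_shapes, contrasts = contrasts,
      drift = drift, common_sd = common_sd,
      ar_coef = ar_coef, ar_sd = ar_sd,
      noise_sd = noise_sd, seed = as.integer(seed),
      populations = sprintf("pop%d", seq_len(p))
    ),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> p =", x$n_pop, "T =", x$n_years,
      "J =", length(x$ages), "K =", x$n_common, "L =", x$n_deviation,
      "seed =", x$seed, "\n")
  invisible(x)
}

# Deviation basis curve for population i, component l:
# phi_l^(i)(x) = shape_l(x) * contrast_l[i]; multivariate-orthonormal by
# construction (orthonormal shapes x orthonormal zero-sum contrasts).
deviation_basis <- function(spec, i) {
  sweep(spec$deviation_shapes, 2L, spec$contrasts[i, ], "*")  # J x L
}

#' Simulate log-mortality surfaces with known ground truth
#'
#' Draws `Y_t^(i)(x_j) = mu + eta^(i) + sum_k beta_tk phi_k +
#' sum_l gamma_tl phi_l^(i) + sigma(x_j) e`, with common scores from a
#' random walk with drift (centred over the sample so the simulated common
#' trend has zero sample mean, the identifiability convention the estimators
#' assume) and deviation scores from mean-zero stationary AR(1) processes
#' initialised at their stationary distribution.
#'
#' @param spec a [synthetic_spec()].
#' @param first_year calendar year of the first simulated row.
#' @return A list with `data` (tidy surface tibble for all populations) and
#'   `truth`, a list holding every latent quantity: `mu`, `eta`,
#'   `common_basis`, `deviation_basis` (per population), score matrices
#'   `beta` (T x K) and `gamma` (T x L), and the noiseless surfaces
#'   `f` (per population T x J).
#' @export
generate_mortality <- function(spec, first_year = 1951L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  Tn <- spec$n_years; J <- length(spec$ages)
  K <- spec$n_common; L <- spec$n_deviation; p <- spec$n_pop

  beta <- sapply(seq_len(K), function(k) {
    b <- cumsum(spec$drift[k] + stats::rnorm(Tn, 0, spec$common_sd[k]))
    b - mean(b)
  })
  beta <- matrix(beta, Tn, K)

  gamma <- sapply(seq_len(L), function(l) {
    phi <- spec$ar_coef[l]; s <- spec$ar_sd[l]
    g <- numeric(Tn)
    g[1] <- stats::rnorm(1, 0, if (s > 0) s / sqrt(1 - phi^2) else 0)
    for (t in seq_len(Tn)[-1]) g[t] <- phi * g[t - 1] + stats::rnorm(1, 0, s)
    g
  })
  gamma <- matrix(gamma, Tn, L)

  G <- beta %*% t(spec$common_basis)             # T x J common trend
  years <- first_year + seq_len(Tn) - 1L

  truth <- list(
    mu = spec$mu, eta = spec$eta,
    common_basis = spec$common_basis,
    deviation_basis = lapply(seq_len(p), function(i) deviation_basis(spec, i)),
    beta = beta, gamma = gamma, f = vector("list", p),
    years = years, ages = spec$ages, populations = spec$populations
  )
  names(truth$deviation_basis) <- spec$populations
  names(truth$f) <- spec$populations

  data <- vector("list", p)
  for (i in seq_len(p)) {
    Zi <- gamma %*% t(deviation_basis(spec, i))  # T x J
    f <- matrix(spec$mu, Tn, J, byrow = TRUE) +
      matrix(spec$eta[i, ], Tn, J, byrow = TRUE) + G + Zi
    truth$f[[i]] <- f
    noise <- matrix(stats::rnorm(Tn * J), Tn, J) *
      matrix(spec$noise_sd, Tn, J, byrow = TRUE)
    data[[i]] <- new_surface(f + noise, years, spec$ages, spec$populations[i])
  }
  list(data = dplyr::bind_rows(data), truth = truth)
}

# ---- helpers -----------------------------------------------------------

# Plausible log-mortality age profile: high infant mortality, young-adult
# hump, exponential (Gompertz-like) rise in later life.
base_log_mortality <- function(x) {
  log(0.02 * exp(-25 * x) +
        0.0004 * exp(-((x - 0.2)^2) / 0.005) +
        0.00003 + 0.00002 * exp(9 * x))
}

# Orthonormalise columns under the unit-spacing quadrature (plain dot
# products on the grid).
gram_schmidt <- function(M) {
  M <- as.matrix(M)
  Q <- matrix(0, nrow(M), ncol(M))
  for (k in seq_len(ncol(M))) {
    v <- M[, k]
    if (k > 1L) v <- v - Q[, 1:(k - 1L), drop = FALSE] %*%
        crossprod(Q[, 1:(k - 1L), drop = FALSE], v)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10) abort("age grid too small to orthonormalise the bases")
    Q[, k] <- v / nv
  }
  Q
}
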