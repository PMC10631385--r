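#' Select the number of components by cumulative variance
#'
#' Returns the smallest N whose leading eigenvalues explain at least a
#' fraction `P` of total variance (default 0.9, the usual minimum
#' acceptance level for functional principal component truncation).
#'
#' @param eigenvalues non-negative, non-increasing eigenvalue spectrum.
#' @param P required cumulative fraction of total variance in (0, 1].
#' @return integer N.
#' @export
#' @examples
#' select_ncomp(c(0.8, 0.15, 0.05), P = 0.9)  # 2
select_ncomp <- function(eigenvalues, P = 0.9) {
  ev <- as.numeric(eigenvalues)
  if (any(ev < -1e-10)) abort("eigenvalues must be non-negative")
  ev <- pmax(ev, 0)
  tot <- sum(ev)
  if (tot <= 0) abort("all-zero eigenvalue spectrum")
  if (!is.numeric(P) || P <= 0 || P > 1) abort("P must be in (0, 1]")
  as.integer(which(cumsum(ev) / tot >= P - 1e-12)[1])
}

#' Weighted univariate functional principal component analysis
#'
#' Discretised FPCA of one population's smoothed curves: weighted mean,
#' eigendecomposition of the weighted sample covariance on the age grid
#' (rectangle-rule quadrature with the grid spacing), truncation by
#' [select_ncomp()], and scores obtained by projecting the *unweighted*
#' centred curves onto the weighted eigenfunctions — so the score series
#' keep their time dynamics and can be extrapolated, while the
#' eigenfunctions and eigenvalues reflect the recency weighting.
#'
#' @param curves T x J matrix of smoothed log-rate curves (years in rows),
#'   or a `smooth_curves` object together with `population`.
#' @param scheme a [geometric_weights()] scheme (defaults to uniform).
#' @param P cumulative-variance threshold for truncation.
#' @param n_components override the truncation: an integer, or `"all"` to
#'   retain every numerically nonzero component.
#' @param ages age grid (for the quadrature spacing); taken from
#'   `smooth_curves` input when omitted.
#' @param population which population of a `smooth_curves` object to use.
#' @param literal_w passed to [weight_rows_for_eigen()].
#' @return An object of class `ufpca`: mean curve, orthonormal
#'   `eigenfunctions` (N x J), `eigenvalues` (full spectrum in `values`),
#'   `scores` (T x N), explained-variance fractions and the scheme used.
#' @export
ufpca <- function(curves, scheme = NULL, P = 0.9, n_components = NULL,
                  ages = NULL, population = NULL, literal_w = FALSE) {
  if (inherits(curves, "smooth_curves")) {
    population <- population %||% curves$populations[1]
    ages <- curves$ages
    curves <- curves$curves[[population]]
  }
  curves <- as.matrix(curves)
  Tn <- nrow(curves); J <- ncol(curves)
  if (Tn < 3L) abort("need at least 3 years of curves")
  ages <- ages %||% seq_len(J)
  dx <- grid_spacing(ages)
  scheme <- scheme %||% geometric_weights(Tn, 0)
  stopifnot(inherits(scheme, "weight_scheme"), scheme$n_years == Tn)

  mu <- weighted_mean_curve(curves, scheme)
  centred <- sweep(curves, 2L, mu)
  Xw <- weight_rows_for_eigen(centred, scheme, literal_w = literal_w)
  S <- crossprod(Xw) / weighted_cov_denom(scheme)   # J x J weighted covariance
  if (!all(is.finite(S))) abort("weighted covariance is not finite")
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  values <- pmax(eg$values, 0) * dx                 # operator eigenvalues
  vecs <- eg$vectors / sqrt(dx)                     # orthonormal under quadrature

  N <- resolve_ncomp(values, P, n_components)
  vecs <- fix_signs(vecs[, seq_len(N), drop = FALSE], dx)
  scores <- centred %*% vecs * dx                   # T x N quadrature projections

  structure(
    list(
      mean = mu, eigenfunctions = t(vecs), eigenvalues = values[seq_len(N)],
      values = values, scores = scores,
      explained = values / sum(values),
      N = N, P = P, ages = ages, dx = dx, scheme = scheme,
      population = population %||% "pop1"
    ),
    class = "ufpca"
  )
}

resolve_ncomp <- function(values, P, n_components) {
  # an (effectively) zero spectrum carries no structure: keep one
  # component of zeros rather than erroring, so degenerate inputs
  # (e.g. identical populations in the coherent decomposition) fit
  if (is.null(n_components) && sum(values) <= 1e-14 * length(values)) {
    return(1L)
  }
  if (is.null(n_components)) return(select_ncomp(values, P))
  if (identical(n_components, "all")) {
    return(max(1L, sum(values > max(values) * 1e-12)))
  }
  n <- as.integer(n_components)
  if (n < 1L || n > length(values)) abort("n_components out of range")
  n
}

# Deterministic eigenvector signs: positive quadrature integral, falling
# back to a positive largest-magnitude grid value for near-zero integrals.
fix_signs <- function(vecs, dx) {
  for (k in seq_len(ncol(vecs))) {
    s <- sum(vecs[, k]) * dx
    flip <- if (abs(s) > 1e-12) s < 0 else vecs[which.max(abs(vecs[, k])), k] < 0
    if (flip) vecs[, k] <- -vecs[, k]
  }
  vecs
}

grid_spacing <- function(ages) {
  if (length(ages) < 2L) return(1)
  d <- diff(ages)
  if (any(abs(d - d[1]) > 1e-8)) abort("age grid must be equally spaced")
  as.numeric(d[1])
}

#' @export
print.ufpca <- function(x, ...) {
  cat("<ufpca> ", nrow(x$scores), " years x ", length(x$mean), " ages; ",
      x$N, " component(s) explaining ",
      sprintf("%.1f%%", 100 * sum(x$explained[seq_len(x$N)])), "\n", sep = "")
  invisible(x)
}

#' Multivariate FPCA from per-population univariate fits
#'
#' Implements the score-matrix algorithm: the per-population score blocks
#' are concatenated into the T x (sum N_i) matrix Xi, its weighted sample
#' covariance Z is eigendecomposed, and the multivariate eigenfunctions and
#' shared scores are assembled from the eigenvectors:
#' `psi_n^(i) = sum_m c_n[m,(i)] phi_m^(i)` and
#' `rho_tn = sum_i sum_m c_n[m,(i)] beta_tm^(i)`.  With a single population
#' this reduces exactly to the univariate fit.
#'
#' @param fits list of [ufpca()] fits sharing the same years, quadrature and
#'   weight scheme.
#' @param P cumulative-variance threshold for the multivariate truncation.
#' @param n_components override, as in [ufpca()].
#' @return An object of class `mfpca`: per-population `eigenfunctions`
#'   (list of N x J matrices), shared `scores` (T x N), joint score
#'   covariance `Z`, its spectrum `values`, and the retained `N`.
#' @export
mfpca_from_ufpca <- function(fits, P = 0.9, n_components = NULL) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, TRUE, "ufpca")))
  Tn <- nrow(fits[[1]]$scores)
  for (f in fits) {
    if (nrow(f$scores) != Tn) abort("all populations must share the same years")
  }
  scheme <- fits[[1]]$scheme
  populations <- vapply(seq_along(fits), function(i) {
    fits[[i]]$population %||% paste0("pop", i)
  }, "")
  names(fits) <- populations

  blocks <- lapply(fits, `[[`, "scores")
  Xi <- do.call(cbind, blocks)                      # T x pN
  block_id <- rep(seq_along(fits), vapply(blocks, ncol, 1L))
  Xw <- Xi * sqrt(scheme$weights)
  Z <- crossprod(Xw) / weighted_cov_denom(scheme)
  eg <- eigen((Z + t(Z)) / 2, symmetric = TRUE)
  values <- pmax(eg$values, 0)
  N <- resolve_ncomp(values, P, n_components)
  C <- eg$vectors[, seq_len(N), drop = FALSE]       # pN x N

  # Deterministic signs via the implied multivariate eigenfunctions.
  eigenfunctions <- vector("list", length(fits))
  for (n in seq_len(N)) {
    psi_all <- unlist(lapply(seq_along(fits), function(i) {
      drop(crossprod(fits[[i]]$eigenfunctions, C[block_id == i, n]))
    }))
    s <- sum(psi_all) * fits[[1]]$dx
    flip <- if (abs(s) > 1e-12) s < 0 else psi_all[which.max(abs(psi_all))] < 0
    if (flip) C[, n] <- -C[, n]
  }
  for (i in seq_along(fits)) {
    eigenfunctions[[i]] <- t(crossprod(fits[[i]]$eigenfunctions,
                                       C[block_id == i, , drop = FALSE]))  # N x J
  }
  names(eigenfunctions) <- populations

  structure(
    list(
      populations = populations, fits = fits,
      Xi = Xi, Z = Z, values = values,
      eigenvalues = values[seq_len(N)],
      explained = values / sum(values),
      vectors = C, block_id = block_id,
      eigenfunctions = eigenfunctions,
      scores = Xi %*% C,                            # T x N shared scores
      N = N, P = P, ages = fits[[1]]$ages, dx = fits[[1]]$dx,
      scheme = scheme
    ),
    class = "mfpca"
  )
}

#' @export
print.mfpca <- function(x, ...) {
  cat("<mfpca> ", length(x$populations), " population(s); ", x$N,
      " joint component(s) explaining ",
      sprintf("%.1f%%", 100 * sum(x$explained[seq_len(x$N)])), "\n", sep = "")
  invisible(x)
}

#' Truncated Karhunen-Loeve reconstruction of the demeaned curves
#'
#' @param fit an [mfpca_from_ufpca()] or [ufpca()] fit.
#' @param n_components how many leading components to use (defaults to the
#'   retained number).
#' @param population which population to reconstruct (`mfpca` fits).
#' @return T x J matrix of fitted demeaned curves; add the population mean
#'   to recover fitted log rates.
#' @export
reconstruct <- function(fit, n_components = NULL, population = NULL) {
  if (inherits(fit, "ufpca")) {
    n <- n_components %||% fit$N
    if (n < 0L || n > fit$N) abort("n_components out of range")
    if (n == 0L) return(matrix(0, nrow(fit$scores), length(fit$mean)))
    return(fit$scores[, seq_len(n), drop = FALSE] %*%
             fit$eigenfunctions[seq_len(n), , drop = FALSE])
  }
  stopifnot(inherits(fit, "mfpca"))
  population <- population %||% fit$populations[1]
  n <- n_components %||% fit$N
  if (n < 0L || n > fit$N) abort("n_components out of range")
  if (n == 0L) {
    return(matrix(0, nrow(fit$scores), length(fit$fits[[population]]$mean)))
  }
  fit$scores[, seq_len(n), drop = FALSE] %*%
    fit$eigenfunctions[[population]][seq_len(n), , drop = FALSE]
}
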