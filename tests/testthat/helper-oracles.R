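# Shared fixtures and independent oracles used across the suite.

# Small synthetic dataset shared by several tests.
tiny_sim <- function(seed = 7, n_years = 50, ages = 0:20, ...) {
  generate_mortality(synthetic_spec(n_years = n_years, ages = ages,
                                    seed = seed, ...))
}

# Weighted correlation of score columns under a weight scheme (weighted
# covariance about the weighted means).
weighted_cor <- function(S, scheme) {
  w <- scheme$weights
  mu <- colSums(S * w)
  Sc <- sweep(S, 2L, mu)
  V <- crossprod(Sc * sqrt(w)) / weighted_cov_denom_oracle(w)
  stats::cov2cor(V)
}

weighted_cov_denom_oracle <- function(w) 1 - sum(w^2)

# Brute-force multivariate FPCA oracle: eigendecomposition of the stacked
# (pJ x pJ) weighted sample covariance of the concatenated centred curves.
# Returns operator eigenvalues and a projector for fitted curves.
stacked_mfpca_oracle <- function(curve_list, scheme, dx = 1) {
  w <- scheme$weights
  centred <- lapply(curve_list, function(M) {
    sweep(M, 2L, colSums(M * w))
  })
  X <- do.call(cbind, centred)                       # T x pJ
  S <- crossprod(X * sqrt(w)) / weighted_cov_denom_oracle(w)
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(
    values = pmax(eg$values, 0) * dx,
    vectors = eg$vectors,
    fitted = function(n) {
      V <- eg$vectors[, seq_len(n), drop = FALSE]
      X %*% V %*% t(V)                               # T x pJ projection
    },
    X = X
  )
}

# Independent textbook period life table, coded as an explicit loop so it
# shares nothing with the vectorised implementation under test.
lifetable_oracle_e0 <- function(m) {
  A <- length(m)
  q <- numeric(A)
  for (x in seq_len(A)) q[x] <- min(m[x] / (1 + 0.5 * m[x]), 1)
  q[A] <- 1
  l <- 1
  total <- 0
  for (x in seq_len(A)) {
    if (x < A) {
      d <- l * q[x]
      total <- total + (l - 0.5 * d)
      l <- l - d
    } else {
      total <- total + l / m[x]
    }
  }
  total
}

# Full e_x curve from the same loop-based oracle.
lifetable_oracle_ex <- function(m) {
  A <- length(m)
  vapply(seq_len(A), function(x) lifetable_oracle_e0(m[x:A]), 0)
}

# Write a toy HMD Mx_1x1 file; rates is a matrix years x ages.
write_toy_hmd <- function(path, years, ages, female, male = female,
                          total = female) {
  lines <- c(
    "Toyland, Death rates (period 1x1), synthetic fixture",
    "",
    "  Year          Age             Female            Male           Total"
  )
  for (i in seq_along(years)) {
    for (j in seq_along(ages)) {
      fmt <- function(v) {
        if (is.na(v[i, j])) "." else sprintf("%.5f", v[i, j])
      }
      lines <- c(lines, sprintf("  %d          %s            %s          %s          %s",
                                years[i], ages[j], fmt(female), fmt(male), fmt(total)))
    }
  }
  writeLines(lines, path)
  path
}

# Largest principal angle (degrees) between the column spans of A and B.
principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(pmin(pmax(s, -1), 1))) * 180 / pi
}
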