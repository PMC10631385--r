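test_that("component selection implements the cumulative-variance rule", {
  expect_identical(select_ncomp(c(0.8, 0.15, 0.05), P = 0.9), 2L)
  expect_identical(select_ncomp(c(0.9, 0.06, 0.04), P = 0.9), 1L)
  expect_identical(select_ncomp(1.0, P = 1), 1L)
  expect_identical(select_ncomp(c(5, 4, 1), P = 0.5), 1L)
  expect_error(select_ncomp(c(0, 0)), "zero")
  expect_error(select_ncomp(c(1, -2)), "non-negative")
})

test_that("ufpca recovers rank-1 structure exactly", {
  set.seed(2)
  v <- rnorm(15); v <- v / sqrt(sum(v^2))
  a <- rnorm(30, sd = 2)
  curves <- a %o% v
  f <- ufpca(curves, geometric_weights(30, 0), P = 0.9)
  expect_identical(f$N, 1L)
  expect_lt(f$values[2] / f$values[1], 1e-12)
  # eigenfunction matches v up to sign
  expect_equal(abs(sum(f$eigenfunctions[1, ] * v)), 1, tolerance = 1e-8)
  # scores reproduce the centred coefficients
  expect_equal(f$scores[, 1] %o% f$eigenfunctions[1, ],
               sweep(curves, 2, colMeans(curves)), tolerance = 1e-8)
})

test_that("eigenfunctions are orthonormal and scores uncorrelated, weighted or not", {
  sim <- tiny_sim(seed = 13)
  sc <- smooth_surface(sim$data)
  for (k in c(0, 0.1)) {
    ws <- geometric_weights(50, k)
    f <- ufpca(sc, ws, population = "pop1", n_components = "all")
    G <- f$eigenfunctions %*% t(f$eigenfunctions) * f$dx
    expect_equal(G, diag(nrow(G)), tolerance = 1e-8, ignore_attr = TRUE)
    r <- weighted_cor(f$scores[, 1:3], ws)
    expect_lt(max(abs(r[upper.tri(r)])), 1e-8)
    # eigenvalues non-increasing and non-negative
    expect_true(all(diff(f$values) <= 1e-12))
    expect_true(all(f$values >= -1e-10))
  }
})

test_that("ufpca recovers a known generating basis without noise", {
  sp <- synthetic_spec(n_years = 150, ages = 0:40, n_common = 2,
                       n_deviation = 1, seed = 3)
  # noiseless rank-2 curves with *exactly* uncorrelated scores, so the
  # individual eigenfunctions (not just their span) are identified
  set.seed(3)
  s1 <- as.vector(scale(cumsum(rnorm(150))))
  s2 <- as.vector(scale(residuals(lm(rnorm(150) ~ s1)))) * 0.5
  curves <- matrix(sp$mu, 150, 41, byrow = TRUE) +
    s1 %o% sp$common_basis[, 1] + s2 %o% sp$common_basis[, 2]
  f <- ufpca(curves, geometric_weights(150, 0), ages = 0:40,
             n_components = 2)
  expect_equal(sum(f$explained[1:2]), 1, tolerance = 1e-10)
  for (k in 1:2) {
    ip <- abs(sum(f$eigenfunctions[k, ] * sp$common_basis[, k]))
    expect_gt(ip, 0.999)
  }

  # on generator output (correlated random-walk scores) the common
  # *subspace* is still recovered
  sim <- generate_mortality(synthetic_spec(
    n_years = 150, ages = 0:40, n_common = 2, n_deviation = 1,
    ar_sd = 0, ar_coef = 0, noise_sd = 0, seed = 3))
  g <- ufpca(sim$truth$f$pop1, geometric_weights(150, 0), ages = 0:40,
             n_components = 2)
  ang <- principal_angle(t(g$eigenfunctions), sim$truth$common_basis)
  expect_lt(ang, 1)  # degrees
})

test_that("the joint score algorithm matches hand-computed small cases", {
  set.seed(5)
  v <- rnorm(12); v <- v / sqrt(sum(v^2))
  a <- as.vector(scale(rnorm(40), scale = FALSE)) * 3
  curves <- a %o% v
  ws <- geometric_weights(40, 0)
  f1 <- ufpca(curves, ws, n_components = 1)
  f2 <- ufpca(curves, ws, n_components = 1)
  f2$population <- "pop2"
  m <- mfpca_from_ufpca(list(f1, f2), n_components = "all")

  # identical populations: score covariance [[l,l],[l,l]] -> c1 = (1,1)/sqrt(2)
  expect_equal(abs(m$vectors[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-8)
  expect_equal(m$values[2] / m$values[1], 0, tolerance = 1e-10)
  # psi_1^(i) = phi_1 / sqrt(2) up to sign; rho = sqrt(2) beta
  expect_equal(abs(m$eigenfunctions[[1]][1, ]),
               abs(f1$eigenfunctions[1, ]) / sqrt(2), tolerance = 1e-8)
  expect_equal(abs(m$scores[, 1]), sqrt(2) * abs(f1$scores[, 1]),
               tolerance = 1e-8)

  # uncorrelated blocks with variances 2 and 1 -> nu = (2,1), c = e1, e2
  b1 <- sqrt(2) * as.vector(scale(rnorm(200), scale = FALSE))
  b2 <- as.vector(scale(rnorm(200), scale = FALSE))
  b2 <- as.vector(residuals(lm(b2 ~ b1)))
  b1 <- b1 / sd(b1) * sqrt(2); b2 <- b2 / sd(b2)
  w <- rnorm(12); w <- w - v * sum(w * v); w <- w / sqrt(sum(w^2))
  g1 <- ufpca(b1 %o% v, geometric_weights(200, 0), n_components = 1)
  g2 <- ufpca(b2 %o% w, geometric_weights(200, 0), n_components = 1)
  g2$population <- "pop2"
  mm <- mfpca_from_ufpca(list(g1, g2), n_components = "all")
  expect_equal(mm$values[1:2], c(2, 1), tolerance = 1e-6)
  expect_equal(abs(mm$vectors), diag(2), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("multivariate eigenfunctions are orthonormal with uncorrelated scores", {
  sim <- tiny_sim(seed = 17)
  sc <- smooth_surface(sim$data)
  for (k in c(0, 0.15)) {
    ws <- geometric_weights(50, k)
    fits <- lapply(c("pop1", "pop2"), function(p) {
      ufpca(sc, ws, population = p, n_components = "all")
    })
    m <- mfpca_from_ufpca(fits, n_components = 3L)
    G <- Reduce(`+`, lapply(m$eigenfunctions, function(E) E %*% t(E) * m$dx))
    expect_equal(G, diag(m$N), tolerance = 1e-8, ignore_attr = TRUE)
    r <- weighted_cor(m$scores, ws)
    expect_lt(max(abs(r[upper.tri(r)])), 1e-8)
  }
})

test_that("total variance is conserved between blocks and joint spectrum", {
  sim <- tiny_sim(seed = 23)
  sc <- smooth_surface(sim$data)
  ws <- geometric_weights(50, 0.1)
  fits <- lapply(c("pop1", "pop2"), function(p) {
    ufpca(sc, ws, population = p, n_components = "all")
  })
  m <- mfpca_from_ufpca(fits)
  expect_equal(sum(m$values), sum(diag(m$Z)), tolerance = 1e-8)
  # trace(Z) equals the summed weighted score variances of the blocks
  wvar <- function(s, w) {
    mu <- sum(s * w); sum(w * (s - mu)^2) / (1 - sum(w^2))
  }
  tr <- sum(vapply(fits, function(f) {
    sum(apply(f$scores, 2, wvar, w = ws$weights))
  }, 0))
  expect_equal(sum(diag(m$Z)), tr, tolerance = 1e-8)
})

test_that("the score-matrix algorithm equals the stacked-covariance oracle", {
  for (k in c(0, 0.2)) {
    sim <- tiny_sim(seed = 31, n_years = 60, ages = 0:20)
    sc <- smooth_surface(sim$data)
    ws <- geometric_weights(60, k)
    fits <- lapply(c("pop1", "pop2"), function(p) {
      ufpca(sc, ws, population = p, n_components = "all")
    })
    m <- mfpca_from_ufpca(fits, n_components = "all")
    oracle <- stacked_mfpca_oracle(sc$curves, ws, dx = 1)

    n_cmp <- min(m$N, 20)
    expect_equal(m$values[1:n_cmp], oracle$values[1:n_cmp],
                 tolerance = 1e-6)

    # fitted (demeaned) curves agree at several truncation levels
    for (n in c(1, 3, n_cmp)) {
      ours <- cbind(reconstruct(m, n, "pop1"), reconstruct(m, n, "pop2"))
      expect_lt(max(abs(ours - oracle$fitted(n))), 1e-6)
    }
  }
})

test_that("reconstruction error is zero at full rank and monotone in rank", {
  sim <- tiny_sim(seed = 37, n_years = 30, ages = 0:15)
  sc <- smooth_surface(sim$data)
  fits <- lapply(c("pop1", "pop2"), function(p) {
    ufpca(sc, population = p, n_components = "all")
  })
  m <- mfpca_from_ufpca(fits, n_components = "all")
  centred <- lapply(c("pop1", "pop2"), function(p) {
    sweep(sc$curves[[p]], 2L, fits[[match(p, c("pop1", "pop2"))]]$mean)
  })
  errs <- vapply(0:m$N, function(n) {
    d <- cbind(reconstruct(m, n, "pop1"), reconstruct(m, n, "pop2")) -
      do.call(cbind, centred)
    sqrt(mean(d^2))
  }, 0)
  expect_lt(errs[length(errs)], 1e-8)
  expect_true(all(diff(errs) <= 1e-10))
  expect_equal(reconstruct(m, 0, "pop1"), matrix(0, 30, 16))
  expect_error(reconstruct(m, m$N + 1, "pop1"), "range")
})

test_that("a single population reduces the joint fit to the univariate one", {
  sim <- tiny_sim(seed = 41)
  sc <- smooth_surface(sim$data)
  f <- ufpca(sc, population = "pop1", P = 0.9)
  m <- mfpca_from_ufpca(list(f))
  expect_equal(m$values[seq_len(f$N)], f$eigenvalues, tolerance = 1e-8)
  expect_equal(abs(m$eigenfunctions[[1]]),
               abs(f$eigenfunctions[seq_len(m$N), , drop = FALSE]),
               tolerance = 1e-8)
})
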