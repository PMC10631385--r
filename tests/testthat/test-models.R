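sim_small <- tiny_sim(seed = 19, n_years = 50, ages = 0:20)
curves_small <- smooth_surface(sim_small$data)

test_that("wMFPCA degenerates to the independent fit for one population", {
  one <- dplyr::filter(sim_small$data, population == "pop1")
  w1 <- fit_wmfpca(one, kappa = 0.1)
  i1 <- fit_independent(one, kappa = 0.1)
  fw <- forecast(w1, h = 5, max_order = c(2, 1, 2))
  fi <- forecast(i1, h = 5, max_order = c(2, 1, 2))
  expect_equal(fw$results$pop1$point, fi$results$pop1$point, tolerance = 1e-8)
  expect_equal(fw$results$pop1$variance, fi$results$pop1$variance,
               tolerance = 1e-8)
})

test_that("in-sample full-rank fits reproduce the smoothed curves", {
  w <- fit_wmfpca(curves_small, kappa = 0.1, n_components = "all",
                  n_joint = "all")
  for (p in c("pop1", "pop2")) {
    expect_lt(max(abs(fitted_surface(w, p) - curves_small$curves[[p]])), 1e-6)
  }
  ch <- fit_coherent(curves_small, kappa = 0.1, n_common = "all",
                     n_deviation = "all")
  for (p in c("pop1", "pop2")) {
    expect_lt(max(abs(fitted_surface(ch, p) - curves_small$curves[[p]])), 1e-6)
  }
})

test_that("the coherent decomposition identities hold", {
  ch <- fit_coherent(curves_small, kappa = 0.2)
  ws <- ch$scheme
  # population mean identity mu^(i) = mu + eta^(i) equals the weighted mean
  # of the population's smoothed curves
  for (p in c("pop1", "pop2")) {
    expect_equal(ch$means[[p]],
                 weighted_mean_curve(curves_small$curves[[p]], ws),
                 tolerance = 1e-8)
  }
  # common and deviation scores mutually uncorrelated on long samples
  simL <- tiny_sim(seed = 29, n_years = 220, ages = 0:20)
  chL <- fit_coherent(smooth_surface(simL$data), kappa = 0)
  r <- cor(cbind(chL$common$scores[, seq_len(chL$K)],
                 chL$deviation$scores))
  off <- r[seq_len(chL$K), chL$K + seq_len(chL$L)]
  expect_lt(max(abs(off)), 0.2)
})

test_that("identical populations collapse the deviation structure", {
  one <- dplyr::filter(sim_small$data, population == "pop1")
  two <- dplyr::mutate(one, population = "pop2")
  both <- dplyr::bind_rows(one, two)
  # full-rank common stage: the total function is fitted exactly, so the
  # deviations -- and their whole spectrum -- vanish
  ch_full <- fit_coherent(both, kappa = 0.1, n_common = "all")
  for (p in c("pop1", "pop2")) {
    expect_lt(max(abs(ch_full$eta[[p]])), 1e-8)
  }
  expect_lt(ch_full$deviation$values[1], 1e-12)

  ch <- fit_coherent(both, kappa = 0.1)
  for (p in c("pop1", "pop2")) {
    expect_lt(max(abs(ch$eta[[p]])), 1e-8)
  }
  fc <- forecast(ch, h = 8, max_order = c(2, 1, 2))
  expect_equal(fc$results$pop1$point, fc$results$pop2$point, tolerance = 1e-8)
})

test_that("recovery of the coherent ground truth from synthetic data", {
  sim <- generate_mortality(synthetic_spec(
    n_years = 200, ages = 0:100, noise_sd = 0.01, seed = 4))
  ch <- fit_coherent(smooth_surface(sim$data), kappa = 0, n_common = 2)
  for (i in 1:2) {
    p <- paste0("pop", i)
    expect_lt(max(abs(ch$eta[[p]] - sim$truth$eta[i, ])), 0.05)
  }
  ang <- principal_angle(t(ch$common$eigenfunctions[1:2, ]),
                         sim$truth$common_basis)
  expect_lt(ang, 5)
})

test_that("forecasts of constant surfaces are the constant curve", {
  ages <- 0:15
  Y <- matrix(rep(-4 + 0.01 * ages, 30), 30, 16, byrow = TRUE)
  data <- dplyr::bind_rows(new_surface(Y, 1971:2000, ages, "a"),
                           new_surface(Y, 1971:2000, ages, "b"))
  w <- fit_wmfpca(data, kappa = 0)
  fc <- forecast(w, h = 6)
  for (p in c("a", "b")) {
    expect_equal(fc$results[[p]]$point,
                 matrix(-4 + 0.01 * ages, 6, 16, byrow = TRUE),
                 tolerance = 1e-6)
    # no dynamics: interval width reduces to the tau and sigma terms
    width <- fc$results[[p]]$upper - fc$results[[p]]$lower
    expect_equal(width,
                 2 * fc$z * sqrt(fc$results[[p]]$addends$tau2 +
                                   fc$results[[p]]$addends$sigma2 +
                                   fc$results[[p]]$addends$component),
                 tolerance = 1e-10)
    expect_lt(max(fc$results[[p]]$addends$component), 1e-10)
  }
  expect_equal(fc$z, 1.959964, tolerance = 1e-6)
})

test_that("variance is the exact sum of its addends with valid intervals", {
  ch <- fit_coherent(curves_small, kappa = 0.1)
  fc <- forecast(ch, h = 10, max_order = c(2, 1, 2), alpha = 0.2)
  for (p in c("pop1", "pop2")) {
    r <- fc$results[[p]]
    expect_identical(r$variance,
                     r$addends$tau2 + r$addends$component + r$addends$sigma2)
    expect_true(all(r$lower <= r$point & r$point <= r$upper))
    expect_equal(r$upper - r$point, r$point - r$lower, tolerance = 1e-12)
    expect_true(all(r$variance >= 0))
  }
  expect_error(forecast(ch, h = 0), "positive")
  expect_error(forecast(ch, h = 5, alpha = 2), "alpha")
})

test_that("independently fitted populations share nothing", {
  i2 <- fit_independent(sim_small$data, kappa = 0)
  fc <- forecast(i2, h = 4, max_order = c(1, 1, 1))
  # permute pop2's years: pop1's forecast must be bit-identical
  perm <- sim_small$data
  p2 <- perm$population == "pop2"
  set.seed(1)
  yr <- perm$year[p2]
  new_order <- sample(sort(unique(yr)))
  perm$log_mx[p2] <- perm$log_mx[p2][order(match(yr, new_order))]
  i2p <- fit_independent(perm, kappa = 0)
  fcp <- forecast(i2p, h = 4, max_order = c(1, 1, 1))
  expect_identical(fc$results$pop1$point, fcp$results$pop1$point)
})

test_that("coherent forecasts converge to the mean gaps, wMFPCA's can diverge", {
  ch <- fit_coherent(curves_small, kappa = 0.1)
  fc <- forecast(ch, h = 400, max_order = c(1, 1, 1),
                 max_order_stationary = c(2, 1))
  gap_err <- vapply(seq_len(400), function(hh) {
    gap <- fc$results$pop1$point[hh, ] - fc$results$pop2$point[hh, ]
    max(abs(gap - (ch$eta$pop1 - ch$eta$pop2)))
  }, 0)
  expect_lt(gap_err[400], 1e-3)
  expect_true(all(diff(gap_err[50:400]) <= 1e-10))

  # negative control: populations with different drifts under wMFPCA
  set.seed(33)
  ages <- 0:15
  phi <- sin(pi * (ages / 15)); phi <- phi / sqrt(sum(phi^2))
  mk <- function(drift, label) {
    b <- cumsum(drift + rnorm(60, 0, 0.05))
    new_surface(matrix(-4, 60, 16, byrow = TRUE) + b %o% phi,
                1951:2010, ages, label)
  }
  div <- dplyr::bind_rows(mk(-0.3, "fast"), mk(0.05, "slow"))
  wd <- fit_wmfpca(div, kappa = 0)
  fcd <- forecast(wd, h = 150, max_order = c(1, 1, 1))
  gap <- vapply(c(10, 50, 150), function(hh) {
    max(abs(fcd$results$fast$point[hh, ] - fcd$results$slow$point[hh, ]))
  }, 0)
  expect_true(all(diff(gap) > 0))
  # linear (unbounded) growth: roughly constant positive slope per step
  slope1 <- (gap[2] - gap[1]) / 40
  slope2 <- (gap[3] - gap[2]) / 100
  expect_gt(slope1, 0.05)
  expect_gt(slope2, 0.05)
})
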