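test_that("the averaged RMSE takes per-population roots before averaging", {
  expect_equal(rmse_avg(c(3, 4), c(0, 0)), sqrt(12.5))
  expect_equal(rmse_avg(matrix(1:6, 2), matrix(1:6, 2)), 0)
  # per-population RMSEs 1 and 3 average to 2
  a <- rbind(rep(1, 4), rep(3, 4))
  expect_equal(rmse_avg(a, matrix(0, 2, 4)), 2)
  expect_error(rmse_avg(1:3, 1:4), "mismatch")
})

test_that("rolling windows collapse to the single-year formula and hit zero", {
  # constant surfaces: every model forecasts the constant -> rolling RMSE 0
  ages <- 0:12
  Y <- matrix(rep(-3 - 0.02 * ages, 40), 40, 13, byrow = TRUE)
  data <- dplyr::bind_rows(new_surface(Y, 1961:2000, ages, "a"),
                           new_surface(Y, 1961:2000, ages, "b"))
  ev <- rolling_rmse(data, "independent", h = 2, n_windows = 3, kappa = 0)
  expect_equal(ev$by_population$rmse, c(0, 0), tolerance = 1e-6)

  # n_windows = 1 equals the inner term of rmse_avg on the one test year
  sim <- tiny_sim(seed = 43, n_years = 40, ages = 0:12)
  ev1 <- rolling_rmse(sim$data, "wmfpca", h = 3, n_windows = 1, kappa = 0,
                      max_order = c(1, 1, 1))
  al <- wmfpca:::aligned_matrices(sim$data)
  cw <- smooth_surface(dplyr::filter(sim$data, year <= max(year) - 3))
  fit <- fit_wmfpca(cw, kappa = 0)
  fc <- forecast(fit, h = 3, max_order = c(1, 1, 1))
  manual <- vapply(c("pop1", "pop2"), function(p) {
    sqrt(mean((al$mats[[p]]$Y[40, ] - fc$results[[p]]$point[3, ])^2))
  }, 0)
  expect_equal(ev1$by_population$rmse, unname(manual), tolerance = 1e-8)

  expect_error(rolling_rmse(sim$data, "wmfpca", h = 30, n_windows = 10),
               "insufficient years")
})

test_that("rolling RMSE grows with the horizon on synthetic data", {
  worse <- 0
  for (s in 1:8) {
    sim <- tiny_sim(seed = 100 + s, n_years = 45, ages = 0:10)
    e_short <- rolling_rmse(sim$data, "coherent", h = 2, n_windows = 3,
                            kappa = 0, max_order = c(1, 1, 1),
                            max_order_stationary = c(1, 0))
    e_long <- rolling_rmse(sim$data, "coherent", h = 12, n_windows = 3,
                           kappa = 0, max_order = c(1, 1, 1),
                           max_order_stationary = c(1, 0))
    if (mean(e_long$by_population$rmse) >= mean(e_short$by_population$rmse)) {
      worse <- worse + 1
    }
  }
  expect_gte(worse, 6)
})

test_that("kappa tuning returns the profile and honours the grid", {
  sim <- tiny_sim(seed = 47, n_years = 40, ages = 0:10)
  single <- tune_kappa(sim$data, "wmfpca", h = 2, grid = 0, n_windows = 2,
                       max_order = c(1, 1, 1))
  expect_identical(single$kappa, 0)
  expect_identical(nrow(single$profile), 1L)

  multi <- tune_kappa(sim$data, "wmfpca", h = 2, grid = c(0, 0.1, 0.3),
                      n_windows = 2, max_order = c(1, 1, 1))
  expect_identical(nrow(multi$profile), 3L)
  expect_true(all(is.finite(multi$profile$rmse)))
  expect_equal(min(multi$profile$rmse),
               multi$profile$rmse[multi$profile$kappa == multi$kappa])
  expect_error(tune_kappa(sim$data, "wmfpca", h = 2, grid = numeric(0)),
               "non-empty")
})

test_that("life expectancy matches the loop-based life-table oracle", {
  # constant hazard: e_0 is within rounding of 1/m
  e0 <- life_expectancy(rep(log(0.01), 101))$ex[1]
  expect_equal(e0, lifetable_oracle_e0(rep(0.01, 101)), tolerance = 1e-12)
  expect_lt(abs(e0 - 100), 0.5)

  set.seed(55)
  for (r in 1:5) {
    m <- exp(rnorm(60, log(0.02), 1))
    ours <- life_expectancy(log(m))
    expect_equal(ours$ex, lifetable_oracle_ex(m), tolerance = 1e-9)
  }

  # huge infant mortality: e_0 -> 0.5 under the midpoint convention
  m_hi <- c(1e6, rep(0.01, 30))
  expect_lt(abs(life_expectancy(log(m_hi))$ex[1] - 0.5), 1e-3)

  # uniformly lower rates strictly increase e_0
  m0 <- exp(rnorm(50, log(0.03), 0.5))
  expect_gt(life_expectancy(log(m0 * 0.8))$ex[1],
            life_expectancy(log(m0))$ex[1])

  expect_error(life_expectancy(c(log(0.1), log(0))), "positive")
})

test_that("sex ratios are elementwise rate ratios", {
  a <- log(c(0.02, 0.01)); b <- log(c(0.01, 0.01))
  expect_equal(sex_ratio(a, b), c(2, 1))
  expect_equal(sex_ratio(a, a), c(1, 1))
  expect_equal(sex_ratio(a, b) * sex_ratio(b, a), c(1, 1))
  expect_equal(sex_ratio(b + log(2), b), c(2, 2))
  expect_error(sex_ratio(a, 1), "mismatch")
})
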