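ar_table <- function(n, alpha, sd0 = 0.5, sd_eta = 0.2, seed = 1,
                     years = c(2000, 2010), A = 0) {
  set.seed(seed)
  d0 <- rnorm(n, 0, sd0)
  d1 <- A + alpha * d0 + rnorm(n, 0, sd_eta)
  make_sami(rep(sprintf("%05d", 1:n), 2), "homicides",
            rep(years, each = n), c(d0, d1))
}

test_that("identity dynamics fit to alpha = 1, A = 0, rho = 1", {
  tab <- ar_table(50, alpha = 1, sd_eta = 0, seed = 2)
  f <- fit_memory(tab, "homicides", c(2000, 2010))
  expect_equal(f$slope, 1, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$rho, 1, tolerance = 1e-12)
})

test_that("the OLS slope equals the covariance ratio and rho is Pearson", {
  tab <- ar_table(200, alpha = 0.7, seed = 3)
  f <- fit_memory(tab, "homicides", c(2000, 2010))
  d0 <- f$data$d_t; d1 <- f$data$d_t1
  expect_equal(f$slope, cov(d0, d1) / var(d0), tolerance = 1e-12)
  expect_equal(f$rho, cor(d0, d1), tolerance = 1e-12)
  expect_lt(abs(f$slope - 0.7), 2 * f$se_slope + 0.05)
})

test_that("memory fit errors are specific", {
  tab <- ar_table(20, alpha = 0.7)
  expect_error(fit_memory(tab, "homicides", c(2000, 2020)), "not both present")
  const <- make_sami(rep(c("a", "b", "c"), 2), "homicides",
                     rep(c(2000, 2010), each = 3), c(1, 1, 1, 2, 1, 0))
  expect_error(fit_memory(const, "homicides", c(2000, 2010)), "zero variance")
})

test_that("the closed-form trajectory solves the ODE (RK4 oracle)", {
  skip_if_not_installed("deSolve")
  set.seed(6)
  cases <- rbind(
    data.frame(A = 0.2, alpha = 1, k = 1),     # exact linear branch
    data.frame(A = runif(5, -0.5, 0.5), alpha = runif(5, 0, 1.05),
               k = runif(5, -2, 2))
  )
  for (i in seq_len(nrow(cases))) {
    A <- cases$A[i]; alpha <- cases$alpha[i]; k <- cases$k[i]
    sol <- ode_solution(A, alpha, k)
    times <- seq(0, 50, by = 0.05)
    num <- deSolve::ode(y = c(D = k), times = times, parms = NULL,
                        func = function(t, y, p) list(A + (alpha - 1) * y),
                        method = "rk4")
    expect_lt(max(abs(sol$evaluate(times) - num[, "D"])), 1e-6)
  }
})

test_that("linear branch and asymptote match hand arithmetic", {
  sol <- ode_solution(A = 0.2, alpha = 1, k = 1)
  expect_equal(sol$evaluate(5), 2)
  expect_true(is.na(sol$asymptote))
  sol2 <- ode_solution(A = 0, alpha = 0.5, k = 3)
  expect_equal(sol2$asymptote, 0)
  expect_equal(sol2$evaluate(100), 0, tolerance = 1e-12)
  expect_equal(sol2$evaluate(2) / sol2$evaluate(0), exp(-1), tolerance = 1e-12)
  # alpha > 1: valid exponentially growing branch
  sol3 <- ode_solution(A = 0, alpha = 1.5, k = 1)
  expect_gt(sol3$evaluate(10), sol3$evaluate(1))
})

test_that("iterating the map with shrinking steps converges to the ODE", {
  A <- 0.1; alpha <- 0.6; k <- 1.5
  dt <- 1e-3
  d <- k
  for (i in seq_len(round(1 / dt))) d <- d + dt * (A + (alpha - 1) * d)
  sol <- ode_solution(A, alpha, k)
  expect_lt(abs(d - sol$evaluate(1)), 1e-3)
})

test_that("characteristic time is 1/(1-alpha), monotone, and tagged beyond 1", {
  expect_equal(characteristic_time(0.5), 2)
  expect_equal(characteristic_time(0), 1)
  expect_identical(characteristic_time(1), Inf)
  expect_true(is.nan(characteristic_time(1.05)))
  a <- seq(-3, 0.95, by = 0.05)
  expect_true(all(diff(characteristic_time(a)) > 0))
  # faster dynamics for homicides (alpha 0.41) than elderly (alpha 0.89)
  expect_lt(characteristic_time(0.41), characteristic_time(0.89))
})

test_that("alpha < 1 systems contract the residual spread; alpha > 1 expand", {
  contr <- generate_panel(tiny_config(n_cities = 800, seed = 17))
  sds <- tapply(contr$sami_truth$D[contr$sami_truth$indicator == "homicides"],
                contr$sami_truth$year[contr$sami_truth$indicator == "homicides"],
                sd)
  stationary <- sqrt(0.1^2 / (1 - 0.6^2))  # sigma_eta^2 / (1 - alpha^2)
  expect_gt(sds[1] - stationary, 0)
  expect_true(all(diff(sds) < 0))
  tr <- tiny_truth(sigma_D0 = c(0.1, 0.1), sigma_eta = c(0.05, 0.05),
                   alpha = c(1.3, 1.2))
  exp_cfg <- suppressWarnings(synthetic_config(n_cities = 800, truth = tr, seed = 18))
  expg <- generate_panel(exp_cfg)
  sds2 <- tapply(expg$sami_truth$D[expg$sami_truth$indicator == "homicides"],
                 expg$sami_truth$year[expg$sami_truth$indicator == "homicides"],
                 sd)
  expect_true(all(diff(sds2) > 0))
})

test_that("the CvM statistic equals a direct-sum implementation and frozen oracle", {
  x <- c(-1.76, -1.24, -0.95, -0.72, -0.53, -0.36, -0.21, -0.07, 0.07, 0.21,
         0.36, 0.53, 0.72, 0.95, 1.24, 1.76, -0.40, 0.88, -1.10, 0.15)
  ct <- cvm_test(x)
  expect_equal(ct$statistic, cvm_statistic_direct(x), tolerance = 1e-10)
  # frozen from an independent implementation (scipy.stats.cramervonmises)
  expect_equal(ct$statistic, 0.014315731536461221, tolerance = 1e-10)
  expect_equal(ct$p_value, 0.9998641355445378, tolerance = 1e-6)
  set.seed(10)
  y <- rnorm(50, 3, 2)
  ct2 <- cvm_test(y, mean = 3, sd = 2)
  expect_equal(ct2$statistic, cvm_statistic_direct(y, 3, 2), tolerance = 1e-10)
  ct3 <- cvm_test(y, method = "composite")
  expect_true(ct3$p_value > 0 && ct3$p_value <= 1)
})

test_that("residual diagnostics standardize, test and window correctly", {
  tab <- ar_table(500, alpha = 0.7, seed = 21)
  f <- fit_memory(tab, "homicides", c(2000, 2010))
  d <- residual_diagnostics(f)
  expect_lt(abs(mean(d$xi)), 1e-10)
  expect_lt(abs(sd(d$xi) - 1), 1e-10)
  expect_equal(nrow(d$window_sd), 5)
  expect_equal(sum(d$window_sd$n), f$n_used)   # windows partition the data
  expect_true(d$cvm_p > 0.001)  # Gaussian residuals should rarely reject
  # constant-variance data: window SDs agree within sampling error
  sds <- d$window_sd$sd_d_t1[d$window_sd$n >= 20]
  expect_lt(max(sds) / min(sds), 2.5)
})

test_that("sparse windows report missing SDs rather than failing", {
  tab <- make_sami(rep(letters[1:4], 2), "homicides",
                   rep(c(2000, 2010), each = 4),
                   c(0, 0.01, 0.02, 5, 0.1, 0.12, 0.09, 4))
  f <- fit_memory(tab, "homicides", c(2000, 2010))
  d <- residual_diagnostics(f)
  expect_true(any(is.na(d$window_sd$sd_d_t1)))
  expect_true(any(d$window_sd$n == 0))
})
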