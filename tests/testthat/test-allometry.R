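make_panel <- function(N, Y, year = 1991, indicator = "homicides") {
  df <- tibble::tibble(
    city_id = sprintf("%04d", seq_along(N)), city_name = "c", state = "ST",
    year = year, population = N
  )
  df[[indicator]] <- Y
  structure(df, indicators = indicator,
            class = c("census_panel", class(df)))
}

test_that("points exactly on a power law are fitted exactly", {
  N <- c(1e2, 1e3, 1e4, 1e5)
  Y <- 10^(2 + 1.5 * log10(N))
  panel <- make_panel(N, Y)
  f <- suppressWarnings(fit_allometry(panel, "homicides", 1991,
                                      n_boot = 200, seed = 1))
  expect_equal(f$intercept, 2, tolerance = 1e-10)
  expect_equal(f$exponent, 1.5, tolerance = 1e-10)
  expect_equal(f$rho, 1, tolerance = 1e-12)
  # zero scatter => zero bootstrap spread
  expect_lt(f$se_exponent, 1e-10)
  expect_warning(fit_allometry(panel, "homicides", 1991, n_boot = 50, seed = 1),
                 "fewer than 10")
})

test_that("closed-form slope matches the brute-force perpendicular oracle", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(5:20, 1)
    x <- runif(n, 2, 7)
    y <- runif(1, -2, 2) + runif(1, -3, 3) * x + rnorm(n, 0, 0.5)
    b_closed <- deming_line(x, y)$slope
    b_brute <- brute_force_odr_slope(x, y)
    expect_equal(b_closed, b_brute, tolerance = 1e-6)
  }
})

test_that("major-axis slope obeys the swap symmetry b -> 1/b", {
  set.seed(7)
  x <- rnorm(40, 5, 1); y <- 1 + 0.8 * x + rnorm(40, 0, 0.3)
  b <- deming_line(x, y)$slope
  b_swap <- deming_line(y, x)$slope
  expect_equal(b_swap, 1 / b, tolerance = 1e-10)
})

test_that("rho is plain Pearson correlation and positive S_xy gives b > 0", {
  set.seed(8)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    x <- rnorm(n, 4, 0.8)
    y <- rnorm(1) + abs(rnorm(1, 1, 0.5)) * x + rnorm(n, 0, 0.4)
    panel <- make_panel(10^x, 10^y)
    f <- fit_allometry(panel, "homicides", 1991, se_method = "analytic")
    expect_equal(f$rho, cor(x, y), tolerance = 1e-12)
    if (cov(x, y) > 0) expect_gt(f$exponent, 0)
  }
})

test_that("the infinite variance ratio reproduces ordinary least squares", {
  set.seed(9)
  x <- rnorm(60, 4, 1); y <- 2 + 1.2 * x + rnorm(60, 0, 0.5)
  d <- deming_line(x, y, variance_ratio = Inf)
  ols <- coef(lm(y ~ x))
  expect_equal(d$slope, unname(ols[2]), tolerance = 1e-12)
  expect_equal(d$intercept, unname(ols[1]), tolerance = 1e-12)
})

test_that("degenerate clouds hit the documented tie-break and errors", {
  x <- c(1, 2, 3, 4)
  expect_warning(deming_line(x, c(5, 5, 5, 5) + c(1, -1, 1, -1) * 0), "S_xy = 0")
  expect_error(deming_line(rep(2, 4), c(1, 2, 3, 4)), "zero variance in x")
  set.seed(1)
  y_uncor <- c(1, -1, -1, 1)  # cov(x, y) = 0 exactly
  expect_warning(b <- deming_line(x, y_uncor)$slope, "S_xy = 0")
  expect_true(is.finite(b))
})

test_that("nonpositive indicator values are dropped and counted", {
  N <- c(1e3, 1e4, 1e5, 1e6, 1e4)
  Y <- c(0, 10^(2 + 1.5 * c(4, 5, 6)), NA)
  panel <- make_panel(N, Y)
  f <- fit_allometry(panel, "homicides", 1991, se_method = "analytic")
  expect_equal(f$n_used, 3)
  expect_equal(f$n_dropped_nonpositive, 1)
  # offset handling keeps the zero row
  f2 <- fit_allometry(panel, "homicides", 1991, zero_handling = "offset",
                      se_method = "analytic")
  expect_equal(f2$n_used, 4)
})

test_that("per-capita bias classifies exponents around one", {
  expect_equal(per_capita_bias(1)$bias_exponent, 0)
  expect_equal(per_capita_bias(1)$class, "linear")
  b <- per_capita_bias(1.35)
  expect_equal(b$bias_exponent, 0.35)
  expect_equal(b$class, "superlinear")
  expect_equal(per_capita_bias(0.92)$class, "sublinear")
  expect_equal(per_capita_bias(1.004, tolerance = 0.01)$class, "linear")
})

test_that("per-capita values regress on population with slope beta - 1", {
  g <- generate_panel(tiny_config(n_cities = 1600, seed = 33))
  panel <- g$panel
  x <- log10(panel$population[panel$year == 1991])
  ypc <- log10(panel$homicides[panel$year == 1991]) - x
  m <- summary(lm(ypc ~ x))
  expect_lt(abs(unname(m$coefficients[2, 1]) - (1.35 - 1)),
            2 * m$coefficients[2, 2])
})

test_that("per-capita means and their bootstrap behave on edge cases", {
  panel <- make_panel(c(10, 20), c(2, 8), indicator = "homicides")
  set.seed(1)
  pc <- per_capita_group_means(panel, 1991, indicators = "homicides",
                               n_boot = 500)
  expect_equal(pc$mean_per_capita, 0.3)
  # constant per-capita value: CI degenerates to a point
  panel2 <- make_panel(c(10, 20, 40), c(2, 4, 8), indicator = "homicides")
  pc2 <- per_capita_group_means(panel2, 1991, indicators = "homicides",
                                n_boot = 500, seed = 2)
  expect_equal(pc2$ci_low, 0.2)
  expect_equal(pc2$ci_high, 0.2)
  expect_error(per_capita_group_means(panel, 1960), "absent")
})

test_that("bootstrap and analytic exponent SEs agree at scale", {
  g <- generate_panel(tiny_config(n_cities = 800, seed = 13))
  f <- fit_allometry(g$panel, "unemployment", 2000, variance_ratio = Inf,
                     n_boot = 400, seed = 99)
  se_an <- exponent_se(f, "analytic")
  expect_equal(unname(se_an["se_exponent"]), f$se_exponent, tolerance = 0.25)
  se_b2 <- exponent_se(f, "bootstrap", n_boot = 400, seed = 99)
  expect_equal(unname(se_b2["se_exponent"]), f$se_exponent, tolerance = 1e-12)
})
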