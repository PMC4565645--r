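# Shared fixtures and independent oracles, all built in code.

# Small synthetic configuration used where full study scale is not needed.
small_config <- function(n_cities = 300, seed = 1, ...) {
  suppressWarnings(synthetic_config(n_cities = n_cities, seed = seed, ...))
}

# A 2-indicator truth table with contracting dynamics (no spectral-radius
# warning) for quick, warning-free generation.
tiny_truth <- function(sigma_D0 = c(0.2, 0.3), sigma_eta = c(0.1, 0.15),
                       alpha = c(0.6, 0.8)) {
  tibble::tibble(
    indicator = c("homicides", "unemployment"),
    intercept = c(-5.4, -3.5),
    exponent = c(1.35, 1.45),
    sigma_D0 = sigma_D0, sigma_eta = sigma_eta, alpha = alpha
  )
}

tiny_config <- function(n_cities = 200, seed = 1, ...) {
  synthetic_config(n_cities = n_cities, truth = tiny_truth(), seed = seed, ...)
}

# Hand-rolled wide panel for io tests: 3 cities x 2 years, 2 indicators.
toy_panel_df <- function() {
  tibble::tibble(
    city_id = rep(c("0100", "0200", "0300"), 2),
    city_name = rep(c("Alfa", "Beta", "Gama"), 2),
    state = "SP",
    year = rep(c(1991, 2000), each = 3),
    population = c(1e4, 2e5, 5e4, 1.2e4, 2.3e5, 5.5e4),
    homicides = c(3, 210, 21, 4, 260, 24),
    unemployment = c(120, 9000, 800, 150, 11000, 900)
  )
}

write_toy_panel <- function(df = toy_panel_df()) {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(df, path)
  path
}

# Independent orthogonal-distance oracle: for a fixed slope the optimal
# intercept passes through the centroid, so minimize the summed squared
# perpendicular distance over the line angle by dense grid + local
# refinement. Never uses the closed form.
brute_force_odr_slope <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  perp_ss <- function(theta) {
    b <- tan(theta)
    sum((y - yb - b * (x - xb))^2) / (1 + b^2)
  }
  thetas <- seq(-pi / 2 + 1e-4, pi / 2 - 1e-4, length.out = 20001)
  vals <- vapply(thetas, perp_ss, 0)
  i <- which.min(vals)
  lo <- thetas[max(i - 1, 1)]; hi <- thetas[min(i + 1, length(thetas))]
  opt <- stats::optimize(perp_ss, c(lo, hi), tol = 1e-14)
  tan(opt$minimum)
}

# Direct-sum Cramer-von Mises statistic, independent of goftest.
cvm_statistic_direct <- function(x, mean = 0, sd = 1) {
  n <- length(x)
  Fi <- stats::pnorm(sort(x), mean, sd)
  1 / (12 * n) + sum(((2 * seq_len(n) - 1) / (2 * n) - Fi)^2)
}

# Long SAMI table from explicit vectors.
make_sami <- function(city_id, indicator, year, D) {
  tibble::tibble(city_id = as.character(city_id), indicator = indicator,
                 year = as.integer(year), D = D)
}
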