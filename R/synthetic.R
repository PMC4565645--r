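# Synthetic multi-census city systems with known ground truth.
#
# The forward model composes the two stochastic layers of the analysis:
#   log10 Y_i(t) = A_i + beta_i * log10 N(t) + D_i(t)        (allometry)
#   D_i(t+1)     = C0_i + sum_k C[i,k] D_k(t) + eta_i(t)     (lagged map)
# with D_i at the first census drawn Normal(0, sigma_D0_i). Populations are
# log-normal across cities and drift multiplicatively between censuses.
# Every parameter is recorded so downstream stages have exact recovery
# targets.

#' Reference indicator parameters
#'
#' Study-scale parameters for the eight urban indicators of the Brazilian
#' municipal census panel: allometric intercept and exponent with the
#' log-log Pearson correlation (1991 values), and the one-lag memory slope
#' `alpha` (mean of the two published inter-census fits) with its Pearson
#' correlation. These drive the default synthetic configuration; the noise
#' scales `sigma_D0` and `sigma_eta` are derived from the correlations (see
#' [synthetic_config()]).
#'
#' @return tibble with columns `indicator`, `intercept`, `exponent`,
#'   `rho_allometry`, `alpha`, `rho_memory`.
#' @export
default_indicator_truth <- function() {
  tibble(
    indicator = c("child_labor", "elderly_population", "family_income",
                  "female_population", "homicides", "illiteracy",
                  "male_population", "unemployment"),
    intercept = c(-0.64, -0.99, 0.82, -0.367, -5.4, -0.29, -0.239, -3.50),
    exponent  = c(0.96, 0.992, 0.33, 1.014, 1.35, 0.92, 0.987, 1.45),
    rho_allometry = c(0.909, 0.976, 0.428, 1.000, 0.769, 0.789, 1.000, 0.880),
    alpha     = c(0.635, 0.865, 0.845, 0.78, 0.505, 1.03, 0.805, 0.51),
    rho_memory = c(0.53, 0.92, 0.91, 0.83, 0.59, 0.98, 0.84, 0.53)
  )
}

#' Build a synthetic-system configuration
#'
#' Collects and validates every parameter of the generator. Noise scales left
#' `NULL` are derived from the truth table's correlations: the initial
#' residual spread from the allometric correlation,
#' \eqn{\sigma_{D0} = \beta \, s_x \sqrt{1/\rho^2 - 1}} with \eqn{s_x} the
#' log-population spread (\eqn{\rho} capped at 0.9995 since the population
#' indicators round to 1.000), and the dynamics noise from the memory
#' correlation, \eqn{\sigma_\eta = |\alpha| \, \sigma_{D0}
#' \sqrt{1/\rho_m^2 - 1}}.
#'
#' @param n_cities number of cities.
#' @param census_years strictly increasing integer census years (>= 2).
#' @param log10_pop_mean,log10_pop_sd log-normal population parameters
#'   (base-10 logs).
#' @param pop_growth_factor multiplicative population drift per census step.
#' @param truth per-indicator parameter tibble, see
#'   [default_indicator_truth()] for the required columns (`sigma_D0` /
#'   `sigma_eta` columns, if present, override the derived values).
#' @param C0 intercept vector of the lagged map (recycled; default 0 —
#'   published intercepts are ~1e-6).
#' @param C coefficient matrix of the lagged map (rows = target indicator,
#'   columns = predictor); default `diag(truth$alpha)`.
#' @param init_correlation equicorrelation of the initial residuals across
#'   indicators (default 0: independent initialisation).
#' @param seed integer seed; the same seed reproduces the panel exactly.
#' @return object of class `synthetic_config` (a list). Its
#'   `spectral_radius` element reports the modulus of the dominant eigenvalue
#'   of `C`; a warning is raised when it is >= 1 (non-contracting dynamics).
#' @export
synthetic_config <- function(n_cities = 1600,
                             census_years = c(1991, 2000, 2010),
                             log10_pop_mean = 4.3, log10_pop_sd = 0.7,
                             pop_growth_factor = 1.15,
                             truth = default_indicator_truth(),
                             C0 = 0, C = NULL,
                             init_correlation = 0,
                             seed = 1L) {
  stopifnot(n_cities >= 3, length(census_years) >= 2,
            all(diff(census_years) > 0), log10_pop_sd >= 0,
            pop_growth_factor > 0,
            init_correlation >= 0, init_correlation <= 1)
  need <- c("indicator", "intercept", "exponent")
  stopifnot(all(need %in% names(truth)))
  truth <- truth[order(truth$indicator), , drop = FALSE]
  p <- nrow(truth)
  if (!"sigma_D0" %in% names(truth)) {
    stopifnot("rho_allometry" %in% names(truth))
    rho <- pmin(truth$rho_allometry, 0.9995)
    truth$sigma_D0 <- abs(truth$exponent) * log10_pop_sd * sqrt(1 / rho^2 - 1)
  }
  if (!"sigma_eta" %in% names(truth)) {
    stopifnot(all(c("alpha", "rho_memory") %in% names(truth)))
    rho_m <- pmin(truth$rho_memory, 0.9995)
    truth$sigma_eta <- abs(truth$alpha) * truth$sigma_D0 * sqrt(1 / rho_m^2 - 1)
  }
  stopifnot(all(truth$sigma_D0 >= 0), all(truth$sigma_eta >= 0))
  if (is.null(C)) {
    stopifnot("alpha" %in% names(truth))
    C <- diag(truth$alpha, p)
  }
  C <- as.matrix(C)
  stopifnot(nrow(C) == p, ncol(C) == p)
  dimnames(C) <- list(truth$indicator, truth$indicator)
  C0 <- rep_len(C0, p)
  radius <- max(Mod(eigen(C, only.values = TRUE)$values))
  if (radius >= 1) {
    warning("spectral radius of the coefficient matrix is ", signif(radius, 4),
            " (>= 1): residual dynamics are not contracting")
  }
  structure(list(
    n_cities = as.integer(n_cities),
    census_years = as.integer(census_years),
    log10_pop_mean = log10_pop_mean, log10_pop_sd = log10_pop_sd,
    pop_growth_factor = pop_growth_factor,
    truth = truth, C0 = C0, C = C,
    init_correlation = init_correlation,
    spectral_radius = radius,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic city-system config: %d cities x %d censuses (%s)\n  %d indicators; spectral radius of C = %.3f; seed = %d\n",
    x$n_cities, length(x$census_years),
    paste(x$census_years, collapse = ", "),
    nrow(x$truth), x$spectral_radius, x$seed
  ))
  invisible(x)
}

#' Generate a synthetic census panel with known ground truth
#'
#' Draws city populations log-normal (with per-census multiplicative drift),
#' initialises the scale-adjusted residuals \eqn{D_i} at the first census,
#' evolves them with the configured lagged linear map plus Gaussian noise, and
#' assembles indicator values as \eqn{Y_i = 10^{A_i + \beta_i \log_{10} N +
#' D_i}}. Populations are rounded to whole inhabitants; indicator values are
#' left continuous so that the stored ground-truth residuals reproduce
#' exactly from the written panel.
#'
#' @param config a [synthetic_config()].
#' @return list with `panel` (a `census_panel`), `sami_truth` (long tibble of
#'   the true `D` values) and `config`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_cities
  yrs <- config$census_years
  truth <- config$truth
  p <- nrow(truth)
  ids <- sprintf("%07d", seq_len(n))

  x0 <- rnorm(n, config$log10_pop_mean, config$log10_pop_sd)

  # initial residuals: optional equicorrelation via a shared factor
  r <- config$init_correlation
  z <- matrix(rnorm(n * p), n, p)
  if (r > 0) {
    common <- rnorm(n)
    z <- sqrt(r) * matrix(common, n, p) + sqrt(1 - r) * z
  }
  D <- sweep(z, 2, truth$sigma_D0, `*`)

  panel_rows <- vector("list", length(yrs))
  truth_rows <- vector("list", length(yrs))
  for (ti in seq_along(yrs)) {
    if (ti > 1) {
      eta <- sweep(matrix(rnorm(n * p), n, p), 2, truth$sigma_eta, `*`)
      D <- sweep(D %*% t(config$C), 2, config$C0, `+`) + eta
    }
    pop <- pmax(1, round(10^(x0 + (ti - 1) * log10(config$pop_growth_factor))))
    logY <- sweep(outer(log10(pop), truth$exponent), 2, truth$intercept, `+`) + D
    if (any(!is.finite(10^logY))) {
      stop("config error: indicator values overflow double precision; ",
           "reduce |intercept|, |exponent| or the noise scales", call. = FALSE)
    }
    Y <- 10^logY
    colnames(Y) <- truth$indicator
    panel_rows[[ti]] <- tibble(
      city_id = ids, city_name = paste0("city_", ids), state = "SY",
      year = yrs[ti], population = pop
    ) |> dplyr::bind_cols(as_tibble(Y))
    truth_rows[[ti]] <- tibble(
      city_id = rep(ids, p),
      indicator = rep(truth$indicator, each = n),
      year = yrs[ti],
      D = as.vector(D)
    )
  }
  panel <- .as_census_panel(dplyr::bind_rows(panel_rows), truth$indicator)
  list(panel = panel,
       sami_truth = dplyr::arrange(dplyr::bind_rows(truth_rows),
                                   .data$indicator, .data$year, .data$city_id),
       config = config)
}

#' Ground truth of a synthetic configuration
#'
#' Echoes the exact generative parameters in the shapes downstream recovery
#' assertions need: the per-indicator allometric parameters expanded per
#' census year (usable directly as the `fits` argument of [compute_sami()]),
#' the lagged-map intercepts and coefficient matrix, and the noise scales.
#'
#' @param config a [synthetic_config()].
#' @return list with `allometry` (tibble `indicator`, `year`, `intercept`,
#'   `exponent`), `C0`, `C`, `sigma_D0`, `sigma_eta`, `census_years`, `seed`.
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  truth <- config$truth
  allo <- tidyr::crossing(
    tibble(indicator = truth$indicator, intercept = truth$intercept,
           exponent = truth$exponent),
    year = config$census_years
  )
  list(
    allometry = dplyr::select(allo, "indicator", "year", "intercept", "exponent"),
    C0 = setNames(config$C0, truth$indicator),
    C = config$C,
    sigma_D0 = setNames(truth$sigma_D0, truth$indicator),
    sigma_eta = setNames(truth$sigma_eta, truth$indicator),
    census_years = config$census_years,
    seed = config$seed
  )
}
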