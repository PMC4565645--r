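# Allometric scaling fits in log-log space.
#
# The model is Y_i = 10^A_i * N^beta_i, fitted as a straight line between
# x = log10 N and y = log10 Y_i. Because both coordinates of a city are
# measured quantities, the default estimator minimizes *perpendicular*
# distances (major-axis / orthogonal-distance regression, the equal-variance
# special case of Deming regression). The error-variance ratio
# delta = var(vertical error) / var(horizontal error) is exposed:
# delta = 1 is the major axis, delta = Inf is ordinary least squares of y on x
# (all scatter vertical), the consistent choice when the data are known to
# deviate from the law only in the indicator.

#' Deming / major-axis line through a point cloud
#'
#' Closed-form slope of the line minimizing the weighted sum of squared
#' orthogonal offsets, with the intercept constrained through the centroid.
#' The slope solves
#' \deqn{b = \frac{S_{yy} - \delta S_{xx} +
#'   \sqrt{(S_{yy} - \delta S_{xx})^2 + 4 \delta S_{xy}^2}}{2 S_{xy}}}
#' where \eqn{S_{xx}, S_{yy}, S_{xy}} are sample (co)variances and
#' \eqn{\delta} the error-variance ratio. \code{variance_ratio = 1} gives the
#' major axis; \code{variance_ratio = Inf} reduces to ordinary least squares.
#'
#' @param x,y numeric vectors of equal length (>= 3, not all equal in x).
#' @param variance_ratio ratio of vertical to horizontal error variance
#'   (\eqn{\delta \ge 0}, may be \code{Inf}).
#' @return list with `slope` and `intercept`.
#' @export
deming_line <- function(x, y, variance_ratio = 1) {
  stopifnot(length(x) == length(y), length(x) >= 3, variance_ratio >= 0)
  sxx <- var(x); syy <- var(y); sxy <- cov(x, y)
  if (sxx <= 0) stop("degenerate fit: zero variance in x (all points vertically collinear)")
  if (is.infinite(variance_ratio)) {
    b <- sxy / sxx
  } else if (sxy == 0) {
    # principal axis of an uncorrelated cloud: direction set by which
    # variance dominates; sign convention follows sign(S_yy - delta*S_xx)
    warning("S_xy = 0: degenerate orientation, slope sign taken from sign(S_yy - delta*S_xx)")
    b <- sign(syy - variance_ratio * sxx) * sqrt(syy / sxx)
  } else {
    d <- syy - variance_ratio * sxx
    b <- (d + sqrt(d^2 + 4 * variance_ratio * sxy^2)) / (2 * sxy)
  }
  list(slope = b, intercept = mean(y) - b * mean(x))
}

.allometry_xy <- function(panel, indicator, year, zero_handling = "drop", offset = 1) {
  if (!indicator %in% names(panel)) {
    stop("indicator '", indicator, "' not found in panel", call. = FALSE)
  }
  rows <- panel[panel$year == year, , drop = FALSE]
  if (nrow(rows) == 0) stop("year ", year, " absent from panel", call. = FALSE)
  yv <- rows[[indicator]]
  nv <- rows$population
  keep <- is.finite(yv) & is.finite(nv) & nv > 0
  if (zero_handling == "offset") {
    yv <- yv + offset
  }
  pos <- keep & yv > 0
  list(
    x = log10(nv[pos]), y = log10(yv[pos]),
    city_id = rows$city_id[pos],
    n_dropped_nonpositive = sum(keep) - sum(pos),
    n_missing = sum(!keep)
  )
}

.analytic_line_se <- function(x, y, slope) {
  # large-n approximation; exact for the OLS (variance_ratio = Inf) limit
  n <- length(x)
  rho <- cor(x, y)
  se_b <- abs(slope) * sqrt(max(1 / rho^2 - 1, 0) / (n - 2))
  resid <- y - (mean(y) - slope * mean(x)) - slope * x
  s2 <- sum(resid^2) / (n - 2)
  se_a <- sqrt(s2 / n + mean(x)^2 * se_b^2)
  c(se_intercept = se_a, se_exponent = se_b)
}

.bootstrap_line_se <- function(x, y, variance_ratio, n_boot, seed) {
  n <- length(x)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  est <- matrix(NA_real_, n_boot, 2)
  for (b in seq_len(n_boot)) {
    i <- sample.int(n, n, replace = TRUE)
    # a degenerate resample (e.g. one city drawn n times) contributes nothing
    fit <- tryCatch(suppressWarnings(deming_line(x[i], y[i], variance_ratio)),
                    error = function(e) NULL)
    if (!is.null(fit)) est[b, ] <- c(fit$intercept, fit$slope)
  }
  c(se_intercept = sd(est[, 1], na.rm = TRUE),
    se_exponent = sd(est[, 2], na.rm = TRUE))
}

#' Fit the allometric law for one indicator and census year
#'
#' Fits \eqn{\log_{10} Y_i = A_i + \beta_i \log_{10} N} by orthogonal-distance
#' (major-axis) regression, the estimator appropriate when both axes carry
#' comparable error. Cities with nonpositive indicator values (e.g. zero
#' homicides) or nonpositive population are excluded and counted; an optional
#' additive offset can retain them instead.
#'
#' @param panel a census panel (see [read_census_panel()] / [generate_panel()]).
#' @param indicator name of the indicator column.
#' @param year census year to fit.
#' @param variance_ratio Deming error-variance ratio; 1 (default) is the major
#'   axis, `Inf` is ordinary least squares (all scatter treated as vertical).
#' @param zero_handling `"drop"` (default) excludes nonpositive indicator
#'   values; `"offset"` adds `offset` to the indicator before taking logs.
#' @param offset additive offset used when `zero_handling = "offset"`.
#' @param se_method `"bootstrap"` (seeded nonparametric city resampling,
#'   default) or `"analytic"` (large-n approximation).
#' @param n_boot bootstrap resamples for the standard errors.
#' @param seed integer seed for the bootstrap.
#' @return An object of class `allometric_fit`: a list with `indicator`,
#'   `year`, `intercept` (\eqn{A_i}), `exponent` (\eqn{\beta_i}),
#'   `se_intercept`, `se_exponent`, `rho` (Pearson correlation of the log
#'   pairs), `n_used`, `n_dropped_nonpositive`, `se_method`,
#'   `variance_ratio` and the log-log `data` used.
#' @seealso [deming_line()], [per_capita_bias()], [compute_sami()]
#' @export
fit_allometry <- function(panel, indicator, year,
                          variance_ratio = 1,
                          zero_handling = c("drop", "offset"), offset = 1,
                          se_method = c("bootstrap", "analytic"),
                          n_boot = 1000, seed = NULL) {
  zero_handling <- match.arg(zero_handling)
  se_method <- match.arg(se_method)
  xy <- .allometry_xy(panel, indicator, year, zero_handling, offset)
  if (length(xy$x) < 3) {
    stop("fewer than 3 usable cities for ", indicator, " in ", year, call. = FALSE)
  }
  line <- deming_line(xy$x, xy$y, variance_ratio)
  if (length(xy$x) < 10 && se_method == "bootstrap") {
    warning("bootstrap standard errors on fewer than 10 cities are unreliable")
  }
  se <- switch(se_method,
    analytic = .analytic_line_se(xy$x, xy$y, line$slope),
    bootstrap = .bootstrap_line_se(xy$x, xy$y, variance_ratio, n_boot, seed)
  )
  structure(list(
    indicator = indicator, year = year,
    intercept = line$intercept, exponent = line$slope,
    se_intercept = unname(se["se_intercept"]),
    se_exponent = unname(se["se_exponent"]),
    rho = cor(xy$x, xy$y),
    n_used = length(xy$x),
    n_dropped_nonpositive = xy$n_dropped_nonpositive,
    se_method = se_method, variance_ratio = variance_ratio,
    data = tibble(city_id = xy$city_id, log10_population = xy$x, log10_value = xy$y)
  ), class = "allometric_fit")
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat(sprintf(
    "Allometric fit: %s (%d)\n  A = %.4f (SE %.4f)   beta = %.4f (SE %.4f)\n  rho = %.3f   n = %d (dropped nonpositive: %d)\n",
    x$indicator, x$year, x$intercept, x$se_intercept, x$exponent,
    x$se_exponent, x$rho, x$n_used, x$n_dropped_nonpositive
  ))
  invisible(x)
}

#' Recompute standard errors for an allometric fit
#'
#' Returns bootstrap (default) or large-n analytic standard errors for the
#' intercept and exponent of an existing fit, without refitting the line.
#'
#' @param fit an `allometric_fit`.
#' @param method `"bootstrap"` or `"analytic"`.
#' @inheritParams fit_allometry
#' @return named numeric vector `c(se_intercept, se_exponent)`.
#' @export
exponent_se <- function(fit, method = c("bootstrap", "analytic"),
                        n_boot = 1000, seed = NULL) {
  stopifnot(inherits(fit, "allometric_fit"))
  method <- match.arg(method)
  x <- fit$data$log10_population
  y <- fit$data$log10_value
  if (method == "bootstrap" && length(x) < 10) {
    warning("bootstrap standard errors on fewer than 10 cities are unreliable")
  }
  switch(method,
    analytic = .analytic_line_se(x, y, fit$exponent),
    bootstrap = .bootstrap_line_se(x, y, fit$variance_ratio, n_boot, seed)
  )
}

#' Fit all indicator-year allometries of a panel
#'
#' Convenience wrapper running [fit_allometry()] for every combination of the
#' given indicators and census years, returning a tidy table analogous to a
#' published parameter table (one row per indicator-year).
#'
#' @inheritParams fit_allometry
#' @param indicators indicator columns to fit; defaults to every configured
#'   indicator present in the panel.
#' @param years census years to fit; defaults to all years in the panel.
#' @return tibble with columns `indicator`, `year`, `intercept`, `exponent`,
#'   `se_intercept`, `se_exponent`, `rho`, `n_used`, `n_dropped_nonpositive`,
#'   plus a `fits` list-column of the underlying `allometric_fit` objects.
#' @export
fit_allometry_panel <- function(panel, indicators = NULL, years = NULL,
                                variance_ratio = 1,
                                zero_handling = c("drop", "offset"), offset = 1,
                                se_method = c("bootstrap", "analytic"),
                                n_boot = 1000, seed = NULL) {
  zero_handling <- match.arg(zero_handling)
  se_method <- match.arg(se_method)
  if (is.null(indicators)) indicators <- intersect(panel_indicators(panel), names(panel))
  if (is.null(years)) years <- sort(unique(panel$year))
  grid <- expand.grid(indicator = indicators, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    fits[[i]] <- fit_allometry(
      panel, grid$indicator[i], grid$year[i],
      variance_ratio = variance_ratio, zero_handling = zero_handling,
      offset = offset, se_method = se_method, n_boot = n_boot,
      seed = if (is.null(seed)) NULL else seed + i
    )
  }
  out <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble(
      indicator = f$indicator, year = f$year,
      intercept = f$intercept, exponent = f$exponent,
      se_intercept = f$se_intercept, se_exponent = f$se_exponent,
      rho = f$rho, n_used = f$n_used,
      n_dropped_nonpositive = f$n_dropped_nonpositive
    )
  }))
  out$fits <- fits
  out
}

#' Per-capita bias exponent of an allometric fit
#'
#' With \eqn{Y \sim N^{\beta}}, the per-capita value \eqn{Y/N \sim
#' N^{\beta - 1}} retains a population dependence whenever \eqn{\beta \neq 1}:
#' per-capita comparisons are biased towards large cities for superlinear
#' indicators (\eqn{\beta > 1}) and towards small cities for sublinear ones
#' (\eqn{\beta < 1}).
#'
#' @param fit an `allometric_fit`, or a bare numeric exponent.
#' @param tolerance half-width of the band around 1 classified as `"linear"`;
#'   the default 0 classifies only an exact \eqn{\beta = 1} as linear. A
#'   common practical choice is `2 * fit$se_exponent`.
#' @return list with `bias_exponent` (\eqn{\beta - 1}) and `class` (one of
#'   `"superlinear"`, `"sublinear"`, `"linear"`).
#' @export
per_capita_bias <- function(fit, tolerance = 0) {
  beta <- if (inherits(fit, "allometric_fit")) fit$exponent else as.numeric(fit)
  stopifnot(tolerance >= 0)
  cls <- if (abs(beta - 1) <= tolerance) "linear" else if (beta > 1) "superlinear" else "sublinear"
  list(bias_exponent = beta - 1, class = cls)
}

#' Mean per-capita indicator values with bootstrap confidence intervals
#'
#' The conventional summary the scale-adjusted analysis is contrasted with:
#' for each indicator, the unweighted mean over cities of \eqn{Y_i/N} in one
#' census year, with a seeded percentile-bootstrap 95\% confidence interval.
#'
#' @inheritParams fit_allometry
#' @param indicators indicators to summarize (default: all in the panel).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return tibble with `indicator`, `year`, `mean_per_capita`, `ci_low`,
#'   `ci_high`, `n_cities`.
#' @export
per_capita_group_means <- function(panel, year, indicators = NULL,
                                   n_boot = 10000, seed = NULL, conf = 0.95) {
  if (!year %in% panel$year) stop("year ", year, " absent from panel", call. = FALSE)
  if (is.null(indicators)) indicators <- intersect(panel_indicators(panel), names(panel))
  rows <- panel[panel$year == year, , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(indicators, function(ind) {
    pc <- rows[[ind]] / rows$population
    pc <- pc[is.finite(pc)]
    ci <- bootstrap_mean_ci(pc, n_boot = n_boot, conf = conf)
    tibble(indicator = ind, year = year, mean_per_capita = mean(pc),
           ci_low = ci[1], ci_high = ci[2], n_cities = length(pc))
  })
  dplyr::bind_rows(res)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param x numeric vector.
#' @param n_boot number of resamples.
#' @param conf confidence level.
#' @return numeric vector `c(low, high)`. Zero-width for constant `x`.
#' @export
bootstrap_mean_ci <- function(x, n_boot = 10000, conf = 0.95) {
  n <- length(x)
  stopifnot(n >= 1)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  means <- rowMeans(matrix(x[idx], nrow = n_boot, ncol = n))
  alpha <- (1 - conf) / 2
  unname(quantile(means, c(alpha, 1 - alpha), names = FALSE, type = 7))
}
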