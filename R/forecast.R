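# Cross-indicator linear forecasting: each indicator's scale-adjusted metric
# at the next census is modelled as a linear combination of all eight metrics
# at the current one,
#   D_i(t + dt) = C_0 + sum_k C_k D_k(t) + eta_i(t),
# fitted by OLS per census interval. Coefficients are assumed constant over
# time for forecasting; the interval-specific fits are averaged.

#' Reshape a metric table to one row per city, one column per indicator
#'
#' @param table a scale-adjusted metric table.
#' @param year census year to extract.
#' @param indicators indicator set (default: all in the table, alphabetical).
#' @return tibble `city_id` plus one `D` column per indicator.
#' @export
sami_wide <- function(table, year, indicators = NULL) {
  if (is.null(indicators)) indicators <- sort(unique(table$indicator))
  sub <- table[table$year == year & table$indicator %in% indicators,
               c("city_id", "indicator", "D")]
  wide <- tidyr::pivot_wider(sub, names_from = "indicator", values_from = "D")
  missing_ind <- setdiff(indicators, names(wide))
  for (mi in missing_ind) wide[[mi]] <- NA_real_
  wide[c("city_id", indicators)]
}

#' Fit the eight-predictor cross-indicator model for one indicator
#'
#' OLS with intercept of the target indicator's metric at the later census on
#' every indicator's metric at the earlier one, over cities holding all
#' predictors and the response. Optionally reports heteroskedasticity-
#' consistent (HC1) standard errors; the point estimates are unchanged.
#'
#' @param table a scale-adjusted metric table.
#' @param indicator response indicator.
#' @param year_pair length-2 `c(t, t + dt)`.
#' @param robust use HC1 sandwich standard errors.
#' @param indicators predictor set (default: all indicators in the table,
#'   alphabetical — the fixed serialization order).
#' @return object of class `forecast_model`: list with `indicator`,
#'   `year_pair`, `coefficients` (named `C_0` then one per predictor),
#'   `se`, `r_squared`, `sigma_eta` (residual SD), `robust`, `n_used`,
#'   `predictors`.
#' @export
fit_cross_model <- function(table, indicator, year_pair, robust = FALSE,
                            indicators = NULL) {
  stopifnot(length(year_pair) == 2)
  if (is.null(indicators)) indicators <- sort(unique(table$indicator))
  X <- sami_wide(table, year_pair[1], indicators)
  yv <- sami_wide(table, year_pair[2], indicator)
  names(yv)[2] <- ".response"
  d <- dplyr::inner_join(X, yv, by = "city_id")
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 10) {
    stop("fewer than 10 cities with all predictors at ", year_pair[1],
         " and ", indicator, " at ", year_pair[2], call. = FALSE)
  }
  form <- stats::as.formula(paste(".response ~", paste(indicators, collapse = " + ")))
  m <- lm(form, data = d)
  if (anyNA(coef(m))) {
    bad <- names(coef(m))[is.na(coef(m))]
    stop("rank-deficient design: collinear predictor(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  vc <- if (robust) sandwich::vcovHC(m, type = "HC1") else stats::vcov(m)
  cf <- coef(m)
  names(cf)[1] <- "C_0"
  se <- sqrt(diag(vc)); names(se) <- names(cf)
  structure(list(
    indicator = indicator, year_pair = as.numeric(year_pair),
    coefficients = cf, se = se,
    r_squared = summary(m)$r.squared,
    sigma_eta = sd(stats::residuals(m)),
    robust = robust, n_used = nrow(d), predictors = indicators
  ), class = "forecast_model")
}

#' @export
print.forecast_model <- function(x, ...) {
  cat(sprintf("Cross-indicator model: %s, %d-%d (n = %d, R^2 = %.3f%s)\n",
              x$indicator, x$year_pair[2], x$year_pair[1], x$n_used,
              x$r_squared, if (x$robust) ", HC1 SEs" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Fit cross-indicator models for every indicator and census interval
#'
#' @inheritParams fit_cross_model
#' @param years census years (default: all in the table); consecutive pairs
#'   form the intervals.
#' @return list of `forecast_model` objects, plus a tidy `summary` tibble
#'   attached as attribute (`indicator`, `year_from`, `year_to`,
#'   `r_squared`, `n_used`).
#' @export
fit_cross_models <- function(table, indicators = NULL, years = NULL,
                             robust = FALSE) {
  if (is.null(indicators)) indicators <- sort(unique(table$indicator))
  if (is.null(years)) years <- sort(unique(table$year))
  pairs <- Map(c, years[-length(years)], years[-1])
  models <- list()
  for (ind in indicators) for (yp in pairs) {
    models[[length(models) + 1L]] <-
      fit_cross_model(table, ind, yp, robust = robust, indicators = indicators)
  }
  smry <- dplyr::bind_rows(lapply(models, function(m) {
    tibble(indicator = m$indicator, year_from = m$year_pair[1],
           year_to = m$year_pair[2], r_squared = m$r_squared,
           n_used = m$n_used)
  }))
  attr(models, "summary") <- smry
  models
}

#' Lagged cross-correlation matrix of the scale-adjusted metrics
#'
#' Entry (i, j) is the Pearson correlation between indicator i's metric at
#' the later census and indicator j's at the earlier one, over the cities
#' holding both. The diagonal is each indicator's memory of its own past.
#'
#' @inheritParams fit_cross_model
#' @return numeric matrix (rows: `D_i(t+dt)`, columns: `D_j(t)`); entries
#'   with fewer than 3 common cities are `NA`, with the shortfall reported in
#'   the `n_common` attribute matrix.
#' @export
cross_correlation_matrix <- function(table, year_pair, indicators = NULL) {
  stopifnot(length(year_pair) == 2)
  if (is.null(indicators)) indicators <- sort(unique(table$indicator))
  if (!all(year_pair %in% table$year)) {
    stop("both years of the pair must be present in the table", call. = FALSE)
  }
  w0 <- sami_wide(table, year_pair[1], indicators)
  w1 <- sami_wide(table, year_pair[2], indicators)
  m <- dplyr::inner_join(w1, w0, by = "city_id", suffix = c(".t1", ".t0"))
  p <- length(indicators)
  out <- matrix(NA_real_, p, p, dimnames = list(indicators, indicators))
  ncom <- matrix(0L, p, p, dimnames = list(indicators, indicators))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    a <- m[[paste0(indicators[i], ".t1")]]
    b <- m[[paste0(indicators[j], ".t0")]]
    ok <- is.finite(a) & is.finite(b)
    ncom[i, j] <- sum(ok)
    if (sum(ok) >= 3) out[i, j] <- cor(a[ok], b[ok])
  }
  attr(out, "n_common") <- ncom
  out
}

#' Average cross-indicator models over census intervals
#'
#' Unweighted arithmetic mean of the intercept and coefficients of one
#' indicator's models across intervals, the constant-coefficient assumption
#' used for forecasting beyond the observed censuses. A single model averages
#' to itself.
#'
#' @param models list of `forecast_model` objects for the same indicator.
#' @return a `forecast_model` with the averaged coefficients; `year_pair` is
#'   `NA` and the contributing intervals are recorded in `provenance`.
#' @export
average_models <- function(models) {
  if (inherits(models, "forecast_model")) models <- list(models)
  stopifnot(length(models) >= 1)
  ind <- unique(vapply(models, `[[`, "", "indicator"))
  if (length(ind) != 1) {
    stop("models to average must target the same indicator, got: ",
         paste(ind, collapse = ", "), call. = FALSE)
  }
  preds <- lapply(models, `[[`, "predictors")
  if (length(unique(lapply(preds, sort))) != 1) {
    stop("config error: mismatched predictor sets across models", call. = FALSE)
  }
  cf <- rowMeans(vapply(models, `[[`, models[[1]]$coefficients, "coefficients"))
  structure(list(
    indicator = ind, year_pair = c(NA_real_, NA_real_),
    coefficients = cf, se = NULL,
    r_squared = mean(vapply(models, `[[`, 0, "r_squared")),
    sigma_eta = mean(vapply(models, `[[`, 0, "sigma_eta")),
    robust = any(vapply(models, `[[`, FALSE, "robust")),
    n_used = min(vapply(models, `[[`, 0L, "n_used")),
    predictors = models[[1]]$predictors,
    provenance = lapply(models, `[[`, "year_pair")
  ), class = "forecast_model")
}

#' Forecast scale-adjusted metrics one census ahead
#'
#' Applies each indicator's (averaged) cross-indicator model to the metrics
#' at `from_year`: \eqn{\hat D_i(\mathrm{horizon}) = \bar C_0 + \sum_k \bar
#' C_k D_k(t)} per city. Cities missing any predictor are skipped and
#' counted. The model is one census step deep; a horizon further than the
#' table's own inter-census spacing triggers a warning, not an error.
#'
#' @param table a scale-adjusted metric table containing `from_year`.
#' @param models named list of `forecast_model`s (one per indicator to
#'   predict), e.g. from [average_models()].
#' @param from_year census year supplying the predictors.
#' @param horizon_year year stamped on the predictions.
#' @return tibble `city_id`, `indicator`, `year` (= `horizon_year`), `D`;
#'   attribute `n_skipped` counts cities lacking a full predictor set.
#' @export
predict_next <- function(table, models, from_year, horizon_year) {
  if (inherits(models, "forecast_model")) models <- list(models)
  steps <- diff(sort(unique(table$year)))
  if (length(steps) && !(horizon_year - from_year) %in% steps) {
    warning("horizon ", horizon_year, " is not one observed census step (",
            paste(unique(steps), collapse = "/"), " years) beyond ",
            from_year, "; the model is one-step")
  }
  preds <- models[[1]]$predictors
  X <- sami_wide(table, from_year, preds)
  full <- complete.cases(X[preds])
  Xc <- X[full, , drop = FALSE]
  M <- cbind(1, as.matrix(Xc[preds]))
  out <- dplyr::bind_rows(lapply(models, function(m) {
    stopifnot(identical(m$predictors, preds))
    tibble(city_id = Xc$city_id, indicator = m$indicator,
           year = horizon_year,
           D = as.vector(M %*% m$coefficients))
  }))
  out <- dplyr::arrange(out, .data$indicator, .data$city_id)
  attr(out, "n_skipped") <- sum(!full)
  out
}

#' Compare predicted and empirical scale-adjusted metrics
#'
#' Joins the two tables on (city, indicator, year) and summarizes, per
#' indicator: the mean prediction error, the maximum vertical distance
#' between the empirical and predicted cumulative distributions (the
#' two-sample KS distance), and — when a `labels` table is given — the
#' above/below-group means of both versions with percentile-bootstrap
#' confidence intervals.
#'
#' @param predicted,empirical scale-adjusted metric tables with overlapping
#'   (city_id, indicator, year) keys.
#' @param labels optional tibble `city_id`, `indicator`, `baseline_label`
#'   (from [label_baseline_groups()]) used for the group-mean comparison.
#' @param n_boot,seed,conf bootstrap settings for the group means.
#' @return list with `by_indicator` (tibble `indicator`, `n_common`,
#'   `mean_diff`, `cdf_distance`) and `group_means` (tibble or `NULL`).
#' @export
compare_predicted_empirical <- function(predicted, empirical, labels = NULL,
                                        n_boot = 2000, seed = NULL,
                                        conf = 0.95) {
  keep <- c("city_id", "indicator", "year", "D")
  m <- dplyr::inner_join(predicted[intersect(keep, names(predicted))],
                         empirical[intersect(keep, names(empirical))],
                         by = c("city_id", "indicator", "year"),
                         suffix = c("_pred", "_emp"))
  if (nrow(m) == 0) stop("no overlapping (city, indicator, year) keys", call. = FALSE)
  by_ind <- m |>
    dplyr::group_by(.data$indicator) |>
    dplyr::summarise(
      n_common = dplyr::n(),
      mean_diff = mean(.data$D_pred - .data$D_emp),
      cdf_distance = {
        grid <- sort(unique(c(.data$D_pred, .data$D_emp)))
        max(abs(stats::ecdf(.data$D_pred)(grid) - stats::ecdf(.data$D_emp)(grid)))
      },
      .groups = "drop"
    )
  gm <- NULL
  if (!is.null(labels)) {
    if (!is.null(seed)) set.seed(seed)
    lab <- unique(labels[c("city_id", "indicator", "baseline_label")])
    ml <- dplyr::inner_join(m, lab, by = c("city_id", "indicator"))
    ml <- ml[!is.na(ml$baseline_label), ]
    gm <- ml |>
      dplyr::group_by(.data$indicator, .data$baseline_label, .data$year) |>
      dplyr::summarise(
        n_cities = dplyr::n(),
        mean_pred = mean(.data$D_pred),
        ci_pred_low = bootstrap_mean_ci(.data$D_pred, n_boot, conf)[1],
        ci_pred_high = bootstrap_mean_ci(.data$D_pred, n_boot, conf)[2],
        mean_emp = mean(.data$D_emp),
        ci_emp_low = bootstrap_mean_ci(.data$D_emp, n_boot, conf)[1],
        ci_emp_high = bootstrap_mean_ci(.data$D_emp, n_boot, conf)[2],
        .groups = "drop"
      )
  }
  list(by_indicator = by_ind, group_means = gm)
}
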