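# Scale-adjusted metrics: vertical log10 residuals from the fitted
# allometric laws, D = log10 Y - (A + beta log10 N). D > 0 marks a city above
# the law for its size, D < 0 below; the metric is size-independent for any
# exponent, unlike per-capita values.

.fits_frame <- function(fits) {
  if (inherits(fits, "allometric_fit")) fits <- list(fits)
  if (is.data.frame(fits)) {
    stopifnot(all(c("indicator", "year", "intercept", "exponent") %in% names(fits)))
    return(fits[c("indicator", "year", "intercept", "exponent")])
  }
  dplyr::bind_rows(lapply(fits, function(f) {
    tibble(indicator = f$indicator, year = f$year,
           intercept = f$intercept, exponent = f$exponent)
  }))
}

#' Compute scale-adjusted metrics from a panel and allometric fits
#'
#' For every retained (city, indicator, year) with positive indicator value,
#' \eqn{D = \log_{10} Y - (A + \beta \log_{10} N)} using that indicator-year's
#' fitted (or ground-truth) parameters. Rows with nonpositive indicator or
#' population values carry no metric. Because the per-year fit is used, the
#' adjustment tracks any drift of the law over time.
#'
#' Note on centring: residuals measured perpendicular to a major-axis line
#' average to ~0, but the *vertical* residuals D need not — their mean is
#' bounded by |b - b_OLS| * SD(log10 N), which vanishes only when the
#' major-axis and least-squares slopes coincide.
#'
#' @param panel a `census_panel`.
#' @param fits allometric parameters: the tibble from [fit_allometry_panel()],
#'   a list of `allometric_fit` objects, or any data frame with columns
#'   `indicator`, `year`, `intercept`, `exponent` (e.g. [ground_truth()]'s
#'   `allometry` element).
#' @return tibble with columns `city_id`, `indicator`, `year`, `D`.
#' @export
compute_sami <- function(panel, fits) {
  ff <- .fits_frame(fits)
  ind <- intersect(panel_indicators(panel), names(panel))
  long <- tidyr::pivot_longer(
    as_tibble(panel)[c("city_id", "year", "population", ind)],
    dplyr::all_of(ind), names_to = "indicator", values_to = "value"
  )
  have <- unique(long[c("indicator", "year")])
  missing_fit <- dplyr::anti_join(have, ff, by = c("indicator", "year"))
  if (nrow(missing_fit)) {
    stop("missing fit for ", missing_fit$indicator[1], " in year ",
         missing_fit$year[1], call. = FALSE)
  }
  out <- dplyr::inner_join(long, ff, by = c("indicator", "year"))
  out <- out[is.finite(out$value) & out$value > 0 & out$population > 0, ]
  out$D <- log10(out$value) - (out$intercept + out$exponent * log10(out$population))
  dplyr::arrange(out[c("city_id", "indicator", "year", "D")],
                 .data$indicator, .data$year, .data$city_id)
}

#' Label cities above/below the allometric law at a baseline year
#'
#' Splits cities per indicator by the sign of their scale-adjusted metric at
#' the baseline census: `"above"` for D > 0, `"below"` otherwise (an exact
#' zero counts as below, since "above" is defined strictly). The label is
#' frozen at the baseline and attached to every year of that (city,
#' indicator), so later group summaries follow the same cities through time.
#' Cities absent at the baseline are left unlabelled and counted.
#'
#' @param table a scale-adjusted metric table (`city_id`, `indicator`,
#'   `year`, `D`).
#' @param baseline_year census year at which groups are defined; defaults to
#'   the earliest year present.
#' @return the table with a `baseline_label` column (`"above"`, `"below"` or
#'   `NA`), plus attribute `n_unlabelled` (rows whose city-indicator is
#'   missing at baseline).
#' @export
label_baseline_groups <- function(table, baseline_year = min(table$year)) {
  if (!baseline_year %in% table$year) {
    stop("baseline year ", baseline_year, " absent from table", call. = FALSE)
  }
  base <- table[table$year == baseline_year, c("city_id", "indicator", "D")]
  base$baseline_label <- ifelse(base$D > 0, "above", "below")
  base$D <- NULL
  out <- dplyr::left_join(table[setdiff(names(table), "baseline_label")],
                          base, by = c("city_id", "indicator"))
  attr(out, "baseline_year") <- baseline_year
  attr(out, "n_unlabelled") <- sum(is.na(out$baseline_label))
  out
}

#' Group mean of the scale-adjusted metric with a bootstrap CI
#'
#' Mean of D over one baseline group's cities at one census year, with a
#' seeded percentile-bootstrap confidence interval over city resampling.
#'
#' @param table a labelled metric table (see [label_baseline_groups()]).
#' @param indicator,year,group which cell to summarize (`group` is `"above"`
#'   or `"below"`).
#' @param n_boot bootstrap resamples (default 10000).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return one-row tibble: `indicator`, `group`, `year`, `mean_D`, `ci_low`,
#'   `ci_high`, `n_cities`.
#' @export
group_mean_ci <- function(table, indicator, year, group,
                          n_boot = 10000, seed = NULL, conf = 0.95) {
  stopifnot("baseline_label" %in% names(table))
  d <- table$D[table$indicator == indicator & table$year == year &
                 !is.na(table$baseline_label) & table$baseline_label == group]
  if (length(d) == 0) {
    stop("empty group: no '", group, "' cities for ", indicator,
         " in ", year, call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ci <- bootstrap_mean_ci(d, n_boot = n_boot, conf = conf)
  tibble(indicator = indicator, group = group, year = year,
         mean_D = mean(d), ci_low = ci[1], ci_high = ci[2],
         n_cities = length(d))
}

#' Group-mean evolution for all indicators, groups and years
#'
#' @inheritParams group_mean_ci
#' @return tibble of [group_mean_ci()] rows for every (indicator, group,
#'   year) cell present in the table.
#' @export
group_summary <- function(table, n_boot = 10000, seed = NULL, conf = 0.95) {
  stopifnot("baseline_label" %in% names(table))
  cells <- unique(table[!is.na(table$baseline_label),
                        c("indicator", "baseline_label", "year")])
  if (!is.null(seed)) set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(nrow(cells)), function(i) {
    group_mean_ci(table, cells$indicator[i], cells$year[i],
                  cells$baseline_label[i], n_boot = n_boot, conf = conf)
  })) |>
    dplyr::arrange(.data$indicator, .data$group, .data$year)
}
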