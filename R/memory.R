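# One-lag memory of the scale-adjusted metrics:
#   D(t + dt) = A + alpha * D(t)
# fitted by ordinary least squares per indicator and census interval. In the
# small-step limit the map becomes dD/dt = A + (alpha - 1) D, whose solution
# relaxes exponentially towards A/(1 - alpha) for alpha < 1 with
# characteristic time 1/(1 - alpha); alpha > 1 departs exponentially and
# alpha = 1 drifts linearly.

#' Fit the one-lag memory model for one indicator
#'
#' Ordinary least squares of \eqn{D(t+\Delta t)} on \eqn{D(t)} over the
#' cities present at both censuses.
#'
#' @param table a scale-adjusted metric table (`city_id`, `indicator`,
#'   `year`, `D`).
#' @param indicator indicator name.
#' @param year_pair length-2 numeric `c(t, t + dt)` naming the two censuses.
#' @return object of class `memory_fit`: list with `indicator`, `year_pair`,
#'   `intercept` (A), `slope` (alpha), `se_intercept`, `se_slope`, `rho`,
#'   `r_squared`, `n_used`, and `data` (tibble `city_id`, `d_t`, `d_t1`,
#'   `residual`).
#' @export
fit_memory <- function(table, indicator, year_pair) {
  stopifnot(length(year_pair) == 2)
  sub <- table[table$indicator == indicator & table$year %in% year_pair,
               c("city_id", "year", "D")]
  wide <- tidyr::pivot_wider(sub, names_from = "year", values_from = "D")
  y0 <- as.character(year_pair[1]); y1 <- as.character(year_pair[2])
  if (!all(c(y0, y1) %in% names(wide))) {
    stop("year pair (", y0, ", ", y1, ") not both present for ", indicator,
         call. = FALSE)
  }
  wide <- wide[is.finite(wide[[y0]]) & is.finite(wide[[y1]]), ]
  if (nrow(wide) < 3) stop("fewer than 3 cities present at both years", call. = FALSE)
  d0 <- wide[[y0]]; d1 <- wide[[y1]]
  if (var(d0) == 0) stop("degenerate fit: zero variance in D(t)", call. = FALSE)
  m <- lm(d1 ~ d0)
  sm <- summary(m)
  structure(list(
    indicator = indicator,
    year_pair = as.numeric(year_pair),
    intercept = unname(coef(m)[1]), slope = unname(coef(m)[2]),
    se_intercept = sm$coefficients[1, 2], se_slope = sm$coefficients[2, 2],
    rho = cor(d0, d1), r_squared = sm$r.squared,
    n_used = nrow(wide),
    data = tibble(city_id = wide$city_id, d_t = d0, d_t1 = d1,
                  residual = unname(stats::residuals(m)))
  ), class = "memory_fit")
}

#' @export
print.memory_fit <- function(x, ...) {
  cat(sprintf(
    "Memory fit: %s, %d-%d\n  alpha = %.4f (SE %.4f)   A = %.3g   rho = %.3f   n = %d\n",
    x$indicator, x$year_pair[2], x$year_pair[1], x$slope, x$se_slope,
    x$intercept, x$rho, x$n_used
  ))
  invisible(x)
}

#' Fit the memory model for every indicator and consecutive census interval
#'
#' @param table a scale-adjusted metric table.
#' @param indicators indicators to fit (default: all in the table).
#' @param years census years (default: all in the table, in order); each
#'   consecutive pair forms one interval.
#' @return tibble with one row per indicator-interval (`indicator`,
#'   `year_from`, `year_to`, `intercept`, `slope`, `se_slope`, `rho`,
#'   `r_squared`, `n_used`) and a `fits` list-column.
#' @export
fit_memory_panel <- function(table, indicators = NULL, years = NULL) {
  if (is.null(indicators)) indicators <- sort(unique(table$indicator))
  if (is.null(years)) years <- sort(unique(table$year))
  pairs <- Map(c, years[-length(years)], years[-1])
  fits <- list()
  for (ind in indicators) for (yp in pairs) {
    fits[[length(fits) + 1L]] <- fit_memory(table, ind, yp)
  }
  out <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble(indicator = f$indicator,
           year_from = f$year_pair[1], year_to = f$year_pair[2],
           intercept = f$intercept, slope = f$slope, se_slope = f$se_slope,
           rho = f$rho, r_squared = f$r_squared, n_used = f$n_used)
  }))
  out$fits <- fits
  out
}

#' Continuous-time solution of the memory model
#'
#' The small-step limit of the one-lag map is the linear ODE
#' \eqn{dD/dt = A + (\alpha - 1) D}. Its solution is
#' \deqn{D(t) = \frac{A}{1-\alpha} + \Big(k - \frac{A}{1-\alpha}\Big)
#'   e^{-(1-\alpha) t}} for \eqn{\alpha \neq 1} and \eqn{D(t) = A t + k} for
#' \eqn{\alpha = 1}, with integration constant \eqn{k = D(0)}. The linear
#' branch is taken when \eqn{|1-\alpha| < 10^{-12}} (the discontinuity is
#' removable). For \eqn{\alpha < 1} trajectories relax exponentially to the
#' asymptote \eqn{A/(1-\alpha)}; for \eqn{\alpha > 1} they grow
#' exponentially.
#'
#' @param A intercept of the memory model.
#' @param alpha slope of the memory model.
#' @param k initial condition D(0).
#' @return object of class `ode_solution`: list with `A`, `alpha`, `k`,
#'   `asymptote` (`A/(1-alpha)`, `NA` on the linear branch),
#'   `characteristic_time` and `evaluate(t)`, a vectorized trajectory
#'   function.
#' @export
ode_solution <- function(A, alpha, k) {
  linear <- abs(1 - alpha) < 1e-12
  asym <- if (linear) NA_real_ else A / (1 - alpha)
  evaluate <- if (linear) {
    function(t) A * t + k
  } else {
    function(t) asym + (k - asym) * exp(-(1 - alpha) * t)
  }
  structure(list(
    A = A, alpha = alpha, k = k,
    asymptote = asym,
    characteristic_time = characteristic_time(alpha),
    evaluate = evaluate
  ), class = "ode_solution")
}

#' Characteristic time of the relaxation towards the allometric law
#'
#' \eqn{1/(1-\alpha)}: the e-folding time of the continuous-time solution.
#' Finite and positive for \eqn{\alpha < 1}, and monotonically increasing in
#' \eqn{\alpha} there — the smaller \eqn{\alpha}, the faster the indicator
#' changes. Returns `Inf` at \eqn{\alpha = 1} and `NaN` for \eqn{\alpha > 1}
#' (no relaxation: the dynamics departs from the law); neither case raises an
#' error.
#'
#' @param alpha memory slope(s); vectorized.
#' @return numeric vector of characteristic times.
#' @export
characteristic_time <- function(alpha) {
  out <- ifelse(alpha < 1, 1 / (1 - alpha), ifelse(alpha == 1, Inf, NaN))
  as.numeric(out)
}

#' Cramér-von Mises test against a fully specified normal
#'
#' Simple-null goodness-of-fit test of a sample against
#' \eqn{N(\mu, \sigma^2)} with *fixed* parameters (default the standard
#' normal), as used on standardized regression residuals. The statistic is
#' \deqn{W^2 = \frac{1}{12n} + \sum_{i=1}^n
#'   \Big(\frac{2i-1}{2n} - F(x_{(i)})\Big)^2} and the p-value comes from the
#' asymptotic null distribution (via \pkg{goftest}). `method = "composite"`
#' instead estimates the parameters from the sample and applies the
#' normality-test variant with Stephens' modification (via \pkg{nortest}).
#'
#' @param x numeric sample.
#' @param mean,sd null-hypothesis parameters (simple method only).
#' @param method `"simple"` (default) or `"composite"`.
#' @return list with `statistic`, `p_value`, `method`.
#' @export
cvm_test <- function(x, mean = 0, sd = 1, method = c("simple", "composite")) {
  method <- match.arg(method)
  if (method == "composite") {
    if (!requireNamespace("nortest", quietly = TRUE)) {
      stop("nortest is required for the composite-null variant", call. = FALSE)
    }
    ht <- nortest::cvm.test(x)
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                method = "composite"))
  }
  ht <- goftest::cvm.test(x, null = "pnorm", mean = mean, sd = sd,
                          estimated = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = "simple")
}

#' Residual diagnostics for a memory fit
#'
#' Standardizes the fit residuals to mean 0 and SD 1, tests them against the
#' standard normal with the simple-null Cramér-von Mises test, and profiles
#' the conditional spread: the SD of \eqn{D(t+\Delta t)} in five equal-width,
#' right-closed windows of \eqn{D(t)}, reported against each window's mean
#' abscissa (a flat profile indicates homoskedastic dynamics noise).
#'
#' @param fit a `memory_fit`.
#' @param n_windows number of equal-width windows (default 5).
#' @param cvm_method passed to [cvm_test()].
#' @return list with `xi` (standardized residuals), `cvm_statistic`,
#'   `cvm_p`, and `window_sd` (tibble `window`, `center_d_t`, `sd_d_t1`,
#'   `n`; SD is `NA` for windows holding fewer than 2 points).
#' @export
residual_diagnostics <- function(fit, n_windows = 5, cvm_method = "simple") {
  stopifnot(inherits(fit, "memory_fit"))
  r <- fit$data$residual
  xi <- (r - mean(r)) / sd(r)
  ct <- cvm_test(xi, method = cvm_method)
  edges <- seq(min(fit$data$d_t), max(fit$data$d_t), length.out = n_windows + 1)
  # right-closed windows; the first edge is included so no point is lost
  bin <- findInterval(fit$data$d_t, edges, left.open = TRUE,
                      rightmost.closed = TRUE)
  bin[bin == 0] <- 1L
  win <- lapply(seq_len(n_windows), function(w) {
    inw <- bin == w
    tibble(window = w,
           center_d_t = if (any(inw)) mean(fit$data$d_t[inw]) else NA_real_,
           sd_d_t1 = if (sum(inw) >= 2) sd(fit$data$d_t1[inw]) else NA_real_,
           n = sum(inw))
  })
  list(xi = xi, cvm_statistic = ct$statistic, cvm_p = ct$p_value,
       window_sd = dplyr::bind_rows(win))
}
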