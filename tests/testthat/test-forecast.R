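# Helpers building small deterministic metric tables in the wide-truth shape.
two_year_system <- function(n = 60, p = 3, seed = 1, C0 = NULL, C = NULL,
                            sd_eta = 0, years = c(2000, 2010)) {
  set.seed(seed)
  inds <- paste0("ind", seq_len(p))
  if (is.null(C0)) C0 <- rep(0.05, p)
  if (is.null(C)) C <- diag(0.6, p) + 0.1
  D0 <- matrix(rnorm(n * p, 0, 0.5), n, p)
  D1 <- sweep(D0 %*% t(C), 2, C0, `+`) +
    matrix(rnorm(n * p, 0, sd_eta), n, p)
  ids <- sprintf("%04d", 1:n)
  dplyr::bind_rows(
    make_sami(rep(ids, p), rep(inds, each = n), years[1], as.vector(D0)),
    make_sami(rep(ids, p), rep(inds, each = n), years[2], as.vector(D1))
  )
}

test_that("noise-free cross models recover coefficients exactly with R^2 = 1", {
  C0 <- c(0.1, -0.2, 0)
  C <- matrix(c(0.5, 0.2, 0, 0.1, 0.6, -0.1, 0, 0.05, 0.7), 3, 3, byrow = TRUE)
  tab <- two_year_system(n = 40, C0 = C0, C = C, sd_eta = 0)
  for (i in 1:3) {
    m <- suppressWarnings(fit_cross_model(tab, paste0("ind", i), c(2000, 2010)))
    expect_equal(unname(m$coefficients["C_0"]), C0[i], tolerance = 1e-10)
    expect_equal(unname(m$coefficients[paste0("ind", 1:3)]), C[i, ],
                 tolerance = 1e-10)
    expect_equal(m$r_squared, 1, tolerance = 1e-10)
    expect_lt(m$sigma_eta, 1e-10)
  }
})

test_that("R^2 equals 1 - SSE/SST computed independently", {
  tab <- two_year_system(n = 80, sd_eta = 0.2, seed = 4)
  m <- fit_cross_model(tab, "ind2", c(2000, 2010))
  X <- sami_wide(tab, 2000); y <- sami_wide(tab, 2010, "ind2")
  names(y)[2] <- "resp"
  d <- dplyr::inner_join(X, y, by = "city_id")
  yy <- d$resp
  pred <- as.vector(cbind(1, as.matrix(d[paste0("ind", 1:3)])) %*% m$coefficients)
  r2 <- 1 - sum((yy - pred)^2) / sum((yy - mean(yy))^2)
  expect_equal(m$r_squared, r2, tolerance = 1e-12)
})

test_that("robust standard errors change SEs but not coefficients", {
  tab <- two_year_system(n = 100, sd_eta = 0.3, seed = 5)
  m1 <- fit_cross_model(tab, "ind1", c(2000, 2010), robust = FALSE)
  m2 <- fit_cross_model(tab, "ind1", c(2000, 2010), robust = TRUE)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(m1$se, m2$se, tolerance = 1e-12)))
})

test_that("degenerate designs raise informative errors", {
  tab <- two_year_system(n = 30, sd_eta = 0.1, seed = 6)
  dup <- tab[tab$indicator == "ind1", ]
  dup$indicator <- "ind4"   # perfect copy of ind1 => collinear
  expect_error(fit_cross_model(dplyr::bind_rows(tab, dup), "ind1",
                               c(2000, 2010)),
               "collinear")
  expect_error(fit_cross_model(tab[tab$city_id %in% sprintf("%04d", 1:5), ],
                               "ind1", c(2000, 2010)),
               "fewer than 10")
})

test_that("the lagged cross-correlation matrix matches hand computation", {
  d0 <- c(0.1, -0.2, 0.4, 0, -0.3)
  d1 <- c(0.2, -0.1, 0.5, 0.1, -0.2)
  e0 <- c(1, 2, 3, 4, 5) / 10
  tab <- dplyr::bind_rows(
    make_sami(letters[1:5], "x", 2000, d0),
    make_sami(letters[1:5], "y", 2000, e0),
    make_sami(letters[1:5], "x", 2010, d1),
    make_sami(letters[1:5], "y", 2010, d0)
  )
  M <- cross_correlation_matrix(tab, c(2000, 2010))
  expect_equal(M["x", "x"], cor(d1, d0), tolerance = 1e-12)
  expect_equal(M["x", "y"], cor(d1, e0), tolerance = 1e-12)
  expect_equal(M["y", "x"], cor(d0, d0), tolerance = 1e-12)
  # identity lag: diagonal exactly 1
  tab2 <- dplyr::bind_rows(
    make_sami(letters[1:5], "x", 2000, d0),
    make_sami(letters[1:5], "x", 2010, d0)
  )
  expect_equal(cross_correlation_matrix(tab2, c(2000, 2010))["x", "x"], 1)
  expect_error(cross_correlation_matrix(tab, c(2000, 2031)), "both years")
})

test_that("too few common cities leaves entries missing with counts", {
  tab <- dplyr::bind_rows(
    make_sami(c("a", "b"), "x", 2000, c(0.1, 0.2)),
    make_sami(c("a", "b", "c", "d"), "x", 2010, c(0.2, 0.1, 0, 0.4))
  )
  M <- cross_correlation_matrix(tab, c(2000, 2010))
  expect_true(is.na(M["x", "x"]))
  expect_equal(attr(M, "n_common")["x", "x"], 2L)
})

test_that("averaging models is the arithmetic mean with provenance", {
  tab1 <- two_year_system(n = 50, sd_eta = 0.1, seed = 7, years = c(1991, 2000))
  tab2 <- two_year_system(n = 50, sd_eta = 0.1, seed = 8, years = c(2000, 2010))
  m1 <- fit_cross_model(tab1, "ind1", c(1991, 2000))
  m2 <- fit_cross_model(tab2, "ind1", c(2000, 2010))
  avg <- average_models(list(m1, m2))
  expect_equal(avg$coefficients, (m1$coefficients + m2$coefficients) / 2,
               tolerance = 1e-12)
  expect_length(avg$provenance, 2)
  # idempotence
  same <- average_models(list(m1, m1))
  expect_equal(same$coefficients, m1$coefficients, tolerance = 1e-12)
  # degenerate averaging: single interval passes through
  single <- average_models(m1)
  expect_equal(single$coefficients, m1$coefficients)
  m_bad <- m2; m_bad$predictors <- c("ind1", "ind2", "other")
  expect_error(average_models(list(m1, m_bad)), "mismatched predictor")
  m_other <- m2; m_other$indicator <- "ind2"
  expect_error(average_models(list(m1, m_other)), "same indicator")
})

test_that("predictions are the stated linear combinations", {
  tab <- two_year_system(n = 20, sd_eta = 0.1, seed = 9)
  # constant model: only the intercept
  m <- fit_cross_model(tab, "ind1", c(2000, 2010))
  m$coefficients[] <- c(0.1, 0, 0, 0)
  pred <- suppressWarnings(predict_next(tab, list(m), 2010, 2021))
  expect_true(all(pred$D == 0.1))
  # three-city hand-computed combination
  D0 <- matrix(c(0.1, -0.2, 0.3,   0, 0.5, -0.1,   0.2, 0.2, 0.2), 3, 3,
               byrow = TRUE)
  hand_tab <- make_sami(rep(c("a", "b", "c"), 3),
                        rep(paste0("ind", 1:3), each = 3), 2010,
                        as.vector(D0))
  cf <- c(0.05, 0.5, -0.2, 0.1)
  m$coefficients[] <- cf
  got <- predict_next(hand_tab, list(m), 2010, 2020)
  expect_equal(got$D[got$city_id == "a"],
               cf[1] + sum(cf[2:4] * D0[1, ]), tolerance = 1e-12)
  expect_equal(got$D[got$city_id == "c"],
               cf[1] + sum(cf[2:4] * D0[3, ]), tolerance = 1e-12)
})

test_that("one-step horizon is silent; other horizons warn; gaps are skipped", {
  tab <- two_year_system(n = 20, sd_eta = 0.1, seed = 10)
  m <- fit_cross_model(tab, "ind1", c(2000, 2010))
  expect_silent(p1 <- predict_next(tab, list(m), 2010, 2020))
  expect_warning(predict_next(tab, list(m), 2010, 2050), "one-step")
  # drop one predictor cell for one city: that city is skipped and counted
  tab2 <- tab[!(tab$city_id == "0001" & tab$year == 2010 &
                  tab$indicator == "ind2"), ]
  p2 <- predict_next(tab2, list(m), 2010, 2020)
  expect_equal(attr(p2, "n_skipped"), 1)
  expect_false("0001" %in% p2$city_id)
  expect_equal(nrow(p2), 19)
})

test_that("prediction is affine-linear in the predictor tables", {
  tab <- two_year_system(n = 15, sd_eta = 0.2, seed = 11)
  m <- fit_cross_model(tab, "ind2", c(2000, 2010))
  a <- 2; b <- -0.5
  t10 <- tab[tab$year == 2010, ]
  tX <- t10; tX$D <- a * t10$D
  tY <- t10; tY$D <- b * t10$D
  tXY <- t10; tXY$D <- (a + b) * t10$D
  f <- function(tt) predict_next(tt, list(m), 2010, 2020)$D
  lhs <- f(tXY)
  rhs <- f(tX) + f(tY) - unname(m$coefficients["C_0"])
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("the eight-predictor model never explains less than the single lag", {
  g <- generate_panel(tiny_config(n_cities = 250, seed = 12))
  tab <- compute_sami(g$panel, ground_truth(g$config)$allometry)
  for (ind in c("homicides", "unemployment")) {
    mem <- fit_memory(tab, ind, c(1991, 2000))
    full <- fit_cross_model(tab, ind, c(1991, 2000))
    expect_gte(full$r_squared + 1e-12, mem$r_squared)
  }
})

test_that("predicted-vs-empirical comparison detects identity and shifts", {
  tab <- two_year_system(n = 40, sd_eta = 0.2, seed = 13)
  emp <- tab[tab$year == 2010, ]
  cmp <- compare_predicted_empirical(emp, emp)
  expect_true(all(cmp$by_indicator$mean_diff == 0))
  expect_true(all(cmp$by_indicator$cdf_distance == 0))
  shifted <- emp; shifted$D <- emp$D + 0.1
  cmp2 <- compare_predicted_empirical(shifted, emp)
  expect_equal(cmp2$by_indicator$mean_diff, rep(0.1, 3), tolerance = 1e-12)
  expect_true(all(cmp2$by_indicator$cdf_distance > 0))
  labels <- tibble::tibble(city_id = unique(emp$city_id)) |>
    tidyr::crossing(indicator = paste0("ind", 1:3)) |>
    dplyr::mutate(baseline_label = ifelse(substr(city_id, 4, 4) %in%
                                            c("1", "3", "5", "7", "9"),
                                          "above", "below"))
  cmp3 <- compare_predicted_empirical(shifted, emp, labels = labels,
                                      n_boot = 200, seed = 3)
  expect_equal(cmp3$group_means$mean_pred - cmp3$group_means$mean_emp,
               rep(0.1, nrow(cmp3$group_means)), tolerance = 1e-12)
  expect_error(compare_predicted_empirical(emp,
                                           dplyr::mutate(emp, year = 1800)),
               "no overlapping")
})

test_that("predicted CDFs close on the empirical ones as the system grows", {
  # one-step-ahead forecasts from estimated coefficients: the distributional
  # gap to the realized metrics shrinks with city count
  dist_at <- function(n, seed) {
    tab <- two_year_system(n = n, sd_eta = 0.05, seed = seed)
    m <- fit_cross_model(tab, "ind1", c(2000, 2010))
    pred <- predict_next(tab[tab$year == 2000, ] |>
                           dplyr::mutate(year = 2000), list(m), 2000, 2010)
    emp <- tab[tab$year == 2010 & tab$indicator == "ind1", ]
    compare_predicted_empirical(pred, emp)$by_indicator$cdf_distance
  }
  d_small <- mean(vapply(1:3, function(s) dist_at(200, s), 0))
  d_big <- mean(vapply(1:3, function(s) dist_at(2000, s + 10), 0))
  expect_lt(d_big, d_small)
})
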