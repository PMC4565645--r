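#!/usr/bin/env Rscript
# Cross-indicator forecasting: fit D_i(t+dt) = C_0 + sum_k C_k D_k(t) per
# indicator and interval, inspect the lagged cross-correlations, average the
# coefficients over the two intervals (constant-coefficient assumption) and
# forecast the 2020 metrics from the 2010 ones. An in-sample one-step check
# (predict 2010 from 2000) quantifies the agreement with realized values.

suppressPackageStartupMessages(library(urbansami))
tab <- read_sami_table("results/sami.csv")
labels <- tab[!is.na(tab$baseline_label),
              c("city_id", "indicator", "baseline_label")] |> unique()

cc <- cross_correlation_matrix(tab, c(2000, 2010))
readr::write_csv(tibble::as_tibble(unclass(cc), rownames = "indicator"),
                 "results/cross_correlations_2010_2000.csv")
diag_dom <- all(vapply(seq_len(nrow(cc)),
                       function(i) which.max(abs(cc[i, ])) == i, TRUE))
message("diagonal dominance of lagged correlations (own past strongest): ",
        diag_dom)

models <- fit_cross_models(tab)
smry <- attr(models, "summary")
coefs <- dplyr::bind_rows(lapply(models, function(m) {
  dplyr::bind_cols(tibble::tibble(indicator = m$indicator,
                                  year_from = m$year_pair[1],
                                  year_to = m$year_pair[2],
                                  r_squared = m$r_squared),
                   tibble::as_tibble(as.list(m$coefficients)))
}))
readr::write_csv(coefs, "results/cross_model_coefficients.csv")
message(sprintf("cross models explain %.0f%%-%.0f%% of next-census variance",
                100 * min(smry$r_squared), 100 * max(smry$r_squared)))

inds <- sort(unique(tab$indicator))
averaged <- lapply(inds, function(ind) {
  average_models(Filter(function(m) m$indicator == ind, models))
})
names(averaged) <- inds

# in-sample check: one-step prediction of 2010 from 2000
models_1 <- Filter(function(m) m$year_pair[1] == 2000, models)
names(models_1) <- vapply(models_1, `[[`, "", "indicator")
pred_2010 <- predict_next(tab, models_1, 2000, 2010)
cmp <- compare_predicted_empirical(pred_2010, tab[tab$year == 2010, ],
                                   labels = labels, n_boot = 2000, seed = 11)
readr::write_csv(cmp$by_indicator, "results/insample_comparison.csv")
readr::write_csv(cmp$group_means, "results/insample_group_means.csv")
message("in-sample CDF distances: ",
        paste(sprintf("%s %.3f", cmp$by_indicator$indicator,
                      cmp$by_indicator$cdf_distance), collapse = ", "))

pred_2020 <- predict_next(tab, averaged, 2010, 2020)
write_sami_table(pred_2020, "results/forecast_2020.csv")
message("forecast written for ", length(unique(pred_2020$city_id)),
        " cities (skipped: ", attr(pred_2020, "n_skipped"), ")")

ggplot2::ggsave("results/insample_cdf_overlay.pdf",
                plot_cdf_overlay(pred_2010, tab[tab$year == 2010, ]),
                width = 10, height = 6)
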