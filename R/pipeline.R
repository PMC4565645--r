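# End-to-end orchestration: allometry -> scale-adjusted metrics -> group
# trends -> memory -> cross-indicator models -> forecast -> map. Every
# numeric artifact carries the run's seed and config hash in its comment
# header, and a manifest records each artifact with a content hash so a
# re-run with the same inputs is verifiably identical.

.config_hash <- function(opts) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(opts, tf, auto_unbox = TRUE, digits = 15)
  unname(tools::md5sum(tf))
}

#' Run the full scale-adjusted analysis pipeline
#'
#' Restricts the panel to its complete cities, fits every indicator-year
#' allometry, computes the scale-adjusted metrics, labels above/below-law
#' groups at the baseline year, summarizes group means with bootstrap CIs,
#' fits the one-lag memory model and its diagnostics per interval, fits and
#' averages the cross-indicator models, forecasts the next census, and (when
#' coordinates are supplied) writes the predicted-change GeoJSON and map.
#' Each stage's tables are written to `out_dir` as CSV; figures as PDF. A
#' failing stage is recorded in the manifest and does not destroy the
#' artifacts already produced.
#'
#' @param panel a `census_panel`.
#' @param out_dir output directory (created if needed).
#' @param coords optional coordinate table for the change map.
#' @param baseline_year year at which above/below groups are frozen
#'   (default: earliest census in the panel).
#' @param horizon_year forecast year (default: last census plus the last
#'   inter-census spacing).
#' @param boot_reps bootstrap resamples for all confidence intervals and SEs.
#' @param seed integer seed; fixes every random draw of the run.
#' @param variance_ratio,zero_handling,se_method passed to
#'   [fit_allometry_panel()].
#' @param robust_se use HC1 standard errors in the cross-indicator models.
#' @param make_plots write PDF figures (disable for headless speed).
#' @return invisibly, a list with every stage result plus `manifest`
#'   (tibble `artifact`, `path`, `md5`, `status`). Figures are listed in the
#'   manifest without a hash (PDF bytes embed timestamps).
#' @export
run_full_pipeline <- function(panel, out_dir, coords = NULL,
                              baseline_year = NULL, horizon_year = NULL,
                              boot_reps = 1000, seed = 1L,
                              variance_ratio = 1,
                              zero_handling = c("drop", "offset"),
                              se_method = c("bootstrap", "analytic"),
                              robust_se = FALSE, make_plots = TRUE) {
  zero_handling <- match.arg(zero_handling)
  se_method <- match.arg(se_method)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  years <- sort(unique(panel$year))
  if (is.null(baseline_year)) baseline_year <- years[1]
  if (is.null(horizon_year)) {
    horizon_year <- years[length(years)] + diff(years)[length(years) - 1]
  }
  opts <- list(baseline_year = baseline_year, horizon_year = horizon_year,
               boot_reps = boot_reps, seed = seed,
               variance_ratio = variance_ratio, zero_handling = zero_handling,
               se_method = se_method, robust_se = robust_se,
               years = years, n_rows = nrow(panel))
  hash <- .config_hash(opts)
  meta <- list(seed = seed, config_hash = hash)
  manifest <- list()
  note <- function(artifact, path, hashed = TRUE, status = "ok") {
    manifest[[length(manifest) + 1L]] <<- tibble(
      artifact = artifact, path = basename(path),
      md5 = if (hashed && file.exists(path)) unname(tools::md5sum(path)) else NA_character_,
      status = status
    )
  }
  stage <- function(artifact, expr) {
    tryCatch(expr, error = function(e) {
      manifest[[length(manifest) + 1L]] <<- tibble(
        artifact = artifact, path = NA_character_, md5 = NA_character_,
        status = paste0("failed: ", conditionMessage(e)))
      NULL
    })
  }
  set.seed(seed)
  res <- list(options = opts, config_hash = hash)

  panel <- complete_cities(panel)

  res$allometry <- stage("allometry", {
    fits <- fit_allometry_panel(panel, variance_ratio = variance_ratio,
                                zero_handling = zero_handling,
                                se_method = se_method, n_boot = boot_reps,
                                seed = seed)
    p <- file.path(out_dir, "allometry_fits.csv")
    .write_csv_meta(dplyr::select(fits, -"fits"), p, meta)
    note("allometry", p)
    fits
  })

  res$sami <- stage("sami", {
    tab <- compute_sami(panel, res$allometry)
    tab <- label_baseline_groups(tab, baseline_year)
    p <- file.path(out_dir, "sami.csv")
    write_sami_table(tab, p, meta)
    note("sami", p)
    tab
  })

  res$per_capita <- stage("per_capita", {
    pc <- dplyr::bind_rows(lapply(years, function(y) {
      per_capita_group_means(panel, y, n_boot = boot_reps)
    }))
    p <- file.path(out_dir, "per_capita_means.csv")
    .write_csv_meta(pc, p, meta)
    note("per_capita", p)
    pc
  })

  res$group_summary <- stage("group_summary", {
    gs <- group_summary(res$sami, n_boot = boot_reps, seed = seed)
    p <- file.path(out_dir, "group_summary.csv")
    .write_csv_meta(gs, p, meta)
    note("group_summary", p)
    gs
  })

  res$memory <- stage("memory", {
    mem <- fit_memory_panel(res$sami)
    diag <- dplyr::bind_rows(lapply(mem$fits, function(f) {
      d <- residual_diagnostics(f)
      dplyr::mutate(d$window_sd, indicator = f$indicator,
                    year_from = f$year_pair[1], year_to = f$year_pair[2],
                    cvm_statistic = d$cvm_statistic, cvm_p = d$cvm_p)
    }))
    p1 <- file.path(out_dir, "memory_fits.csv")
    .write_csv_meta(dplyr::select(mem, -"fits"), p1, meta)
    note("memory", p1)
    p2 <- file.path(out_dir, "memory_diagnostics.csv")
    .write_csv_meta(diag, p2, meta)
    note("memory_diagnostics", p2)
    list(fits = mem, diagnostics = diag)
  })

  res$models <- stage("cross_models", {
    models <- fit_cross_models(res$sami, robust = robust_se)
    coefs <- dplyr::bind_rows(lapply(models, function(m) {
      dplyr::bind_cols(
        tibble(indicator = m$indicator, year_from = m$year_pair[1],
               year_to = m$year_pair[2], r_squared = m$r_squared,
               sigma_eta = m$sigma_eta, n_used = m$n_used),
        as_tibble(as.list(m$coefficients))
      )
    }))
    p <- file.path(out_dir, "cross_model_coefficients.csv")
    .write_csv_meta(coefs, p, meta)
    note("cross_models", p)
    models
  })

  res$forecast <- stage("forecast", {
    inds <- sort(unique(res$sami$indicator))
    averaged <- lapply(inds, function(ind) {
      average_models(Filter(function(m) m$indicator == ind, res$models))
    })
    names(averaged) <- inds
    pred <- predict_next(res$sami, averaged, from_year = years[length(years)],
                         horizon_year = horizon_year)
    p <- file.path(out_dir, "forecast.csv")
    write_sami_table(pred, p, meta)
    note("forecast", p)
    list(averaged = averaged, predictions = pred)
  })

  res$changes <- stage("changes", {
    latest <- res$sami[res$sami$year == years[length(years)],
                       c("city_id", "indicator", "year", "D")]
    ch <- sami_changes(res$forecast$predictions, latest)
    p <- file.path(out_dir, "predicted_changes.csv")
    .write_csv_meta(ch, p, meta)
    note("changes", p)
    ch
  })

  if (!is.null(coords)) {
    res$geojson <- stage("change_geojson", {
      p <- file.path(out_dir, "predicted_changes.geojson")
      # one layer per indicator would be large; ship the mean change per city
      mean_ch <- res$changes |>
        dplyr::group_by(.data$city_id) |>
        dplyr::summarise(delta = mean(.data$delta), .groups = "drop")
      write_change_geojson(mean_ch, coords, p)
      note("change_geojson", p)
      p
    })
  }

  if (make_plots) {
    res$plots <- stage("plots", {
      paths <- c()
      gp <- file.path(out_dir, "group_means.pdf")
      ggplot2::ggsave(gp, plot_group_means(res$group_summary),
                      width = 12, height = 6)
      note("plot_group_means", gp, hashed = FALSE)
      mp <- file.path(out_dir, "memory_scatter.pdf")
      ggplot2::ggsave(mp, plot_memory_scatter(res$memory$fits$fits[[1]]),
                      width = 6, height = 5)
      note("plot_memory_scatter", mp, hashed = FALSE)
      if (!is.null(coords)) {
        cp <- file.path(out_dir, "change_map.pdf")
        ggplot2::ggsave(cp, render_change_map(res$changes, coords),
                        width = 10, height = 8)
        note("plot_change_map", cp, hashed = FALSE)
      }
      c(paths, gp, mp)
    })
  }

  res$manifest <- dplyr::bind_rows(manifest)
  mpath <- file.path(out_dir, "manifest.csv")
  .write_csv_meta(res$manifest, mpath, meta)
  invisible(res)
}
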