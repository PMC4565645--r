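# Tabular I/O with a fixed dialect: UTF-8, comma separator, "." decimal mark,
# header row, empty cells for missing values. City identifiers are always
# read and written as strings so that zero-padded municipality codes survive
# round trips. Metadata (seed, config hash) travels in leading '#' comment
# lines, which all readers here skip.

.meta_header <- function(meta) {
  if (is.null(meta) || length(meta) == 0) return(character())
  paste0("# ", names(meta), ": ", unlist(meta))
}

.write_csv_meta <- function(df, path, meta = NULL) {
  hdr <- .meta_header(meta)
  if (length(hdr)) {
    writeLines(hdr, path)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_csv(df, path)
  }
  invisible(path)
}

#' Indicators configured for a panel
#'
#' @param panel a census panel.
#' @return character vector of indicator column names (the `indicators`
#'   attribute if present, otherwise the canonical set intersected with the
#'   panel's columns).
#' @export
panel_indicators <- function(panel) {
  ind <- attr(panel, "indicators")
  if (is.null(ind)) ind <- intersect(urban_indicators(), names(panel))
  ind
}

.as_census_panel <- function(df, indicators) {
  df <- as_tibble(df)
  dup <- duplicated(df[c("city_id", "year")])
  if (any(dup)) {
    k <- df[dup, c("city_id", "year")][1, ]
    stop("integrity error: duplicate (city_id, year) pair: (",
         k$city_id, ", ", k$year, ")", call. = FALSE)
  }
  structure(df, indicators = indicators, class = c("census_panel", class(df)))
}

#' Read a city-census panel from CSV
#'
#' Expects one row per municipality per census year. The wide layout (default)
#' has columns `city_id`, `city_name`, `state`, `year`, `population` plus one
#' column per indicator; the long layout instead has `indicator` and `value`
#' columns and is pivoted on read. Rows with missing or nonpositive population
#' are dropped and counted. Rows missing an indicator value are retained (each
#' indicator-year analysis uses all rows valid for it), but excluded from the
#' "complete" city set — the cities holding all configured indicators in all
#' census years, which is the subset the headline pipeline runs on.
#'
#' @param path CSV file path.
#' @param indicators indicator set expected; defaults to [urban_indicators()].
#'   Only those present in the file are required to be columns, unless
#'   `require_all = TRUE`.
#' @param layout `"wide"` (default) or `"long"`.
#' @param require_all error if any configured indicator column is absent.
#' @return A `census_panel` tibble with attributes `indicators`,
#'   `n_input_rows`, `n_dropped_population`, `n_incomplete_rows`,
#'   `complete_city_ids` (cities with every indicator in every year) and
#'   `n_complete_cities`.
#' @export
read_census_panel <- function(path, indicators = urban_indicators(),
                              layout = c("wide", "long"), require_all = FALSE) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(city_id = readr::col_character(),
                                                 .default = readr::col_guess()))
  mandatory <- c("city_id", "city_name", "state", "year", "population",
                 if (layout == "long") c("indicator", "value"))
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    stop("format error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (layout == "long") {
    raw <- tidyr::pivot_wider(raw, names_from = "indicator", values_from = "value")
  }
  present <- intersect(indicators, names(raw))
  if (require_all && length(present) < length(indicators)) {
    stop("format error: missing indicator column(s): ",
         paste(setdiff(indicators, present), collapse = ", "), call. = FALSE)
  }
  if (length(present) == 0) {
    stop("format error: no indicator column found among: ",
         paste(indicators, collapse = ", "), call. = FALSE)
  }
  n_input <- nrow(raw)
  ok_pop <- !is.na(raw$population) & raw$population > 0
  panel <- raw[ok_pop, , drop = FALSE]
  incomplete_row <- !complete.cases(panel[present])
  years <- sort(unique(panel$year))
  per_city_ok <- stats::aggregate(
    cbind(ok = !incomplete_row, n = 1L) ~ city_id, data = panel, FUN = sum
  )
  complete_ids <- per_city_ok$city_id[
    per_city_ok$ok == length(years) & per_city_ok$n == length(years)
  ]
  out <- .as_census_panel(panel, present)
  attr(out, "n_input_rows") <- n_input
  attr(out, "n_dropped_population") <- n_input - nrow(panel)
  attr(out, "n_incomplete_rows") <- sum(incomplete_row)
  attr(out, "complete_city_ids") <- sort(complete_ids)
  attr(out, "n_complete_cities") <- length(complete_ids)
  out
}

#' Write a census panel to CSV
#'
#' @param panel a `census_panel`.
#' @param path output path.
#' @param meta optional named list written as `#`-comment header lines.
#' @return the path, invisibly.
#' @export
write_census_panel <- function(panel, path, meta = NULL) {
  stopifnot(nrow(panel) > 0)
  .write_csv_meta(as_tibble(panel), path, meta)
}

#' Restrict a panel to its complete cities
#'
#' Keeps only cities for which every configured indicator is present in every
#' census year of the panel — the complete-case filter the headline analysis
#' runs on.
#'
#' @param panel a `census_panel`.
#' @return filtered `census_panel` (attributes preserved and updated).
#' @export
complete_cities <- function(panel) {
  ind <- panel_indicators(panel)
  years <- sort(unique(panel$year))
  ok <- complete.cases(panel[ind]) & !is.na(panel$population) & panel$population > 0
  cnt <- tapply(ok, panel$city_id, sum)
  nyr <- tapply(ok, panel$city_id, length)
  keep_ids <- names(cnt)[cnt == length(years) & nyr == length(years)]
  out <- panel[panel$city_id %in% keep_ids, , drop = FALSE]
  attr(out, "indicators") <- ind
  attr(out, "complete_city_ids") <- sort(keep_ids)
  attr(out, "n_complete_cities") <- length(keep_ids)
  out
}

#' Read a table of scale-adjusted metrics
#'
#' Long layout (default) expects columns `city_id`, `indicator`, `year`, `D`
#' (plus optional `baseline_label`); arbitrary source column names can be
#' mapped via `col_map`. The wide layout accepts one `city_id` column plus one
#' column per indicator-year named `<indicator>_<year>` (the shape of
#' published per-city metric tables) and is reshaped long. `.xls`/`.xlsx`
#' files are read with \pkg{readxl} when available.
#'
#' @param path CSV or XLS/XLSX path.
#' @param col_map optional named character vector mapping standard names to
#'   source names, e.g. `c(city_id = "ibge", D = "sami")`.
#' @param layout `"long"` or `"wide"`.
#' @return tibble with columns `city_id`, `indicator`, `year`, `D` (and
#'   `baseline_label` when present).
#' @export
read_sami_table <- function(path, col_map = NULL, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xls", "xlsx")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("readxl is required to read ", ext, " files", call. = FALSE)
    }
    raw <- readxl::read_excel(path)
    raw$city_id <- as.character(raw[[if (!is.null(col_map) && "city_id" %in% names(col_map)) col_map[["city_id"]] else "city_id"]])
  } else {
    raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  }
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(raw)) {
        stop("format error: mapped column '", col_map[[std]], "' not found", call. = FALSE)
      }
      names(raw)[names(raw) == col_map[[std]]] <- std
    }
  }
  if (layout == "wide") {
    if (!"city_id" %in% names(raw)) stop("format error: missing mandatory column: city_id", call. = FALSE)
    raw <- tidyr::pivot_longer(raw, -dplyr::any_of(c("city_id")),
                               names_to = c("indicator", "year"),
                               names_pattern = "^(.*)_(\\d{4})$", values_to = "D")
  }
  need <- c("city_id", "indicator", "year", "D")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("format error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  d_num <- suppressWarnings(as.numeric(raw$D))
  bad <- which(!is.na(raw$D) & raw$D != "" & is.na(d_num))
  if (length(bad)) {
    stop("parse error: non-numeric D value at data row ", bad[1],
         " ('", raw$D[bad[1]], "')", call. = FALSE)
  }
  out <- tibble(
    city_id = as.character(raw$city_id),
    indicator = as.character(raw$indicator),
    year = as.integer(raw$year),
    D = d_num
  )
  if ("baseline_label" %in% names(raw)) out$baseline_label <- as.character(raw$baseline_label)
  out
}

#' Write a table of scale-adjusted metrics
#'
#' Values survive a write-read round trip exactly (doubles are serialized at
#' full precision).
#'
#' @param table tibble with `city_id`, `indicator`, `year`, `D`.
#' @param path output CSV path.
#' @param meta optional named list written as `#`-comment header lines.
#' @return the path, invisibly.
#' @export
write_sami_table <- function(table, path, meta = NULL) {
  if (is.null(table) || nrow(table) == 0) {
    stop("refusing to write an empty scale-adjusted metric table", call. = FALSE)
  }
  need <- c("city_id", "indicator", "year", "D")
  stopifnot(all(need %in% names(table)))
  .write_csv_meta(table, path, meta)
}

#' Read a city-coordinate table
#'
#' @param path CSV with columns `city_id`, `latitude`, `longitude`.
#' @return tibble; coordinates validated to lie in range, `city_id` unique.
#' @export
read_coordinates <- function(path) {
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(city_id = readr::col_character(),
                                                 .default = readr::col_double()))
  missing_cols <- setdiff(c("city_id", "latitude", "longitude"), names(raw))
  if (length(missing_cols)) {
    stop("format error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$city_id)) stop("integrity error: duplicate city_id in coordinates", call. = FALSE)
  if (any(abs(raw$latitude) > 90, na.rm = TRUE)) stop("latitude outside [-90, 90]", call. = FALSE)
  if (any(abs(raw$longitude) > 180, na.rm = TRUE)) stop("longitude outside [-180, 180]", call. = FALSE)
  raw
}

#' Write predicted changes as a GeoJSON bubble layer
#'
#' Emits an RFC 7946 FeatureCollection with one Point feature per city
#' (longitude-latitude order). Each feature carries properties `city_id`,
#' `delta` (the change in the scale-adjusted metric), `radius`
#' (`scale * abs(delta)`) and `sign` (`"increase"` for `delta > 0`,
#' `"decrease"` otherwise — a zero change counts as a decrease). Cities
#' without coordinates are skipped, not fatal; their ids are returned.
#'
#' @param changes tibble with columns `city_id` and `delta`.
#' @param coords coordinate table (see [read_coordinates()]).
#' @param path output `.geojson` path.
#' @param scale multiplier from `abs(delta)` to the stored radius.
#' @return invisibly, a list with `n_written` and `skipped` (city ids lacking
#'   coordinates).
#' @export
write_change_geojson <- function(changes, coords, path, scale = 1) {
  stopifnot(all(c("city_id", "delta") %in% names(changes)))
  m <- dplyr::inner_join(changes, coords, by = "city_id")
  skipped <- setdiff(changes$city_id, m$city_id)
  features <- lapply(seq_len(nrow(m)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(m$longitude[i], m$latitude[i])),
      properties = list(
        city_id = m$city_id[i],
        delta = m$delta[i],
        radius = scale * abs(m$delta[i]),
        sign = if (m$delta[i] > 0) "increase" else "decrease"
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(skipped)) {
    message(length(skipped), " city(ies) skipped for missing coordinates: ",
            paste(head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ...")
  }
  invisible(list(n_written = nrow(m), skipped = skipped))
}
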