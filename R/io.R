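#' @name schemas
#' @title Tidy CSV schemas
#' @description
#' All stages exchange three tidy long-format CSV tables (ISO-8601 dates,
#' units implicit per column):
#'
#' * `water.csv`: `station_id, site_id, date, temperature, salinity, do, ph,
#'   no3_n, no2_n, nh4, po4_p, dsi, chla` (one row per site-date; a `season`
#'   column is derived from the month map when absent).
#' * `ctd.csv`: `station_id, date, axis_km, depth_m, salinity, temperature`
#'   (depth-ordered rows within a cast; `temperature` optional).
#' * `counts.csv`: `source, sample_id, fish_length_cm, fish_weight_g, genus,
#'   phylum, count` (one row per taxon per sample; fish columns present only
#'   for `source = "gut"`; an optional `date` column carries the sampling
#'   date so compositions can be split by season).
NULL

.water_value_cols <- c("temperature", "salinity", "do", "ph",
                       "no3_n", "no2_n", "nh4", "po4_p", "dsi", "chla")
.water_nonneg_cols <- c("salinity", "do", "no3_n", "no2_n", "nh4",
                        "po4_p", "dsi", "chla")
.known_phyla <- c("Bacillariophyta", "Chlorophyta", "Cyanobacteria",
                  "Euglenophyta", "Xanthophyta", "Miozoa", "Other")

.check_columns <- function(df, required, what) {
  names(df) <- tolower(names(df))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s: missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  df
}

.validate_water <- function(df) {
  for (col in .water_nonneg_cols) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad) > 0L)
      stop(sprintf("water table: negative %s at row %d", col, bad[1]),
           call. = FALSE)
  }
  bad_ph <- which(!is.na(df$ph) & (df$ph < 0 | df$ph > 14))
  if (length(bad_ph) > 0L)
    stop(sprintf("water table: ph outside [0, 14] at row %d", bad_ph[1]),
         call. = FALSE)
  df
}

#' Read a water-quality panel
#'
#' Reads the ten-parameter physico-chemical panel (temperature, salinity,
#' DO, pH, nitrate-N, nitrite-N, ammonium, phosphate/DIP, dissolved silica,
#' chlorophyll-a) from a tidy CSV, validates invariants (non-negative
#' concentrations, pH in 0-14) and fills the `season` column from the
#' configured month map when absent.
#'
#' @param path CSV file following the `water.csv` schema (see [schemas]).
#' @param config an [analysis_config()].
#' @return a `data.frame` of class `water_panel`.
#' @export
read_water_table <- function(path, config = analysis_config()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_water_panel(df, config)
}

#' Coerce a data frame to a validated water panel
#'
#' @param df data frame with the `water.csv` columns.
#' @inheritParams read_water_table
#' @return a `data.frame` of class `water_panel`.
#' @export
as_water_panel <- function(df, config = analysis_config()) {
  df <- .check_columns(df, c("station_id", "site_id", "date",
                             .water_value_cols), "water table")
  df$date <- as.Date(df$date)
  if (is.null(df$season))
    df$season <- season_of_month(as.integer(format(df$date, "%m")), config)
  df <- .validate_water(df)
  class(df) <- c("water_panel", "data.frame")
  df
}

#' Write a water panel to CSV
#' @param df a water panel data frame.
#' @param path output CSV path.
#' @export
write_water_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Derive dissolved inorganic nitrogen
#'
#' DIN is the sum of the three measured nitrogen species (nitrate-N,
#' nitrite-N and ammonium); the ammonium fraction of DIN tracks which
#' species dominates the pool. The fraction is undefined (NA) when DIN is
#' zero.
#'
#' @param x a water panel data frame (or any data frame with columns
#'   `no3_n`, `no2_n`, `nh4`).
#' @return `x` with columns `din` and `nh4_fraction_of_din` appended.
#' @export
#' @examples
#' derive_nutrients(data.frame(no3_n = 0.05, no2_n = 0.008, nh4 = 0.06))
derive_nutrients <- function(x) {
  for (col in c("no3_n", "no2_n", "nh4"))
    if (is.null(x[[col]]))
      stop("missing nitrogen species: ", col, call. = FALSE)
  x$din <- x$no3_n + x$no2_n + x$nh4
  x$nh4_fraction_of_din <- ifelse(!is.na(x$din) & x$din > 0,
                                  x$nh4 / x$din, NA_real_)
  x
}

#' Read a CTD section
#'
#' @param path CSV file following the `ctd.csv` schema (see [schemas]).
#' @return a `data.frame` of class `ctd_table`.
#' @export
read_ctd_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- .check_columns(df, c("station_id", "date", "axis_km", "depth_m",
                             "salinity"), "ctd table")
  if (any(!is.na(df$salinity) & df$salinity < 0))
    stop("ctd table: negative salinity", call. = FALSE)
  df$date <- as.Date(df$date)
  class(df) <- c("ctd_table", "data.frame")
  df
}

#' Write a CTD table to CSV
#' @param df a CTD data frame.
#' @param path output CSV path.
#' @export
write_ctd_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Split a CTD table into casts
#'
#' A cast is one station-date profile with depth-ordered salinity (and
#' optionally temperature). Depths must be unique within a cast; rows are
#' ordered surface first.
#'
#' @param df a CTD data frame (long format).
#' @return list of `ctd_cast` objects with fields `station_id`, `date`,
#'   `axis_km`, `depths`, `salinity`, `temperature`.
#' @export
as_ctd_casts <- function(df) {
  key <- interaction(df$station_id, df$date, drop = TRUE)
  lapply(split(seq_len(nrow(df)), key), function(idx) {
    sub <- df[idx, ]
    ord <- order(sub$depth_m)
    sub <- sub[ord, ]
    if (anyDuplicated(sub$depth_m))
      stop(sprintf("cast %s %s: duplicate depth levels",
                   sub$station_id[1], sub$date[1]), call. = FALSE)
    structure(list(station_id = sub$station_id[1],
                   date = sub$date[1],
                   axis_km = sub$axis_km[1],
                   depths = sub$depth_m,
                   salinity = sub$salinity,
                   temperature = sub$temperature),
              class = "ctd_cast")
  })
}

#' Read a taxon count table
#'
#' @param path CSV file following the `counts.csv` schema (see [schemas]).
#' @return a `data.frame` of class `counts_table`.
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_counts_table(df)
}

#' Coerce and validate a taxon count table
#'
#' Counts must be non-negative integers, genus labels unique within a
#' sample, sources in `{water, gut}`, and gut samples must carry a fish
#' length within the accepted 10-50 cm range.
#'
#' @param df data frame with the `counts.csv` columns.
#' @return a `data.frame` of class `counts_table`.
#' @export
as_counts_table <- function(df) {
  df <- .check_columns(df, c("source", "sample_id", "genus", "phylum",
                             "count"), "counts table")
  if (!all(df$source %in% c("water", "gut")))
    stop("counts table: source must be 'water' or 'gut'", call. = FALSE)
  bad <- which(is.na(df$count) | df$count < 0 |
                 df$count != round(df$count))
  if (length(bad) > 0L)
    stop(sprintf("counts table: count must be a non-negative integer (row %d)",
                 bad[1]), call. = FALSE)
  dup <- stats::aggregate(list(n = df$count),
                          by = list(sample_id = df$sample_id,
                                    genus = df$genus), FUN = length)
  if (any(dup$n > 1L))
    stop(sprintf("counts table: duplicate genus '%s' in sample %s",
                 dup$genus[dup$n > 1L][1], dup$sample_id[dup$n > 1L][1]),
         call. = FALSE)
  gut <- df[df$source == "gut", ]
  if (nrow(gut) > 0L) {
    if (is.null(gut$fish_length_cm) || anyNA(gut$fish_length_cm))
      stop("counts table: gut samples require fish_length_cm", call. = FALSE)
    if (any(gut$fish_length_cm < 10 | gut$fish_length_cm > 50))
      stop("counts table: fish_length_cm outside accepted 10-50 cm range",
           call. = FALSE)
  }
  class(df) <- c("counts_table", "data.frame")
  df
}

#' Write a counts table to CSV
#' @param df a counts data frame.
#' @param path output CSV path.
#' @export
write_counts_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
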