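#' Trophic-state thresholds
#'
#' Per-indicator percentile choice and class bounds for the four trophic
#' indicators. The nutrient indicators (DIN, DIP) are summarised at the
#' 80th percentile, dissolved silica at the 10th (its orientation is
#' reversed: higher silica is the healthier state, since diatom blooms
#' deplete it), and phytoplankton biomass (chlorophyll-a) at the 90th.
#' Classes: Good = oligotrophic, Fair = mesotrophic, Poor = eutrophic,
#' Very poor = hypereutrophic.
#'
#' Default bounds (statistic `s`, indicator units mg/L except chl-a ug/L):
#' * DIN: good `s < 0.1`; fair `0.1 <= s < 1`; poor `s >= 1`.
#' * DIP: good `s < 0.01`; fair `0.01 <= s < 0.1`; poor `s >= 0.1`.
#' * DSi (reversed): good `s > 5`; fair `2 < s <= 5`; poor `s <= 2`.
#' * Chl-a: good `s <= 5`; fair `5 < s <= 20`; poor `20 < s <= 60`;
#'   very poor `s > 60`.
#'
#' Exact boundary membership on the nutrient scales is resolved upward
#' (e.g. DIN = 1 is poor), matching the published ranges' closure.
#'
#' @return named list of per-indicator threshold definitions.
#' @export
trophic_thresholds <- function() {
  list(
    din = list(percentile = 80, bounds = c(0.1, 1), reversed = FALSE,
               states = c("good_oligotrophic", "fair_mesotrophic",
                          "poor_eutrophic")),
    dip = list(percentile = 80, bounds = c(0.01, 0.1), reversed = FALSE,
               states = c("good_oligotrophic", "fair_mesotrophic",
                          "poor_eutrophic")),
    dsi = list(percentile = 10, bounds = c(2, 5), reversed = TRUE,
               states = c("good_oligotrophic", "fair_mesotrophic",
                          "poor_eutrophic")),
    chla = list(percentile = 90, bounds = c(5, 20, 60), reversed = FALSE,
                states = c("good_oligotrophic", "fair_mesotrophic",
                           "poor_eutrophic", "very_poor_hypereutrophic")))
}

#' Percentile statistic of an indicator
#'
#' The configured percentile of the seasonal values, computed by linear
#' interpolation between order statistics (the default quantile convention
#' of most statistical software; configurable via `type`).
#'
#' @param values numeric vector; missing values are dropped.
#' @param percentile percent in (0, 100).
#' @param type quantile algorithm passed to [stats::quantile()].
#' @return the percentile value.
#' @export
#' @examples
#' indicator_statistic(1:5, 80)  # 4.2
indicator_statistic <- function(values, percentile, type = 7) {
  values <- values[!is.na(values)]
  if (length(values) == 0L)
    stop("indicator_statistic needs at least one value")
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must be in (0, 100)")
  unname(stats::quantile(values, percentile / 100, type = type))
}

#' Classify a trophic indicator statistic
#'
#' Applies the per-indicator class bounds (see [trophic_thresholds()]) to a
#' percentile statistic. DIN/DIP classify upward at exact bounds; silica
#' runs in the reversed orientation (good above 5, poor at or below 2);
#' chlorophyll-a uses the four-class biomass scale.
#'
#' @param indicator one of `"din"`, `"dip"`, `"dsi"`, `"chla"`.
#' @param statistic finite numeric value.
#' @param thresholds threshold list, default [trophic_thresholds()].
#' @return the state label.
#' @export
#' @examples
#' classify_trophic("din", 0.29)   # fair_mesotrophic
#' classify_trophic("dsi", 8.1)    # good_oligotrophic
classify_trophic <- function(indicator, statistic,
                             thresholds = trophic_thresholds()) {
  th <- thresholds[[indicator]]
  if (is.null(th)) stop("unknown indicator: ", indicator)
  if (!is.finite(statistic)) stop("statistic must be finite")
  if (indicator == "chla") {
    b <- th$bounds
    state <- if (statistic <= b[1]) th$states[1]
             else if (statistic <= b[2]) th$states[2]
             else if (statistic <= b[3]) th$states[3]
             else th$states[4]
    return(state)
  }
  if (th$reversed) {
    b <- th$bounds  # c(2, 5): poor <= 2 < fair <= 5 < good
    if (statistic > b[2]) th$states[1]
    else if (statistic > b[1]) th$states[2]
    else th$states[3]
  } else {
    b <- th$bounds
    if (statistic < b[1]) th$states[1]
    else if (statistic < b[2]) th$states[2]
    else th$states[3]
  }
}

#' Three-state estuary class from an upper-percentile chlorophyll-a value
#'
#' The coarser biomass-only scheme: oligotrophic up to 5 ug/L, mesotrophic
#' above 5 up to 20, eutrophic above 20 (boundary values belong to the
#' class on the left).
#'
#' @param p80_chla upper-percentile chlorophyll-a, ug/L, non-negative.
#' @return `"oligotrophic"`, `"mesotrophic"` or `"eutrophic"`.
#' @export
#' @examples
#' chla_estuary_class(6.8)  # mesotrophic
chla_estuary_class <- function(p80_chla) {
  if (is.na(p80_chla) || p80_chla < 0)
    stop("chlorophyll-a must be non-negative")
  if (p80_chla <= 5) "oligotrophic"
  else if (p80_chla <= 20) "mesotrophic"
  else "eutrophic"
}

#' Seasonal trophic report for a water panel
#'
#' Derives DIN, takes each indicator's configured percentile of the
#' seasonal values and classifies it.
#'
#' @param water a `water_panel` data frame.
#' @param season `"dry"`, `"wet"`, or `NULL` for all records.
#' @param thresholds threshold list, default [trophic_thresholds()].
#' @return data frame with `indicator`, `season`, `percentile`,
#'   `statistic`, `state`.
#' @export
trophic_report <- function(water, season = NULL,
                           thresholds = trophic_thresholds()) {
  if (!is.null(season)) water <- water[water$season == season, ]
  if (nrow(water) == 0L) stop("no records for the requested season")
  water <- derive_nutrients(water)
  vals <- list(din = water$din, dip = water$po4_p, dsi = water$dsi,
               chla = water$chla)
  rows <- lapply(names(thresholds), function(ind) {
    th <- thresholds[[ind]]
    stat <- indicator_statistic(vals[[ind]], th$percentile)
    data.frame(indicator = ind,
               season = if (is.null(season)) "all" else season,
               percentile = th$percentile, statistic = stat,
               state = classify_trophic(ind, stat, thresholds),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
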