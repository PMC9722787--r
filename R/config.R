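#' Analysis configuration
#'
#' Bundles the conventions shared by all stages: the month-to-season map,
#' Venice salinity class boundaries, stratification-parameter mixing
#' thresholds, trophic thresholds, correlation star levels, and the RNG seed.
#'
#' The default season map follows the monsoonal low-flow/high-flow cycle:
#' December-March is the dry season and July-October the wet season. Months
#' outside both sets (the pre- and post-monsoon transitions, e.g. April and
#' June) are labelled `"transitional"` and excluded from seasonal tests.
#'
#' @param month_to_season named list with integer month vectors `dry` and
#'   `wet`; the two sets must be disjoint.
#' @param venice_boundaries increasing PSU cut points separating freshwater,
#'   oligohaline, mesohaline, polyhaline and euhaline waters.
#' @param mixing_thresholds two increasing cut points on the stratification
#'   parameter separating well-mixed, partially mixed and stratified columns.
#' @param correlation_star_levels decreasing p-value levels for one, two and
#'   three significance stars.
#' @param trophic_thresholds per-indicator thresholds, see
#'   [trophic_thresholds()].
#' @param rng_seed integer seed used by stages that randomise.
#' @return an object of class `analysis_config`.
#' @seealso [season_of_month()], [venice_class()], [stratification()]
#' @export
#' @examples
#' cfg <- analysis_config()
#' season_of_month(1, cfg)
analysis_config <- function(month_to_season = list(dry = c(12L, 1L, 2L, 3L),
                                                   wet = c(7L, 8L, 9L, 10L)),
                            venice_boundaries = c(freshwater = 0.5,
                                                  oligohaline = 5,
                                                  mesohaline = 18,
                                                  polyhaline = 30),
                            mixing_thresholds = c(0.1, 1.0),
                            correlation_star_levels = c(0.05, 0.01, 0.001),
                            trophic_thresholds = NULL,
                            rng_seed = 1L) {
  stopifnot(is.list(month_to_season),
            all(c("dry", "wet") %in% names(month_to_season)))
  if (length(intersect(month_to_season$dry, month_to_season$wet)) > 0L)
    stop("dry and wet month sets overlap")
  if (is.unsorted(venice_boundaries, strictly = TRUE))
    stop("venice_boundaries must be strictly increasing")
  if (length(mixing_thresholds) != 2L ||
      is.unsorted(mixing_thresholds, strictly = TRUE))
    stop("mixing_thresholds must be two strictly increasing values")
  if (is.unsorted(rev(correlation_star_levels), strictly = TRUE))
    stop("correlation_star_levels must be strictly decreasing")
  if (is.null(trophic_thresholds)) trophic_thresholds <- trophic_thresholds()
  structure(list(month_to_season = lapply(month_to_season, as.integer),
                 venice_boundaries = venice_boundaries,
                 mixing_thresholds = mixing_thresholds,
                 correlation_star_levels = correlation_star_levels,
                 trophic_thresholds = trophic_thresholds,
                 rng_seed = as.integer(rng_seed)),
            class = "analysis_config")
}

#' Map calendar months to hydrological seasons
#'
#' @param month integer month(s) 1-12.
#' @param config an [analysis_config()].
#' @return character vector: `"dry"`, `"wet"` or `"transitional"`.
#' @export
season_of_month <- function(month, config = analysis_config()) {
  month <- as.integer(month)
  if (any(is.na(month) | month < 1L | month > 12L))
    stop("month must be in 1..12")
  out <- rep("transitional", length(month))
  out[month %in% config$month_to_season$dry] <- "dry"
  out[month %in% config$month_to_season$wet] <- "wet"
  out
}

# Rounding used for reported percentages. Inputs carried at one decimal can
# sit an ulp below the exact half (53.65 is stored as 53.6499...), so nudge
# upward by an amount far below the data's resolution before rounding.
round_half_up <- function(x, digits = 1) {
  round(x + sign(x) * 1e-8, digits)
}
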