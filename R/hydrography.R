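#' Stratification parameter of a CTD cast
#'
#' The stratification parameter is the surface-to-bottom salinity difference
#' normalised by the depth-mean salinity,
#' \deqn{n_s = (S_{bot} - S_{sur}) / \tfrac{1}{2}(S_{bot} + S_{sur}),}
#' taking surface and bottom from the first and last recorded levels. A
#' column is well mixed when \eqn{n_s < 0.1}, partially mixed between 0.1
#' and 1, and stratified above 1. When both levels are fresh (depth-mean
#' salinity zero) the class is `"undefined"`.
#'
#' @param cast a `ctd_cast` (see [as_ctd_casts()]) or a list with `depths`
#'   and `salinity`.
#' @param config an [analysis_config()] supplying the mixing thresholds.
#' @return an object of class `stratification`: `s_sur`, `s_bot`, `delta_s`,
#'   `s_m`, `n_s`, `mixing_class`.
#' @export
#' @examples
#' cast <- list(depths = c(1, 10), salinity = c(12.0, 12.1))
#' stratification(cast)$mixing_class
stratification <- function(cast, config = analysis_config()) {
  if (length(cast$depths) < 2L)
    stop("stratification needs at least two depth levels", call. = FALSE)
  if (is.unsorted(cast$depths, strictly = TRUE))
    stop("cast depths must be strictly increasing", call. = FALSE)
  s_sur <- cast$salinity[1L]
  s_bot <- cast$salinity[length(cast$salinity)]
  delta_s <- s_bot - s_sur
  s_m <- (s_bot + s_sur) / 2
  th <- config$mixing_thresholds
  if (s_m == 0) {
    n_s <- NA_real_
    mixing_class <- "undefined"
  } else {
    n_s <- delta_s / s_m
    mixing_class <- if (n_s < th[1]) "well_mixed"
                    else if (n_s <= th[2]) "partially_mixed"
                    else "stratified"
  }
  structure(list(station_id = cast$station_id, date = cast$date,
                 axis_km = cast$axis_km,
                 s_sur = s_sur, s_bot = s_bot, delta_s = delta_s,
                 s_m = s_m, n_s = n_s, mixing_class = mixing_class),
            class = "stratification")
}

#' Stratification of every cast in a section
#'
#' @param casts list of `ctd_cast` objects, or a `ctd_table` data frame.
#' @inheritParams stratification
#' @return data frame with one row per cast.
#' @export
stratify_section <- function(casts, config = analysis_config()) {
  if (is.data.frame(casts)) casts <- as_ctd_casts(casts)
  rows <- lapply(casts, function(cc) {
    st <- stratification(cc, config)
    data.frame(station_id = st$station_id %||% NA_character_,
               date = as.character(st$date %||% NA),
               axis_km = st$axis_km %||% NA_real_,
               s_sur = st$s_sur, s_bot = st$s_bot, delta_s = st$delta_s,
               s_m = st$s_m, n_s = st$n_s, mixing_class = st$mixing_class,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$axis_km, out$date), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Venice salinity class
#'
#' Classifies water by salinity into the Venice-system zones: freshwater
#' (< 0.5 PSU), oligohaline (0.5-5), mesohaline (5-18), polyhaline (18-30)
#' and euhaline (> 30). Boundaries are half-open on the low side, so 0.5
#' PSU is oligohaline and 5 PSU mesohaline.
#'
#' @param salinity numeric vector, PSU, non-negative.
#' @param config an [analysis_config()] supplying the boundaries.
#' @return character vector of class labels.
#' @export
#' @examples
#' venice_class(c(0.3, 0.5, 13, 25, 31))
venice_class <- function(salinity, config = analysis_config()) {
  if (any(is.na(salinity)) || any(salinity < 0))
    stop("salinity must be non-negative", call. = FALSE)
  b <- config$venice_boundaries
  labels <- c("freshwater", "oligohaline", "mesohaline", "polyhaline",
              "euhaline")
  idx <- findInterval(salinity, b) + 1L
  labels[idx]
}

#' Hilsa habitat suitability from salinity
#'
#' Hilsa shad uses nested salinity windows across its life cycle: spawning
#' in freshwater below 0.1 PSU, juvenile nursery in 0-1 PSU estuarine
#' water, and brood fish in 0-2 PSU estuarine and coastal water, so any
#' water suitable for spawning is also suitable for nursery and brood use.
#'
#' @param salinity scalar salinity, PSU, non-negative.
#' @param config an [analysis_config()].
#' @return an object of class `habitat_assessment`: `salinity`,
#'   `suitable_stages` (character subset of spawning/nursery/brood) and
#'   `venice_class`.
#' @export
#' @examples
#' habitat_suitability(0.05)$suitable_stages
habitat_suitability <- function(salinity, config = analysis_config()) {
  if (is.na(salinity) || salinity < 0)
    stop("salinity must be non-negative", call. = FALSE)
  stages <- c("spawning", "nursery", "brood")
  ok <- c(salinity < 0.1, salinity <= 1, salinity <= 2)
  structure(list(salinity = salinity,
                 suitable_stages = stages[ok],
                 venice_class = venice_class(salinity, config)),
            class = "habitat_assessment")
}

#' Along-axis position of a near-bottom isohaline
#'
#' Tracks the salt intrusion by interpolating the bottom salinity of a
#' section (casts ordered seaward by `axis_km`) at a target salinity,
#' default the 2 PSU isohaline. Returns the first landward crossing by
#' linear interpolation, the exact cast position on an exact hit, or `NA`
#' when the whole section sits on one side (e.g. a fresh wet-season
#' estuary).
#'
#' @param section list of `ctd_cast` objects or a `ctd_table` data frame.
#' @param iso target salinity, PSU.
#' @return axis position in km, or `NA_real_` when the isohaline is absent.
#' @export
isohaline_position <- function(section, iso = 2) {
  if (is.data.frame(section)) {
    # a long table carries its own axis coordinate; order casts seaward
    section <- as_ctd_casts(section)
    section <- section[order(vapply(section, function(cc) cc$axis_km,
                                    numeric(1)))]
  }
  axis <- vapply(section, function(cc) cc$axis_km, numeric(1))
  if (is.unsorted(axis))
    stop("section casts must be sorted by axis_km", call. = FALSE)
  bottom <- vapply(section, function(cc) cc$salinity[length(cc$salinity)],
                   numeric(1))
  for (i in seq_along(axis)) {
    if (bottom[i] == iso) return(axis[i])
    if (i < length(axis) &&
        (bottom[i] - iso) * (bottom[i + 1] - iso) < 0) {
      return(axis[i] + (axis[i + 1] - axis[i]) *
               (iso - bottom[i]) / (bottom[i + 1] - bottom[i]))
    }
  }
  NA_real_
}
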