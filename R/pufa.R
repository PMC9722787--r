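# Diet-to-fatty-acid attribution: annotate community or gut composition
# with literature PUFA fractions per phylum and reduce seasonal percent
# tables to the headline contribution numbers.

#' Literature PUFA fractions per phylum
#'
#' Percent of total fatty acids that are polyunsaturated, from published
#' meta-analysis of marine phytoplankton fatty-acid profiles: green algae
#' are the richest source (60%), diatoms and blue-green algae the poorest
#' (28% and 26%).
#'
#' @param overrides optional named numeric vector replacing or extending
#'   the defaults (percent, 0-100).
#' @return named numeric vector, percent PUFA of total fatty acids.
#' @export
pufa_table <- function(overrides = NULL) {
  tab <- c(Chlorophyta = 60, Bacillariophyta = 28, Cyanobacteria = 26)
  if (!is.null(overrides)) {
    if (any(overrides < 0 | overrides > 100))
      stop("PUFA percents must be in [0, 100]")
    tab[names(overrides)] <- overrides
  }
  tab
}

#' Season-averaged percent contribution per phylum
#'
#' Unweighted mean of the dry- and wet-season percent contributions of each
#' phylum for one source. A phylum recorded in only one season is averaged
#' with zero and flagged in the `flagged` attribute. Averages are returned
#' unrounded so downstream sums can round last; for display, round half-up
#' at one decimal (`digits = 1`), the convention that reproduces published
#' one-decimal tables.
#'
#' @param by_season named list with numeric percent vectors `dry` and
#'   `wet` (phylum names as names), e.g. one source's column of a seasonal
#'   composition table.
#' @param digits optional reporting precision; `NULL` (default) keeps the
#'   averages unrounded.
#' @return named numeric vector of season-averaged percents; attribute
#'   `flagged` lists phyla observed in a single season.
#' @export
#' @examples
#' gut <- list(dry = c(Chlorophyta = 45.8, Bacillariophyta = 21.6),
#'             wet = c(Chlorophyta = 61.5, Bacillariophyta = 23.5))
#' season_average_contribution(gut, digits = 1)
season_average_contribution <- function(by_season, digits = NULL) {
  if (!all(c("dry", "wet") %in% names(by_season)))
    stop("both seasons must be present")
  phyla <- union(names(by_season$dry), names(by_season$wet))
  dry <- by_season$dry[phyla]; names(dry) <- phyla
  wet <- by_season$wet[phyla]; names(wet) <- phyla
  flagged <- phyla[is.na(dry) | is.na(wet)]
  dry[is.na(dry)] <- 0; wet[is.na(wet)] <- 0
  avg <- (dry + wet) / 2
  if (!is.null(digits)) avg <- round_half_up(avg, digits)
  if (length(flagged) > 0L)
    warning("phyla present in one season only, averaged with 0: ",
            paste(flagged, collapse = ", "))
  attr(avg, "flagged") <- flagged
  avg
}

#' Combined contribution of a set of phyla
#'
#' Sum of (season-averaged or single-season) percent contributions over a
#' subset of phyla -- e.g. the share of the community covered by the three
#' PUFA-annotated groups.
#'
#' @param contributions named percent vector.
#' @param phyla character subset of `names(contributions)`.
#' @return percent (one decimal, half-up).
#' @export
combined_contribution <- function(contributions, phyla) {
  if (length(phyla) == 0L) stop("phyla subset must be non-empty")
  missing <- setdiff(phyla, names(contributions))
  if (length(missing) > 0L)
    stop("unknown phylum: ", paste(missing, collapse = ", "))
  round_half_up(sum(contributions[phyla]), 1)
}

#' Composition-weighted PUFA score
#'
#' Weights the PUFA fraction of each annotated phylum by its share of the
#' community: compositions are restricted to annotated phyla, renormalised
#' to sum to 1, and reduced to `sum(share * pufa_percent)`. The score
#' always lies between the smallest and largest annotated PUFA percent.
#'
#' @param composition named numeric vector of community shares (fractions
#'   or percents; renormalised internally).
#' @param pufa named percent vector, default [pufa_table()].
#' @return list: `score` (percent PUFA of total fatty acids of the
#'   consumed mix) and `annotated_mass` (fraction of the composition the
#'   annotation covers).
#' @export
#' @examples
#' pufa_weighted_score(c(Chlorophyta = 0.5, Bacillariophyta = 0.5))$score
pufa_weighted_score <- function(composition, pufa = pufa_table()) {
  annotated <- intersect(names(composition), names(pufa))
  if (length(annotated) == 0L)
    stop("no annotated phylum present in the composition")
  total <- sum(composition)
  if (total <= 0) stop("composition must have positive mass")
  mass <- sum(composition[annotated]) / total
  shares <- composition[annotated] / sum(composition[annotated])
  list(score = unname(sum(shares * pufa[annotated])),
       annotated_mass = unname(mass))
}
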