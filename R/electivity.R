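#' Pooled taxon proportions
#'
#' Pools counts across tables of one source and returns per-taxon
#' proportions of the grand total, the \eqn{a_i} (environment) or
#' \eqn{g_i} (gut) of the electivity index.
#'
#' @param counts a `counts_table` data frame; all rows must share one
#'   source.
#' @param level `"phylum"` or `"genus"`.
#' @return named numeric vector of proportions summing to 1.
#' @export
taxon_proportions <- function(counts, level = c("phylum", "genus")) {
  level <- match.arg(level)
  if (nrow(counts) == 0L) stop("taxon_proportions needs at least one table")
  if (length(unique(counts$source)) > 1L)
    stop("mixed sources: pool water and gut tables separately")
  tot <- tapply(counts$count, counts[[level]], sum)
  grand <- sum(tot)
  if (grand == 0) stop("grand total is zero")
  p <- stats::setNames(as.numeric(tot / grand), names(tot))
  p[order(names(p))]
}

#' Odds-ratio electivity index
#'
#' Compares a taxon's share of the predator's gut contents (`g`) with its
#' share of the environment (`a`) through the odds ratio
#' \deqn{O = \frac{g}{1-g} \cdot \frac{1-a}{a}}
#' and its logistic transform \deqn{X = O / (1 + O) \in [0, 1].}
#' X is 0.5 when gut and environment agree (O = 1), 1 at the `g = 1` limit
#' (exclusive feeding) and 0 at `g = 0` (complete avoidance); values above
#' 0.5 indicate positive selection.
#'
#' @param g gut proportion in `[0, 1]`.
#' @param a environmental proportion, strictly inside `(0, 1)`.
#' @param taxon optional taxon label carried through.
#' @param size_class optional size-class label carried through.
#' @return an object of class `electivity_result`: `taxon`, `a`, `g`,
#'   `odds_ratio`, `index`, `size_class`.
#' @export
#' @examples
#' electivity_index(0.3, 0.3)$index       # 0.5, the neutral point
#' electivity_index(0.615, 0.36)$index    # ~0.74, positive selection
electivity_index <- function(g, a, taxon = NA_character_,
                             size_class = "all") {
  if (is.na(g) || g < 0 || g > 1) stop("g must be in [0, 1]")
  if (is.na(a) || a <= 0 || a >= 1)
    stop("degenerate environmental proportion a = ", a,
         ": the taxon is absent from (or fills) the water sample; ",
         "use correction = \"add_half\" or drop the taxon", call. = FALSE)
  if (g == 1) {
    o <- Inf; x <- 1
  } else {
    # product form cancels exactly when g == a, so the neutral point is
    # O = 1, X = 0.5 in floating point too
    o <- (g * (1 - a)) / ((1 - g) * a)
    x <- o / (1 + o)
  }
  structure(list(taxon = taxon, a = a, g = g, odds_ratio = o, index = x,
                 size_class = size_class),
            class = "electivity_result")
}

.pooled_props <- function(counts, level, universe, correction) {
  tot <- tapply(counts$count, factor(counts[[level]], levels = universe),
                sum, default = 0)
  if (correction == "add_half") tot <- tot + 0.5
  stats::setNames(as.numeric(tot / sum(tot)), universe)
}

#' Electivity profile across taxa and fish size classes
#'
#' Computes the odds-ratio electivity index for every taxon in the union of
#' the water and gut tables, pooled over all fish (`size_class = "all"`)
#' and, when requested, within fork-length bins (defaults: small 10-20 cm,
#' medium 20-30 cm, large 30-35 cm; the last bin is closed). Fish outside
#' every bin are excluded with a warning. With `correction = "add_half"`
#' half a count is added to every taxon in both pooled samples
#' (Haldane-Anscombe style), which keeps the index defined when a taxon is
#' missing from one source; with the default `"none"`, a taxon absent from
#' the water sample is an error.
#'
#' @param water water-source `counts_table` rows.
#' @param gut gut-source `counts_table` rows (with `fish_length_cm`).
#' @param level `"phylum"` or `"genus"`.
#' @param size_bins increasing bin edges in cm, or `NULL` for pooled only.
#' @param correction `"none"` or `"add_half"`.
#' @return data frame of electivity results (one row per taxon per size
#'   class).
#' @export
electivity_profile <- function(water, gut, level = c("phylum", "genus"),
                               size_bins = c(10, 20, 30, 35),
                               correction = c("none", "add_half")) {
  level <- match.arg(level)
  correction <- match.arg(correction)
  if (nrow(water) == 0L || nrow(gut) == 0L)
    stop("both water and gut tables are required")
  stopifnot(all(water$source == "water"), all(gut$source == "gut"))
  universe <- sort(unique(c(water[[level]], gut[[level]])))
  a <- .pooled_props(water, level, universe, correction)
  classes <- list(all = gut)
  if (!is.null(size_bins)) {
    if (is.unsorted(size_bins, strictly = TRUE))
      stop("size_bins must be strictly increasing")
    len <- gut$fish_length_cm
    bin <- findInterval(len, size_bins, rightmost.closed = TRUE)
    outside <- bin == 0L | bin >= length(size_bins)
    if (any(outside)) {
      warning(sprintf("%d gut rows outside all size bins; excluded",
                      sum(outside)))
    }
    labels <- c("small", "medium", "large",
                paste0("bin", seq_len(max(0, length(size_bins) - 4))))
    for (b in seq_len(length(size_bins) - 1L)) {
      sub <- gut[!outside & bin == b, , drop = FALSE]
      if (nrow(sub) > 0L) classes[[labels[b]]] <- sub
    }
  }
  rows <- list()
  for (cls in names(classes)) {
    g <- .pooled_props(classes[[cls]], level, universe, correction)
    for (taxon in universe) {
      if (correction == "none" && (a[[taxon]] <= 0 || a[[taxon]] >= 1))
        stop("taxon '", taxon, "' has degenerate water proportion ",
             a[[taxon]], "; use correction = \"add_half\"", call. = FALSE)
      gi <- g[[taxon]]
      res <- if (gi == 0) {
        list(taxon = taxon, a = a[[taxon]], g = 0, odds_ratio = 0,
             index = 0, size_class = cls)
      } else {
        electivity_index(gi, a[[taxon]], taxon = taxon, size_class = cls)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(taxon = res$taxon, a = res$a, g = res$g,
                   odds_ratio = res$odds_ratio, index = res$index,
                   size_class = res$size_class, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
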