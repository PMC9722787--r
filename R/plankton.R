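#' Chlorophyll-a from trichromatic extract absorbances
#'
#' Evaluates the SCOR-UNESCO trichromatic equation on a solvent extract,
#' with the 750 nm reading subtracted from each band as a turbidity blank:
#' \deqn{chla = [11.64 (A_{663}-A_{750}) - 2.16 (A_{645}-A_{750}) +
#'   0.10 (A_{630}-A_{750})] \times v / (V \times l)}
#' where `v` is the extract volume (mL), `V` the filtered water volume (L)
#' and `l` the cuvette path length (cm). A negative result (possible with
#' noisy blanks) is floored at zero with a warning.
#'
#' @param a663,a645,a630,a750 absorbances.
#' @param extract_volume_ml extract volume, mL.
#' @param filtered_volume_l filtered water volume, L.
#' @param path_length_cm cuvette path length, cm.
#' @return chlorophyll-a concentration, ug/L.
#' @export
#' @examples
#' chlorophyll_a(0.1, 0, 0, 0, 10, 1, 1)  # 11.64
chlorophyll_a <- function(a663, a645, a630, a750 = 0,
                          extract_volume_ml = 10, filtered_volume_l = 1,
                          path_length_cm = 1) {
  if (filtered_volume_l <= 0) stop("filtered_volume_l must be positive")
  if (extract_volume_ml <= 0 || path_length_cm <= 0)
    stop("extract volume and path length must be positive")
  if (any(c(a663, a645, a630, a750) < 0))
    stop("absorbances must be non-negative")
  ca <- 11.64 * (a663 - a750) - 2.16 * (a645 - a750) +
    0.10 * (a630 - a750)
  chla <- ca * extract_volume_ml / (filtered_volume_l * path_length_cm)
  if (chla < 0) {
    warning("negative chlorophyll-a estimate floored at 0")
    chla <- 0
  }
  chla
}

#' Cell density from a Sedgwick-Rafter chamber count
#'
#' Converts a field count to cells per litre of original (pre-tow) water:
#' \deqn{density = \frac{cells}{fields \times v_{field}} \times
#'   \frac{1000}{concentration\ factor}}
#' with `v_field` the volume of one counted field in mL and the
#' concentration factor the net-tow volume concentration (original volume /
#' concentrate volume).
#'
#' @param cells_counted non-negative integer.
#' @param fields_counted number of chamber fields counted, >= 1.
#' @param field_volume_ml volume per field, mL.
#' @param concentration_factor dimensionless tow concentration.
#' @return cells/L.
#' @export
cell_density <- function(cells_counted, fields_counted, field_volume_ml,
                         concentration_factor = 1) {
  if (fields_counted < 1) stop("fields_counted must be >= 1")
  if (field_volume_ml <= 0 || concentration_factor <= 0)
    stop("volumes and concentration factor must be positive")
  if (cells_counted < 0) stop("cells_counted must be non-negative")
  cells_counted / (fields_counted * field_volume_ml) * 1000 /
    concentration_factor
}

#' Pooled community composition
#'
#' Pools counts across tables of one source and returns the percent
#' contribution of each phylum (or genus); percentages sum to 100 before
#' any rounding.
#'
#' @param counts a `counts_table` data frame (one source).
#' @param level `"phylum"` or `"genus"`.
#' @return named numeric vector of percents, sorted decreasing.
#' @export
composition <- function(counts, level = c("phylum", "genus")) {
  level <- match.arg(level)
  if (nrow(counts) == 0L) stop("composition needs at least one table")
  if (length(unique(counts$source)) > 1L)
    stop("composition requires a single source; split water and gut first")
  tot <- tapply(counts$count, counts[[level]], sum)
  grand <- sum(tot)
  if (grand == 0) stop("composition undefined: grand total is zero")
  pc <- stats::setNames(as.numeric(100 * tot / grand), names(tot))
  sort(pc, decreasing = TRUE)
}

#' Simpson diversity index
#'
#' The Simpson index here is the dominance orientation,
#' \deqn{D = \sum n_i (n_i - 1) / (N (N - 1)),}
#' the probability that two individuals drawn without replacement are
#' conspecific: 0 means every individual its own taxon (high diversity), 1
#' a monoculture. The reciprocal 1/D (an effective-dominance number) is
#' computed from the unrounded D and is undefined when D = 0.
#'
#' @param counts either a `counts_table` data frame (counts pooled by taxon
#'   label) or a numeric vector of per-taxon counts.
#' @param level pooling level when `counts` is a data frame.
#' @return an object of class `diversity_result`: `d`, `reciprocal`,
#'   `n_taxa`, `n_total`.
#' @export
#' @examples
#' simpson(c(5, 5))$d  # 0.444...
simpson <- function(counts, level = c("genus", "phylum")) {
  level <- match.arg(level)
  if (is.data.frame(counts))
    n <- as.vector(tapply(counts$count, counts[[level]], sum))
  else n <- counts
  n <- n[!is.na(n) & n > 0]
  N <- sum(n)
  if (N < 2) stop("Simpson index undefined for N < 2")
  d <- sum(n * (n - 1)) / (N * (N - 1))
  structure(list(d = d,
                 reciprocal = if (d > 0) 1 / d else NA_real_,
                 n_taxa = length(n), n_total = N),
            class = "diversity_result")
}

#' Median across stations
#'
#' Standard sample median (mean of the central pair for even n), used to
#' summarise per-station statistics into a seasonal value.
#'
#' @param values numeric vector, at least one non-missing value.
#' @return the median.
#' @export
station_median <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("station_median needs at least one value")
  stats::median(values)
}

#' Per-group diversity summary
#'
#' Convenience wrapper computing Simpson D and 1/D either pooled over all
#' samples in a group or per sample then medianed ("per_sample" mode); the
#' pooled mode is the default.
#'
#' @param counts a `counts_table` data frame (one source).
#' @param by column(s) of `counts` to group by (e.g. a season column).
#' @param level pooling level.
#' @param mode `"pooled"` or `"per_sample"`.
#' @return data frame with one row per group: `d`, `reciprocal`, `n_taxa`,
#'   `n_total`.
#' @export
diversity_by <- function(counts, by = NULL, level = "genus",
                         mode = c("pooled", "per_sample")) {
  mode <- match.arg(mode)
  groups <- if (is.null(by)) list(rep("all", nrow(counts)))
            else counts[by]
  split_idx <- split(seq_len(nrow(counts)), groups, drop = TRUE)
  rows <- lapply(names(split_idx), function(g) {
    sub <- counts[split_idx[[g]], ]
    if (mode == "pooled") {
      dv <- simpson(sub, level = level)
      data.frame(group = g, d = dv$d, reciprocal = dv$reciprocal,
                 n_taxa = dv$n_taxa, n_total = dv$n_total)
    } else {
      per <- vapply(split(sub, sub$sample_id),
                    function(s) simpson(s, level = level)$d, numeric(1))
      d <- station_median(per)
      data.frame(group = g, d = d,
                 reciprocal = if (d > 0) 1 / d else NA_real_,
                 n_taxa = length(unique(sub[[level]])),
                 n_total = sum(sub$count))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
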