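# Descriptive tables, seasonal (paired Wilcoxon) and spatial
# (Kruskal-Wallis) nonparametric comparisons, the starred Pearson
# correlation matrix, and correlation-matrix PCA of the ten-parameter
# panel. The classical tests are delegated to stats::wilcox.test /
# kruskal.test / cor.test; the PCA is an explicit eigendecomposition with a
# deterministic sign convention so loadings are reproducible across
# backends.

.panel_parameters <- function() .water_value_cols

#' Median and standard-error table
#'
#' Cell median and standard error (sd/sqrt(n)) of each parameter by station
#' and season; the layout of a classical descriptive water-quality table.
#'
#' @param water a `water_panel` data frame.
#' @param parameters panel columns to summarise.
#' @param group_by grouping columns (default station and season).
#' @return long data frame: `parameter`, grouping columns, `n`, `median`,
#'   `se` (SE is `NA`, flagged, for cells with fewer than 2 values).
#' @export
descriptives <- function(water, parameters = .panel_parameters(),
                         group_by = c("station_id", "season")) {
  rows <- list()
  groups <- water[group_by]
  for (pn in parameters) {
    agg <- stats::aggregate(list(value = water[[pn]]), by = groups,
                            FUN = function(v) {
                              v <- v[!is.na(v)]
                              c(n = length(v),
                                median = stats::median(v),
                                se = if (length(v) >= 2L)
                                       stats::sd(v) / sqrt(length(v))
                                     else NA_real_)
                            })
    cell <- as.data.frame(agg$value)
    out <- cbind(parameter = pn, agg[group_by], cell)
    rows[[pn]] <- out
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.stars_of <- function(p, levels = c(0.05, 0.01, 0.001)) {
  if (is.na(p)) return("none")
  if (p < levels[3]) "***"
  else if (p < levels[2]) "**"
  else if (p < levels[1]) "*"
  else "none"
}

.finest_level <- function(p, levels = c(0.05, 0.01, 0.001)) {
  passed <- levels[p < levels]
  if (length(passed) == 0L) NA_real_ else min(passed)
}

#' Paired seasonal comparison (Wilcoxon signed-rank)
#'
#' Compares the dry and wet seasons for one parameter with the paired
#' Wilcoxon signed-rank test. The pairing unit is the site: each site's
#' within-season replicates are averaged first, sites observed in both
#' seasons are matched, and the exact null distribution is used up to 25
#' pairs (falling back to the tie-corrected normal approximation when
#' zeros or ties force it).
#'
#' @param water a `water_panel` data frame with a `season` column.
#' @param parameter panel column name.
#' @param config an [analysis_config()] (star levels).
#' @param min_pairs minimum matched site pairs required.
#' @return list of class `seasonal_comparison`: `parameter`, `dry_median`,
#'   `wet_median`, `n_pairs`, `test`, `statistic`, `p_value`,
#'   `significant_at` (finest of 0.05/0.01/0.001 passed, or `NA`).
#' @export
seasonal_test <- function(water, parameter, config = analysis_config(),
                          min_pairs = 5L) {
  sub <- water[water$season %in% c("dry", "wet"), ]
  site_means <- stats::aggregate(
    list(value = sub[[parameter]]),
    by = list(site_id = sub$site_id, season = sub$season),
    FUN = function(v) mean(v, na.rm = TRUE))
  wide <- stats::reshape(site_means, idvar = "site_id",
                         timevar = "season", direction = "wide")
  dry <- wide$value.dry
  wet <- wide$value.wet
  keep <- !is.na(dry) & !is.na(wet)
  dry <- dry[keep]; wet <- wet[keep]
  if (length(dry) < min_pairs)
    stop("seasonal_test needs at least ", min_pairs, " matched site pairs")
  if (all(dry == wet)) {
    stat <- 0; p <- 1
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(dry, wet, paired = TRUE,
                         exact = length(dry) <= 25))
    stat <- unname(wt$statistic); p <- wt$p.value
  }
  structure(list(parameter = parameter,
                 dry_median = stats::median(dry),
                 wet_median = stats::median(wet),
                 n_pairs = length(dry),
                 test = "wilcoxon_paired", statistic = stat, p_value = p,
                 significant_at = .finest_level(p,
                                                config$correlation_star_levels)),
            class = "seasonal_comparison")
}

#' Spatial comparison across stations (Kruskal-Wallis)
#'
#' Kruskal-Wallis rank test of one parameter across stations (tie-corrected
#' H, chi-square p on k-1 degrees of freedom).
#'
#' @param water a `water_panel` data frame.
#' @param parameter panel column name.
#' @param config an [analysis_config()].
#' @return list of class `seasonal_comparison` with `test =
#'   "kruskal_wallis"`.
#' @export
spatial_test <- function(water, parameter, config = analysis_config()) {
  vals <- water[[parameter]]
  grp <- factor(water$station_id)
  ok <- !is.na(vals)
  vals <- vals[ok]; grp <- droplevels(grp[ok])
  sizes <- table(grp)
  if (length(sizes) < 2L || any(sizes < 2L))
    stop("spatial_test needs >= 2 stations with >= 2 values each")
  kt <- stats::kruskal.test(vals, grp)
  structure(list(parameter = parameter,
                 dry_median = NA_real_, wet_median = NA_real_,
                 n_pairs = NA_integer_,
                 test = "kruskal_wallis",
                 statistic = unname(kt$statistic),
                 p_value = kt$p.value,
                 significant_at = .finest_level(kt$p.value,
                                                config$correlation_star_levels)),
            class = "seasonal_comparison")
}

#' Starred Pearson correlation matrix
#'
#' Pairwise Pearson correlations of the panel parameters with two-sided
#' t-test p-values and significance stars (* < 0.05, ** < 0.01,
#' *** < 0.001), missing values deleted pairwise. Constant parameters give
#' an undefined (NA, flagged) correlation.
#'
#' @param water a `water_panel` data frame.
#' @param parameters panel columns.
#' @param config an [analysis_config()].
#' @param min_pairs minimum complete pairs per cell.
#' @return data frame of cells: `p1`, `p2`, `n`, `r`, `p_value`, `stars`.
#' @export
correlation_matrix <- function(water, parameters = .panel_parameters(),
                               config = analysis_config(), min_pairs = 3L) {
  rows <- list()
  for (i in seq_along(parameters)) for (j in seq_along(parameters)) {
    if (j < i) next
    x <- water[[parameters[i]]]; y <- water[[parameters[j]]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < min_pairs)
      stop("fewer than ", min_pairs, " complete pairs for ",
           parameters[i], " vs ", parameters[j])
    if (i == j) {
      r <- 1; p <- 0
    } else if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(x, y)
      r <- unname(ct$estimate)
      p <- if (abs(r) >= 1) 0 else ct$p.value
    }
    rows[[length(rows) + 1L]] <-
      data.frame(p1 = parameters[i], p2 = parameters[j], n = length(x),
                 r = r, p_value = p,
                 stars = .stars_of(p, config$correlation_star_levels),
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' PCA of the standardised panel
#'
#' Principal component analysis on the correlation matrix: each parameter
#' is z-scored over the complete cases, the correlation matrix is
#' eigendecomposed, and eigenvector signs are fixed so the
#' largest-magnitude loading of each component is positive (deterministic
#' across linear-algebra backends). Components beyond the numerical rank
#' are zeroed and flagged. Variable contributions are squared unit
#' loadings scaled to sum to 100 per dimension.
#'
#' @param water a `water_panel` data frame.
#' @param parameters panel columns to include.
#' @param n_retain components retained for reporting (the full spectrum is
#'   always computed).
#' @return list of class `pca_result`: `eigenvalues`, `percent_variance`,
#'   `cumulative_percent`, `loadings` (unit eigenvectors), `contributions`,
#'   `scores` (with season/station labels), `n_components_retained`,
#'   `rank`, `n_samples`.
#' @export
pca_panel <- function(water, parameters = .panel_parameters(),
                      n_retain = 4L) {
  x <- as.matrix(water[parameters])
  complete <- stats::complete.cases(x)
  x <- x[complete, , drop = FALSE]
  if (nrow(x) < length(parameters) + 1L)
    stop("pca_panel needs at least parameters + 1 complete samples")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant parameter(s): ",
         paste(parameters[sds == 0], collapse = ", "))
  z <- scale(x)
  cm <- stats::cor(x)
  eig <- eigen(cm, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  vectors <- eig$vectors
  tol <- max(values) * 1e-10
  rank <- sum(values > tol)
  if (rank < length(values)) {
    values[(rank + 1):length(values)] <- 0
    vectors[, (rank + 1):length(values)] <- 0
  }
  for (k in seq_len(rank)) {
    v <- vectors[, k]
    if (v[which.max(abs(v))] < 0) vectors[, k] <- -v
  }
  dimnames(vectors) <- list(parameters,
                            paste0("Dim", seq_along(values)))
  scores <- z %*% vectors
  meta <- water[complete, intersect(c("station_id", "site_id", "season"),
                                    names(water)), drop = FALSE]
  pv <- 100 * values / sum(values)
  contributions <- 100 * vectors^2
  structure(list(eigenvalues = values,
                 percent_variance = pv,
                 cumulative_percent = cumsum(pv),
                 loadings = vectors,
                 contributions = contributions,
                 scores = cbind(meta, as.data.frame(scores)),
                 n_components_retained = min(n_retain, rank),
                 rank = rank,
                 n_samples = nrow(z)),
            class = "pca_result")
}
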