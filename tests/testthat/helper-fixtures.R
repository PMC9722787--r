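# Shared fixture builders and independent oracles.

# one-sample counts table from a named count vector
make_counts <- function(counts, source = "water", sample_id = "S1",
                        phylum = NULL, fish_length_cm = NA_real_) {
  if (is.null(phylum)) phylum <- names(counts)
  df <- data.frame(source = source, sample_id = sample_id,
                   fish_length_cm = if (source == "gut") fish_length_cm
                                    else NA_real_,
                   fish_weight_g = NA_real_,
                   genus = names(counts), phylum = phylum,
                   count = unname(counts),
                   stringsAsFactors = FALSE)
  as_counts_table(df)
}

# minimal valid water panel: one row per site x season around given values
make_water_panel <- function(n_sites = 6, dry = 1, wet = 2,
                             parameter = "salinity") {
  base <- expand.grid(site = seq_len(n_sites),
                      season = c("dry", "wet"),
                      stringsAsFactors = FALSE)
  df <- data.frame(station_id = paste0("S", (base$site - 1) %/% 2 + 1),
                   site_id = paste0("site", base$site),
                   date = ifelse(base$season == "dry", "2020-01-15",
                                 "2020-08-15"),
                   temperature = 25, salinity = 1, do = 7, ph = 7.5,
                   no3_n = 0.05, no2_n = 0.008, nh4 = 0.06, po4_p = 0.3,
                   dsi = 5, chla = 3, stringsAsFactors = FALSE)
  vals <- ifelse(base$season == "dry", dry, wet)
  df[[parameter]] <- vals
  as_water_panel(df)
}

# Simpson oracle: enumerate all unordered pairs of individuals and count
# conspecific ones (probability of a same-taxon draw without replacement)
simpson_pair_oracle <- function(n) {
  ids <- rep(seq_along(n), n)
  N <- length(ids)
  same <- outer(ids, ids, "==")
  (sum(same) - N) / 2 / choose(N, 2)
}

# exact two-sided signed-rank p by enumeration of all sign patterns
signed_rank_enum_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu))
}
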