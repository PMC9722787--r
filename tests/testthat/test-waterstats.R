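test_that("descriptives give cell medians and standard errors", {
  df <- make_water_panel(n_sites = 6)
  df$do[df$season == "dry"] <- rep(c(8.4, 8.3, 8.2, 8.3, 8.3),c(2, 1, 1, 1, 1))[1:6]
  tab <- descriptives(df, parameters = "do", group_by = "season")
  dry <- tab[tab$season == "dry", ]
  expect_equal(dry$median, 8.3)
  expect_equal(dry$se, sd(df$do[df$season == "dry"]) / sqrt(6))

  const <- descriptives(df, parameters = "temperature",
                        group_by = "season")
  expect_equal(const$se, c(0, 0))

  # zero-spread generator panel reproduces the configured medians exactly
  spec <- scenario_spec(n_eff = 0)
  panel <- simulate_water_panel(spec)
  tab2 <- descriptives(panel, parameters = "temperature")
  for (i in seq_len(nrow(tab2)))
    expect_equal(tab2$median[i],
                 spec$params$temperature[[tab2$season[i]]]$med[[tab2$station_id[i]]])
})

test_that("seasonal_test pairs sites and matches exact enumeration", {
  same <- make_water_panel(dry = 2, wet = 2)
  res <- seasonal_test(same, "salinity")
  expect_equal(res$p_value, 1)

  # 6 site pairs, distinct positive differences: two-sided exact p = 2/64
  panel <- make_water_panel(n_sites = 6)
  d <- c(0.11, 0.22, 0.35, 0.41, 0.57, 0.63)
  panel$salinity <- ifelse(panel$season == "dry",
                           1 + d[as.integer(factor(panel$site_id))], 1)
  res2 <- seasonal_test(panel, "salinity")
  expect_equal(res2$n_pairs, 6L)
  expect_equal(res2$p_value, 2 / 64)
  # independent oracle: enumerate all 2^6 sign patterns
  expect_equal(res2$p_value, signed_rank_enum_p(d))

  expect_error(seasonal_test(make_water_panel(n_sites = 4), "salinity"),
               "matched site pairs")
})

test_that("spatial_test flags the synthetic dry salinity gradient", {
  null_panel <- make_water_panel(n_sites = 6)
  # every station receives the same value multiset {1, 2, 10, 20}
  null_panel$salinity[order(null_panel$station_id)] <-
    rep(c(1, 2, 10, 20), 3)
  kw <- spatial_test(null_panel, "salinity")
  expect_equal(kw$statistic, 0, tolerance = 1e-12)
  expect_gt(kw$p_value, 0.9)

  panel <- simulate_water_panel(scenario_spec(rng_seed = 3L))
  dry <- panel[panel$season == "dry", ]
  expect_lt(spatial_test(dry, "salinity")$p_value, 0.05)

  one <- null_panel[null_panel$station_id == "S1", ]
  expect_error(spatial_test(one, "salinity"), "2 stations")
})

test_that("two-group Kruskal-Wallis matches the hand rank formula", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  y <- c(0.4, 6.3, 7.7)
  df <- make_water_panel(n_sites = 6)
  df <- df[1:7, ]
  df$station_id <- rep(c("A", "B"), c(4, 3))
  df$salinity <- c(x, y)
  kw <- spatial_test(df, "salinity")
  r <- rank(c(x, y))
  n <- 7
  h <- 12 / (n * (n + 1)) *
    (sum(r[1:4])^2 / 4 + sum(r[5:7])^2 / 3) - 3 * (n + 1)
  expect_equal(kw$statistic, h)  # no ties, so no correction
})

test_that("correlation matrix stars and degenerate cells behave", {
  df <- make_water_panel(n_sites = 6)
  df$salinity <- seq_len(nrow(df))
  df$do <- -df$salinity
  cm <- correlation_matrix(df, parameters = c("salinity", "do"))
  self <- cm[cm$p1 == "salinity" & cm$p2 == "salinity", ]
  expect_equal(self$r, 1)
  expect_equal(self$stars, "***")
  cross <- cm[cm$p1 == "salinity" & cm$p2 == "do", ]
  expect_equal(cross$r, -1)

  cm2 <- correlation_matrix(df, parameters = c("salinity", "temperature"))
  flat <- cm2[cm2$p1 == "salinity" & cm2$p2 == "temperature", ]
  expect_true(is.na(flat$r))
  expect_equal(flat$stars, "none")
})

test_that("synthetic panel encodes the expected correlation signs", {
  panel <- derive_nutrients(simulate_water_panel(scenario_spec(rng_seed = 2L)))
  r_st <- cor(panel$salinity, panel$temperature)
  r_nd <- cor(panel$nh4, panel$din)
  expect_lt(r_st, 0)
  expect_gt(r_nd, 0)
})

test_that("pca_panel decomposes the correlation matrix deterministically", {
  set.seed(9)
  n <- 300
  base <- rnorm(n)
  df <- make_water_panel(n_sites = 6)
  df <- df[rep(seq_len(nrow(df)), length.out = n), ]
  df$salinity <- base
  df$do <- 2 * base + 5  # perfectly correlated pair
  pca <- pca_panel(df, parameters = c("salinity", "do"))
  expect_equal(pca$percent_variance[1], 100)
  expect_equal(pca$rank, 1L)

  for (p in c("temperature", "ph", "no3_n", "chla"))
    df[[p]] <- rnorm(n)
  full <- pca_panel(df, parameters = c("salinity", "temperature", "ph",
                                       "no3_n", "chla"))
  expect_equal(sum(full$percent_variance), 100)
  expect_true(all(diff(full$eigenvalues) <= 1e-12))
  expect_equal(colSums(full$contributions)[seq_len(full$rank)],
               setNames(rep(100, full$rank),
                        paste0("Dim", seq_len(full$rank))))
  # deterministic sign convention: dominant loading positive
  for (k in seq_len(full$rank)) {
    v <- full$loadings[, k]
    expect_gte(v[which.max(abs(v))], 0)
  }
  # reconstruction at full rank
  z <- scale(as.matrix(df[c("salinity", "temperature", "ph", "no3_n",
                            "chla")]))
  recon <- as.matrix(full$scores[, paste0("Dim", 1:5)]) %*%
    t(full$loadings)
  expect_lt(max(abs(recon - z)), 1e-8)
})

test_that("dim-1 scores separate the seasons on the default panel", {
  panel <- simulate_water_panel(scenario_spec(rng_seed = 5L))
  pca <- pca_panel(panel)
  s <- split(pca$scores$Dim1, pca$scores$season)
  pooled_sd <- sqrt((var(s$dry) + var(s$wet)) / 2)
  expect_gt(abs(mean(s$dry) - mean(s$wet)), 2 * pooled_sd)
})
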