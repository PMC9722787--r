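test_that("water table round-trips through CSV with seasons filled", {
  df <- data.frame(
    station_id = rep(c("UE", "ME", "LE"), each = 2),
    site_id = paste0("s", 1:6),
    date = rep(c("2020-01-15", "2020-08-15"), 3),
    temperature = c(22, 31, 23, 30, 22, 31),
    salinity = c(0.5, 0.1, 6.5, 0.2, 7.0, 0.1),
    do = c(8.4, 6.9, 8.3, 6.8, 8.2, 6.9),
    ph = c(7.1, 6.8, 7.3, 7.4, 7.2, 7.3),
    no3_n = 0.05, no2_n = 0.008, nh4 = 0.06,
    po4_p = 0.3, dsi = 5, chla = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_water_table(as_water_panel(df), path)
  back <- read_water_table(path)
  expect_equal(nrow(back), 6L)
  expect_true(all(back$season %in% c("dry", "wet")))
  expect_equal(back$salinity, df$salinity)
  expect_equal(as.character(back$date), df$date)
})

test_that("schema and validation errors name the offender", {
  df <- data.frame(station_id = "UE", site_id = "s1", date = "2020-01-15",
                   temperature = 22, salinity = 1, do = 8, ph = 7,
                   no3_n = 0.05, no2_n = 0.008, nh4 = -0.1,
                   po4_p = 0.3, dsi = 5, chla = 3)
  expect_error(as_water_panel(df), "nh4.*row 1")
  expect_error(as_water_panel(df[, setdiff(names(df), "chla")]), "chla")
  df$nh4 <- 0.1; df$ph <- 15
  expect_error(as_water_panel(df), "ph")
})

test_that("synthetic panel round-trips field-for-field (seed 42)", {
  panel <- simulate_water_panel(scenario_spec(rng_seed = 42L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_water_table(panel, path)
  back <- read_water_table(path)
  for (col in c("station_id", "site_id", "season"))
    expect_identical(back[[col]], panel[[col]])
  for (col in c("temperature", "salinity", "do", "ph", "no3_n", "no2_n",
                "nh4", "po4_p", "dsi", "chla"))
    expect_equal(back[[col]], panel[[col]], tolerance = 1e-12)
})

test_that("derive_nutrients sums the three N species", {
  d <- derive_nutrients(data.frame(no3_n = 0.05, no2_n = 0.008,
                                   nh4 = 0.06))
  expect_equal(d$din, 0.118)
  expect_equal(d$nh4_fraction_of_din, 0.06 / 0.118)

  z <- derive_nutrients(data.frame(no3_n = 0, no2_n = 0, nh4 = 0))
  expect_equal(z$din, 0)
  expect_true(is.na(z$nh4_fraction_of_din))

  s <- derive_nutrients(data.frame(no3_n = 0, no2_n = 0, nh4 = 0.25))
  expect_equal(s$nh4_fraction_of_din, 1.0)

  expect_error(derive_nutrients(data.frame(no3_n = 1, no2_n = 1)), "nh4")
})

test_that("derive_nutrients is additive under scaling", {
  set.seed(11)
  for (i in 1:20) {
    x <- data.frame(no3_n = runif(1), no2_n = runif(1), nh4 = runif(1))
    c0 <- runif(1, 0.1, 10)
    expect_equal(derive_nutrients(x * c0)$din,
                 c0 * derive_nutrients(x)$din)
  }
})

test_that("counts table validation enforces integer counts, unique genera
           and fish length range", {
  expect_error(make_counts(c(A = 1.5, B = 2)), "non-negative integer")
  df <- rbind(make_counts(c(A = 1, B = 2)), make_counts(c(A = 3)))
  expect_error(as_counts_table(df), "duplicate genus")
  expect_error(make_counts(c(A = 5), source = "gut", fish_length_cm = 60),
               "10-50")
  expect_silent(make_counts(c(A = 5), source = "gut",
                            fish_length_cm = 25))
})

test_that("ctd casts reject duplicate depths and split by station-date", {
  df <- data.frame(station_id = c("UE", "UE", "ME", "ME"),
                   date = "2020-01-15", axis_km = c(0, 0, 30, 30),
                   depth_m = c(1, 5, 1, 5),
                   salinity = c(0.2, 0.3, 4, 4.1), temperature = 22)
  casts <- as_ctd_casts(df)
  expect_length(casts, 2L)
  df$depth_m <- c(1, 1, 1, 5)
  expect_error(as_ctd_casts(df), "duplicate depth")
})
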