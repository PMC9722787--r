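test_that("identical seed and spec give identical outputs", {
  spec <- scenario_spec(rng_seed = 9L)
  expect_identical(simulate_water_panel(spec), simulate_water_panel(spec))
  expect_identical(simulate_ctd_section(spec, "dry"),
                   simulate_ctd_section(spec, "dry"))
  a <- simulate_counts(spec, "gut", "wet")
  b <- simulate_counts(spec, "gut", "wet")
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("wet-season salinity respects the freshwater bound (seed 1)", {
  panel <- simulate_water_panel(scenario_spec(rng_seed = 1L))
  expect_true(all(panel$salinity[panel$season == "wet"] < 0.5))
  expect_true(all(panel$salinity >= 0))
  expect_true(all(panel$ph <= 14))
})

test_that("zero spread degenerates to the seasonal station medians", {
  spec <- scenario_spec(n_eff = 0)
  panel <- simulate_water_panel(spec)
  for (st in c("UE", "HI")) for (ss in c("dry", "wet")) {
    sub <- panel[panel$station_id == st & panel$season == ss, ]
    expect_equal(unique(sub$temperature),
                 spec$params$temperature[[ss]]$med[[st]])
    expect_equal(unique(sub$salinity),
                 min(spec$params$salinity[[ss]]$med[[st]],
                     if (ss == "wet") 0.5 - 1e-9 else Inf))
  }
})

test_that("dry-season temperature locations recover the configured median", {
  meds <- vapply(1:50, function(r) {
    p <- simulate_water_panel(scenario_spec(rng_seed = 7L + r))
    median(p$temperature[p$season == "dry"])
  }, numeric(1))
  # overall dry median is 22.5 with median SE 0.17
  expect_lt(abs(median(meds) - 22.5), 2 * 0.17)
})

test_that("dry CTD sections are well-mixed with 13 PSU at the seaward end", {
  for (seed in 1:5) {
    sec <- simulate_ctd_section(scenario_spec(), "dry", seed = seed)
    st <- stratify_section(sec)
    expect_true(all(st$mixing_class == "well_mixed"))
    expect_true(all(st$n_s < 0.01))
    expect_equal(max(sec$salinity), 13)
    expect_equal(sec$axis_km[which.max(sec$salinity)],
                 max(sec$axis_km))
  }
})

test_that("wet CTD sections run fresh and carry no 2 PSU isohaline", {
  sec <- simulate_ctd_section(scenario_spec(), "wet", seed = 4L)
  expect_true(all(sec$salinity < 0.15))
  expect_true(is.na(isohaline_position(sec)))
  expect_error(simulate_ctd_section(scenario_spec(), "monsoon"),
               "unknown season")
})

test_that("gut wet composition concentrates near the configured percents", {
  cnt <- simulate_counts(scenario_spec(), "gut", "wet", seed = 3L)
  expect_equal(length(unique(cnt$sample_id)), 90L)
  expect_true(all(cnt$fish_length_cm >= 18 & cnt$fish_length_cm <= 35))
  comp <- composition(cnt, "phylum")
  # configured 61.5 of a 98-total renormalises to 62.8
  expect_lt(abs(comp[["Chlorophyta"]] - 61.5), 3)
  expect_equal(attr(cnt, "renormalisation"), 100 / 98)
})

test_that("water dry composition recovers the configured phylum shares", {
  cnt <- simulate_counts(scenario_spec(), "water", "dry", seed = 5L)
  comp <- composition(cnt, "phylum")
  expect_lt(abs(comp[["Bacillariophyta"]] - 32), 3)
  expect_lt(abs(comp[["Chlorophyta"]] - 26), 3)
  expect_lt(abs(comp[["Cyanobacteria"]] - 16), 3)
})

test_that("degenerate compositions are handled", {
  spec <- scenario_spec()
  spec$gut_composition$wet <- c(Chlorophyta = 100)
  cnt <- simulate_counts(spec, "gut", "wet", n_tables = 5, seed = 2L)
  expect_true(all(cnt$phylum == "Chlorophyta"))
  spec$gut_composition$wet <- c(Chlorophyta = 0)
  expect_error(simulate_counts(spec, "gut", "wet"), "all-zero")
})
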