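test_that("taxon proportions pool counts within one source", {
  one <- make_counts(c(A = 3), phylum = "Chlorophyta")
  expect_equal(unname(taxon_proportions(one)), 1.0)

  two <- make_counts(c(a = 615, b = 385),
                     phylum = c("Chlorophyta", "Bacillariophyta"))
  p <- taxon_proportions(two, "phylum")
  expect_equal(unname(p[c("Chlorophyta", "Bacillariophyta")]),
               c(0.615, 0.385))
  expect_equal(sum(p), 1)

  mixed <- rbind(make_counts(c(A = 1)),
                 make_counts(c(B = 1), source = "gut", sample_id = "F1",
                             fish_length_cm = 25))
  expect_error(taxon_proportions(mixed), "mixed sources")
  expect_error(taxon_proportions(two[0, ]), "at least one")
})

test_that("electivity index reproduces the odds-ratio arithmetic", {
  neutral <- electivity_index(0.3, 0.3)
  expect_equal(neutral$odds_ratio, 1)
  expect_equal(neutral$index, 0.5)

  expect_equal(electivity_index(1, 0.4)$index, 1)
  expect_equal(electivity_index(0, 0.4)$index, 0)

  sel <- electivity_index(0.615, 0.36)
  expect_equal(sel$odds_ratio, (0.615 / 0.385) * (0.64 / 0.36))
  expect_equal(sel$index, sel$odds_ratio / (1 + sel$odds_ratio))
  expect_equal(round(sel$index, 2), 0.74)

  expect_error(electivity_index(0.5, 0), "degenerate")
  expect_error(electivity_index(0.5, 1), "degenerate")
})

test_that("reciprocal identity and monotonicity hold on interior points", {
  set.seed(3)
  g <- runif(50, 0.01, 0.99)
  a <- runif(50, 0.01, 0.99)
  for (i in 1:50) {
    x <- electivity_index(g[i], a[i])$index
    expect_equal(x, 1 - electivity_index(1 - g[i], 1 - a[i])$index)
    # strictly increasing in g, decreasing in a
    expect_gt(electivity_index(min(g[i] + 0.005, 0.995), a[i])$index, x)
    expect_lt(electivity_index(g[i], min(a[i] + 0.005, 0.995))$index, x)
  }
})

test_that("electivity profile handles size bins and limits", {
  water <- make_counts(c(a = 50, b = 30, c = 20),
                       phylum = c("Chlorophyta", "Bacillariophyta",
                                  "Cyanobacteria"))
  gut1 <- make_counts(c(x = 10), phylum = "Chlorophyta", source = "gut",
                      sample_id = "F1", fish_length_cm = 15)
  prof <- electivity_profile(water, gut1)
  all_rows <- prof[prof$size_class == "all", ]
  expect_equal(all_rows$index[all_rows$taxon == "Chlorophyta"], 1)
  expect_equal(all_rows$index[all_rows$taxon != "Chlorophyta"], c(0, 0))
  expect_true("small" %in% prof$size_class)

  # medium and large fish fall in their own bins
  gut2 <- rbind(gut1,
                make_counts(c(x = 5), phylum = "Bacillariophyta",
                            source = "gut", sample_id = "F2",
                            fish_length_cm = 25),
                make_counts(c(x = 5), phylum = "Cyanobacteria",
                            source = "gut", sample_id = "F3",
                            fish_length_cm = 33))
  prof2 <- electivity_profile(water, gut2)
  expect_setequal(unique(prof2$size_class),
                  c("all", "small", "medium", "large"))
  # 35 cm sits in the closed last bin; 40 cm is excluded with a warning
  gut3 <- make_counts(c(x = 5), phylum = "Chlorophyta", source = "gut",
                      sample_id = "F4", fish_length_cm = 40)
  expect_warning(electivity_profile(water, rbind(gut2, gut3)),
                 "outside all size bins")
})

test_that("a taxon absent from water needs the add-half correction", {
  water <- make_counts(c(a = 50, b = 30),
                       phylum = c("Chlorophyta", "Bacillariophyta"))
  gut <- make_counts(c(x = 5, y = 5),
                     phylum = c("Chlorophyta", "Miozoa"),
                     source = "gut", sample_id = "F1",
                     fish_length_cm = 25)
  expect_error(electivity_profile(water, gut, correction = "none"),
               "Miozoa")
  prof <- electivity_profile(water, gut, correction = "add_half")
  expect_true(all(is.finite(prof$index)))
  expect_gt(prof$index[prof$taxon == "Miozoa" &
                         prof$size_class == "all"], 0.5)
})

test_that("generator-matched gut and water compositions give X near 0.5", {
  spec <- scenario_spec()
  spec$gut_composition <- spec$water_composition
  water <- simulate_counts(spec, "water", "wet", seed = 21L)
  gut <- simulate_counts(spec, "gut", "wet", seed = 22L)
  prof <- electivity_profile(water, gut, size_bins = NULL)
  expect_true(all(abs(prof$index - 0.5) < 0.1))
})

test_that("default scenario prefers Chlorophyta over Cyanobacteria", {
  spec <- scenario_spec()
  water <- simulate_counts(spec, "water", "wet", seed = 31L)
  gut <- simulate_counts(spec, "gut", "wet", seed = 32L)
  prof <- electivity_profile(water, gut, size_bins = NULL,
                             correction = "add_half")
  x <- setNames(prof$index, prof$taxon)
  expect_gt(x[["Chlorophyta"]], x[["Cyanobacteria"]])
})
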