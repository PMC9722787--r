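test_that("chlorophyll-a trichromatic equation evaluates correctly", {
  expect_equal(chlorophyll_a(0, 0, 0, 0), 0)
  expect_equal(chlorophyll_a(0.1, 0, 0, 0, 10, 1, 1), 11.64 * 0.1 * 10)
  # all bands equal to the 750 nm blank: turbidity fully subtracted
  expect_equal(chlorophyll_a(0.05, 0.05, 0.05, 0.05), 0)
  expect_warning(v <- chlorophyll_a(0, 0.2, 0, 0), "floored")
  expect_equal(v, 0)
  expect_error(chlorophyll_a(0.1, 0, 0, 0, filtered_volume_l = 0),
               "filtered_volume")
})

test_that("cell density converts chamber counts dimensionally", {
  expect_equal(cell_density(0, 10, 0.001), 0)
  expect_equal(cell_density(100, 10, 0.001, 100), 1e5)
  expect_error(cell_density(10, 0, 0.001), "fields_counted")
})

test_that("synthetic water totals stay inside the seasonal density range", {
  cnt <- simulate_counts(scenario_spec(), "water", "wet", seed = 8L)
  totals <- tapply(cnt$count, cnt$sample_id, sum)
  expect_true(all(totals >= 10300 & totals <= 215100))
})

test_that("composition pools counts and sums to 100", {
  one <- make_counts(c(A = 7), phylum = "Chlorophyta")
  expect_equal(unname(composition(one)), 100)

  mix <- make_counts(c(a = 36, b = 27, c = 14, d = 4, e = 4),
                     phylum = c("Bacillariophyta", "Chlorophyta",
                                "Cyanobacteria", "Euglenophyta", "Miozoa"))
  pc <- composition(mix, "phylum")
  expect_equal(unname(round(pc[c("Bacillariophyta", "Chlorophyta",
                                 "Cyanobacteria", "Euglenophyta",
                                 "Miozoa")], 1)),
               c(42.4, 31.8, 16.5, 4.7, 4.7))
  expect_equal(sum(pc), 100)

  eq <- make_counts(c(a = 5, b = 5), phylum = c("Chlorophyta", "Miozoa"))
  expect_equal(unname(composition(eq, "phylum")), c(50, 50))
  expect_error(composition(make_counts(c(A = 0))), "grand total")
})

test_that("Simpson index matches the printed-formula arithmetic", {
  expect_equal(simpson(c(10))$d, 1)          # monoculture
  expect_equal(simpson(c(10))$reciprocal, 1)
  expect_equal(simpson(rep(1, 8))$d, 0)      # all singletons
  expect_true(is.na(simpson(rep(1, 8))$reciprocal))
  dv <- simpson(c(5, 5))
  expect_equal(dv$d, 40 / 90)
  expect_equal(dv$reciprocal, 2.25)
  expect_error(simpson(c(1)), "N < 2")
})

test_that("Simpson D is invariant to permutation and zero rows", {
  set.seed(5)
  for (i in 1:25) {
    n <- rpois(sample(3:8, 1), 5) + 1
    d0 <- simpson(n)$d
    expect_equal(simpson(sample(n))$d, d0)
    expect_equal(simpson(c(n, 0, 0))$d, d0)
  }
})

test_that("Simpson D equals the all-pairs enumeration oracle", {
  set.seed(6)
  for (i in 1:200) {
    k <- sample(2:8, 1)
    n <- as.vector(rmultinom(1, sample(5:50, 1), rep(1 / k, k)))
    n <- n[n > 0]
    if (sum(n) < 2) next
    expect_equal(simpson(n)$d, simpson_pair_oracle(n))
  }
})

test_that("station_median follows the even-n convention", {
  expect_equal(station_median(c(1, 2, 3, 4)), 2.5)
  expect_equal(station_median(c(0.17, 0.13, 0.16, 0.37, 0.14)), 0.16)
  expect_error(station_median(numeric(0)), "at least one")
})

test_that("diversity_by offers pooled and per-sample modes", {
  cnt <- rbind(make_counts(c(A = 5, B = 5), sample_id = "s1"),
               make_counts(c(A = 9, B = 1), sample_id = "s2"))
  pooled <- diversity_by(cnt, level = "genus", mode = "pooled")
  expect_equal(pooled$d, simpson(c(14, 6))$d)
  per <- diversity_by(cnt, level = "genus", mode = "per_sample")
  expect_equal(per$d, median(c(simpson(c(5, 5))$d, simpson(c(9, 1))$d)))
})
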