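# Seeded generator for a monsoonal, well-mixed estuary: a seasonal
# water-quality panel over five stations (12 sites), along-axis CTD salinity
# sections, and phylum/genus-resolved phytoplankton counts in water tows and
# hilsa guts. Defaults encode the stated seasonal station medians/SEs and
# percent compositions; genus identity carries no signal (uniform split
# within phylum).

.station_frame <- function() {
  data.frame(station_id = c("UE", "ME", "LE", "CK", "HI"),
             axis_km = c(0, 30, 60, 95, 100),
             n_sites = c(2L, 2L, 2L, 3L, 3L),
             stringsAsFactors = FALSE)
}

# location (station median) and scale (station SE) per parameter and season,
# stations ordered UE, ME, LE, CK, HI
.water_param_defaults <- function() {
  p <- list(
    temperature = list(
      dry = list(med = c(22.0, 22.7, 22.0, 22.9, 23.1),
                 se = c(0.4, 0.3, 0.3, 0.5, 0.3)),
      wet = list(med = c(31.2, 30.4, 30.5, 29.8, 30.1),
                 se = c(0.4, 0.5, 1.1, 0.7, 0.3))),
    salinity = list(
      dry = list(med = c(0.50, 6.5, 7.0, 12.2, 12.4),
                 se = c(0.2, 2.0, 1.2, 2.2, 1.8)),
      wet = list(med = c(0.22, 0.22, 0.08, 0.09, 0.48),
                 se = c(0.10, 0.06, 0.01, 0.01, 0.06))),
    do = list(
      dry = list(med = c(8.4, 8.3, 8.2, 8.3, 8.3),
                 se = c(0.06, 0.07, 0.01, 0.03, 0.04)),
      wet = list(med = c(6.9, 6.8, 6.9, 6.9, 6.7),
                 se = c(0.2, 0.1, 0.1, 0.0, 0.2))),
    ph = list(
      dry = list(med = c(7.1, 7.3, 7.2, 6.5, 7.2),
                 se = c(0.27, 0.14, 0.23, 0.70, 0.01)),
      wet = list(med = c(6.8, 7.4, 7.3, 7.6, 8.6),
                 se = c(0.6, 0.5, 0.7, 0.5, 0.1))),
    no3_n = list(
      dry = list(med = c(0.05, 0.05, 0.07, 0.03, 0.06),
                 se = c(0.01, 0.01, 0.02, 0.02, 0.03)),
      wet = list(med = c(0.07, 0.04, 0.04, 0.04, 0.07),
                 se = c(0.04, 0.01, 0.02, 0.01, 0.01))),
    no2_n = list(
      dry = list(med = c(0.008, 0.01, 0.013, 0.007, 0.005),
                 se = c(0.002, 0.002, 0.002, 0.001, 0.001)),
      wet = list(med = c(0.008, 0.012, 0.007, 0.01, 0.005),
                 se = c(0.002, 0.005, 0.001, 0.004, 0.001))),
    nh4 = list(
      dry = list(med = c(0.06, 0.10, 0.33, 0.16, 0.14),
                 se = c(0.02, 0.02, 0.14, 0.15, 0.04)),
      wet = list(med = c(0.37, 0.23, 0.08, 0.27, 0.22),
                 se = c(0.15, 0.09, 0.03, 0.12, 0.07))),
    po4_p = list(
      dry = list(med = c(0.34, 0.49, 1.39, 0.31, 0.33),
                 se = c(0.11, 0.27, 0.73, 0.13, 0.12)),
      wet = list(med = c(0.13, 0.59, 0.23, 0.89, 0.46),
                 se = c(0.04, 0.34, 0.11, 0.71, 0.23))),
    dsi = list(
      dry = list(med = c(5.19, 4.53, 5.75, 2.71, 4.46),
                 se = c(0.51, 0.27, 1.52, 1.09, 0.33)),
      wet = list(med = c(8.3, 5.0, 6.9, 3.2, 7.1),
                 se = c(1.8, 1.0, 3.2, 0.7, 2.0))),
    chla = list(
      dry = list(med = c(4.46, 2.54, 3.24, 4.15, 1.11),
                 se = c(0.77, 0.47, 1.60, 1.35, 0.07)),
      wet = list(med = c(3.4, 3.0, 4.9, 5.9, 4.0),
                 se = c(0.6, 0.4, 0.3, 1.0, 0.8))))
  for (nm in names(p)) for (ss in c("dry", "wet")) {
    names(p[[nm]][[ss]]$med) <- c("UE", "ME", "LE", "CK", "HI")
    names(p[[nm]][[ss]]$se) <- c("UE", "ME", "LE", "CK", "HI")
  }
  p
}

# percent contributions per phylum; within-season sums deliberately fall
# short of 100 (field tables often do); the generator renormalises and
# records the factor
.composition_defaults <- function() {
  list(
    water = list(
      dry = c(Bacillariophyta = 32, Chlorophyta = 26, Cyanobacteria = 16,
              Xanthophyta = 6, Euglenophyta = 3, Miozoa = 9),
      wet = c(Bacillariophyta = 27, Chlorophyta = 36, Cyanobacteria = 14,
              Euglenophyta = 4, Miozoa = 4)),
    gut = list(
      dry = c(Bacillariophyta = 21.6, Chlorophyta = 45.8,
              Cyanobacteria = 14.08, Xanthophyta = 2.6),
      wet = c(Bacillariophyta = 23.5, Chlorophyta = 61.5,
              Cyanobacteria = 12, Euglenophyta = 1)))
}

.genus_defaults <- function() {
  list(
    water = list(
      dry = list(
        Bacillariophyta = c("Coscinodiscus", "Lioloma", "Asterionella",
                            "Pleorosigma", "Chaetoceros", "Proboscia",
                            "Ditylum", "Cerataulina", "Fragilaria",
                            "Melosira", "Asteromphalus", "Triceratium",
                            "Nitzchia"),
        Chlorophyta = c("Hydrodictyon", "Muogeotia", "Microspora",
                        "Chlorella", "Volvox", "Ulothrix", "Merismopedium",
                        "Uroglena", "Closterium", "Pediastrum", "Oedogonium",
                        "Spirogyra", "Tetraedron"),
        Cyanobacteria = c("Microcystis", "Gomphosphaeria", "Oscillatoria",
                          "Aphanizomenon", "Lyngbya", "Rivularia"),
        Xanthophyta = "Botrydium",
        Euglenophyta = "Euglena",
        Miozoa = "Ceratium"),
      wet = list(
        Bacillariophyta = c("Coscinodiscus", "Lioloma", "Pleorosigma",
                            "Cyclotella", "Fragilaria", "Asterionella",
                            "Odontella", "Licmophora", "Synedra",
                            "Thalassonema", "Surirella", "Triceratium",
                            "Melosira", "Nitzchia"),
        Chlorophyta = c("Hydrodictyon", "Pediastrum", "Oedogonium",
                        "Muogeotia", "Phytoconis", "Microspora", "Volvox",
                        "Arthrospira", "Zygnema", "Spirogyra", "Tetraedron"),
        Cyanobacteria = c("Microcystis", "Anabaena", "Gomphosphaeria",
                          "Oscillatoria"),
        Euglenophyta = "Euglena",
        Miozoa = c("Ceratium", "Detonula"))),
    gut = list(
      dry = list(
        Bacillariophyta = c("Synedra", "Coscinodiscus", "Pleorosigma",
                            "Triceratium", "Navicula", "Fragilaria",
                            "Lioloma", "Ditylum", "Odontella", "Gomphonema"),
        Chlorophyta = c("Oedogonium", "Spirogyra", "Pediastrum", "Muogeotia",
                        "Ulothrix", "Microspora", "Volvox", "Tetraedron",
                        "Chlorella", "Zygnema", "Closterium", "Stichococcus"),
        Cyanobacteria = c("Oscillatoria", "Chroococcus", "Microcystis",
                          "Aphanizomenon", "Gomphosphaeria", "Anabaena",
                          "Merismopedium"),
        Xanthophyta = "Botrydium"),
      wet = list(
        Bacillariophyta = c("Coscinodiscus", "Melosira", "Synedra",
                            "Fragilaria", "Asterionella", "Odontella",
                            "Diatoma", "Navicula", "Surirella", "Nitzchia",
                            "Lioloma"),
        Chlorophyta = c("Muogeotia", "Spirogyra", "Zygnema", "Ulothrix",
                        "Pediastrum", "Phytocoris", "Cladophora",
                        "Arthrospira"),
        Cyanobacteria = c("Gomphosphaeria", "Microcystis", "Oscillatoria",
                          "Gleocapsa", "Anabena"),
        Euglenophyta = "Euglena")))
}

#' Scenario specification for the synthetic estuary
#'
#' Describes the world the generator emulates: five stations (12 sites)
#' spanning ~100 km of estuary axis, a dry (December-March) and wet
#' (July/August/October) sampling season, per-station seasonal medians and
#' standard errors for the ten-parameter panel, percent compositions of the
#' phytoplankton community in water tows and in hilsa guts, 90 fish of
#' 18-35 cm, and seasonal cell-density ranges (dry 16.2-94.1 thousand,
#' wet 10.3-215.1 thousand cells/L).
#'
#' Noise model: each record is drawn from a normal law centred on its
#' seasonal station median with spread `se * sqrt(n_eff)`, truncated at 0
#' (and at 14 for pH). Wet-season salinity is additionally truncated below
#' the 0.5 PSU freshwater bound, the generator's structural contract that
#' the whole estuary runs fresh in the monsoon.
#'
#' @param stations data frame with `station_id`, `axis_km` (strictly
#'   increasing) and `n_sites`.
#' @param months named list of integer sampling months per season.
#' @param params per-parameter seasonal location/scale lists.
#' @param n_eff effective replicates per season-station; spread =
#'   `se * sqrt(n_eff)`. Zero gives degenerate (exact-median) records.
#' @param water_composition,gut_composition named percent vectors per season.
#' @param genus_lists genus labels per source/season/phylum.
#' @param n_fish number of gut samples.
#' @param fish_length_range fork-length range, cm.
#' @param density_range per-season water-sample total-count range (cells/L,
#'   one litre equivalent per table).
#' @param gut_total_range per-fish total prey count range.
#' @param rng_seed default seed for the simulation functions.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(stations = .station_frame(),
                          months = list(dry = c(12L, 1L, 2L, 3L),
                                        wet = c(7L, 8L, 10L)),
                          params = .water_param_defaults(),
                          n_eff = 6,
                          water_composition = .composition_defaults()$water,
                          gut_composition = .composition_defaults()$gut,
                          genus_lists = .genus_defaults(),
                          n_fish = 90L,
                          fish_length_range = c(18, 35),
                          density_range = list(dry = c(16200, 94100),
                                               wet = c(10300, 215100)),
                          gut_total_range = c(50, 500),
                          rng_seed = 1L) {
  if (is.unsorted(stations$axis_km, strictly = TRUE))
    stop("station axis_km must be strictly increasing")
  if (n_eff < 0) stop("n_eff must be non-negative")
  for (comp in c(water_composition, gut_composition))
    if (any(comp < 0)) stop("composition percents must be non-negative")
  structure(list(stations = stations, months = months, params = params,
                 n_eff = n_eff,
                 water_composition = water_composition,
                 gut_composition = gut_composition,
                 genus_lists = genus_lists,
                 n_fish = as.integer(n_fish),
                 fish_length_range = fish_length_range,
                 density_range = density_range,
                 gut_total_range = gut_total_range,
                 rng_seed = as.integer(rng_seed)),
            class = "scenario_spec")
}

# inverse-CDF truncated normal; sd = 0 degenerates to the (clamped) mean
.rtruncnorm <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (any(sd < 0)) stop("spread must be non-negative")
  out <- numeric(n)
  u <- stats::runif(n)  # always consume n draws so streams stay aligned
  deg <- sd == 0
  out[deg] <- pmin(pmax(mean[deg], lower), upper)
  if (any(!deg)) {
    plo <- stats::pnorm(lower, mean[!deg], sd[!deg])
    phi <- stats::pnorm(upper, mean[!deg], sd[!deg])
    out[!deg] <- stats::qnorm(plo + u[!deg] * (phi - plo),
                              mean[!deg], sd[!deg])
  }
  out
}

.season_year <- c(dry = 2020L, wet = 2020L)

#' Simulate the seasonal water-quality panel
#'
#' One record per site and sampling month; each parameter is drawn from a
#' truncated normal centred on the seasonal station median with spread
#' `se * sqrt(n_eff)`. Structural contrasts are built in: dry-season
#' salinity rises monotonically seaward at the station medians, wet-season
#' salinity is truncated below 0.5 PSU everywhere, dry DO exceeds wet DO
#' and wet temperature exceeds dry temperature.
#'
#' @param spec a [scenario_spec()].
#' @param seed integer seed (defaults to the scenario's `rng_seed`).
#' @return a `water_panel` data frame.
#' @export
simulate_water_panel <- function(spec = scenario_spec(),
                                 seed = spec$rng_seed) {
  set.seed(seed)
  rows <- list()
  for (season in c("dry", "wet")) {
    for (month in spec$months[[season]]) {
      date <- sprintf("%04d-%02d-15", .season_year[[season]], month)
      for (k in seq_len(nrow(spec$stations))) {
        st <- spec$stations$station_id[k]
        for (s in seq_len(spec$stations$n_sites[k])) {
          rec <- list(station_id = st, site_id = sprintf("%s-%d", st, s),
                      date = date)
          for (pn in names(spec$params)) {
            loc <- spec$params[[pn]][[season]]$med[[st]]
            sca <- spec$params[[pn]][[season]]$se[[st]] * sqrt(spec$n_eff)
            upper <- Inf
            if (pn == "ph") upper <- 14
            if (pn == "salinity" && season == "wet") upper <- 0.5 - 1e-9
            rec[[pn]] <- .rtruncnorm(1L, loc, sca, 0, upper)
          }
          rows[[length(rows) + 1L]] <- as.data.frame(rec)
        }
      }
    }
  }
  as_water_panel(do.call(rbind, rows))
}

#' Simulate an along-axis CTD salinity section
#'
#' Dry season: near-bottom salinity increases linearly along the axis from
#' 0.15 PSU at the head to exactly 13 PSU at the seaward end, and each cast
#' is built well-mixed -- the surface-to-bottom difference is a random
#' fraction below 1% of the depth-mean, so the stratification parameter is
#' below 0.01 by construction. Wet season: the whole section runs fresh,
#' every value below 0.15 PSU.
#'
#' @param spec a [scenario_spec()].
#' @param season `"dry"` or `"wet"`.
#' @param seed integer seed.
#' @return a `ctd_table` data frame (long format, one row per depth).
#' @export
simulate_ctd_section <- function(spec = scenario_spec(), season,
                                 seed = spec$rng_seed) {
  if (!season %in% c("dry", "wet")) stop("unknown season: ", season)
  if (nrow(spec$stations) < 2L) stop("need at least 2 stations")
  set.seed(seed)
  axis_max <- max(spec$stations$axis_km)
  t_med <- c(dry = 22.5, wet = 30.8)
  rows <- list()
  for (k in seq_len(nrow(spec$stations))) {
    ax <- spec$stations$axis_km[k]
    depth_max <- 8 + round(ax / 25)
    depths <- seq(1, depth_max)
    if (season == "dry") {
      s_bot <- 0.15 + (13 - 0.15) * ax / axis_max
      ns <- stats::runif(1, 0.002, 0.009)
      s_sur <- s_bot * (1 - ns / 2) / (1 + ns / 2)
    } else {
      s_bot <- stats::runif(1, 0.02, 0.14)
      s_sur <- s_bot * (1 - stats::runif(1, 0.001, 0.004))
    }
    frac <- (depths - depths[1]) / (depth_max - depths[1])
    sal <- s_sur + (s_bot - s_sur) * frac
    temp <- t_med[[season]] + stats::rnorm(1, 0, 0.3) -
      0.01 * (depths - depths[1])
    rows[[k]] <- data.frame(
      station_id = spec$stations$station_id[k],
      date = sprintf("%04d-%02d-15", .season_year[[season]],
                     spec$months[[season]][1]),
      axis_km = ax, depth_m = depths, salinity = sal, temperature = temp)
  }
  df <- do.call(rbind, rows)
  df$date <- as.Date(df$date)
  class(df) <- c("ctd_table", "data.frame")
  df
}

#' Simulate taxon count tables
#'
#' Water tows get one table per site (12 per season) with totals drawn
#' uniformly within the seasonal density range; gut samples get one table
#' per fish with totals in the configured 50-500 prey range, fish length
#' uniform on 18-35 cm and weight following an allometric length-weight
#' curve. Per-phylum counts are multinomial with probabilities equal to the
#' configured percents renormalised to 1 (the renormalisation factor is
#' recorded as attribute `renormalisation`); counts are split uniformly
#' across the genus list of each phylum, so genus identity carries no
#' signal.
#'
#' @param spec a [scenario_spec()].
#' @param source `"water"` or `"gut"`.
#' @param season `"dry"` or `"wet"`.
#' @param n_tables number of tables (defaults: total sites for water,
#'   `n_fish` for gut).
#' @param seed integer seed.
#' @return a `counts_table` data frame.
#' @export
simulate_counts <- function(spec = scenario_spec(), source, season,
                            n_tables = NULL, seed = spec$rng_seed) {
  if (!source %in% c("water", "gut")) stop("unknown source: ", source)
  if (!season %in% c("dry", "wet")) stop("unknown season: ", season)
  comp <- if (source == "water") spec$water_composition[[season]]
          else spec$gut_composition[[season]]
  if (is.null(comp) || sum(comp) <= 0)
    stop("all-zero composition for ", source, " / ", season)
  renorm <- 100 / sum(comp)
  probs <- comp / sum(comp)
  genus_lists <- spec$genus_lists[[source]][[season]]
  set.seed(seed)
  if (is.null(n_tables))
    n_tables <- if (source == "water") sum(spec$stations$n_sites)
                else spec$n_fish
  months <- spec$months[[season]]
  rows <- list()
  for (i in seq_len(n_tables)) {
    if (source == "water") {
      rng <- spec$density_range[[season]]
      sample_id <- sprintf("W-%s-%02d", season, i)
      len <- NA_real_; wt <- NA_real_
    } else {
      rng <- spec$gut_total_range
      sample_id <- sprintf("F-%s-%03d", season, i)
      len <- stats::runif(1, spec$fish_length_range[1],
                          spec$fish_length_range[2])
      wt <- 0.0188 * len^3 * exp(stats::rnorm(1, 0, 0.05))
    }
    total <- round(stats::runif(1, rng[1], rng[2]))
    phylum_counts <- as.vector(stats::rmultinom(1, total, probs))
    names(phylum_counts) <- names(probs)
    month <- months[1L + (i - 1L) %% length(months)]
    for (ph in names(phylum_counts)) {
      n_ph <- phylum_counts[[ph]]
      genera <- genus_lists[[ph]]
      if (is.null(genera)) genera <- paste0(ph, "_sp")
      gcounts <- as.vector(stats::rmultinom(1, n_ph,
                                            rep(1 / length(genera),
                                                length(genera))))
      keep <- gcounts > 0
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        source = source, sample_id = sample_id,
        fish_length_cm = len, fish_weight_g = wt,
        genus = genera[keep], phylum = ph, count = gcounts[keep],
        date = sprintf("%04d-%02d-15", .season_year[[season]], month))
    }
  }
  out <- as_counts_table(do.call(rbind, rows))
  attr(out, "renormalisation") <- renorm
  out
}

#' Run the full generator and write the three CSV tables
#'
#' @param spec a [scenario_spec()].
#' @param out_dir output directory (created if needed).
#' @param seed master seed; stage seeds are derived deterministically.
#' @return invisibly, named paths of `water.csv`, `ctd.csv`, `counts.csv`.
#' @export
simulate_all <- function(spec = scenario_spec(), out_dir,
                         seed = spec$rng_seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  water <- simulate_water_panel(spec, seed = seed)
  ctd <- rbind(simulate_ctd_section(spec, "dry", seed = seed + 1L),
               simulate_ctd_section(spec, "wet", seed = seed + 2L))
  counts <- rbind(simulate_counts(spec, "water", "dry", seed = seed + 3L),
                  simulate_counts(spec, "water", "wet", seed = seed + 4L),
                  simulate_counts(spec, "gut", "dry",
                                  n_tables = spec$n_fish %/% 2L,
                                  seed = seed + 5L),
                  simulate_counts(spec, "gut", "wet",
                                  n_tables = spec$n_fish -
                                    spec$n_fish %/% 2L,
                                  seed = seed + 6L))
  paths <- c(water = file.path(out_dir, "water.csv"),
             ctd = file.path(out_dir, "ctd.csv"),
             counts = file.path(out_dir, "counts.csv"))
  write_water_table(water, paths[["water"]])
  write_ctd_table(ctd, paths[["ctd"]])
  write_counts_table(counts, paths[["counts"]])
  invisible(paths)
}
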