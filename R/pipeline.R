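#' Run the full analysis pipeline
#'
#' End-to-end orchestration: simulate (or load) the three input tables,
#' then run hydrography, community composition/diversity, electivity,
#' trophic classification, panel statistics and PUFA attribution, writing
#' one CSV per stage plus a JSON run manifest. Deterministic under a fixed
#' seed.
#'
#' @param out_dir output directory (created if needed).
#' @param spec a [scenario_spec()] used when inputs are simulated.
#' @param config an [analysis_config()].
#' @param seed master seed.
#' @param inputs optional named paths (`water`, `ctd`, `counts`) to
#'   existing CSVs; when `NULL` the generator produces them under
#'   `out_dir/inputs`.
#' @return invisibly, the manifest list (`seed`, `config_hash`, `inputs`,
#'   `outputs`, `warnings`, `version`).
#' @export
run_pipeline <- function(out_dir, spec = scenario_spec(),
                         config = analysis_config(), seed = spec$rng_seed,
                         inputs = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  note <- function(...) warnings_log <<- c(warnings_log, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  if (is.null(inputs)) {
    inputs <- stage("simulate",
                    simulate_all(spec, file.path(out_dir, "inputs"),
                                 seed = seed))
    note("inputs simulated with seed %d", seed)
  }
  water <- stage("simulate", read_water_table(inputs[["water"]], config))
  ctd <- stage("simulate", read_ctd_table(inputs[["ctd"]]))
  counts <- stage("simulate", read_counts_table(inputs[["counts"]]))
  known <- unique(water$station_id)
  if (!is.null(counts$station_id)) {
    bad <- setdiff(unique(counts$station_id), known)
    if (length(bad) > 0L)
      stop("unknown station label in counts table: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(counts$date)) {
    counts$season <- "all"
    note("counts.csv has no date column; compositions pooled over seasons")
  } else {
    counts$season <- season_of_month(
      as.integer(format(as.Date(counts$date), "%m")), config)
  }
  outputs <- character()
  emit <- function(name, df) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  # hydrography: per-cast stratification, Venice class, isohaline per season
  hydro <- stage("hydrography", {
    strat <- stratify_section(ctd, config)
    strat$venice_class <- venice_class(strat$s_bot, config)
    strat$season <- season_of_month(
      as.integer(format(as.Date(strat$date), "%m")), config)
    iso <- vapply(split(strat, strat$season), function(sub) {
      casts <- lapply(seq_len(nrow(sub)), function(i)
        list(axis_km = sub$axis_km[i],
             salinity = c(sub$s_sur[i], sub$s_bot[i])))
      isohaline_position(casts)
    }, numeric(1))
    strat$isohaline2_km <- iso[strat$season]
    strat
  })
  emit("hydrography.csv", hydro)

  # community: composition and Simpson diversity per source and season
  community <- stage("community", {
    comp_rows <- list(); div_rows <- list()
    for (src in unique(counts$source)) {
      for (ss in unique(counts$season[counts$source == src])) {
        sub <- counts[counts$source == src & counts$season == ss, ]
        pc <- composition(sub, "phylum")
        comp_rows[[paste(src, ss)]] <-
          data.frame(source = src, season = ss, phylum = names(pc),
                     percent = as.vector(pc))
        dv <- simpson(sub, "genus")
        div_rows[[paste(src, ss)]] <-
          data.frame(source = src, season = ss, d = dv$d,
                     reciprocal = dv$reciprocal, n_taxa = dv$n_taxa,
                     n_total = dv$n_total)
      }
    }
    list(composition = do.call(rbind, comp_rows),
         diversity = do.call(rbind, div_rows))
  })
  emit("composition.csv", community$composition)
  emit("diversity.csv", community$diversity)

  # electivity: water vs gut, pooled seasons, phylum level with size bins
  elec <- stage("electivity", {
    withCallingHandlers(
      electivity_profile(counts[counts$source == "water", ],
                         counts[counts$source == "gut", ],
                         level = "phylum", correction = "add_half"),
      warning = function(w) {
        note("electivity: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  })
  emit("electivity.csv", elec)

  trophic <- stage("trophic", {
    do.call(rbind, lapply(intersect(c("dry", "wet"), unique(water$season)),
                          function(ss)
                            trophic_report(water, ss,
                                           config$trophic_thresholds)))
  })
  emit("trophic.csv", trophic)

  stats_out <- stage("stats", {
    tests <- do.call(rbind, lapply(.panel_parameters(), function(pn) {
      st <- seasonal_test(water, pn, config)
      kt <- spatial_test(water, pn, config)
      data.frame(parameter = pn,
                 test = c(st$test, kt$test),
                 statistic = c(st$statistic, kt$statistic),
                 p_value = c(st$p_value, kt$p_value),
                 significant_at = c(st$significant_at, kt$significant_at))
    }))
    pca <- pca_panel(water)
    list(tests = tests,
         correlations = correlation_matrix(water, config = config),
         pca_summary = data.frame(
           dimension = seq_along(pca$eigenvalues),
           eigenvalue = pca$eigenvalues,
           percent_variance = pca$percent_variance,
           cumulative_percent = pca$cumulative_percent))
  })
  emit("tests.csv", stats_out$tests)
  emit("correlations.csv", stats_out$correlations)
  emit("pca_summary.csv", stats_out$pca_summary)

  pufa_out <- stage("pufa", {
    comp <- community$composition
    rows <- lapply(unique(comp$source), function(src) {
      sub <- comp[comp$source == src, ]
      seasons <- split(stats::setNames(sub$percent, sub$phylum), sub$season)
      if (all(c("dry", "wet") %in% names(seasons))) {
        avg <- suppressWarnings(season_average_contribution(seasons))
      } else {
        avg <- seasons[[1]]
      }
      score <- pufa_weighted_score(avg)
      data.frame(source = src, phylum = names(avg),
                 season_avg_percent = round_half_up(as.vector(avg), 1),
                 pufa_score = score$score,
                 annotated_mass = score$annotated_mass)
    })
    do.call(rbind, rows)
  })
  emit("pufa.csv", pufa_out)

  cfg_file <- tempfile()
  dput(list(spec = unclass(spec), config = unclass(config)), cfg_file)
  manifest <- list(seed = seed,
                   config_hash = unname(tools::md5sum(cfg_file)),
                   inputs = as.list(inputs),
                   outputs = outputs,
                   warnings = warnings_log,
                   version = as.character(utils::packageVersion("phytodiet")))
  unlink(cfg_file)
  stopifnot(all(file.exists(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Command-line interface
#'
#' Subcommand dispatcher used by the `phytodiet` executable script
#' (`inst/cli/phytodiet`): `simulate`, `hydro`, `community`, `electivity`,
#' `trophic`, `stats`, `pufa` and `run-all`, each taking `--out DIR` plus
#' stage-specific inputs (`--water`, `--ctd`, `--counts`, `--seed`,
#' `--iso`, `--level`, `--correction`, `--season`).
#'
#' @param args character vector, default the command line.
#' @return invisibly, the paths written.
#' @export
phytodiet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: phytodiet <simulate|hydro|community|electivity|trophic|",
         "stats|pufa|run-all> [--key value ...]")
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  while (length(rest) >= 2L) {
    if (!startsWith(rest[1], "--")) stop("unexpected argument: ", rest[1])
    opts[[substring(rest[1], 3)]] <- rest[2]
    rest <- rest[-(1:2)]
  }
  out <- opts[["out"]] %||% "."
  seed <- as.integer(opts[["seed"]] %||% 1L)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- switch(
    cmd,
    "simulate" = simulate_all(scenario_spec(rng_seed = seed), out,
                              seed = seed),
    "hydro" = {
      ctd <- read_ctd_table(opts[["ctd"]])
      strat <- stratify_section(ctd)
      strat$venice_class <- venice_class(strat$s_bot)
      path <- file.path(out, "hydrography.csv")
      utils::write.csv(strat, path, row.names = FALSE)
      path
    },
    "community" = {
      counts <- read_counts_table(opts[["counts"]])
      src <- opts[["source"]] %||% "water"
      sub <- counts[counts$source == src, ]
      pc <- composition(sub, "phylum")
      dv <- simpson(sub, "genus")
      p1 <- file.path(out, "composition.csv")
      utils::write.csv(data.frame(source = src, phylum = names(pc),
                                  percent = as.vector(pc)),
                       p1, row.names = FALSE)
      p2 <- file.path(out, "diversity.csv")
      utils::write.csv(data.frame(source = src, d = dv$d,
                                  reciprocal = dv$reciprocal,
                                  n_taxa = dv$n_taxa,
                                  n_total = dv$n_total),
                       p2, row.names = FALSE)
      c(p1, p2)
    },
    "electivity" = {
      water <- read_counts_table(opts[["water"]])
      gut <- read_counts_table(opts[["gut"]])
      prof <- electivity_profile(
        water[water$source == "water", ], gut[gut$source == "gut", ],
        level = opts[["level"]] %||% "phylum",
        correction = gsub("-", "_", opts[["correction"]] %||% "none"))
      path <- file.path(out, "electivity.csv")
      utils::write.csv(prof, path, row.names = FALSE)
      path
    },
    "trophic" = {
      water <- read_water_table(opts[["water"]])
      rep <- trophic_report(water, opts[["season"]])
      path <- file.path(out, "trophic.csv")
      utils::write.csv(rep, path, row.names = FALSE)
      path
    },
    "stats" = {
      water <- read_water_table(opts[["water"]])
      tests <- do.call(rbind, lapply(.panel_parameters(), function(pn) {
        st <- seasonal_test(water, pn)
        data.frame(parameter = pn, test = st$test,
                   statistic = st$statistic, p_value = st$p_value)
      }))
      path <- file.path(out, "tests.csv")
      utils::write.csv(tests, path, row.names = FALSE)
      path
    },
    "pufa" = {
      comp <- utils::read.csv(opts[["composition"]])
      seasons <- split(stats::setNames(comp$percent, comp$phylum),
                       comp$season)
      avg <- suppressWarnings(season_average_contribution(seasons))
      score <- pufa_weighted_score(avg)
      path <- file.path(out, "pufa_report.csv")
      utils::write.csv(data.frame(phylum = names(avg),
                                  season_avg_percent =
                                    round_half_up(as.vector(avg), 1),
                                  pufa_score = score$score),
                       path, row.names = FALSE)
      path
    },
    "run-all" = {
      manifest <- run_pipeline(out, scenario_spec(rng_seed = seed),
                               seed = seed)
      unlist(manifest$outputs)
    },
    stop("unknown subcommand: ", cmd))
  invisible(written)
}
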