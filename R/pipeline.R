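#' Run configuration
#'
#' Single validated configuration object consumed by [run_pipeline()].
#' Either a `scenario` (synthetic generation) or the two input paths must
#' be supplied.
#'
#' @param scenario A [scenario_config()], or NULL when reading real files.
#' @param tracks_csv,hurdat Input paths (ignored when `scenario` given).
#' @param out_dir Where stage outputs are written.
#' @param geo A [geo_params()].
#' @param encounter An [encounter_config()].
#' @param season List: `start_md`, `end_md`, `year_min`, `year_max`,
#'   `min_status`.
#' @param kde List: `bandwidth_method`, `cell_km`, `mass`.
#' @param plant_spec For synthetic runs: fraction of each population's
#'   journeys given a planted encounter, and the planted separation (km).
#' @param seed Integer seed for any stage randomness.
#' @return A validated `run_config`.
#' @export
run_config <- function(scenario = NULL, tracks_csv = NULL, hurdat = NULL,
                       out_dir = tempfile("stormcross_run_"),
                       geo = geo_params(),
                       encounter = encounter_config(),
                       season = list(start_md = "07-15", end_md = "11-30",
                                     year_min = 1961, year_max = 2030,
                                     min_status = "TD"),
                       kde = list(bandwidth_method = "nrd", cell_km = 25,
                                  mass = 0.5),
                       plant_spec = list(frac = c(MackenzieDelta = 0.12,
                                                  HudsonBay = 0.62),
                                         separation_km = 80),
                       seed = 1L) {
  cfg <- list(scenario = scenario, tracks_csv = tracks_csv, hurdat = hurdat,
              out_dir = out_dir, geo = geo, encounter = encounter,
              season = season, kde = kde, plant_spec = plant_spec,
              seed = as.integer(seed))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$scenario) &&
      (is.null(cfg$tracks_csv) || is.null(cfg$hurdat)))
    stop("run_config needs a scenario or both input paths")
  if (!inherits(cfg$geo, "geo_params")) stop("geo must be geo_params()")
  if (!inherits(cfg$encounter, "encounter_config"))
    stop("encounter must be encounter_config()")
  need_season <- c("start_md", "end_md", "year_min", "year_max", "min_status")
  if (!all(need_season %in% names(cfg$season)))
    stop("season must name: ", paste(need_season, collapse = ", "))
  if (!grepl("^[01][0-9]-[0-3][0-9]$", cfg$season$start_md))
    stop("season start_md must be 'mm-dd'")
  if (!all(c("bandwidth_method", "cell_km", "mass") %in% names(cfg$kde)))
    stop("kde must name bandwidth_method, cell_km, mass")
  if (cfg$kde$mass <= 0 || cfg$kde$mass >= 1) stop("kde mass in (0,1)")
  invisible(TRUE)
}

#' Read a run configuration from a YAML file
#'
#' Scalar overrides of the [run_config()] defaults, validated against the
#' same schema.
#'
#' @param path YAML file with (optionally nested) keys `tracks_csv`,
#'   `hurdat`, `out_dir`, `seed`, `geo`, `encounter`, `season`, `kde`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  geo <- do.call(geo_params, raw$geo %||% list())
  enc <- do.call(encounter_config, raw$encounter %||% list())
  args <- list(tracks_csv = raw$tracks_csv, hurdat = raw$hurdat,
               geo = geo, encounter = enc,
               seed = raw$seed %||% 1L)
  if (!is.null(raw$out_dir)) args$out_dir <- raw$out_dir
  if (!is.null(raw$season)) args$season <- utils::modifyList(
    formals(run_config)$season |> eval(), raw$season)
  if (!is.null(raw$kde)) args$kde <- utils::modifyList(
    formals(run_config)$kde |> eval(), raw$kde)
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Choose planted encounters from generator truth: for the requested
# fraction of each cohort, the storm/instant pair (during the bird's ocean
# crossing, inside the storm's track span with 36 h of warp headroom) that
# minimizes the bird-storm distance; plants needing a displacement beyond
# what the storm-speed limit allows are skipped.
choose_plants <- function(tracks, truth, storms, plant_spec,
                          params = geo_params(), max_shift_km = 1500) {
  plants <- list()
  for (pop in names(plant_spec$frac)) {
    tp <- truth[truth$population == pop, , drop = FALSE]
    n_plant <- round(plant_spec$frac[[pop]] * nrow(tp))
    planted <- 0L
    for (i in seq_len(nrow(tp))) {
      if (planted >= n_plant) break
      w0 <- as.numeric(tp$t_coast_exit[i]) + 6 * 3600
      w1 <- as.numeric(tp$t_coast_enter[i]) - 6 * 3600
      if (w1 <= w0) next
      cands <- list()
      for (s in storms) {
        st <- as.numeric(s$points$timestamp)
        lo <- max(w0, st[1] + 36 * 3600); hi <- min(w1, st[length(st)] - 36 * 3600)
        if (lo >= hi) next
        tg <- seq(lo, hi, by = 6 * 3600)
        bp <- interpolate_position(tracks[[tp$bird_id[i]]], tg, params)
        sp <- interpolate_position(s$points, tg, params)
        d <- gc_distance(bp, sp, params)
        m <- which.min(d)
        cands[[length(cands) + 1L]] <- list(storm_id = s$storm_id,
                                            t = tg[m], d = d[m])
      }
      if (length(cands) == 0L) next
      cands <- cands[order(vapply(cands, `[[`, numeric(1), "d"))]
      best <- NULL
      for (cand in cands) {
        if (cand$d > max_shift_km) break
        # avoid overlapping warp windows (taper is +/- 36 h) on one storm
        clash <- vapply(plants, function(p)
          p$storm_id == cand$storm_id &&
            abs(as.numeric(p$time) - cand$t) < 72 * 3600, logical(1))
        if (!any(clash)) { best <- cand; break }
      }
      if (is.null(best)) next
      planted <- planted + 1L
      plants[[length(plants) + 1L]] <- data.frame(
        bird_id = tp$bird_id[i], storm_id = best$storm_id,
        time = as.POSIXct(best$t, origin = "1970-01-01", tz = "UTC"),
        separation_km = plant_spec$separation_km,
        population = pop, stringsAsFactors = FALSE)
    }
  }
  if (length(plants) == 0L) return(NULL)
  do.call(rbind, c(plants, list(make.row.names = FALSE)))
}

#' Run the full track-storm interaction pipeline
#'
#' Ingest (or synthesize) telemetry and best-track inputs, quality-filter
#' and segment each bird's journey, build the seasonal cyclone-density risk
#' region, measure per-journey exposure, detect and classify encounters,
#' and fit the inferential layer. Stage outputs are written under
#' `config$out_dir`; re-running with the same config and seed reproduces
#' identical tables.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A `results_bundle`: journeys, exposure, encounters,
#'   encounter-rate and statistics tables plus a provenance block.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  validate_run_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  geom <- if (!is.null(config$scenario)) config$scenario$geometry
  else scenario_geometry()
  params <- config$geo

  # ---- stage 0: inputs ----------------------------------------------------
  plant_truth <- NULL
  if (!is.null(config$scenario)) {
    sc <- config$scenario
    gen_b <- generate_bird_tracks(sc, params)
    gen_s <- generate_storm_basin(sc, params = params)
    storms0 <- gen_s$storms
    plants <- if (!is.null(sc$plants)) sc$plants
    else choose_plants(gen_b$tracks, gen_b$truth, storms0,
                       config$plant_spec, params)
    if (!is.null(plants)) {
      ok <- vapply(seq_len(nrow(plants)), function(i)
        !inherits(tryCatch(plant_encounters(gen_b$tracks, storms0,
                                            plants[i, ], params),
                           error = function(e) e), "error"), logical(1))
      if (any(ok)) {
        pl <- plant_encounters(gen_b$tracks, storms0,
                               plants[ok, , drop = FALSE], params)
        storms0 <- pl$storms
        plant_truth <- pl$truth
      }
    }
    tracks_csv <- file.path(config$out_dir, "tracks.csv")
    hurdat <- file.path(config$out_dir, "basin.hurdat2")
    write_telemetry_csv(gen_b$tracks, tracks_csv)
    write_hurdat2(storms0, hurdat)
  } else {
    tracks_csv <- config$tracks_csv
    hurdat <- config$hurdat
  }

  raw_tracks <- parse_telemetry_csv(
    tracks_csv, column_map = c(id = "bird_id", timestamp = "timestamp",
                               lat = "lat", lon = "lon", lc = "lc",
                               population = "population"))
  tracks <- lapply(raw_tracks, filter_by_location_class, allowed = c("1", "2", "3"))
  say("ingest: %d birds (%d fixes raw, %d after LC filter)",
      length(tracks), sum(vapply(raw_tracks, nrow, numeric(1))),
      sum(vapply(tracks, nrow, numeric(1))))
  storms <- parse_hurdat2(hurdat)

  # ---- stage 1: climatology ----------------------------------------------
  season <- config$season
  storms_f <- filter_storm_season(storms, season$start_md, season$end_md,
                                  season$year_min, season$year_max,
                                  season$min_status)
  pts <- build_storm_points(storms_f)
  say("climatology: %d storms, %d synoptic points after season filter",
      length(storms_f), nrow(pts))
  grid <- fit_kde(pts, bandwidth_method = config$kde$bandwidth_method,
                  cell_km = config$kde$cell_km, params = params)
  region <- hdr_region(grid, config$kde$mass)
  write_region_geojson(region, file.path(config$out_dir, "region.geojson"))

  # ---- stage 2: journeys, exposure, encounters ----------------------------
  journeys <- list(); exposures <- list(); encounters <- list()
  for (id in names(tracks)) {
    tr <- tracks[[id]]
    res <- tryCatch({
      ph <- detect_residency(tr, params = params)
      da <- detect_departure_arrival(ph, tr, params = params)
      oc <- segment_transoceanic(tr, geom, params)
      enc <- detect_inflight_encounters(
        tr[tr$timestamp >= oc$phase$start & tr$timestamp <= oc$phase$end, ],
        storms, config$encounter, params)
      stat_ph <- ph[ph$kind == "staging", , drop = FALSE]
      for (si in seq_len(nrow(stat_ph)))
        enc <- rbind(enc, detect_grounded_encounters(
          stat_ph[si, ], storms, bird_id = id, config$encounter, params))
      if (nrow(enc))
        enc$response <- vapply(seq_len(nrow(enc)), function(i)
          classify_response(tr, enc[i, ], geom$islands, config$encounter,
                            params), character(1))
      grounded <- nrow(enc) > 0 && any(enc$response == "grounded",
                                       na.rm = TRUE)
      js <- summarize_journey(tr, da, oc, grounded = grounded, params)
      ex <- exposure_time(
        tr[tr$timestamp >= da$departure & tr$timestamp <= da$arrival, ],
        region, params, mode = if (grounded) "grounded" else "nonstop")
      list(js = js, ex = ex, enc = enc)
    }, error = function(e) {
      say("journey %s skipped: %s", id, conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    journeys[[id]] <- res$js
    exposures[[id]] <- data.frame(bird_id = id,
                                  population = res$js$population,
                                  total_days = res$ex$total_days,
                                  mode = res$ex$mode,
                                  stringsAsFactors = FALSE)
    if (nrow(res$enc)) encounters[[id]] <- res$enc
  }
  journeys <- do.call(rbind, c(journeys, list(make.row.names = FALSE)))
  exposures <- do.call(rbind, c(exposures, list(make.row.names = FALSE)))
  encounters <- if (length(encounters))
    do.call(rbind, c(encounters, list(make.row.names = FALSE)))
  else empty_encounters()
  rates <- summarize_encounter_rates(journeys, encounters)

  # ---- stage 3: statistics ------------------------------------------------
  stats_tab <- pipeline_statistics(journeys, exposures, encounters, rates)

  bundle <- structure(list(
    journeys = journeys, exposure = exposures, encounters = encounters,
    rates = rates, statistics = stats_tab$tests,
    model_ranking = stats_tab$ranking, region = region, grid = grid,
    plant_truth = plant_truth,
    provenance = list(
      config = unclass(config),
      inputs = as.list(tools::md5sum(c(tracks_csv, hurdat))),
      package_version = as.character(utils::packageVersion("stormcross")))),
    class = "results_bundle")
  for (nm in c("journeys", "exposure", "rates"))
    utils::write.csv(bundle[[nm]], file.path(config$out_dir,
                                             paste0(nm, ".csv")),
                     row.names = FALSE)
  utils::write.csv(bundle$encounters,
                   file.path(config$out_dir, "encounters.csv"),
                   row.names = FALSE)
  bundle
}

# the inferential layer over the pipeline tables
pipeline_statistics <- function(journeys, exposures, encounters, rates) {
  tests <- list()
  pops <- sort(unique(journeys$population))
  if (length(pops) == 2L) {
    g <- lapply(pops, function(p)
      group_summary_of(journeys$ocean_flight_length_km[
        journeys$population == p]))
    tests$flight_length_t <- t_test_from_summary(g[[1]], g[[2]])
    gd <- lapply(pops, function(p)
      group_summary_of(journeys$ocean_flight_duration_days[
        journeys$population == p]))
    tests$flight_duration_t <- t_test_from_summary(gd[[1]], gd[[2]])
    tab <- cbind(rates$n_with_encounter,
                 rates$n_crossings - rates$n_with_encounter)
    tests$encounter_g <- tryCatch(g_test_yates(tab),
                                  error = function(e) NULL)
  }
  ranking <- NULL
  enc_year <- if (nrow(encounters))
    as.integer(format(encounters$time, "%Y", tz = "UTC")) else integer()
  hit <- vapply(seq_len(nrow(journeys)), function(i)
    any(encounters$bird_id == journeys$bird_id[i] &
          enc_year == journeys$year[i]), logical(1))
  jn <- stats::ave(seq_len(nrow(journeys)), journeys$bird_id,
                   FUN = seq_along)
  dat <- data.frame(hit = as.numeric(hit),
                    population = factor(journeys$population),
                    journey = factor(pmin(jn, 3)),
                    year = factor(journeys$year))
  if (nlevels(dat$year) >= 2L && length(pops) == 2L) {
    forms <- list(null = ~ 1, population = ~ population)
    if (nlevels(dat$journey) >= 2L) {
      forms$journey <- ~ journey
      forms$population_journey <- ~ population + journey
    }
    fits <- lapply(forms, function(f)
      tryCatch(fit_logistic_random_intercept(dat$hit, f, dat$year,
                                             data = dat),
               error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) >= 2L) {
      nest <- c(population = "null")
      if ("population_journey" %in% names(fits))
        nest <- c(nest, population_journey = "population")
      ranking <- rank_models(fits, nested_within = nest)
      tests$mixed_logit_population <- fits$population
    }
  }
  list(tests = tests, ranking = ranking)
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("stormcross results bundle\n")
  cat(sprintf("  journeys: %d (%s)\n", nrow(x$journeys),
              paste(sprintf("%s: %d", x$rates$population, x$rates$n_crossings),
                    collapse = ", ")))
  cat(sprintf("  encounters: %d (%d in flight, %d grounded)\n",
              nrow(x$encounters),
              sum(x$encounters$bird_state == "in_flight"),
              sum(x$encounters$bird_state == "grounded")))
  cat(sprintf("  risk region: %d polygon(s), mass %.2f\n",
              length(x$region$polygons), x$region$mass_level))
  invisible(x)
}

#' Render a results bundle as a markdown report
#'
#' Group means with standard errors, encounter rates with the integer
#' percentages recomputed from the counts in the same table, and the test
#' statistics.
#'
#' @param bundle A `results_bundle`.
#' @param path Optional file to write.
#' @return Character vector of markdown lines, invisibly when `path` given.
#' @export
report_results <- function(bundle, path = NULL) {
  fmt_gs <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2L)
      return(sprintf("%.1f (n = %d)", if (length(x)) mean(x) else NA_real_,
                     length(x)))
    g <- group_summary_of(x)
    sprintf("%.1f +/- %.2f (n = %d)", g$mean, g$se, g$n)
  }
  lines <- c("# Track-storm interaction results", "",
             "## Journeys")
  for (p in sort(unique(bundle$journeys$population))) {
    j <- bundle$journeys[bundle$journeys$population == p, ]
    lines <- c(lines, sprintf("- %s: ocean flight %s km over %s days; departure latitude %s",
                              p, fmt_gs(j$ocean_flight_length_km),
                              fmt_gs(j$ocean_flight_duration_days),
                              fmt_gs(j$ocean_departure_lat)))
  }
  lines <- c(lines, "", "## Exposure to the cyclone core region")
  for (p in sort(unique(bundle$exposure$population))) {
    e <- bundle$exposure[bundle$exposure$population == p, ]
    lines <- c(lines, sprintf("- %s: %s days inside the %.0f%% region",
                              p, fmt_gs(e$total_days),
                              100 * bundle$region$mass_level))
  }
  lines <- c(lines, "", "## Encounter rates",
             "| population | crossings | with encounter | % |",
             "|---|---|---|---|")
  for (i in seq_len(nrow(bundle$rates))) {
    r <- bundle$rates[i, ]
    lines <- c(lines, sprintf("| %s | %d | %d | %d%% |", r$population,
                              r$n_crossings, r$n_with_encounter,
                              encounter_rate_pct(r$n_with_encounter,
                                                 r$n_crossings)))
  }
  lines <- c(lines, "", "## Tests")
  for (nm in names(bundle$statistics)) {
    s <- bundle$statistics[[nm]]
    if (inherits(s, "stormcross_test"))
      lines <- c(lines, sprintf("- %s [%s]: statistic %.3g, df %.3g, p %.3g",
                                nm, s$method, s$statistic, s$df, s$p_value))
    else if (inherits(s, "mixed_logit"))
      lines <- c(lines, sprintf("- %s: z = %.3g for %s (AICc %.2f%s)",
                                nm, s$z[2], names(s$z)[2], s$aicc,
                                if (s$singular) ", singular" else ""))
  }
  if (!is.null(bundle$model_ranking)) {
    lines <- c(lines, "", "## Model ranking (AICc)",
               utils::capture.output(print(bundle$model_ranking)))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
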