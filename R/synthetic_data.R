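#' Synthetic study geometry
#'
#' Deliberately simplified, fully synthetic stand-ins for the study-area
#' geometry: two rectangular-ish "continent" polygons whose facing edges play
#' the roles of the North American Atlantic coast (slanted, so the two
#' staging regions sit at different coastal latitudes) and the north coast of
#' South America, plus a toy five-island arc standing in for the Antilles.
#' All polygons are closed (lon, lat) rings.
#'
#' @return A list with elements `north_america`, `south_america` (each a list
#'   of one ring), `land` (both), and `islands` (list of five rings).
#' @export
scenario_geometry <- function() {
  na_ring <- rbind(
    c(-135, 80), c(-56, 80), c(-56, 52), c(-81, 25),
    c(-135, 25), c(-135, 80))
  sa_ring <- rbind(
    c(-80, 7), c(-40, 7), c(-40, -20), c(-80, -20), c(-80, 7))
  island <- function(lon, lat, w = 0.6, h = 0.5) {
    rbind(c(lon - w, lat - h), c(lon + w, lat - h), c(lon + w, lat + h),
          c(lon - w, lat + h), c(lon - w, lat - h))
  }
  islands <- list(island(-72.5, 19.5), island(-66.5, 18.2),
                  island(-63.0, 17.0), island(-61.5, 15.0),
                  island(-61.0, 12.8))
  list(north_america = list(na_ring), south_america = list(sa_ring),
       land = list(na_ring, sa_ring), islands = islands,
       # endpoints of the straight Atlantic-facing coast segment
       na_coast = list(top = c(-56, 52), bottom = c(-81, 25)))
}

#' Scenario configuration for the synthetic generator
#'
#' Defaults encode the study conditions for the two tracked populations:
#' cohort sizes 13 (Mackenzie Delta) and 11 (Hudson Bay); ocean-crossing
#' length 5440 km (MD) vs 3643 km (HB) and duration 6.1 vs 4.5 days, with
#' SDs recovered from the printed standard errors (SD = SE * sqrt(n));
#' coastal departure latitudes near 47.5 deg N vs 37.0 deg N; transmitter
#' duty cycles of 24 h off / 5 h on and 48 h off / 10 h on.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param n_birds Named vector of cohort sizes.
#' @param year First (or only) tracking year; each bird is assigned a year
#'   cycling through `years`.
#' @param years Vector of journey years.
#' @param archetypes Per-population route parameters; see the default for
#'   the expected fields.
#' @param storm Storm-field parameters: `storms_per_year`, genesis box,
#'   drift speed (deg/6 h), recurvature probability, intensification rate
#'   (kt/6 h mean and SD), season window.
#' @param plants Optional data.frame of planted encounters with columns
#'   `bird_id`, `storm_id`, `time`, `separation_km` (see
#'   [plant_encounters()]).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(seed = 1L,
                            n_birds = c(MackenzieDelta = 13, HudsonBay = 11),
                            years = 2008:2019,
                            archetypes = NULL,
                            storm = NULL,
                            plants = NULL) {
  if (is.null(archetypes)) {
    archetypes <- list(
      MackenzieDelta = list(
        breeding = c(-134.9, 69.4),
        dep_lat_mean = 47.5, dep_lat_sd = 0.44 * sqrt(13),
        ocean_len_mean = 5440, ocean_len_sd = 120.3 * sqrt(13),
        ocean_dur_mean = 6.1, ocean_dur_sd = 0.18 * sqrt(13),
        total_mean = 11012, total_sd = 72.4 * sqrt(14),
        arrival = c(-55, 6), winter = c(-55, 5.5),
        dep_breed_md = "07-07", dep_breed_sd_days = 2.8 * sqrt(15),
        dep_month_day = "08-28", dep_stage_sd_days = 4,
        duty_cycle = c(off = 48, on = 10)),
      HudsonBay = list(
        breeding = c(-94.0, 57.5),
        dep_lat_mean = 37.0, dep_lat_sd = 0.65 * sqrt(11),
        ocean_len_mean = 3643, ocean_len_sd = 196.2 * sqrt(11),
        ocean_dur_mean = 4.5, ocean_dur_sd = 0.29 * sqrt(11),
        total_mean = 8404, total_sd = 76.0 * sqrt(13),
        arrival = c(-63, 6), winter = c(-63, 5.5),
        dep_breed_md = "07-25", dep_breed_sd_days = 3.5 * sqrt(16),
        dep_month_day = "09-24", dep_stage_sd_days = 4,
        duty_cycle = c(off = 24, on = 5)))
  }
  if (is.null(storm)) {
    storm <- list(storms_per_year = 8,
                  genesis_lon = c(-35, -20), genesis_lat = c(8, 13),
                  drift_deg = 1.3,          # westward deg per 6 h (east basin)
                  slow_lon = -60,           # west of this: slower, poleward
                  recurve_prob = 0.45,
                  intens_mean = 1.5, intens_sd = 4.0,
                  genesis_wind = c(25, 35),
                  season = c("07-20", "10-25"))
  }
  structure(list(seed = as.integer(seed), n_birds = n_birds, years = years,
                 archetypes = archetypes, storm = storm, plants = plants,
                 geometry = scenario_geometry()),
            class = "scenario_config")
}

# LC sampling: retained classes 1-3 dominate; the noise SD per class uses
# the class definitions' accuracy bounds as 1-sigma values.
LC_PROBS <- c(`3` = 0.20, `2` = 0.30, `1` = 0.30, `0` = 0.10, A = 0.05, B = 0.05)
LC_SIGMA_M <- c(`3` = 150, `2` = 350, `1` = 1000, `0` = 2500, A = 5000, B = 5000)

# jitter a (lon, lat) matrix with isotropic Gaussian noise of sd sigma_m
jitter_lc <- function(p, sigma_m, params) {
  n <- nrow(p)
  dx <- stats::rnorm(n, 0, sigma_m); dy <- stats::rnorm(n, 0, sigma_m)
  d <- sqrt(dx^2 + dy^2)
  brg <- (atan2(dx, dy) * 180 / pi) %% 360
  q <- geosphere::destPoint(p, brg, d, r = params$earth_radius_km * 1000)
  colnames(q) <- c("lon", "lat")
  q
}

# fix times over [t0, t1] under an off/on duty cycle, anchored at t0
duty_cycle_times <- function(t0, t1, duty = c(off = 24, on = 5),
                             fix_every_h = 2) {
  cyc <- sum(duty) * 3600
  starts <- seq(as.numeric(t0), as.numeric(t1), by = cyc)
  unlist(lapply(starts, function(s) {
    on0 <- s + duty[["off"]] * 3600
    tt <- seq(on0, on0 + duty[["on"]] * 3600, by = fix_every_h * 3600)
    tt[tt <= as.numeric(t1)]
  }))
}

# Route of true waypoints for one bird; the coast-exit waypoint sits
# exactly on the coast at the drawn departure latitude (the staging site is
# placed ~150 km inland of it), and a mid-ocean bulge waypoint is solved
# for so the over-water path length matches the drawn length.
make_route <- function(arch, year, geom, params) {
  dep_lat <- stats::rnorm(1, arch$dep_lat_mean, arch$dep_lat_sd)
  repeat {
    len <- stats::rnorm(1, arch$ocean_len_mean, arch$ocean_len_sd)
    dur <- stats::rnorm(1, arch$ocean_dur_mean, arch$ocean_dur_sd)
    if (len > 0 && dur > 0.5 && len * 1000 / (dur * 86400) <= 30) break
  }
  ct <- geom$na_coast$top; cb <- geom$na_coast$bottom
  dep_lat <- min(max(dep_lat, cb[2] + 1), ct[2] - 1)
  coast_lon <- ct[1] + (ct[2] - dep_lat) * (cb[1] - ct[1]) / (ct[2] - cb[2])
  C <- c(lon = coast_lon, lat = dep_lat)
  stg <- geosphere::destPoint(rbind(C), 270, 150 * 1000,
                              r = params$earth_radius_km * 1000)
  staging <- c(stg[1, 1], stg[1, 2])
  arrival <- arch$arrival
  enter_sa <- first_region_crossing(C, arrival, geom$south_america, params)
  if (is.null(enter_sa))
    stop("synthetic route does not cross the arrival coast")
  A <- enter_sa$point
  direct <- gc_distance(C, A, params)
  if (len < direct * 1.001) len <- direct * 1.001
  ocean_pts <- curve_waypoints(C, A, len, side = -90, params = params)
  # overland dogleg so the drawn total migration distance is honoured
  total <- stats::rnorm(1, arch$total_mean, arch$total_sd)
  d_stage_coast <- gc_distance(staging, C, params)
  d_arr <- gc_distance(A, arrival, params) +
    gc_distance(arrival, arch$winter, params)
  over_len <- total - (d_stage_coast + len + d_arr)
  d_over_direct <- gc_distance(arch$breeding, staging, params)
  if (over_len < d_over_direct * 1.001) over_len <- d_over_direct * 1.001
  over_pts <- curve_waypoints(arch$breeding, staging, over_len, side = -90,
                              params = params)
  list(dep_lat = dep_lat, ocean_len = len, ocean_dur = dur,
       total = d_stage_coast + len + d_arr + over_len,
       over_len = over_len, over_pts = over_pts,
       staging = staging, coast_exit = C, ocean_pts = ocean_pts,
       coast_enter = A, arrival = arrival)
}

# Smoothly bulged polyline from P to Q with total length target_len:
# spherical quadratic Bezier (de Casteljau with great-circle interpolation)
# whose control point sits perpendicular to the midpoint of the course
# (side = -90 bulges left); the control offset is solved so the n-point
# polyline has exactly the requested length. The polyline IS the route:
# downstream lengths are sums over its segments.
curve_waypoints <- function(P, Q, target_len, side = -90,
                            params = geo_params(), n = 17L) {
  mid <- gc_point_at_fraction(P, Q, 0.5, params)
  brg <- (initial_bearing(rbind(mid), rbind(Q)) + side) %% 360
  curve <- function(x) {
    W <- geosphere::destPoint(rbind(mid), brg, x * 1000,
                              r = params$earth_radius_km * 1000)
    W <- c(W[1, 1], W[1, 2])
    f <- seq(0, 1, length.out = n)
    t(vapply(f, function(ff) {
      a <- gc_point_at_fraction(P, W, ff, params)
      b <- gc_point_at_fraction(W, Q, ff, params)
      gc_point_at_fraction(a, b, ff, params)
    }, numeric(2)))
  }
  plen <- function(pts) sum(gc_distance(pts[-n, , drop = FALSE],
                                        pts[-1, , drop = FALSE], params))
  x <- stats::uniroot(function(x) plen(curve(x)) - target_len,
                      c(0, 6000), tol = 0.05, extendInt = "upX")$root
  pts <- curve(x)
  colnames(pts) <- c("lon", "lat")
  pts
}

# sample true positions at arbitrary times along a piecewise-great-circle
# route given waypoint times
route_positions <- function(wp, wt, times, params) {
  df <- data.frame(timestamp = wt, lon = wp[, 1], lat = wp[, 2])
  interpolate_position(df, times, params)
}

#' Generate synthetic bird tracks with ground truth
#'
#' Builds, for each bird, a full annual southbound track: breeding residency,
#' overland transit, coastal staging, a trans-oceanic crossing whose true
#' over-water length and duration are drawn from the population archetype,
#' and winter residency. Fixes are sampled under the transmitter duty cycle,
#' labelled with ARGOS location classes drawn from a fixed multinomial, and
#' jittered with class-dependent Gaussian noise.
#'
#' @param config A [scenario_config()].
#' @param params A [geo_params()].
#' @return List with `tracks` (list of `bird_track`) and `truth`, a
#'   data.frame of per-bird true departure/arrival instants, coast-crossing
#'   times and latitude, and true ocean length/duration.
#' @export
generate_bird_tracks <- function(config, params = geo_params()) {
  set.seed(config$seed)
  geom <- config$geometry
  tracks <- list(); truth <- list()
  k <- 0L
  for (pop in names(config$n_birds)) {
    arch <- config$archetypes[[pop]]
    for (b in seq_len(config$n_birds[[pop]])) {
      k <- k + 1L
      year <- config$years[((k - 1L) %% length(config$years)) + 1L]
      id <- sprintf("%s_%02d", substr(pop, 1, 2), k)
      rt <- make_route(arch, year, geom, params)
      # timeline (all UTC); overland transit at a nominal 13 m/s
      t_dep_breed <- as.POSIXct(sprintf("%d-%s 12:00:00", year,
                                        arch$dep_breed_md), tz = "UTC") +
        round(stats::rnorm(1, 0, arch$dep_breed_sd_days)) * 86400
      t0 <- t_dep_breed - 30 * 86400                    # breeding residency
      v_trans <- 13
      over_cum <- c(0, cumsum(gc_distance(rt$over_pts[-nrow(rt$over_pts), ],
                                          rt$over_pts[-1, ], params)))
      t_over <- as.numeric(t_dep_breed) + over_cum * 1000 / v_trans
      t_arr_stage <- as.POSIXct(t_over[length(t_over)],
                                origin = "1970-01-01", tz = "UTC")
      t_dep_stage <- as.POSIXct(sprintf("%d-%s %02d:00:00", year,
                                        arch$dep_month_day,
                                        sample(0:23, 1)), tz = "UTC") +
        round(stats::rnorm(1, 0, arch$dep_stage_sd_days)) * 86400
      if (t_dep_stage < t_arr_stage + 3 * 86400)
        t_dep_stage <- t_arr_stage + 10 * 86400
      # ocean timing: crossing spans the over-water distance at constant speed
      d_stage_coast <- gc_distance(rt$staging, rt$coast_exit, params)
      v_ocean <- rt$ocean_len * 1000 / (rt$ocean_dur * 86400)   # m/s
      t_coast_exit <- t_dep_stage + d_stage_coast * 1000 / v_ocean
      ocean_cum <- c(0, cumsum(gc_distance(
        rt$ocean_pts[-nrow(rt$ocean_pts), ], rt$ocean_pts[-1, ], params)))
      t_ocean <- as.numeric(t_coast_exit) + ocean_cum * 1000 / v_ocean
      t_coast_enter <- as.POSIXct(t_ocean[length(t_ocean)],
                                  origin = "1970-01-01", tz = "UTC")
      d_coast_arr <- gc_distance(rt$coast_enter, rt$arrival, params)
      t_arrival <- t_coast_enter + d_coast_arr * 1000 / v_ocean
      t_winter <- t_arrival + 2 * 86400
      t_end <- t_winter + 60 * 86400
      nw <- nrow(rt$over_pts)
      wp <- rbind(arch$breeding, rt$over_pts,
                  rt$staging, rt$ocean_pts,
                  rt$arrival, arch$winter, arch$winter)
      wt <- c(as.numeric(t0), t_over,
              as.numeric(t_dep_stage), t_ocean,
              as.numeric(t_arrival), as.numeric(t_winter),
              as.numeric(t_end))
      ft <- duty_cycle_times(t0, t_end, arch$duty_cycle)
      pos <- route_positions(wp, wt, ft, params)
      lc <- sample(names(LC_PROBS), length(ft), replace = TRUE,
                   prob = LC_PROBS)
      pos <- jitter_lc(pos, LC_SIGMA_M[lc], params)
      df <- data.frame(bird_id = id,
                       timestamp = as.POSIXct(ft, origin = "1970-01-01",
                                              tz = "UTC"),
                       lat = round(pos[, "lat"], 5),
                       lon = round(pos[, "lon"], 5),
                       lc = lc, stringsAsFactors = FALSE)
      tracks[[id]] <- new_bird_track(df, id, pop, arch$duty_cycle)
      truth[[id]] <- data.frame(
        bird_id = id, population = pop, year = year,
        t_departure = t_dep_breed, t_arrival = t_winter,
        t_coast_exit = t_coast_exit, t_coast_enter = t_coast_enter,
        dep_lat = rt$coast_exit[["lat"]],
        ocean_len_km = rt$ocean_len, ocean_dur_days = rt$ocean_dur,
        total_km = rt$total,
        stringsAsFactors = FALSE)
    }
  }
  list(tracks = tracks, truth = do.call(rbind, c(truth,
                                                 list(make.row.names = FALSE))))
}

STORM_NAMES <- c("ALBERTO", "BERYL", "CHRIS", "DEBBY", "ERNESTO", "FLORENCE",
                 "GORDON", "HELENE", "ISAAC", "JOYCE", "KIRK", "LESLIE",
                 "MICHAEL", "NADINE", "OSCAR", "PATTY", "RAFAEL", "SARA",
                 "TONY", "VALERIE", "WILLIAM")

wind_to_status <- function(wind_kt) {
  ifelse(wind_kt >= 64, "HU", ifelse(wind_kt >= 34, "TS", "TD"))
}

#' Generate a synthetic HURDAT2 storm basin with ground truth
#'
#' Minimal kinematic storm model: genesis in an eastern-basin box, westward
#' drift with noise, Bernoulli recurvature to the northeast once west of
#' 60 deg W, and a bounded random walk in sustained wind spanning the
#' tropical-depression to category-5 range. Six-hourly synoptic records on
#' 00/06/12/18 UTC, rounded to HURDAT2 precision (0.1 degree, whole knots).
#'
#' @inheritParams generate_bird_tracks
#' @param path Optional file; when given the basin is also serialized via
#'   [write_hurdat2()].
#' @return List with `storms` (list of `storm_track`) and `truth`, a
#'   data.frame with one row per storm (genesis time/position, peak wind,
#'   record count, category sequence as a string).
#' @export
generate_storm_basin <- function(config, path = NULL, params = geo_params()) {
  set.seed(config$seed + 1L)
  sc <- config$storm
  storms <- list(); truth <- list()
  for (year in config$years) {
    for (si in seq_len(sc$storms_per_year)) {
      id <- sprintf("AL%02d%04d", si, year)
      name <- STORM_NAMES[((si - 1L) %% length(STORM_NAMES)) + 1L]
      doy0 <- as.POSIXct(sprintf("%d-%s", year, sc$season[1]), tz = "UTC")
      doy1 <- as.POSIXct(sprintf("%d-%s", year, sc$season[2]), tz = "UTC")
      g0 <- as.numeric(doy0) + stats::runif(1) * (as.numeric(doy1) -
                                                    as.numeric(doy0))
      g0 <- floor(g0 / 21600) * 21600                     # snap to synoptic
      lon <- stats::runif(1, sc$genesis_lon[1], sc$genesis_lon[2])
      lat <- stats::runif(1, sc$genesis_lat[1], sc$genesis_lat[2])
      wind <- stats::runif(1, sc$genesis_wind[1], sc$genesis_wind[2])
      recurves <- stats::runif(1) < sc$recurve_prob
      recurved <- FALSE
      rows <- list(); tcur <- g0
      for (step in 1:60) {
        rows[[step]] <- data.frame(
          timestamp = as.POSIXct(tcur, origin = "1970-01-01", tz = "UTC"),
          record_id = "", status = wind_to_status(round(wind)),
          lat = round(lat, 1), lon = round(lon, 1),
          max_wind = as.integer(round(wind)), stringsAsFactors = FALSE)
        if (!recurved && recurves && lon < sc$slow_lon - 10) recurved <- TRUE
        if (recurved) {
          # post-recurvature: northeastward and weakening
          lon <- lon + abs(stats::rnorm(1, 0.7, 0.2))
          lat <- lat + abs(stats::rnorm(1, 1.0, 0.2))
          wind <- wind - abs(stats::rnorm(1, 4, 2))
        } else if (lon < sc$slow_lon) {
          # western basin: slow translation, poleward drift, still deepening
          lon <- lon - abs(stats::rnorm(1, 0.45 * sc$drift_deg, 0.15))
          lat <- lat + abs(stats::rnorm(1, 0.45, 0.15))
          wind <- wind + stats::rnorm(1, sc$intens_mean, sc$intens_sd)
        } else {
          # eastern basin: brisk westward drift at low latitude
          lon <- lon - abs(stats::rnorm(1, sc$drift_deg, 0.2))
          lat <- lat + stats::rnorm(1, 0.1, 0.08)
          wind <- wind + stats::rnorm(1, sc$intens_mean, sc$intens_sd)
        }
        wind <- min(max(wind, 10), 160)
        tcur <- tcur + 21600
        if (wind < 15 || lat > 45 || lon < -98) break
      }
      pts <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
      storms[[id]] <- new_storm_track(id, name, pts)
      truth[[id]] <- data.frame(
        storm_id = id, name = name, genesis_time = pts$timestamp[1],
        genesis_lon = pts$lon[1], genesis_lat = pts$lat[1],
        peak_wind = max(pts$max_wind), n_records = nrow(pts),
        categories = paste(unique(saffir_simpson_category(
          knots_to_mph(pts$max_wind))), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(path)) write_hurdat2(storms, path)
  list(storms = storms, truth = do.call(rbind, c(truth,
                                                 list(make.row.names = FALSE))))
}

#' Plant ground-truth encounters by locally warping storm tracks
#'
#' For each requested plant, the storm track is displaced so that the storm
#' centre passes at the specified great-circle separation from the bird's
#' interpolated position at the specified instant. The displacement is
#' tapered linearly to zero at +/- 36 h around the plant time so the rest of
#' the basin's statistics are preserved; the correction is iterated until
#' the achieved separation at the plant time is within 1 km of the request.
#'
#' @param tracks List of `bird_track` (the generator's noise-free fixes are
#'   adequate anchors).
#' @param storms List of `storm_track`.
#' @param plants data.frame with columns `bird_id`, `storm_id`, `time`
#'   (POSIXct), `separation_km`.
#' @inheritParams generate_bird_tracks
#' @return List with the adjusted `storms` and `truth`, the plants table
#'   augmented with the achieved separation and the bird position used.
#' @export
plant_encounters <- function(tracks, storms, plants, params = geo_params()) {
  if (is.null(plants) || nrow(plants) == 0L)
    return(list(storms = storms, truth = plants))
  truth <- plants
  truth$achieved_km <- NA_real_
  truth$bird_lon <- NA_real_; truth$bird_lat <- NA_real_
  for (i in seq_len(nrow(plants))) {
    pl <- plants[i, ]
    tr <- tracks[[pl$bird_id]]
    st <- storms[[pl$storm_id]]
    if (is.null(tr) || is.null(st)) stop("unknown bird or storm id in plants")
    tq <- as.POSIXct(pl$time, tz = "UTC")
    bird <- interpolate_position(tr, tq, params)
    target <- geosphere::destPoint(bird, 90, pl$separation_km * 1000,
                                   r = params$earth_radius_km * 1000)
    p <- st$points
    if (tq < min(p$timestamp) || tq > max(p$timestamp))
      stop("plant time outside storm track span")
    for (iter in 1:6) {
      cur <- interpolate_position(p, tq, params)
      d <- gc_distance(cur, target, params)
      if (d < 0.5) break
      brg <- initial_bearing(cur, target)
      w <- pmax(0, 1 - abs(as.numeric(p$timestamp) - as.numeric(tq)) /
                  (36 * 3600))
      mv <- which(w > 0)
      q <- geosphere::destPoint(cbind(p$lon[mv], p$lat[mv]), brg,
                                d * 1000 * w[mv] / max(w[mv]),
                                r = params$earth_radius_km * 1000)
      p$lon[mv] <- q[, 1]; p$lat[mv] <- q[, 2]
    }
    # storm translation speed sanity (40 kt over a 6 h step = ~445 km)
    step_km <- gc_distance(cbind(p$lon[-nrow(p)], p$lat[-nrow(p)]),
                           cbind(p$lon[-1], p$lat[-1]), params)
    if (any(step_km > 40 * 1.852 * 6))
      stop("plant ", i, ": requested separation unreachable within storm speed limit")
    # note: write_hurdat2 quantizes to 0.1 degree; the in-memory track keeps
    # full precision so the achieved separation honours the request
    storms[[pl$storm_id]] <- new_storm_track(st$storm_id, st$name, p)
    fin <- interpolate_position(storms[[pl$storm_id]]$points, tq, params)
    truth$achieved_km[i] <- gc_distance(fin, bird, params)
    truth$bird_lon[i] <- bird[1, 1]; truth$bird_lat[i] <- bird[1, 2]
  }
  list(storms = storms, truth = truth)
}
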