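#' Encounter-detection configuration
#'
#' The field data never pin a spatial threshold for a track "intersection";
#' the defaults used here are 300 km for in-flight encounters (a typical
#' gale-force wind-field extent) and 100 km for a storm passing over a
#' grounded bird, both first-class settings, with [encounter_sensitivity()]
#' available to sweep them.
#'
#' @param encounter_radius_km In-flight encounter radius (default 300).
#' @param grounded_radius_km Grounded encounter radius (default 100).
#' @param sync_step_min Shared interpolation grid step, minutes (default 30).
#' @param detour_angle_deg Course deflection defining a detour (default 20).
#' @param detour_window_pre_h,detour_window_post_h Bearing windows before /
#'   after the encounter, hours (defaults 24 and 48).
#' @return An `encounter_config` list.
#' @export
encounter_config <- function(encounter_radius_km = 300,
                             grounded_radius_km = 100,
                             sync_step_min = 30,
                             detour_angle_deg = 20,
                             detour_window_pre_h = 24,
                             detour_window_post_h = 48) {
  cfg <- list(encounter_radius_km = encounter_radius_km,
              grounded_radius_km = grounded_radius_km,
              sync_step_min = sync_step_min,
              detour_angle_deg = detour_angle_deg,
              detour_window_pre_h = detour_window_pre_h,
              detour_window_post_h = detour_window_post_h)
  if (any(unlist(cfg) <= 0)) stop("all encounter-config values must be positive")
  structure(cfg, class = "encounter_config")
}

#' Convert sustained wind from knots to mph
#'
#' Best-track winds are archived in knots while the Saffir-Simpson band
#' boundaries are printed in mph; 1 kt = 1.15078 mph.
#'
#' @param wind_kt Wind speed(s), knots.
#' @export
knots_to_mph <- function(wind_kt) wind_kt * 1.15078

#' Saffir-Simpson intensity class from sustained wind
#'
#' Total monotone step function with the printed integer-mph band edges:
#' TD <= 38, TS 39-73, C1 74-95, C2 96-110, C3 111-129, C4 130-156,
#' C5 >= 157.
#'
#' @param wind_mph Sustained wind(s), mph; must be non-negative. NA in,
#'   NA out.
#' @return Character vector over `TD, TS, C1..C5`.
#' @export
saffir_simpson_category <- function(wind_mph) {
  if (any(wind_mph < 0, na.rm = TRUE)) stop("negative wind speed")
  cut_pts <- c(-Inf, 38, 73, 95, 110, 129, 156, Inf)
  labs <- c("TD", "TS", "C1", "C2", "C3", "C4", "C5")
  as.character(cut(wind_mph, breaks = cut_pts, labels = labs, right = TRUE))
}

# storm wind (knots) linearly interpolated in time; NA where either
# bracketing record has missing wind
storm_wind_at <- function(storm, t) {
  tt <- as.numeric(storm$points$timestamp)
  w <- storm$points$max_wind
  tq <- pmin(pmax(as.numeric(t), tt[1]), tt[length(tt)])
  stats::approx(tt, w, xout = tq, rule = 2)$y
}

new_encounter <- function(bird_id, storm_id, time, lon, lat, bird_state,
                          wind_kt, min_separation_km, low_confidence = FALSE) {
  wind_mph <- knots_to_mph(wind_kt)
  data.frame(bird_id = bird_id, storm_id = storm_id,
             time = as.POSIXct(time, origin = "1970-01-01", tz = "UTC"),
             lon = lon, lat = lat, bird_state = bird_state,
             wind_kt = wind_kt,
             storm_category = saffir_simpson_category(wind_mph),
             min_separation_km = min_separation_km,
             response = rep(NA_character_, length(bird_id)),
             low_confidence = low_confidence,
             stringsAsFactors = FALSE)
}

empty_encounters <- function() new_encounter(character(), character(),
                                             numeric(), numeric(), numeric(),
                                             character(), numeric(), numeric(),
                                             logical())

#' Detect in-flight bird-storm encounters
#'
#' Bird and storm are interpolated onto a shared time grid over their
#' temporal overlap; within each maximal run where the separation is at or
#' below the encounter radius, one encounter is recorded at the instant of
#' minimum separation, with the storm's intensity class taken from its
#' (interpolated) wind at that instant. A transmitter gap longer than 72 h
#' spanning the encounter marks it low-confidence.
#'
#' @param track A `bird_track`.
#' @param storms List of `storm_track`.
#' @param config An [encounter_config()].
#' @param params A [geo_params()].
#' @return data.frame of encounters (possibly empty).
#' @export
detect_inflight_encounters <- function(track, storms,
                                       config = encounter_config(),
                                       params = geo_params()) {
  out <- list()
  bt <- as.numeric(track$timestamp)
  for (s in storms) {
    st <- as.numeric(s$points$timestamp)
    t0 <- max(bt[1], st[1]); t1 <- min(bt[length(bt)], st[length(st)])
    if (t0 >= t1) next
    grid <- seq(t0, t1, by = config$sync_step_min * 60)
    if (length(grid) < 2L) grid <- c(t0, t1)
    bp <- interpolate_position(track, grid, params)
    sp <- interpolate_position(s$points, grid, params)
    sep <- gc_distance(bp, sp, params)
    close <- sep <= config$encounter_radius_km
    if (!any(close)) next
    r <- rle(close)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      m <- idx[which.min(sep[idx])]
      gap_i <- findInterval(grid[m], bt)
      gap_h <- if (gap_i >= 1L && gap_i < length(bt))
        (bt[gap_i + 1L] - bt[gap_i]) / 3600 else 0
      out[[length(out) + 1L]] <- new_encounter(
        bird_id = attr(track, "bird_id"), storm_id = s$storm_id,
        time = grid[m], lon = bp[m, 1], lat = bp[m, 2],
        bird_state = "in_flight",
        wind_kt = storm_wind_at(s, grid[m]),
        min_separation_km = sep[m],
        low_confidence = gap_h > 72)
    }
  }
  if (length(out) == 0L) return(empty_encounters())
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Detect encounters of a grounded bird with passing storms
#'
#' A storm encounters a grounded bird when its interpolated centre comes
#' within the grounded radius of the stationary phase's centroid during the
#' phase; at most one encounter per storm, at the approach minimum.
#'
#' @param stationary_phase One phase row (from [detect_residency()] or the
#'   transoceanic grounding) with `start`, `end`, `centroid_lon`,
#'   `centroid_lat`.
#' @param bird_id Id carried onto the encounter records.
#' @inheritParams detect_inflight_encounters
#' @return data.frame of encounters (possibly empty).
#' @export
detect_grounded_encounters <- function(stationary_phase, storms, bird_id = NA,
                                       config = encounter_config(),
                                       params = geo_params()) {
  out <- list()
  cen <- cbind(stationary_phase$centroid_lon, stationary_phase$centroid_lat)
  p0 <- as.numeric(stationary_phase$start)
  p1 <- as.numeric(stationary_phase$end)
  for (s in storms) {
    st <- as.numeric(s$points$timestamp)
    t0 <- max(p0, st[1]); t1 <- min(p1, st[length(st)])
    if (t0 >= t1) next
    grid <- seq(t0, t1, by = config$sync_step_min * 60)
    if (length(grid) < 2L) grid <- c(t0, t1)
    sp <- interpolate_position(s$points, grid, params)
    sep <- gc_distance(sp, matrix(cen, nrow(sp), 2, byrow = TRUE), params)
    if (min(sep) > config$grounded_radius_km) next
    m <- which.min(sep)
    out[[length(out) + 1L]] <- new_encounter(
      bird_id = bird_id, storm_id = s$storm_id, time = grid[m],
      lon = cen[1, 1], lat = cen[1, 2], bird_state = "grounded",
      wind_kt = storm_wind_at(s, grid[m]), min_separation_km = sep[m])
  }
  if (length(out) == 0L) return(empty_encounters())
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# smallest absolute difference between two bearings, degrees in [0, 180]
bearing_diff <- function(b1, b2) {
  d <- abs(b1 - b2) %% 360
  ifelse(d > 180, 360 - d, d)
}

#' Classify a bird's response to a storm encounter
#'
#' `grounded` if a stationary interval beginning within the post-encounter
#' window lies on an island polygon; otherwise `detour` if the course over
#' the post window deflects from the course over the pre window by more than
#' the detour angle (compared on the circle); otherwise `none`. Grounding
#' supersedes detour. Too few post-encounter fixes give `indeterminate`.
#'
#' @param track A `bird_track`.
#' @param encounter One encounter row.
#' @param islands List of island polygon rings (lon/lat).
#' @param config An [encounter_config()].
#' @param params A [geo_params()].
#' @param stationary_radius_km,stationary_min_days Stationarity test for a
#'   post-encounter grounding (defaults 50 km, 2 days).
#' @return One of `"grounded"`, `"detour"`, `"none"`, `"indeterminate"`.
#' @export
classify_response <- function(track, encounter, islands = list(),
                              config = encounter_config(),
                              params = geo_params(),
                              stationary_radius_km = 50,
                              stationary_min_days = 2) {
  t_enc <- as.numeric(encounter$time)
  tt <- as.numeric(track$timestamp)
  post_end <- t_enc + config$detour_window_post_h * 3600
  # grounding: a residency starting within the post window, on an island
  post <- track[tt > t_enc & tt <= t_enc + 30 * 86400, , drop = FALSE]
  if (nrow(post) >= 3L && length(islands) > 0L) {
    ph <- suppressWarnings(detect_residency(post, stationary_radius_km,
                                            stationary_min_days, params))
    if (nrow(ph)) {
      started_in_window <- as.numeric(ph$start) <= post_end
      on_island <- point_in_region(cbind(ph$centroid_lon, ph$centroid_lat),
                                   islands)
      if (any(started_in_window & on_island)) return("grounded")
    }
  }
  pre0 <- t_enc - config$detour_window_pre_h * 3600
  if (pre0 < tt[1] || post_end > tt[length(tt)]) return("indeterminate")
  p_pre <- interpolate_position(track, pre0, params)
  p_enc <- interpolate_position(track, t_enc, params)
  p_post <- interpolate_position(track, post_end, params)
  if (gc_distance(p_pre, p_enc, params) < 1 ||
      gc_distance(p_enc, p_post, params) < 1) return("indeterminate")
  b_pre <- initial_bearing(p_pre, p_enc)
  b_post <- initial_bearing(p_enc, p_post)
  if (bearing_diff(b_pre, b_post) > config$detour_angle_deg) "detour" else "none"
}

#' Per-population encounter-rate table
#'
#' @param journeys data.frame of journey summaries (one row per crossing,
#'   with `bird_id`, `population`, `year`).
#' @param encounters data.frame of encounters; matched to journeys by
#'   `bird_id` and year of the encounter time.
#' @return data.frame per population: crossings, crossings with at least
#'   one encounter, integer percentage, encounter counts in flight and
#'   grounded.
#' @export
summarize_encounter_rates <- function(journeys, encounters) {
  enc_year <- if (nrow(encounters))
    as.integer(format(encounters$time, "%Y", tz = "UTC")) else integer()
  rows <- lapply(split(journeys, journeys$population), function(j) {
    hit <- vapply(seq_len(nrow(j)), function(i)
      any(encounters$bird_id == j$bird_id[i] & enc_year == j$year[i]),
      logical(1))
    enc_pop <- encounters[encounters$bird_id %in% j$bird_id, , drop = FALSE]
    data.frame(population = j$population[1],
               n_crossings = nrow(j),
               n_with_encounter = sum(hit),
               pct_with_encounter = encounter_rate_pct(sum(hit), nrow(j)),
               n_encounters_inflight = sum(enc_pop$bird_state == "in_flight"),
               n_encounters_grounded = sum(enc_pop$bird_state == "grounded"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$population), , drop = FALSE]
}

#' Integer percentage of crossings with an encounter
#'
#' @param k,n Count with encounters, total count.
#' @return `round(100 k / n)` (0 when `n` is 0).
#' @export
encounter_rate_pct <- function(k, n) {
  if (n == 0) return(0)
  round(100 * k / n)
}

#' Encounter-count sensitivity to the detection radius
#'
#' Re-runs in-flight detection across a sweep of encounter radii; counts
#' are non-decreasing in the radius.
#'
#' @inheritParams detect_inflight_encounters
#' @param radii_km Radii to sweep (default 50-500 km).
#' @return data.frame with `radius_km` and `n_encounters`.
#' @export
encounter_sensitivity <- function(track, storms, radii_km = seq(50, 500, 50),
                                  config = encounter_config(),
                                  params = geo_params()) {
  n <- vapply(radii_km, function(r) {
    cfg <- config; cfg$encounter_radius_km <- r
    nrow(detect_inflight_encounters(track, storms, cfg, params))
  }, numeric(1))
  data.frame(radius_km = radii_km, n_encounters = n)
}
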