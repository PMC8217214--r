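# shared fixture builders; everything is generated in code

utc <- function(s) as.POSIXct(s, tz = "UTC")

# rectangular lon/lat ring (closed)
square_ring <- function(lon0, lon1, lat0, lat1) {
  rbind(c(lon0, lat0), c(lon1, lat0), c(lon1, lat1), c(lon0, lat1),
        c(lon0, lat0))
}

# track of fixes moving at constant speed v_ms along the great circle
# from `from` to `to`, one fix every step_s seconds, starting at t0
straight_track <- function(from, to, v_ms = 14.8, t0 = utc("2015-09-01"),
                           step_s = 3600, id = "b1",
                           population = "HudsonBay") {
  d_km <- gc_distance(from, to)
  total_s <- d_km * 1000 / v_ms
  tt <- seq(0, total_s, by = step_s)
  wp <- data.frame(timestamp = as.numeric(t0) + c(0, total_s),
                   lon = c(from[1], to[1]), lat = c(from[2], to[2]))
  pos <- interpolate_position(wp, as.numeric(t0) + tt)
  df <- data.frame(bird_id = id,
                   timestamp = t0 + tt,
                   lat = pos[, "lat"], lon = pos[, "lon"],
                   lc = "3", stringsAsFactors = FALSE)
  stormcross:::new_bird_track(df, id, population)
}

# minimal storm: centre moving at constant velocity through `at` at time t_at
linear_storm <- function(at, t_at, bearing = 270, speed_kmh = 25,
                         span_h = 96, wind_kt = 60, storm_id = "AL011999",
                         name = "TEST") {
  tt <- seq(-span_h / 2, span_h / 2, by = 6) * 3600
  d <- speed_kmh * tt / 3600
  pos <- t(vapply(d, function(dd) {
    if (abs(dd) < 1e-9) c(at[1], at[2])
    else {
      q <- geosphere::destPoint(rbind(at), if (dd > 0) bearing
                                else (bearing + 180) %% 360,
                                abs(dd) * 1000, r = 6371008.8)
      c(q[1, 1], q[1, 2])
    }
  }, numeric(2)))
  pts <- data.frame(timestamp = as.POSIXct(as.numeric(t_at) + tt,
                                           origin = "1970-01-01", tz = "UTC"),
                    record_id = "", status = "HU",
                    lat = pos[, 2], lon = pos[, 1],
                    max_wind = as.integer(wind_kt), stringsAsFactors = FALSE)
  stormcross:::new_storm_track(storm_id, name, pts)
}

# stationary cluster of fixes around a centre, one fix every `step_h` hours
cluster_fixes <- function(center, t0, days, step_h = 6, jitter_km = 2,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tt <- seq(0, days * 86400, by = step_h * 3600)
  n <- length(tt)
  brg <- runif(n, 0, 360); d <- abs(rnorm(n, 0, jitter_km * 1000))
  q <- geosphere::destPoint(matrix(center, n, 2, byrow = TRUE), brg, d,
                            r = 6371008.8)
  data.frame(timestamp = t0 + tt, lon = q[, 1], lat = q[, 2])
}

# independently coded brute-force G-test oracle (Yates-corrected),
# deliberately written cell-by-cell rather than vectorised
g_test_oracle <- function(tab) {
  n <- sum(tab)
  G <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- sum(tab[i, ]) * sum(tab[, j]) / n
    o <- tab[i, j]
    if (o < e) o <- min(o + 0.5, e)
    if (o > e) o <- max(o - 0.5, e)
    if (o > 0) G <- G + o * log(o / e)
  }
  2 * G
}

# spherical-trig initial-bearing oracle
bearing_oracle <- function(p1, p2) {
  rad <- pi / 180
  dl <- (p2[1] - p1[1]) * rad
  y <- sin(dl) * cos(p2[2] * rad)
  x <- cos(p1[2] * rad) * sin(p2[2] * rad) -
    sin(p1[2] * rad) * cos(p2[2] * rad) * cos(dl)
  (atan2(y, x) / rad) %% 360
}

# tiny scenario for pipeline-level tests
small_scenario <- function(seed = 21) {
  scenario_config(seed = seed,
                  n_birds = c(MackenzieDelta = 3, HudsonBay = 3),
                  years = 2012:2015,
                  storm = utils::modifyList(scenario_config()$storm,
                                            list(storms_per_year = 3)))
}
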