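#' Detect stationary residency phases in a track
#'
#' Greedy scan for maximal time intervals during which every fix lies within
#' `radius_km` of the interval's running centroid for at least `min_days`.
#' The first stationary phase is labelled `breeding`, the last `winter`, and
#' interior ones `staging`.
#'
#' @param track A `bird_track`, time-sorted and quality-filtered.
#' @param radius_km Stationarity radius (default 50 km, comfortably above
#'   ARGOS class-1 positional error).
#' @param min_days Minimum dwell time (default 7 days) separating
#'   territories and multi-day staging from transit.
#' @param params A [geo_params()].
#' @return data.frame of phases: `kind`, `start`, `end`, `centroid_lon`,
#'   `centroid_lat`, `i0`, `i1` (supporting fix indices); zero rows (with a
#'   warning) if the bird never settles.
#' @export
detect_residency <- function(track, radius_km = 50, min_days = 7,
                             params = geo_params()) {
  if (isTRUE(attr(track, "empty_track")) || nrow(track) == 0L)
    stop("empty track")
  n <- nrow(track)
  p <- cbind(track$lon, track$lat)
  tt <- as.numeric(track$timestamp)
  phases <- list()
  i <- 1L
  while (i <= n) {
    if (radius_km <= 0) break
    cen <- p[i, , drop = FALSE]
    j <- i
    while (j < n) {
      cand <- j + 1L
      new_cen <- colMeans(p[i:cand, , drop = FALSE])
      dmax <- max(gc_distance(p[i:cand, , drop = FALSE],
                              matrix(new_cen, cand - i + 1L, 2, byrow = TRUE),
                              params))
      if (dmax > radius_km) break
      j <- cand
      cen <- matrix(new_cen, 1)
    }
    if ((tt[j] - tt[i]) / 86400 >= min_days) {
      phases[[length(phases) + 1L]] <- data.frame(
        kind = "staging", start = track$timestamp[i], end = track$timestamp[j],
        centroid_lon = cen[1, 1], centroid_lat = cen[1, 2],
        i0 = i, i1 = j, stringsAsFactors = FALSE)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(phases) == 0L) {
    warning("no stationary phase found; journey unsegmentable")
    return(data.frame(kind = character(), start = track$timestamp[0],
                      end = track$timestamp[0], centroid_lon = numeric(),
                      centroid_lat = numeric(), i0 = integer(),
                      i1 = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, c(phases, list(make.row.names = FALSE)))
  out$kind[1] <- "breeding"
  if (nrow(out) > 1L) out$kind[nrow(out)] <- "winter"
  out
}

#' Departure and arrival instants of the annual migration
#'
#' Departure is the timestamp of the last fix inside the breeding territory
#' radius before a sustained displacement: the bird moves beyond twice the
#' stationarity radius and does not return within `min_days`. A return
#' within `min_days` is logged as a "false start" and the search resumes.
#' Arrival is the first fix inside the winter territory radius.
#'
#' @inheritParams detect_residency
#' @param phases Output of [detect_residency()]; must contain a breeding
#'   and a winter phase.
#' @return List with `departure`, `arrival` (POSIXct) and `false_starts`
#'   (count).
#' @export
detect_departure_arrival <- function(phases, track, radius_km = 50,
                                     min_days = 7, params = geo_params()) {
  if (!"breeding" %in% phases$kind || !"winter" %in% phases$kind)
    stop("breeding and winter phases are both required")
  br <- phases[phases$kind == "breeding", ][1, ]
  wi <- phases[phases$kind == "winter", ][nrow(phases[phases$kind == "winter", ]), ]
  p <- cbind(track$lon, track$lat)
  n <- nrow(track)
  tt <- as.numeric(track$timestamp)
  d_br <- gc_distance(p, matrix(c(br$centroid_lon, br$centroid_lat),
                                n, 2, byrow = TRUE), params)
  false_starts <- 0L
  i <- br$i1
  departure <- NA
  while (i <= n) {
    out_i <- which(d_br > 2 * radius_km & seq_len(n) >= i)
    if (length(out_i) == 0L) break
    e <- out_i[1]
    back <- which(d_br <= radius_km & seq_len(n) > e &
                    tt <= tt[e] + min_days * 86400)
    if (length(back) > 0L) {
      false_starts <- false_starts + 1L
      warning("false start detected; departure re-evaluated")
      i <- back[length(back)] + 1L
      next
    }
    inside_before <- which(d_br <= radius_km & seq_len(n) < e)
    if (length(inside_before) == 0L) stop("no departure found")
    departure <- track$timestamp[inside_before[length(inside_before)]]
    break
  }
  if (is.na(departure)) stop("no departure found (bird never left)")
  d_wi <- gc_distance(p, matrix(c(wi$centroid_lon, wi$centroid_lat),
                                n, 2, byrow = TRUE), params)
  arr_i <- which(d_wi <= radius_km & tt > as.numeric(departure))
  if (length(arr_i) == 0L) stop("no arrival found")
  list(departure = departure, arrival = track$timestamp[arr_i[1]],
       false_starts = false_starts)
}

#' Segment the trans-oceanic flight and compute its metrics
#'
#' Identifies the longest contiguous run of over-water fixes (not inside any
#' land polygon), bounds it by the coastline crossing instants obtained with
#' the fixed-speed rule anchored on the first/last in-flight fix, and
#' returns the ocean phase with its metrics: flight length (sum of
#' over-water fix-to-fix great-circle distances plus the two coast-to-fix
#' stubs), duration, and the latitude at which the bird left the departure
#' coast.
#'
#' @inheritParams detect_residency
#' @param coastlines List with polygon-ring lists `north_america` and
#'   `south_america` (e.g. [scenario_geometry()]); any polygon sets standing
#'   for the two landmasses work.
#' @return List: `phase` (kind `transoceanic`, start/end), `ocean_len_km`,
#'   `ocean_dur_days`, `dep_lat`, `dep_point`, `arr_point`,
#'   `single_fix_lower_bound` flag.
#' @export
segment_transoceanic <- function(track, coastlines, params = geo_params()) {
  land <- c(coastlines$north_america, coastlines$south_america)
  p <- cbind(track$lon, track$lat)
  on_land <- point_in_region(p, land)
  if (all(on_land)) stop("track never leaves land")
  r <- rle(on_land)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  water_runs <- which(!r$values)
  # ocean crossing = the over-water run with the greatest span distance
  span <- vapply(water_runs, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    gc_distance(p[i0, , drop = FALSE], p[i1, , drop = FALSE], params)
  }, numeric(1))
  k <- water_runs[which.max(span)]
  i0 <- starts[k]; i1 <- ends[k]
  if (i0 == 1L || i1 == nrow(p))
    stop("over-water run not bounded by land fixes on both sides")
  water <- track[i0:i1, , drop = FALSE]

  dep_cr <- first_region_crossing(p[i0 - 1L, ], p[i0, ],
                                  coastlines$north_america, params)
  arr_cr <- first_region_crossing(p[i1, ], p[i1 + 1L, ],
                                  coastlines$south_america, params)
  if (is.null(dep_cr) || is.null(arr_cr))
    stop("could not locate a coastline crossing bounding the ocean run")
  t_dep <- crossing_time(track[i0 - 1L, ], track[i0, ],
                         coastlines$north_america, params, anchor = "inside")
  t_arr <- crossing_time(track[i1, ], track[i1 + 1L, ],
                         coastlines$south_america, params, anchor = "outside")
  stub_dep <- gc_distance(dep_cr$point, p[i0, , drop = FALSE], params)
  stub_arr <- gc_distance(p[i1, , drop = FALSE], arr_cr$point, params)
  len <- stub_dep + stub_arr +
    if (nrow(water) >= 2L) path_length(water, params) else 0
  list(phase = data.frame(kind = "transoceanic", start = t_dep, end = t_arr,
                          centroid_lon = mean(water$lon),
                          centroid_lat = mean(water$lat),
                          i0 = i0, i1 = i1, stringsAsFactors = FALSE),
       ocean_len_km = len,
       ocean_dur_days = as.numeric(t_arr - t_dep, units = "days"),
       dep_lat = dep_cr$point[["lat"]],
       dep_point = dep_cr$point, arr_point = arr_cr$point,
       single_fix_lower_bound = nrow(water) < 2L)
}

#' Per-journey summary feeding the statistics layer
#'
#' @inheritParams detect_residency
#' @param dep_arr Output of [detect_departure_arrival()].
#' @param ocean Output of [segment_transoceanic()], or NULL when no ocean
#'   phase was found.
#' @param grounded Did the bird ground on an island during the crossing?
#' @return One-row data.frame (`journey_summary`): id, population, year,
#'   departure/arrival dates, total distance (km), duration (days), rate of
#'   advance (km/day), ocean departure latitude, ocean flight length and
#'   duration, grounded flag.
#' @export
summarize_journey <- function(track, dep_arr, ocean = NULL,
                              grounded = FALSE, params = geo_params()) {
  seg <- track[track$timestamp >= dep_arr$departure &
                 track$timestamp <= dep_arr$arrival, , drop = FALSE]
  if (nrow(seg) < 2L) stop("journey has fewer than 2 fixes")
  dur <- as.numeric(dep_arr$arrival - dep_arr$departure, units = "days")
  if (dur <= 0) stop("non-positive migration duration")
  dist <- path_length(seg, params)
  data.frame(
    bird_id = attr(track, "bird_id"),
    population = attr(track, "population"),
    year = as.integer(format(dep_arr$departure, "%Y", tz = "UTC")),
    departure_date = dep_arr$departure,
    arrival_date = dep_arr$arrival,
    total_distance_km = dist,
    duration_days = dur,
    rate_of_advance_km_day = dist / dur,
    ocean_departure_lat = if (!is.null(ocean)) ocean$dep_lat else NA_real_,
    ocean_flight_length_km = if (!is.null(ocean)) ocean$ocean_len_km else NA_real_,
    ocean_flight_duration_days = if (!is.null(ocean)) ocean$ocean_dur_days else NA_real_,
    grounded = grounded,
    stringsAsFactors = FALSE)
}

#' Group mean and standard error
#'
#' @param x Numeric vector (NAs dropped).
#' @return A `group_summary`: mean, standard error of the mean, n.
#' @export
group_summary_of <- function(x) {
  x <- x[!is.na(x)]
  group_summary(mean(x), stats::sd(x) / sqrt(length(x)), length(x))
}
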