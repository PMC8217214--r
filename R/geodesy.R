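#' Geodesy parameters
#'
#' Bundle of the two geometric constants used throughout the pipeline: the
#' spherical Earth radius and the mean sustained flight speed used to convert
#' a distance-to-boundary into a time offset when a transmitter duty cycle
#' leaves the true boundary-crossing instant unobserved.
#'
#' @param earth_radius_km Sphere radius in kilometres. Default 6371.0088
#'   (IUGG mean radius).
#' @param mean_flight_speed Mean overall flight speed between in-flight
#'   fixes, metres per second. Default 14.8, the cross-population mean for
#'   tracked whimbrels.
#' @return An object of class `geo_params`.
#' @export
geo_params <- function(earth_radius_km = 6371.0088, mean_flight_speed = 14.8) {
  stopifnot(is.numeric(earth_radius_km), earth_radius_km > 0,
            is.numeric(mean_flight_speed), mean_flight_speed > 0)
  structure(list(earth_radius_km = earth_radius_km,
                 mean_flight_speed = mean_flight_speed),
            class = "geo_params")
}

#' @export
print.geo_params <- function(x, ...) {
  cat("Geodesy parameters: R =", x$earth_radius_km, "km, mean flight speed =",
      x$mean_flight_speed, "m/s\n")
  invisible(x)
}

# All positions are (lon, lat) in decimal degrees, matching geosphere.
as_lonlat <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2, byrow = FALSE)
  p <- as.matrix(p)
  if (ncol(p) != 2L) stop("positions must be (lon, lat) pairs")
  if (anyNA(p)) stop("NA/NaN coordinates")
  if (any(p[, 2] < -90 | p[, 2] > 90)) stop("latitude out of [-90, 90]")
  if (any(p[, 1] < -180 | p[, 1] >= 360)) stop("longitude out of range")
  p
}

#' Great-circle distance
#'
#' Haversine distance on a sphere. Symmetric, non-negative, at most pi * R.
#'
#' @param p1,p2 Positions as `c(lon, lat)` vectors or two-column matrices
#'   (recycled row-wise).
#' @param params A [geo_params()] object.
#' @return Distance(s) in kilometres.
#' @export
gc_distance <- function(p1, p2, params = geo_params()) {
  p1 <- as_lonlat(p1); p2 <- as_lonlat(p2)
  geosphere::distHaversine(p1, p2, r = params$earth_radius_km * 1000) / 1000
}

#' Initial great-circle bearing
#'
#' Bearing at `p1` of the great circle towards `p2`, degrees clockwise from
#' north in `[0, 360)`.
#'
#' @inheritParams gc_distance
#' @export
initial_bearing <- function(p1, p2) {
  p1 <- as_lonlat(p1); p2 <- as_lonlat(p2)
  same <- rowSums(abs(p1 - p2)) < 1e-12
  if (any(same)) stop("bearing undefined for coincident points")
  b <- geosphere::bearing(p1, p2, f = 0)      # f = 0: spherical formula
  (b + 360) %% 360
}

#' Interpolate a position along a timestamped track
#'
#' Position at time `t` on the great-circle segment between the bracketing
#' fixes, with the along-arc fraction proportional to elapsed time
#' (spherical linear interpolation).
#'
#' @param track_points data.frame with columns `timestamp` (POSIXct or
#'   numeric seconds), `lon`, `lat`, sorted by time.
#' @param t Instant(s) within the track's time span.
#' @inheritParams gc_distance
#' @return Matrix of (lon, lat) rows, one per element of `t`.
#' @export
interpolate_position <- function(track_points, t, params = geo_params()) {
  tt <- as.numeric(track_points$timestamp)
  tq <- as.numeric(t)
  if (any(tq < tt[1] - 1e-9) || any(tq > tt[length(tt)] + 1e-9))
    stop("interpolation time outside track span (extrapolation refused)")
  tq <- pmin(pmax(tq, tt[1]), tt[length(tt)])
  i <- findInterval(tq, tt, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(tt) - 1L)
  out <- matrix(NA_real_, length(tq), 2, dimnames = list(NULL, c("lon", "lat")))
  for (k in seq_along(tq)) {
    j <- i[k]
    p0 <- c(track_points$lon[j], track_points$lat[j])
    p1 <- c(track_points$lon[j + 1], track_points$lat[j + 1])
    dt <- tt[j + 1] - tt[j]
    f <- if (dt <= 0) 0 else (tq[k] - tt[j]) / dt
    out[k, ] <- gc_point_at_fraction(p0, p1, f, params)
  }
  out
}

# Point at fraction f along the great circle p0 -> p1 (slerp via destPoint).
gc_point_at_fraction <- function(p0, p1, f, params = geo_params()) {
  if (f <= 0) return(c(lon = p0[[1]], lat = p0[[2]]))
  if (f >= 1) return(c(lon = p1[[1]], lat = p1[[2]]))
  d <- gc_distance(p0, p1, params)
  if (d < 1e-12) return(c(lon = p0[[1]], lat = p0[[2]]))
  b <- initial_bearing(p0, p1)
  q <- geosphere::destPoint(p0, b, f * d * 1000,
                            r = params$earth_radius_km * 1000)
  c(lon = q[1, 1], lat = q[1, 2])
}

#' Cumulative path length of a track
#'
#' Sum of great-circle distances over consecutive fixes.
#'
#' @inheritParams interpolate_position
#' @return Length in kilometres.
#' @export
path_length <- function(track_points, params = geo_params()) {
  n <- nrow(track_points)
  if (is.null(n) || n < 2L) stop("path_length needs at least 2 points")
  p <- cbind(track_points$lon, track_points$lat)
  sum(gc_distance(p[-n, , drop = FALSE], p[-1, , drop = FALSE], params))
}

#' Even-odd point-in-region test
#'
#' Membership of points in a region given as a list of closed polygon rings
#' (two-column lon/lat matrices). Crossings are counted over all rings, so a
#' ring lying inside another ring is a hole.
#'
#' @param p Points: `c(lon, lat)` or a two-column matrix.
#' @param region List of closed rings.
#' @return Logical vector.
#' @export
point_in_region <- function(p, region) {
  p <- as_lonlat(p)
  if (length(region) == 0L) return(rep(FALSE, nrow(p)))
  inside <- rep(0L, nrow(p))
  for (ring in region) {
    ring <- as.matrix(ring)
    inside <- inside + as.integer(mgcv::in.out(ring[, 1:2], p))
  }
  inside %% 2L == 1L
}

# First point along the great-circle segment p0 -> p1 where the
# point_in_region status changes from that of p0. Returns list(frac, point)
# or NULL if no change is found. Dense scan then bisection.
first_region_crossing <- function(p0, p1, region, params = geo_params(),
                                  n_scan = 256L) {
  f <- seq(0, 1, length.out = n_scan)
  pts <- t(vapply(f, function(fi) gc_point_at_fraction(p0, p1, fi, params),
                  numeric(2)))
  status <- point_in_region(pts, region)
  flips <- which(status != status[1])
  if (length(flips) == 0L) return(NULL)
  hi <- f[flips[1]]; lo <- f[flips[1] - 1L]
  s0 <- status[1]
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    pm <- gc_point_at_fraction(p0, p1, mid, params)
    if (point_in_region(rbind(pm), region) == s0) lo <- mid else hi <- mid
  }
  fr <- (lo + hi) / 2
  list(frac = fr, point = gc_point_at_fraction(p0, p1, fr, params),
       n_crossings = length(rle(as.integer(status))$lengths) - 1L)
}

#' Fixed-speed boundary crossing time
#'
#' When consecutive fixes straddle a region boundary, the true crossing
#' instant is unobserved. Following the fixed-speed interpolation rule, the
#' crossing point on the great-circle segment between the two fixes is
#' located, and the crossing time is the anchor fix's timestamp offset by
#' (distance to the crossing) / (mean flight speed).
#'
#' @param outside_point,inside_point One-row data.frames (or lists) with
#'   `timestamp`, `lon`, `lat`; `outside_point` must be earlier.
#' @param boundary Region as a list of closed (lon, lat) polygon rings; the
#'   two fixes must lie on opposite sides of it.
#' @param params A [geo_params()]; supplies the fixed mean flight speed.
#' @param anchor `"outside"` (default): time = outside fix + d(outside ->
#'   crossing)/v. `"inside"`: time = inside fix - d(crossing -> inside)/v,
#'   the form used when anchoring on the first/last in-flight fix at a
#'   coastline.
#' @param interpolation `"fixed_speed"` (default) or `"proportional"`
#'   (linear-in-time between the two fixes).
#' @return The crossing instant (same class as the fix timestamps), clamped
#'   into the fix-gap interval with a warning if the speed rule would
#'   overshoot it.
#' @export
crossing_time <- function(outside_point, inside_point, boundary,
                          params = geo_params(),
                          anchor = c("outside", "inside"),
                          interpolation = c("fixed_speed", "proportional")) {
  anchor <- match.arg(anchor)
  interpolation <- match.arg(interpolation)
  p0 <- c(outside_point$lon, outside_point$lat)
  p1 <- c(inside_point$lon, inside_point$lat)
  t0 <- outside_point$timestamp; t1 <- inside_point$timestamp
  if (as.numeric(t1) < as.numeric(t0)) stop("outside_point must be earlier")
  cr <- first_region_crossing(p0, p1, boundary, params)
  if (is.null(cr)) stop("segment does not cross the boundary")
  if (!is.null(cr$n_crossings) && cr$n_crossings > 1L)
    message(sprintf("segment crosses boundary %d times; first crossing used",
                    cr$n_crossings))
  if (interpolation == "proportional") {
    tc <- as.numeric(t0) + cr$frac * (as.numeric(t1) - as.numeric(t0))
  } else if (anchor == "outside") {
    d_km <- gc_distance(p0, cr$point, params)
    tc <- as.numeric(t0) + d_km * 1000 / params$mean_flight_speed
  } else {
    d_km <- gc_distance(cr$point, p1, params)
    tc <- as.numeric(t1) - d_km * 1000 / params$mean_flight_speed
  }
  lo <- as.numeric(t0); hi <- as.numeric(t1)
  if (tc > hi + 1e-9 || tc < lo - 1e-9) {
    warning("fixed-speed crossing time outside the fix gap; clamped")
    tc <- min(max(tc, lo), hi)
  }
  if (inherits(t0, "POSIXct"))
    as.POSIXct(tc, origin = "1970-01-01", tz = "UTC")
  else tc
}
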