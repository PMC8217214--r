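#' Spherical Lambert azimuthal equal-area projection
#'
#' Forward/inverse equal-area projection used before kernel density
#' estimation, so that a kernel of fixed bandwidth represents the same
#' ground area everywhere. Default centre 25 deg N, 60 deg W (mid Atlantic
#' hurricane basin).
#'
#' @param lonlat,xy Two-column matrices: (lon, lat) degrees / (x, y) km.
#' @param center `c(lon, lat)` of the projection centre.
#' @param params A [geo_params()] (supplies the sphere radius).
#' @return Two-column matrix of projected km (`laea_project`) or degrees
#'   (`laea_inverse`).
#' @export
laea_project <- function(lonlat, center = c(-60, 25), params = geo_params()) {
  lonlat <- as_lonlat(lonlat)
  R <- params$earth_radius_km
  lam <- lonlat[, 1] * pi / 180; phi <- lonlat[, 2] * pi / 180
  lam0 <- center[1] * pi / 180; phi1 <- center[2] * pi / 180
  denom <- 1 + sin(phi1) * sin(phi) + cos(phi1) * cos(phi) * cos(lam - lam0)
  kp <- sqrt(2 / denom)
  cbind(x = R * kp * cos(phi) * sin(lam - lam0),
        y = R * kp * (cos(phi1) * sin(phi) -
                        sin(phi1) * cos(phi) * cos(lam - lam0)))
}

#' @rdname laea_project
#' @export
laea_inverse <- function(xy, center = c(-60, 25), params = geo_params()) {
  xy <- as.matrix(xy)
  R <- params$earth_radius_km
  lam0 <- center[1] * pi / 180; phi1 <- center[2] * pi / 180
  rho <- sqrt(xy[, 1]^2 + xy[, 2]^2)
  cc <- 2 * asin(pmin(1, rho / (2 * R)))
  phi <- ifelse(rho < 1e-12, phi1,
                asin(cos(cc) * sin(phi1) +
                       xy[, 2] * sin(cc) * cos(phi1) / pmax(rho, 1e-12)))
  lam <- lam0 + atan2(xy[, 1] * sin(cc),
                      rho * cos(phi1) * cos(cc) - xy[, 2] * sin(phi1) * sin(cc))
  cbind(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

#' Pool filtered storm records into a weighted point set
#'
#' One unit-weight point per retained synoptic record, so a storm
#' contributes in proportion to its lifespan.
#'
#' @param storms List of season/status-filtered `storm_track`.
#' @return data.frame with `lon`, `lat`, `weight`, `storm_id`, `timestamp`.
#' @export
build_storm_points <- function(storms) {
  if (length(storms) == 0L) stop("no storms to pool")
  rows <- lapply(storms, function(s)
    data.frame(lon = s$points$lon, lat = s$points$lat, weight = 1,
               storm_id = s$storm_id, timestamp = s$points$timestamp,
               stringsAsFactors = FALSE))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (nrow(out) == 0L) stop("no storms to pool")
  out
}

# normal-reference (Scott) diagonal bandwidth, km, for projected points
nrd_bandwidth <- function(xy) {
  n <- nrow(xy)
  c(stats::sd(xy[, 1]), stats::sd(xy[, 2])) * n^(-1 / 6)
}

# Smoothed cross-validation criterion for a diagonal bandwidth, Gaussian
# kernels, pilot G fixed at the normal-reference diagonal. O(n^2): evaluated
# on a subsample when n is large.
scv_criterion <- function(h, dx, dy, g, n) {
  phi2 <- function(d2x, s2x, d2y, s2y)
    exp(-0.5 * (d2x / s2x + d2y / s2y)) / (2 * pi * sqrt(s2x * s2y))
  d2x <- dx^2; d2y <- dy^2
  s1x <- 2 * h[1]^2 + 2 * g[1]^2; s1y <- 2 * h[2]^2 + 2 * g[2]^2
  s2x <- h[1]^2 + 2 * g[1]^2;     s2y <- h[2]^2 + 2 * g[2]^2
  s3x <- 2 * g[1]^2;              s3y <- 2 * g[2]^2
  term <- sum(phi2(d2x, s1x, d2y, s1y) - 2 * phi2(d2x, s2x, d2y, s2y) +
                phi2(d2x, s3x, d2y, s3y))
  1 / (n * 4 * pi * h[1] * h[2]) + term / n^2
}

scv_bandwidth <- function(xy, max_n = 1500L) {
  n0 <- nrow(xy)
  if (n0 > max_n) xy <- xy[seq(1L, n0, length.out = max_n), , drop = FALSE]
  n <- nrow(xy)
  g <- nrd_bandwidth(xy)
  dx <- as.numeric(stats::dist(xy[, 1])); dx <- c(dx, dx, numeric(n))
  dy <- as.numeric(stats::dist(xy[, 2])); dy <- c(dy, dy, numeric(n))
  obj <- function(lh) scv_criterion(exp(lh), dx, dy, g, n)
  opt <- stats::optim(log(g), obj, method = "Nelder-Mead")
  exp(opt$par)
}

#' Fit a Gaussian kernel density surface to storm points
#'
#' Points are projected to an equal-area plane, a product Gaussian kernel
#' density is evaluated on a regular grid, and the grid is renormalized to
#' unit mass. Bandwidth selectors: `"nrd"` (bivariate normal-reference
#' rule, the fast default), `"scv"` (smoothed cross-validation, optimised
#' numerically over a diagonal bandwidth), `"fixed"` (caller-supplied `h`).
#'
#' @param points data.frame from [build_storm_points()] (or any `lon`/`lat`
#'   table; with `raw_lonlat = TRUE` coordinates are used unprojected, in
#'   degrees).
#' @param bandwidth_method `"nrd"`, `"scv"` or `"fixed"`.
#' @param h Per-axis kernel standard deviations (km) when
#'   `bandwidth_method = "fixed"`.
#' @param cell_km Grid cell size, default 25 km.
#' @param center Projection centre.
#' @param pad_sd Grid padding beyond the point extent, in bandwidths.
#' @param raw_lonlat Skip the projection (then `cell_km` and `h` are in
#'   degrees).
#' @param params A [geo_params()].
#' @return A `density_grid`: grid axes `x`, `y` (km), matrix `z`
#'   (density per km^2, integrating to 1), `H` (2x2 diagonal bandwidth
#'   matrix, km^2), `cell_km`, `center`, `n_points`, `raw_lonlat`.
#' @export
fit_kde <- function(points, bandwidth_method = c("nrd", "scv", "fixed"),
                    h = NULL, cell_km = 25, center = c(-60, 25),
                    pad_sd = 4, raw_lonlat = FALSE, params = geo_params()) {
  bandwidth_method <- match.arg(bandwidth_method)
  if (nrow(points) < 20L) stop("need at least 20 points for a density fit")
  xy <- if (raw_lonlat) cbind(points$lon, points$lat)
  else laea_project(cbind(points$lon, points$lat), center, params)
  if (min(stats::sd(xy[, 1]), stats::sd(xy[, 2])) < 1e-9)
    stop("degenerate point set: zero variance along one axis (collinear points)")
  hh <- switch(bandwidth_method,
               nrd = nrd_bandwidth(xy),
               scv = scv_bandwidth(xy),
               fixed = {
                 if (is.null(h)) stop("bandwidth_method='fixed' needs h")
                 rep(as.numeric(h), length.out = 2L)
               })
  lims <- c(range(xy[, 1]) + c(-1, 1) * pad_sd * hh[1],
            range(xy[, 2]) + c(-1, 1) * pad_sd * hh[2])
  nx <- max(32L, ceiling(diff(lims[1:2]) / cell_km))
  ny <- max(32L, ceiling(diff(lims[3:4]) / cell_km))
  # MASS::kde2d uses sd = h/4 internally
  kd <- MASS::kde2d(xy[, 1], xy[, 2], h = 4 * hh, n = c(nx, ny), lims = lims)
  cell <- c(diff(kd$x[1:2]), diff(kd$y[1:2]))
  z <- kd$z / (sum(kd$z) * cell[1] * cell[2])
  structure(list(x = kd$x, y = kd$y, z = z,
                 H = diag(hh^2), bandwidth = hh,
                 cell_km = cell, center = center,
                 n_points = nrow(points), raw_lonlat = raw_lonlat,
                 params = params),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d x %d cells (%.1f x %.1f km), n = %d, bandwidth = (%.1f, %.1f) km\n",
              length(x$x), length(x$y), x$cell_km[1], x$cell_km[2],
              x$n_points, x$bandwidth[1], x$bandwidth[2]))
  invisible(x)
}

grid_mass <- function(grid) sum(grid$z) * grid$cell_km[1] * grid$cell_km[2]

#' Highest-density region of a density grid
#'
#' Finds the largest density threshold whose superlevel set holds at least
#' the requested probability mass (exact on the grid), traces its contour
#' polygons, and inverse-projects them to lon/lat.
#'
#' @param grid A `density_grid` from [fit_kde()].
#' @param mass Probability mass, in (0, 1); 0.5 gives the core-occurrence
#'   region.
#' @return A `risk_region`: `mass_level`, `density_threshold`, `polygons`
#'   (closed lon/lat rings), `polygons_km` (projected rings),
#'   `achieved_mass`, `area_km2` (grid-cell area of the superlevel set).
#' @export
hdr_region <- function(grid, mass = 0.5) {
  stopifnot(mass > 0, mass < 1)
  cell_area <- grid$cell_km[1] * grid$cell_km[2]
  zv <- sort(as.numeric(grid$z), decreasing = TRUE)
  cum <- cumsum(zv) * cell_area
  k <- which(cum >= mass)[1]
  if (is.na(k))
    stop("requested mass unreachable on this grid; use a finer/larger grid")
  thr <- zv[k]
  achieved <- sum(grid$z[grid$z >= thr]) * cell_area
  cl <- grDevices::contourLines(grid$x, grid$y, grid$z, levels = thr)
  if (length(cl) == 0L)
    stop("no closed contour at the requested mass; use a finer grid")
  polys_km <- lapply(cl, function(cc) {
    ring <- cbind(cc$x, cc$y)
    if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    ring
  })
  polys <- if (grid$raw_lonlat) polys_km
  else lapply(polys_km, function(r) laea_inverse(r, grid$center, grid$params))
  structure(list(mass_level = mass, density_threshold = thr,
                 polygons = polys, polygons_km = polys_km,
                 achieved_mass = achieved,
                 area_km2 = sum(grid$z >= thr) * cell_area,
                 raw_lonlat = grid$raw_lonlat),
            class = "risk_region")
}

#' @export
print.risk_region <- function(x, ...) {
  cat(sprintf("<risk_region> %.0f%% highest-density region: %d polygon(s), %.0f km^2 (achieved mass %.3f)\n",
              100 * x$mass_level, length(x$polygons), x$area_km2,
              x$achieved_mass))
  invisible(x)
}

#' Export a risk region as GeoJSON
#'
#' @param region A `risk_region`.
#' @param path Output file.
#' @export
write_region_geojson <- function(region, path) {
  rings <- lapply(region$polygons, function(r) {
    coords <- apply(r, 1, function(p) sprintf("[%.6f,%.6f]", p[1], p[2]))
    sprintf("[[%s]]", paste(coords, collapse = ","))
  })
  json <- sprintf(paste0(
    '{"type":"Feature","properties":{"mass_level":%s,"density_threshold":%s},',
    '"geometry":{"type":"MultiPolygon","coordinates":[%s]}}'),
    format(region$mass_level), format(region$density_threshold),
    paste(unlist(rings), collapse = ","))
  writeLines(json, path)
  invisible(path)
}

#' Time a journey spends inside the cyclone risk region
#'
#' Walks the track through the region polygons; every boundary crossing gets
#' an entry/exit instant from the fixed-speed interpolation rule (distance
#' from the last fix on the old side to the boundary, divided by the mean
#' flight speed), and all inside intervals are summed. A track wholly
#' outside yields zero days. Stationary (grounded) time inside the region
#' counts in full.
#'
#' @param track A `bird_track` (or any time-sorted lon/lat data.frame).
#' @param region A `risk_region` (lon/lat polygons).
#' @param params A [geo_params()].
#' @param mode `"nonstop"` or `"grounded"` label carried on the record.
#' @return An `exposure_record`: `bird_id`, `intervals` (data.frame of
#'   entry/exit), `total_days`, `mode`.
#' @export
exposure_time <- function(track, region, params = geo_params(),
                          mode = c("nonstop", "grounded")) {
  mode <- match.arg(mode)
  polys <- region$polygons
  n <- nrow(track)
  inside <- point_in_region(cbind(track$lon, track$lat), polys)
  entries <- c(); exits <- c()
  if (any(inside)) {
    r <- rle(inside)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      t_in <- if (i0 == 1L) as.numeric(track$timestamp[1])
      else as.numeric(crossing_time(track[i0 - 1L, ], track[i0, ], polys,
                                    params, anchor = "outside"))
      t_out <- if (i1 == n) as.numeric(track$timestamp[n])
      else as.numeric(crossing_time(track[i1, ], track[i1 + 1L, ], polys,
                                    params, anchor = "outside"))
      entries <- c(entries, t_in); exits <- c(exits, t_out)
    }
  }
  intervals <- data.frame(
    entry = as.POSIXct(entries, origin = "1970-01-01", tz = "UTC"),
    exit = as.POSIXct(exits, origin = "1970-01-01", tz = "UTC"))
  structure(list(bird_id = attr(track, "bird_id"),
                 intervals = intervals,
                 total_days = if (nrow(intervals)) sum(exits - entries) / 86400 else 0,
                 mode = mode),
            class = "exposure_record")
}

#' @export
print.exposure_record <- function(x, ...) {
  cat(sprintf("<exposure_record> %s: %.2f days inside region over %d interval(s) [%s]\n",
              x$bird_id, x$total_days, nrow(x$intervals), x$mode))
  invisible(x)
}
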