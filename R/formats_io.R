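#' @section Domain containers:
#' A `bird_track` is a data.frame with columns `bird_id`, `timestamp`
#' (POSIXct, UTC), `lat`, `lon`, `lc` (ARGOS location class, one of
#' 3/2/1/0/A/B/Z), carrying attributes `bird_id`, `population`
#' (`"MackenzieDelta"` or `"HudsonBay"`, possibly NA) and `duty_cycle`
#' (`c(off = hours, on = hours)`). A `storm_track` is a list with
#' `storm_id`, `name` and `points`, a data.frame of six-hourly best-track
#' records (`timestamp`, `lat`, `lon`, `max_wind` knots with NA for the
#' missing sentinel, `status`, `record_id`).
#' @name stormcross-containers
NULL

LC_CODES <- c("3", "2", "1", "0", "A", "B", "Z")
STORM_STATUSES <- c("TD", "TS", "HU", "EX", "SD", "SS", "LO", "WV", "DB")

new_bird_track <- function(df, bird_id, population = NA_character_,
                           duty_cycle = c(off = 24, on = 5)) {
  df <- df[order(as.numeric(df$timestamp)), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, bird_id = bird_id, population = population,
            duty_cycle = duty_cycle,
            class = c("bird_track", "data.frame"))
}

#' @export
print.bird_track <- function(x, ...) {
  cat(sprintf("<bird_track> %s  (%s)  %d fixes", attr(x, "bird_id"),
              attr(x, "population"), nrow(x)))
  if (nrow(x) > 0)
    cat(sprintf("  %s .. %s", format(min(x$timestamp)), format(max(x$timestamp))))
  cat("\n")
  invisible(x)
}

new_storm_track <- function(storm_id, name, points) {
  points <- points[order(as.numeric(points$timestamp)), , drop = FALSE]
  rownames(points) <- NULL
  structure(list(storm_id = storm_id, name = name, points = points),
            class = "storm_track")
}

#' @export
print.storm_track <- function(x, ...) {
  w <- suppressWarnings(max(x$points$max_wind, na.rm = TRUE))
  cat(sprintf("<storm_track> %s %s: %d records, peak wind %s kt\n",
              x$storm_id, x$name, nrow(x$points),
              if (is.finite(w)) w else "NA"))
  invisible(x)
}

#' Read an ARGOS-style telemetry CSV into bird tracks
#'
#' One `bird_track` per animal. Rows are time-sorted per bird; duplicate
#' (bird, timestamp) rows are collapsed keeping the best (numerically
#' highest) location class, first occurrence on ties. Rows with an unknown
#' location-class code are dropped with a warning; an unparseable timestamp
#' is a row-level error naming the line.
#'
#' @param path CSV file with a header.
#' @param column_map Named character vector mapping the roles `id`,
#'   `timestamp`, `lat`, `lon`, `lc` to column names in the file.
#' @param populations Optional named character vector `bird_id ->
#'   population`; alternatively a `population` role in `column_map`.
#' @return List of `bird_track`, named by bird id.
#' @export
parse_telemetry_csv <- function(path,
                                column_map = c(id = "bird_id",
                                               timestamp = "timestamp",
                                               lat = "lat", lon = "lon",
                                               lc = "lc"),
                                populations = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("id", "timestamp", "lat", "lon", "lc")
  if (!all(need %in% names(column_map)))
    stop("column_map must name roles: ", paste(need, collapse = ", "))
  missing_cols <- setdiff(unname(column_map[need]), names(raw))
  if (length(missing_cols))
    stop("columns not in file: ", paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) return(list())

  ts_str <- raw[[column_map[["timestamp"]]]]
  ts <- as.POSIXct(rep(NA_real_, length(ts_str)), origin = "1970-01-01",
                   tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M")) {
    idx <- which(is.na(ts))
    if (length(idx) == 0L) break
    ts[idx] <- as.POSIXct(strptime(ts_str[idx], fmt, tz = "UTC"))
  }
  bad_ts <- which(is.na(ts))
  if (length(bad_ts))
    stop(sprintf("unparseable timestamp at data line %d: '%s'",
                 bad_ts[1] + 1L, raw[[column_map[["timestamp"]]]][bad_ts[1]]))

  lc <- toupper(trimws(raw[[column_map[["lc"]]]]))
  bad_lc <- !(lc %in% LC_CODES)
  if (any(bad_lc)) {
    warning(sprintf("%d row(s) with unknown location-class code dropped",
                    sum(bad_lc)))
  }
  df <- data.frame(
    bird_id = trimws(raw[[column_map[["id"]]]]),
    timestamp = ts,
    lat = as.numeric(raw[[column_map[["lat"]]]]),
    lon = as.numeric(raw[[column_map[["lon"]]]]),
    lc = lc, stringsAsFactors = FALSE)[!bad_lc, , drop = FALSE]
  if (any(abs(df$lat) > 90) || any(df$lon < -180 | df$lon >= 180))
    stop("coordinate out of range in ", path)

  pop_col <- if ("population" %in% names(column_map) &&
                 column_map[["population"]] %in% names(raw))
    trimws(raw[[column_map[["population"]]]])[!bad_lc] else NULL

  # best-LC wins on duplicate timestamps; Z (failed) ranks lowest
  lc_rank <- c(Z = 0, B = 1, A = 2, `0` = 3, `1` = 4, `2` = 5, `3` = 6)
  out <- list()
  for (id in unique(df$bird_id)) {
    sub <- df[df$bird_id == id, , drop = FALSE]
    o <- order(as.numeric(sub$timestamp), -lc_rank[sub$lc])
    sub <- sub[o, , drop = FALSE]
    sub <- sub[!duplicated(as.numeric(sub$timestamp)), , drop = FALSE]
    pop <- if (!is.null(populations) && id %in% names(populations))
      populations[[id]]
    else if (!is.null(pop_col)) pop_col[df$bird_id == id][1]
    else NA_character_
    out[[id]] <- new_bird_track(sub, bird_id = id, population = pop)
  }
  out
}

#' Filter a bird track by ARGOS location class
#'
#' Retains exactly the fixes whose location class is in `allowed`
#' (the standard quality filter keeps classes 1-3), preserving order.
#'
#' @param track A `bird_track`.
#' @param allowed Non-empty subset of `c("3","2","1","0","A","B","Z")`.
#' @return The filtered `bird_track`; if no fix survives it carries
#'   attribute `empty_track = TRUE`, which downstream stages reject.
#' @export
filter_by_location_class <- function(track, allowed = c("1", "2", "3")) {
  allowed <- as.character(allowed)
  if (length(allowed) == 0L || !all(allowed %in% LC_CODES))
    stop("allowed must be a non-empty subset of the LC codes")
  keep <- track$lc %in% allowed
  out <- track[keep, , drop = FALSE]
  out <- new_bird_track(as.data.frame(out), attr(track, "bird_id"),
                        attr(track, "population"), attr(track, "duty_cycle"))
  if (nrow(out) == 0L) attr(out, "empty_track") <- TRUE
  out
}

# ---- HURDAT2 --------------------------------------------------------------

hurdat2_coord <- function(txt, line_no) {
  txt <- trimws(txt)
  m <- regmatches(txt, regexec("^([0-9]+\\.?[0-9]*)([NSEW])$", txt))[[1]]
  if (length(m) != 3L)
    stop(sprintf("malformed coordinate '%s' at line %d", txt, line_no))
  val <- as.numeric(m[2])
  if (m[3] %in% c("S", "W")) val <- -val
  val
}

#' Parse an Atlantic HURDAT2 best-track file
#'
#' Reads the comma-delimited (post-2013) National Hurricane Center dialect:
#' a header line per storm (`AL092011, IRENE, 39,`) followed by the declared
#' number of data lines of six-hourly records. West longitudes come out
#' negative; the missing-wind sentinel -99 becomes `NA`.
#'
#' @param path HURDAT2 text file.
#' @return List of `storm_track`, named by storm id.
#' @export
parse_hurdat2 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], ",")[[1]]
    if (length(hdr) < 3L)
      stop(sprintf("expected storm header at line %d: '%s'", i, lines[i]))
    storm_id <- trimws(hdr[1]); name <- trimws(hdr[2])
    if (!grepl("^[A-Z]{2}[0-9]{6}$", storm_id))
      stop(sprintf("line %d: '%s' is not a storm header (pre-2013 fixed-width dialect is not supported)",
                   i, lines[i]))
    n_rec <- suppressWarnings(as.integer(trimws(hdr[3])))
    if (is.na(n_rec))
      stop(sprintf("bad record count in header at line %d", i))
    if (i + n_rec > length(lines))
      stop(sprintf("storm %s declares %d records but file ends early",
                   storm_id, n_rec))
    rows <- lines[seq.int(i + 1L, length.out = n_rec)]
    if (any(grepl("^[A-Z]{2}[0-9]{6},", rows)))
      stop(sprintf("storm %s: declared/actual record count mismatch", storm_id))
    f <- lapply(strsplit(rows, ","), trimws)
    pts <- data.frame(
      timestamp = as.POSIXct(paste0(vapply(f, `[`, "", 1), " ",
                                    vapply(f, `[`, "", 2)),
                             format = "%Y%m%d %H%M", tz = "UTC"),
      record_id = vapply(f, `[`, "", 3),
      status = vapply(f, `[`, "", 4),
      lat = vapply(seq_along(f), function(k)
        hurdat2_coord(f[[k]][5], i + k), numeric(1)),
      lon = vapply(seq_along(f), function(k)
        hurdat2_coord(f[[k]][6], i + k), numeric(1)),
      max_wind = as.integer(vapply(f, `[`, "", 7)),
      stringsAsFactors = FALSE)
    if (anyNA(pts$timestamp))
      stop(sprintf("storm %s: unparseable date/time", storm_id))
    if (!all(pts$status %in% STORM_STATUSES))
      stop(sprintf("storm %s: unknown status code '%s'", storm_id,
                   setdiff(pts$status, STORM_STATUSES)[1]))
    pts$max_wind[pts$max_wind == -99L] <- NA_integer_
    out[[storm_id]] <- new_storm_track(storm_id, name, pts)
    i <- i + 1L + n_rec
  }
  out
}

#' Write storms to a HURDAT2 file
#'
#' Serializes `storm_track`s in the comma-delimited NHC dialect with the
#' standard fixed field widths, so that `parse_hurdat2(write_hurdat2(x))`
#' reproduces `x` and a second write is byte-identical.
#'
#' @param storms List of `storm_track`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hurdat2 <- function(storms, path) {
  fmt_coord <- function(v, pos, neg, width) {
    hemi <- ifelse(v >= 0, pos, neg)
    formatC(sprintf("%.1f%s", abs(v), hemi), width = width)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  for (s in storms) {
    p <- s$points
    if (any(abs(p$lat) > 90) || any(abs(p$lon) > 180))
      stop("storm ", s$storm_id, ": coordinate out of range; refusing to write")
    header <- sprintf("%s,%s,%s,", s$storm_id,
                      formatC(s$name, width = 19), formatC(nrow(p), width = 7))
    wind <- ifelse(is.na(p$max_wind), -99L, p$max_wind)
    body <- sprintf("%s, %s,%s, %s, %s, %s, %s,",
                    format(p$timestamp, "%Y%m%d", tz = "UTC"),
                    format(p$timestamp, "%H%M", tz = "UTC"),
                    formatC(p$record_id, width = 2),
                    formatC(p$status, width = 2),
                    fmt_coord(p$lat, "N", "S", 5),
                    fmt_coord(p$lon, "E", "W", 6),
                    formatC(wind, width = 3))
    writeLines(c(header, body), con, sep = "\n")
  }
  invisible(path)
}

status_rank <- function(status) {
  # rank on the tropical ladder; non-tropical statuses rank below TD
  r <- c(TD = 1, SD = 0, SS = 0, TS = 2, HU = 3)[status]
  r[is.na(r)] <- 0
  unname(r)
}

#' Filter storms to the migration season and tropical statuses
#'
#' Keeps storms with at least one record inside the season window and year
#' range; within each kept storm keeps only in-window synoptic records
#' (00/06/12/18 UTC, so every record carries equal lifespan weight) whose
#' status rank is at least `min_status` on the ladder TD < TS < HU.
#' Subtropical statuses (SD/SS) are excluded from "tropical depression or
#' above" unless `include_subtropical = TRUE`.
#'
#' @param storms List of `storm_track`.
#' @param start_md,end_md Inclusive season window as `"mm-dd"` strings,
#'   compared month-day within each year. Defaults 15 Jul - 30 Nov.
#' @param year_min,year_max Inclusive year range (default 1961-2018).
#' @param min_status `"TD"`, `"TS"` or `"HU"`.
#' @param include_subtropical Count SD/SS as TD-rank? Default FALSE.
#' @return Filtered list of `storm_track` (storms left empty are dropped);
#'   warns if nothing survives.
#' @export
filter_storm_season <- function(storms, start_md = "07-15", end_md = "11-30",
                                year_min = 1961, year_max = 2018,
                                min_status = "TD",
                                include_subtropical = FALSE) {
  stopifnot(min_status %in% c("TD", "TS", "HU"))
  md_ok <- function(ts) {
    md <- format(ts, "%m-%d", tz = "UTC")
    if (start_md <= end_md) md >= start_md & md <= end_md
    else md >= start_md | md <= end_md
  }
  min_rank <- status_rank(min_status)
  out <- list()
  for (s in storms) {
    p <- s$points
    yr <- as.integer(format(p$timestamp, "%Y", tz = "UTC"))
    in_window <- md_ok(p$timestamp) & yr >= year_min & yr <= year_max
    if (!any(in_window)) next
    rank <- status_rank(p$status)
    if (include_subtropical) rank[p$status %in% c("SD", "SS")] <- 1
    synoptic <- as.integer(format(p$timestamp, "%H", tz = "UTC")) %% 6 == 0 &
      as.integer(format(p$timestamp, "%M", tz = "UTC")) == 0
    keep <- in_window & synoptic & rank >= min_rank
    if (!any(keep)) next
    out[[s$storm_id]] <- new_storm_track(s$storm_id, s$name,
                                         p[keep, , drop = FALSE])
  }
  if (length(out) == 0L)
    warning("no storms survive the season/status filter")
  out
}

#' Write bird tracks to a telemetry CSV
#'
#' Fixed-format serialization (ISO-8601 UTC timestamps, 5-decimal
#' coordinates) so identical inputs yield byte-identical files.
#'
#' @param tracks List of `bird_track`.
#' @param path Output file.
#' @export
write_telemetry_csv <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    data.frame(bird_id = tr$bird_id,
               population = attr(tr, "population"),
               timestamp = format(tr$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                  tz = "UTC"),
               lat = sprintf("%.5f", tr$lat),
               lon = sprintf("%.5f", tr$lon),
               lc = tr$lc, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(colnames(all), collapse = ","), con)
  if (!is.null(all) && nrow(all))
    writeLines(do.call(paste, c(unname(as.list(all)), sep = ",")), con)
  invisible(path)
}
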