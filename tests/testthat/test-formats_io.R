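test_that("telemetry CSV parsing sorts, deduplicates and filters rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("bird_id,timestamp,lat,lon,lc", f)
  expect_length(parse_telemetry_csv(f), 0)

  # out-of-order rows come back time-sorted
  writeLines(c("bird_id,timestamp,lat,lon,lc",
               "b1,2015-08-03T00:00:00Z,10,-60,3",
               "b1,2015-08-01T00:00:00Z,12,-62,2",
               "b1,2015-08-02T00:00:00Z,11,-61,1"), f)
  tr <- parse_telemetry_csv(f)
  expect_length(tr, 1)
  expect_equal(nrow(tr$b1), 3)
  expect_true(!is.unsorted(tr$b1$timestamp, strictly = TRUE))
  expect_equal(tr$b1$lat, c(12, 11, 10))

  # duplicate timestamp: best location class wins
  writeLines(c("bird_id,timestamp,lat,lon,lc",
               "b1,2015-08-01T00:00:00Z,12,-62,1",
               "b1,2015-08-01T00:00:00Z,13,-63,3"), f)
  tr <- parse_telemetry_csv(f)
  expect_equal(nrow(tr$b1), 1)
  expect_equal(tr$b1$lc, "3")

  # unknown LC dropped with a warning; bad timestamp is an error with a line
  writeLines(c("bird_id,timestamp,lat,lon,lc",
               "b1,2015-08-01T00:00:00Z,12,-62,3",
               "b1,2015-08-02T00:00:00Z,12,-62,Q"), f)
  expect_warning(tr <- parse_telemetry_csv(f), "unknown location-class")
  expect_equal(nrow(tr$b1), 1)
  writeLines(c("bird_id,timestamp,lat,lon,lc",
               "b1,not-a-time,12,-62,3"), f)
  expect_error(parse_telemetry_csv(f), "line 2")
})

test_that("generated telemetry round-trips through CSV with counts preserved", {
  sc <- scenario_config(seed = 3, n_birds = c(MackenzieDelta = 1,
                                              HudsonBay = 1),
                        years = 2014)
  gb <- generate_bird_tracks(sc)
  f <- withr::local_tempfile(fileext = ".csv")
  write_telemetry_csv(gb$tracks, f)
  back <- parse_telemetry_csv(f, column_map = c(id = "bird_id",
                                                timestamp = "timestamp",
                                                lat = "lat", lon = "lon",
                                                lc = "lc",
                                                population = "population"))
  expect_setequal(names(back), names(gb$tracks))
  for (id in names(back)) {
    expect_equal(nrow(back[[id]]), nrow(gb$tracks[[id]]))
    expect_equal(attr(back[[id]], "population"),
                 attr(gb$tracks[[id]], "population"))
  }
})

test_that("location-class filter keeps exactly the allowed classes in order", {
  df <- data.frame(bird_id = "b", timestamp = utc("2015-08-01") + 1:5 * 3600,
                   lat = 1:5, lon = 1:5,
                   lc = c("3", "B", "1", "0", "2"), stringsAsFactors = FALSE)
  tr <- stormcross:::new_bird_track(df, "b")
  out <- filter_by_location_class(tr, c("1", "2", "3"))
  expect_equal(nrow(out), 3)
  expect_equal(out$lc, c("3", "1", "2"))       # original order preserved
  expect_equal(out$lat, c(1, 3, 5))
  idn <- filter_by_location_class(tr, c("3", "2", "1", "0", "A", "B", "Z"))
  expect_equal(nrow(idn), 5)
  empty <- filter_by_location_class(tr[tr$lc == "B", ], c("3"))
  expect_true(isTRUE(attr(filter_by_location_class(
    stormcross:::new_bird_track(df[df$lc == "B", ], "b"), "3"),
    "empty_track")))
  expect_error(filter_by_location_class(tr, character()), "non-empty")
})

test_that("HURDAT2 parses the comma-delimited dialect with signed coordinates", {
  f <- withr::local_tempfile()
  writeLines(c("AL011999,             TOY,      1,",
               "19990810, 1200,  , TD,  25.0N,  60.0W,  30, 1005,"), f)
  st <- parse_hurdat2(f)
  expect_length(st, 1)
  expect_equal(st[[1]]$storm_id, "AL011999")
  expect_equal(st[[1]]$points$lat, 25)
  expect_equal(st[[1]]$points$lon, -60)
  expect_equal(st[[1]]$points$status, "TD")
  expect_equal(st[[1]]$points$max_wind, 30L)

  # count mismatch and malformed coordinates are named errors
  writeLines(c("AL011999,             TOY,      2,",
               "19990810, 1200,  , TD,  25.0N,  60.0W,  30, 1005,"), f)
  expect_error(parse_hurdat2(f), "AL011999")
  writeLines(c("AL011999,             TOY,      1,",
               "19990810, 1200,  , TD,  25.0X,  60.0W,  30, 1005,"), f)
  expect_error(parse_hurdat2(f), "malformed coordinate")
})

test_that("HURDAT2 write/parse is an identity and a second write is byte-stable", {
  f <- withr::local_tempfile()
  write_hurdat2(list(), f)
  expect_length(readLines(f), 0)

  s <- linear_storm(c(-60, 25), utc("2011-08-24 18:00:00"), span_h = 6)
  write_hurdat2(list(s), f)
  expect_length(readLines(f), 1 + nrow(s$points))

  sc <- scenario_config(seed = 5, years = 2013:2014)
  gs <- generate_storm_basin(sc)
  write_hurdat2(gs$storms, f)
  back <- parse_hurdat2(f)
  expect_equal(length(back), length(gs$storms))
  expect_equal(vapply(back, function(x) nrow(x$points), numeric(1)),
               setNames(gs$truth$n_records, gs$truth$storm_id))
  f2 <- withr::local_tempfile()
  write_hurdat2(back, f2)
  expect_identical(readLines(f), readLines(f2))
  # missing wind sentinel survives the round trip as NA
  s$points$max_wind[1] <- NA_integer_
  write_hurdat2(list(s), f)
  expect_true(grepl("-99", readLines(f)[2]))
  expect_true(is.na(parse_hurdat2(f)[[1]]$points$max_wind[1]))
})

test_that("season filter applies the window, year range and status ladder", {
  mk <- function(times, statuses, id = "AL011999") {
    pts <- data.frame(timestamp = utc(times), record_id = "",
                      status = statuses, lat = 20, lon = -50,
                      max_wind = 40L, stringsAsFactors = FALSE)
    stormcross:::new_storm_track(id, "T", pts)
  }
  june <- mk(c("1999-06-01 00:00:00", "1999-06-02 06:00:00"), c("TD", "TS"))
  expect_warning(out <- filter_storm_season(list(june)), "no storms")
  expect_length(out, 0)

  s <- mk(c("1999-08-01 00:00:00", "1999-08-01 06:00:00",
            "1999-08-01 12:00:00", "1999-08-01 18:00:00"),
          c("LO", "TD", "TS", "EX"))
  out <- filter_storm_season(list(s))
  expect_equal(nrow(out[[1]]$points), 2)          # TD and TS only
  expect_equal(out[[1]]$points$status, c("TD", "TS"))

  # off-synoptic records are dropped so each point has equal lifespan weight
  s2 <- mk(c("1999-08-01 00:00:00", "1999-08-01 03:00:00",
             "1999-08-01 06:00:00"), c("TD", "TD", "TD"), "AL021999")
  out2 <- filter_storm_season(list(s2))
  expect_equal(nrow(out2[[1]]$points), 2)

  # subtropical excluded by default, included on request
  s3 <- mk(c("1999-08-01 00:00:00", "1999-08-01 06:00:00"), c("SD", "SS"),
           "AL031999")
  expect_warning(expect_length(filter_storm_season(list(s3)), 0))
  expect_length(filter_storm_season(list(s3), include_subtropical = TRUE), 1)

  # idempotence and sub-multiset, against a brute-force row scan
  sc <- scenario_config(seed = 8, years = 2012)
  gs <- generate_storm_basin(sc)
  once <- filter_storm_season(gs$storms)
  twice <- filter_storm_season(once)
  expect_equal(twice, once)
  brute <- sum(vapply(gs$storms, function(s) {
    md <- format(s$points$timestamp, "%m-%d", tz = "UTC")
    hh <- as.integer(format(s$points$timestamp, "%H", tz = "UTC"))
    sum(md >= "07-15" & md <= "11-30" & hh %% 6 == 0 &
          s$points$status %in% c("TD", "TS", "HU"))
  }, numeric(1)))
  expect_equal(sum(vapply(once, function(s) nrow(s$points), numeric(1))),
               brute)
})
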