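test_that("Saffir-Simpson classifier reproduces every printed band edge", {
  bands <- list(TD = c(0, 20, 38), TS = c(39, 50, 73), C1 = c(74, 80, 95),
                C2 = c(96, 100, 110), C3 = c(111, 120, 129),
                C4 = c(130, 140, 156), C5 = c(157, 170, 250))
  for (lab in names(bands))
    expect_equal(unique(saffir_simpson_category(bands[[lab]])), lab)
  expect_error(saffir_simpson_category(-1), "negative")
  expect_true(is.na(saffir_simpson_category(NA_real_)))
  # total monotone step function
  w <- seq(0, 200, by = 0.5)
  cat_rank <- match(saffir_simpson_category(w),
                    c("TD", "TS", "C1", "C2", "C3", "C4", "C5"))
  expect_true(all(diff(cat_rank) >= 0))
  expect_equal(knots_to_mph(100), 115.078)
})

test_that("in-flight detection finds a planted close approach once", {
  t0 <- utc("2015-09-01")
  tr <- straight_track(c(-70, 35), c(-60, 0), v_ms = 14.8, t0 = t0,
                       step_s = 4 * 3600)
  t_star <- t0 + 30 * 3600
  bird_at <- interpolate_position(tr, t_star)
  # offset perpendicular to the course; a stationary storm centre makes the
  # closest approach occur exactly at the plant instant
  course <- initial_bearing(bird_at, interpolate_position(tr, t_star + 3600))
  storm_center <- geosphere::destPoint(bird_at, (course + 90) %% 360,
                                       50 * 1000, r = 6371008.8)
  st <- linear_storm(c(storm_center[1], storm_center[2]), t_star,
                     speed_kmh = 0, wind_kt = 120)
  cfg <- encounter_config()
  enc <- detect_inflight_encounters(tr, list(st), cfg)
  expect_equal(nrow(enc), 1)
  expect_lte(abs(as.numeric(enc$time) - as.numeric(t_star)),
             cfg$sync_step_min * 60 + 1)
  expect_equal(enc$min_separation_km, 50, tolerance = 0.02)
  expect_equal(enc$bird_state, "in_flight")
  expect_equal(enc$storm_category,
               saffir_simpson_category(knots_to_mph(120)))

  # same box, ten days apart: no temporal overlap, no encounter
  st_late <- linear_storm(c(storm_center[1], storm_center[2]),
                          t_star + 10 * 86400)
  expect_equal(nrow(detect_inflight_encounters(tr, list(st_late), cfg)), 0)
  # no storms at all
  expect_equal(nrow(detect_inflight_encounters(tr, list(), cfg)), 0)
})

test_that("encounter counts are non-decreasing in the detection radius", {
  t0 <- utc("2015-09-01")
  tr <- straight_track(c(-70, 35), c(-60, 0), v_ms = 14.8, t0 = t0,
                       step_s = 4 * 3600)
  storms <- lapply(c(80, 250, 420), function(d) {
    t_star <- t0 + 24 * 3600
    bird_at <- interpolate_position(tr, t_star)
    ctr <- geosphere::destPoint(bird_at, 90, d * 1000, r = 6371008.8)
    linear_storm(c(ctr[1], ctr[2]), t_star,
                 storm_id = sprintf("AL%02d1999", d %/% 80))
  })
  sweep <- encounter_sensitivity(tr, storms, radii_km = seq(50, 500, 50))
  expect_true(all(diff(sweep$n_encounters) >= 0))
  expect_gte(max(sweep$n_encounters), 3)
})

test_that("grounded encounters require a storm pass within the grounded radius", {
  t0 <- utc("2011-08-20")
  phase <- data.frame(kind = "staging", start = t0, end = t0 + 20 * 86400,
                      centroid_lon = -76.5, centroid_lat = 25.4)
  near <- linear_storm(geosphere::destPoint(c(-76.5, 25.4), 0, 20e3,
                                            r = 6371008.8)[1, 1:2],
                       t0 + 4 * 86400, storm_id = "AL091999")
  far <- linear_storm(geosphere::destPoint(c(-76.5, 25.4), 90, 500e3,
                                           r = 6371008.8)[1, 1:2],
                      t0 + 6 * 86400, bearing = 0, storm_id = "AL101999")
  enc <- detect_grounded_encounters(phase, list(near, far), bird_id = "b")
  expect_equal(nrow(enc), 1)
  expect_equal(enc$storm_id, "AL091999")
  expect_equal(enc$bird_state, "grounded")
  expect_lte(enc$min_separation_km, 100)

  # two successive storms over the same grounded bird give two encounters
  later <- linear_storm(geosphere::destPoint(c(-76.5, 25.4), 0, 40e3,
                                             r = 6371008.8)[1, 1:2],
                        t0 + 15 * 86400, storm_id = "AL111999")
  enc2 <- detect_grounded_encounters(phase, list(near, later), bird_id = "b")
  expect_equal(nrow(enc2), 2)
})

test_that("responses classify as none, detour or grounding, with grounding winning", {
  t0 <- utc("2015-09-01")
  cfg <- encounter_config()
  mk_enc <- function(tr, t_enc) {
    p <- interpolate_position(tr, t_enc)
    stormcross:::new_encounter(attr(tr, "bird_id"), "AL011999", t_enc,
                               p[1, 1], p[1, 2], "in_flight", 60, 50)
  }
  # straight continuation: none
  tr_s <- straight_track(c(-70, 30), c(-60, -8), v_ms = 14.8, t0 = t0,
                         step_s = 2 * 3600)
  t_enc <- t0 + 30 * 3600
  expect_equal(classify_response(tr_s, mk_enc(tr_s, t_enc), list(), cfg),
               "none")

  # a 30-degree turn shortly after the encounter: detour
  pre <- straight_track(c(-70, 30), c(-66.3, 16), v_ms = 14.8, t0 = t0,
                        step_s = 2 * 3600)
  turn_t <- max(pre$timestamp)
  brg_in <- initial_bearing(c(pre$lon[nrow(pre) - 1], pre$lat[nrow(pre) - 1]),
                            c(pre$lon[nrow(pre)], pre$lat[nrow(pre)]))
  new_to <- geosphere::destPoint(c(pre$lon[nrow(pre)], pre$lat[nrow(pre)]),
                                 (brg_in + 30) %% 360, 3200e3, r = 6371008.8)
  post <- straight_track(c(pre$lon[nrow(pre)], pre$lat[nrow(pre)]),
                         new_to[1, 1:2], v_ms = 14.8,
                         t0 = turn_t + 2 * 3600, step_s = 2 * 3600)
  tr_turn <- stormcross:::new_bird_track(
    rbind(as.data.frame(pre), as.data.frame(post)), "b1", "HudsonBay")
  enc_at_turn <- mk_enc(tr_turn, turn_t - 3600)
  expect_equal(classify_response(tr_turn, enc_at_turn, list(), cfg), "detour")

  # stopping on an island for days after the encounter: grounded
  island <- list(square_ring(-67.1, -65.9, 17.7, 18.7))
  pre2 <- straight_track(c(-70, 30), c(-66.5, 18.2), v_ms = 14.8, t0 = t0,
                         step_s = 2 * 3600)
  stay <- cluster_fixes(c(-66.5, 18.2), max(pre2$timestamp) + 2 * 3600,
                        days = 10, jitter_km = 1, seed = 30)
  tr_g <- stormcross:::new_bird_track(
    rbind(as.data.frame(pre2),
          data.frame(bird_id = "b1", timestamp = stay$timestamp,
                     lat = stay$lat, lon = stay$lon, lc = "3")),
    "b1", "HudsonBay")
  enc_g <- mk_enc(tr_g, max(pre2$timestamp) - 5 * 3600)
  expect_equal(classify_response(tr_g, enc_g, island, cfg), "grounded")
  # insufficient post-encounter fixes: indeterminate
  enc_end <- mk_enc(tr_s, max(tr_s$timestamp) - 3600)
  expect_equal(classify_response(tr_s, enc_end, list(), cfg), "indeterminate")
})

test_that("response classification is invariant to rotating the whole scene", {
  t0 <- utc("2015-09-01")
  cfg <- encounter_config()
  shift <- function(tr, dlon) {
    df <- as.data.frame(tr); df$lon <- df$lon + dlon
    stormcross:::new_bird_track(df, attr(tr, "bird_id"), "HudsonBay")
  }
  pre <- straight_track(c(-70, 30), c(-66.3, 16), v_ms = 14.8, t0 = t0,
                        step_s = 2 * 3600)
  turn_t <- max(pre$timestamp)
  last <- c(pre$lon[nrow(pre)], pre$lat[nrow(pre)])
  brg_in <- initial_bearing(c(pre$lon[nrow(pre) - 1], pre$lat[nrow(pre) - 1]),
                            last)
  new_to <- geosphere::destPoint(last, (brg_in + 30) %% 360, 3200e3,
                                 r = 6371008.8)
  post <- straight_track(last, new_to[1, 1:2], v_ms = 14.8,
                         t0 = turn_t + 2 * 3600, step_s = 2 * 3600)
  tr <- stormcross:::new_bird_track(
    rbind(as.data.frame(pre), as.data.frame(post)), "b1", "HudsonBay")
  t_enc <- turn_t - 3600
  for (dlon in c(0, 40, 95)) {
    trd <- shift(tr, dlon)
    p <- interpolate_position(trd, t_enc)
    enc <- stormcross:::new_encounter("b1", "AL011999", t_enc, p[1, 1],
                                      p[1, 2], "in_flight", 60, 50)
    expect_equal(classify_response(trd, enc, list(), cfg), "detour")
  }
})

test_that("encounter-rate arithmetic matches the printed percentages", {
  expect_equal(encounter_rate_pct(3, 26), 12)
  expect_equal(encounter_rate_pct(13, 21), 62)
  expect_equal(encounter_rate_pct(0, 10), 0)
  j <- data.frame(bird_id = c("a", "b", "c"),
                  population = c("MackenzieDelta", "MackenzieDelta",
                                 "HudsonBay"),
                  year = c(2011, 2012, 2011))
  enc <- stormcross:::new_encounter("a", "AL011999",
                                    utc("2011-09-01"), -60, 20,
                                    "in_flight", 60, 40)
  tab <- summarize_encounter_rates(j, enc)
  expect_equal(tab$n_with_encounter[tab$population == "MackenzieDelta"], 1)
  expect_equal(tab$pct_with_encounter[tab$population == "MackenzieDelta"], 50)
  expect_equal(tab$n_with_encounter[tab$population == "HudsonBay"], 0)
})
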