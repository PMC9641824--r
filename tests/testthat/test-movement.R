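test_that("solar times behave sensibly around the equinox", {
  # equinox: roughly 12 h of daylight everywhere temperate
  st <- solar_times(as.Date("2019-03-21"), c(0, 45, -30), c(35, 35, 35))
  daylen <- as.numeric(difftime(st$sunset, st$sunrise, units = "hours"))
  expect_true(all(abs(daylen - 12) < 0.5))
  # April, 30 N: later sunset than sunrise and sun up over the fix window
  st2 <- solar_times(as.Date("2019-04-15"), 29.55, 34.95)
  expect_lt(as.numeric(format(st2$sunrise, "%H")), 5)
  expect_gt(as.numeric(format(st2$sunset, "%H")), 15)
})

test_that("daylight subsampling keeps one fix per hourly slot", {
  day <- as.Date("2019-04-15")
  t0 <- as.POSIXct(paste(day, "03:30:00"), tz = "UTC")
  fixes <- tibble::tibble(
    individual_id = "b1",
    timestamp = t0 + seq(0, 12.5 * 3600, by = 600),  # 10-min over daylight
    lat = 29.55, lon = 34.95 + seq(0, 0.075, length.out = 76),
    acc_var = 1
  )
  sub <- subsample_daylight(fixes)
  expect_true(nrow(sub) %in% 12:14)   # ~13 hourly grid slots
  expect_true(all(as.numeric(diff(sub$timestamp), units = "mins") >= 30))

  # night-only fixes vanish
  night <- dplyr::mutate(fixes, timestamp = .data$timestamp - 8 * 3600)
  night <- night[night$timestamp < as.POSIXct(paste(day, "03:10:00"), tz = "UTC"), ]
  expect_equal(nrow(subsample_daylight(night)), 0)

  # already-hourly fixes pass through unchanged
  hourly <- sub
  sub2 <- subsample_daylight(dplyr::select(hourly, -"solar_date"))
  expect_equal(sub2$timestamp, hourly$timestamp)

  expect_equal(nrow(subsample_daylight(fixes[0, ])), 0)
})

test_that("daily metrics recover totals, beelines and turning angles", {
  # out-and-back: beeline ~0, total ~2x the leg
  day <- as.Date("2019-04-15")
  t0 <- as.POSIXct(paste(day, "06:00:00"), tz = "UTC")
  out <- rhumb_destination(30, 35, 0, seq(0, 30, length.out = 6))
  fixes <- tibble::tibble(
    individual_id = "b1",
    timestamp = t0 + 3600 * (0:10),
    lat = c(out$lat, rev(out$lat)[-1]),
    lon = c(out$lon, rev(out$lon)[-1]),
    acc_var = 1
  )
  seg <- daily_metrics(fixes)
  expect_equal(seg$beeline_km, 0, tolerance = 1e-6)
  expect_equal(seg$total_distance_km, 60, tolerance = 1e-6)

  # stationary day
  still <- dplyr::mutate(fixes, lat = 30, lon = 35)
  seg2 <- daily_metrics(still)
  expect_equal(seg2$total_distance_km, 0)
  expect_equal(seg2$beeline_km, 0)

  # wrap-around turning angle between days at 10 and 350 degrees
  fx <- toy_fixes(c(100, 100), c(10, 350))
  segs <- daily_metrics(fx)
  expect_equal(segs$azimuth_deg, c(10, 350), tolerance = 0.2)
  expect_true(is.na(segs$turning_angle_deg[1]))
  expect_equal(segs$turning_angle_deg[2], 20, tolerance = 0.4)
})

test_that("day classification applies the 40-km and/or 19-km rule", {
  seg <- tibble::tibble(total_distance_km = c(45, 25, 30),
                        beeline_km = c(10, 20, 15))
  cls <- classify_days(seg)
  expect_equal(as.character(cls$day_class),
               c("migratory", "migratory", "stopover"))
  # pure threshold function: permuting rows permutes labels identically
  perm <- sample(3)
  expect_equal(as.character(classify_days(seg[perm, ])$day_class),
               as.character(cls$day_class)[perm])
})

test_that("beeline never exceeds the total path", {
  set.seed(21)
  for (i in 1:5) {
    sc <- track_scenario(seed = i, n_migratory_days = 6,
                         stopover_run_lengths = c(2))
    segs <- daily_metrics(subsample_daylight(simulate_track(sc)$fixes))
    expect_true(all(segs$beeline_km <= segs$total_distance_km + 1e-6))
  }
})

test_that("endpoint detection follows the arrival, death and loss rules", {
  # five 200-km northern days, then a short sharp-turn day, nothing after
  fx <- toy_fixes(c(rep(200, 5), 10), c(rep(5, 5), 190))
  seg <- segment_track(fx)
  expect_equal(seg$outcomes$endpoint, "arrival")
  expect_equal(seg$outcomes$endpoint_date, as.Date("2019-04-15"))
  # arrival location is the previous day's roost
  d5 <- seg$segments[seg$segments$date == as.Date("2019-04-14"), ]
  expect_equal(seg$outcomes$endpoint_lat, d5$roost_end_lat)

  # two flat days mid-track trigger death with the location of the last fix
  fx2 <- toy_fixes(c(rep(150, 3), 0, 0, 0), c(rep(5, 3), 0, 0, 0))
  fx2$acc_var[fx2$timestamp >= as.POSIXct("2019-04-13 00:00:00", tz = "UTC")] <- 1e-4
  seg2 <- segment_track(fx2)
  expect_equal(seg2$outcomes$endpoint, "death")
  expect_equal(seg2$outcomes$endpoint_date, as.Date("2019-04-13"))

  # truncated stream with no behavioural change is a loss
  fx3 <- toy_fixes(rep(150, 4), rep(5, 4))
  seg3 <- segment_track(fx3)
  expect_equal(seg3$outcomes$endpoint, "loss")
})

test_that("migration summary accounts distances by endpoint type", {
  fx <- toy_fixes(c(rep(200, 3), 8), c(rep(5, 3), 200))
  seg <- segment_track(fx)
  s <- seg$segments
  capture <- c(s$roost_start_lat[1], s$roost_start_lon[1])
  out <- seg$outcomes
  winter <- c(-25, 30); breeding <- c(55, 60)
  ms <- migration_summary(s, out, capture, winter, breeding)
  expect_equal(ms$n_migratory_days + ms$n_stopover_days,
               sum(s$date < out$endpoint_date))
  expect_equal(ms$post_eilat_distance_km,
               sum(s$total_distance_km[s$day_class == "migratory" &
                                         s$date < out$endpoint_date]))
  expect_equal(ms$total_migration_distance_km,
               rhumb_distance(winter[1], winter[2], capture[1], capture[2]) +
                 rhumb_distance(capture[1], capture[2], breeding[1], breeding[2]))

  # all-stopover track: zero migration distance
  fx2 <- toy_fixes(rep(5, 4), c(10, 120, 250, 30))
  seg2 <- segment_track(fx2)
  ms2 <- migration_summary(seg2$segments, seg2$outcomes, capture)
  expect_equal(ms2$post_eilat_distance_km, 0)

  # death at the capture roost: distance until death ~ 0
  fx3 <- toy_fixes(c(1, 0, 0, 0), c(0, 0, 0, 0))
  fx3$acc_var[fx3$timestamp >= as.POSIXct("2019-04-11", tz = "UTC")] <- 1e-4
  seg3 <- segment_track(fx3)
  ms3 <- migration_summary(seg3$segments, seg3$outcomes, capture)
  expect_equal(seg3$outcomes$endpoint, "death")
  expect_lt(ms3$distance_until_death_km, 2)
})
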