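test_that("track readers parse GPX, TCX and CSV and validate columns", {
  # CSV
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = c(0, 1, 2), lat = 63.4, lon = 10.4,
                       ele_m = 100, hr_bpm = c(120, NA, 125)),
            f, row.names = FALSE)
  tr <- read_track(f)
  expect_s3_class(tr, "ski_track")
  expect_equal(tr$time, c(0, 1, 2))
  expect_true(is.na(tr$hr[2]))

  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(time_s = 0:2, lat = 63.4, ele_m = 100),
            bad, row.names = FALSE)
  expect_error(read_track(bad), "lon")

  # GPX round trip through the writer
  ref <- lay_out_reference(tiny_course())
  t0 <- track_on_reference(ref, speed = 2, hr = 130)
  g <- tempfile(fileext = ".gpx")
  write_track(t0, g)
  t1 <- read_track(g)
  expect_equal(t1$time, t0$time)
  expect_equal(t1$lat, t0$lat, tolerance = 1e-7)
  expect_equal(t1$lon, t0$lon, tolerance = 1e-7)
  expect_equal(t1$hr, t0$hr)

  # TCX fixture
  tcx <- tempfile(fileext = ".tcx")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<TrainingCenterDatabase xmlns="http://www.garmin.com/xmlschemas/TrainingCenterDatabase/v2">',
    '<Activities><Activity Sport="Other"><Lap><Track>',
    paste0('<Trackpoint><Time>2024-01-01T10:00:0', 0:2, '.000Z</Time>',
           '<Position><LatitudeDegrees>63.4</LatitudeDegrees>',
           '<LongitudeDegrees>10.4</LongitudeDegrees></Position>',
           '<AltitudeMeters>101</AltitudeMeters>',
           '<HeartRateBpm><Value>14', 0:2, '</Value></HeartRateBpm>',
           '</Trackpoint>'),
    '</Track></Lap></Activity></Activities></TrainingCenterDatabase>'), tcx)
  tt <- read_track(tcx, format = "tcx")
  expect_equal(nrow(tt), 3L)
  expect_equal(tt$time, c(0, 1, 2))
  expect_equal(tt$hr, c(140, 141, 142))
  expect_equal(tt$ele, rep(101, 3))

  expect_error(read_track(tempfile(fileext = ".gpx")), "not found")
})

test_that("single-point projection matches a brute-force densified oracle", {
  # 2-segment polyline with a corner
  vx <- c(0, 10, 10); vy <- c(0, 0, 10); dist <- c(0, 10, 20)
  pts <- list(c(3, 2), c(9.5, 1.2), c(11, 5), c(10.4, -0.3), c(12, 12))
  for (p in pts) {
    pr <- sitski:::project_on_segments(p[1], p[2], vx[-3], vy[-3],
                                       vx[-1], vy[-1])
    j <- which.min(pr$d2)
    s_pkg <- dist[j] + pr$t[j] * (dist[j + 1] - dist[j])
    oracle <- brute_force_project(p[1], p[2], vx, vy, dist, step = 0.005)
    expect_equal(s_pkg, oracle$s, tolerance = 0.01)
    expect_equal(sqrt(min(pr$d2)), oracle$d, tolerance = 0.01)
  }
})

test_that("a noise-free track on the reference maps to its arc length", {
  ref <- lay_out_reference(tiny_course())
  tr <- track_on_reference(ref, speed = 2)
  mapped <- map_to_course(tr, ref)
  expected <- pmin(tr$time * 2, attr(ref, "lap_length") - 1e-9)
  expect_lt(max(abs(mapped$course_distance - expected)), 0.1)
  expect_true(all(diff(mapped$course_distance) >= 0))
  # idempotence: remapping the identical coordinates changes nothing
  mapped2 <- map_to_course(tr, ref)
  expect_equal(mapped2$course_distance, mapped$course_distance)
})

test_that("mapping rejects a track drifting beyond the gate distance", {
  ref <- lay_out_reference(tiny_course())
  tr <- track_on_reference(ref, speed = 2)
  tr$lat[10] <- tr$lat[10] + 0.01  # ~1.1 km offset
  expect_error(map_to_course(tr, ref), "sample 10")
})

test_that("virtual splits interpolate boundaries and conserve lap time", {
  course <- tiny_course()
  ref <- lay_out_reference(course)
  tr <- track_on_reference(ref, speed = 2)
  mapped <- map_to_course(tr, ref)
  sp <- virtual_splits(mapped, course)
  expect_s3_class(sp, "split_table")
  # constant 2 m/s: durations = length / 2
  expect_equal(sp$duration, course$length / 2, tolerance = 1e-6)
  expect_equal(sp$mean_speed, rep(2, 3), tolerance = 1e-6)
  # conservation: sum of section times equals lap traversal time
  expect_equal(sum(sp$duration),
               sp$exit_time[nrow(sp)] - sp$entry_time[1],
               tolerance = 1e-6)
  # adjacency: exit of k is entry of k+1
  expect_equal(sp$exit_time[-nrow(sp)], sp$entry_time[-1])
})

test_that("a section never entered is reported missing, not skipped", {
  course <- tiny_course(n_laps = 2)
  ref <- lay_out_reference(course)
  # recording stops 170 m into lap 2: U1 complete, F1 cut short, D1 never
  # entered in lap 2
  tr <- track_on_reference(ref, speed = 2, t_end = (370 + 170) / 2)
  mapped <- map_to_course(tr, ref)
  expect_warning(sp <- virtual_splits(mapped, course), "never entered")
  expect_true("D1" %in% attr(sp, "missing"))
  expect_equal(nrow(sp), 6L)                    # all rows retained
  expect_true(all(!is.na(sp$duration[sp$lap == 1])))
  expect_true(is.na(sp$entry_time[sp$lap == 2 & sp$section == "D1"]))
  # a track shorter than one lap violates the precondition outright
  short <- track_on_reference(ref, speed = 2, t_end = 60)
  expect_error(virtual_splits(map_to_course(short, ref), course),
               "full lap")
})

test_that("section_speed divides length by duration and rejects bad input", {
  expect_equal(section_speed(348, 139.2), 2.5)
  expect_equal(section_speed(20, 5), 4)
  expect_error(section_speed(100, 0), "duration")
  expect_error(section_speed(100, -3), "duration")
})

test_that("time in terrain matches length shares at uniform speed", {
  course <- tiny_course()
  ref <- lay_out_reference(course)
  mapped <- map_to_course(track_on_reference(ref, speed = 2), ref)
  sp <- virtual_splits(mapped, course)
  tit <- time_in_terrain(sp)
  expect_equal(sum(tit), 100, tolerance = 1e-9)
  expect_equal(unname(tit[c("uphill", "flat", "downhill")]),
               100 * course$length / lap_length(course), tolerance = 1e-4)
})

test_that("slow uphill / fast downhill inflates uphill time share", {
  cfg <- synth_config("HIT", course = demo_course(n_laps = 1),
                      gnss_sigma = 0, seed = 2)
  ses <- simulate_session(cfg)
  sp <- virtual_splits(map_to_course(ses$track, ses$reference), cfg$course)
  tit <- time_in_terrain(sp)
  fr <- terrain_fractions(cfg$course)
  expect_gt(tit[["uphill"]], fr[["uphill"]])
  expect_lt(tit[["downhill"]], fr[["downhill"]])
  # qualitative ordering of the high-intensity session: uphill > flat > down
  expect_true(tit[["uphill"]] > tit[["flat"]])
  expect_true(tit[["flat"]] > tit[["downhill"]])
})

test_that("mapping does not depend on the geographic origin", {
  course <- tiny_course()
  for (origin_lat in c(0.1, 45, 69)) {
    ref <- lay_out_reference(course, origin = c(origin_lat, 10))
    mapped <- map_to_course(track_on_reference(ref, speed = 2), ref)
    sp <- virtual_splits(mapped, course)
    expect_equal(sp$duration, course$length / 2, tolerance = 1e-4)
  }
})
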