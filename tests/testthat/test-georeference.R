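test_that("fix interpolation is exact at fixes and linear between them", {
  fixes <- geo_fixes(time = c(0, 10), lon = c(10.0, 10.0),
                     lat = c(48.0, 48.0002))
  at_fix <- interpolate_fixes(fixes, 0)
  expect_equal(at_fix$lat, 48.0)
  expect_equal(at_fix$lon, 10.0)
  mid <- interpolate_fixes(fixes, 5)
  expect_equal(mid$lat, 48.0001)
  expect_equal(mid$lon, 10.0)
  expect_error(interpolate_fixes(fixes, -1), "outside the fix span")
  expect_error(interpolate_fixes(fixes, c(0, 11)), "11")
})

test_that("interpolated positions stay inside the bracketing bounding box", {
  set.seed(3)
  n <- 20
  fixes <- geo_fixes(time = cumsum(runif(n, 0.5, 2)),
                     lon = 10 + cumsum(rnorm(n, sd = 1e-5)),
                     lat = 48 + cumsum(rnorm(n, sd = 1e-5)))
  ts <- sort(runif(30, min(fixes$time), max(fixes$time)))
  pos <- interpolate_fixes(fixes, ts)
  for (k in seq_along(ts)) {
    i <- findInterval(ts[k], fixes$time)
    i2 <- min(i + 1L, n)
    expect_gte(pos$lon[k], min(fixes$lon[i], fixes$lon[i2]) - 1e-12)
    expect_lte(pos$lon[k], max(fixes$lon[i], fixes$lon[i2]) + 1e-12)
    expect_gte(pos$lat[k], min(fixes$lat[i], fixes$lat[i2]) - 1e-12)
    expect_lte(pos$lat[k], max(fixes$lat[i], fixes$lat[i2]) + 1e-12)
  }
})

test_that("GPX tracks round-trip with coordinate fidelity", {
  traces <- list(
    geo_fixes(time = 1700000000 + 0:9, lon = 10 + (0:9) * 1e-5, lat = rep(48, 10)),
    geo_fixes(time = 1700000100 + 0:9, lon = rep(10.001, 10), lat = 48 + (0:9) * 1e-5))
  f <- withr::local_tempfile(fileext = ".gpx")
  write_gpx(traces, f)
  back <- read_gpx(f)
  expect_length(back, 2L)
  expect_equal(nrow(back[[1L]]), 10L)
  for (k in 1:2) {
    expect_lt(max(abs(back[[k]]$lon - traces[[k]]$lon)), 1e-7)
    expect_lt(max(abs(back[[k]]$lat - traces[[k]]$lat)), 1e-7)
    expect_equal(back[[k]]$time, traces[[k]]$time)
  }
})

test_that("empty and malformed GPX are handled", {
  f <- withr::local_tempfile(fileext = ".gpx")
  writeLines('<?xml version="1.0"?><gpx version="1.1" xmlns="http://www.topografix.com/GPX/1/1"></gpx>', f)
  expect_length(read_gpx(f), 0L)
  f2 <- withr::local_tempfile(fileext = ".gpx")
  writeLines('<gpx><trk><trkseg><trkpt lat="48" lon="10"></trkpt></trkseg></trk></gpx>', f2)
  expect_error(read_gpx(f2), "time")
  f3 <- withr::local_tempfile(fileext = ".gpx")
  writeLines("this is not xml <", f3)
  expect_error(read_gpx(f3))
})

test_that("the classify-and-georeference pipeline places strides on the track", {
  samples <- generate_har_dataset(4)
  fn <- stridemap:::feature_names()
  scaler <- fit_scaler(as.matrix(samples[fn]))
  scaled <- samples
  scaled[fn] <- apply_scaler(scaler, as.matrix(samples[fn]))
  model <- train_classifier(scaled, "svm_ovr", seed = 1)

  # 20 walking strides along a straight northbound track
  g <- generate_gait_recording(data.frame(activity = "walk", n_strides = 20L),
                               gait_generator_params(seed = 11), "S90", "T01")
  dur <- max(g$recording$timestamps)
  fixes <- geo_fixes(time = seq(0, dur, length.out = 30),
                     lon = rep(10, 30),
                     lat = seq(48, 48.0003, length.out = 30))
  steps <- classify_and_georeference(g$recording, fixes, model, scaler)
  expect_true(nrow(steps) %in% c(19L, 20L))
  expect_true(all(steps$activity == "walk"))
  expect_true(all(diff(steps$lat) > 0)) # monotone along the track
  # each step's position must sit inside the fix span
  expect_true(all(steps$lat >= 48 & steps$lat <= 48.0003))

  # a stair bout shows up as a contiguous run of stair classifications
  g2 <- generate_gait_recording(
    data.frame(activity = c("walk", "stairs_up", "walk"),
               n_strides = c(8L, 8L, 8L)),
    gait_generator_params(seed = 12), "S91", "T01")
  dur2 <- max(g2$recording$timestamps)
  fixes2 <- geo_fixes(time = seq(0, dur2, length.out = 40),
                      lon = seq(10, 10.0004, length.out = 40), lat = rep(48, 40))
  steps2 <- classify_and_georeference(g2$recording, fixes2, model, scaler)
  up <- which(steps2$activity == "stairs_up")
  expect_gt(length(up), 4L)
  expect_true(all(diff(up) == 1L)) # contiguous
})

test_that("steps outside the GPS span are dropped, empty input passes through", {
  samples <- generate_har_dataset(3)
  fn <- stridemap:::feature_names()
  scaler <- fit_scaler(as.matrix(samples[fn]))
  scaled <- samples
  scaled[fn] <- apply_scaler(scaler, as.matrix(samples[fn]))
  model <- train_classifier(scaled, "svm_ovr", seed = 1)
  g <- generate_gait_recording(data.frame(activity = "walk", n_strides = 10L),
                               gait_generator_params(seed = 4), "S92", "T01")
  # GPS covers only the middle third of the trial
  dur <- max(g$recording$timestamps)
  fixes <- geo_fixes(time = seq(dur / 3, 2 * dur / 3, length.out = 10),
                     lon = rep(10, 10), lat = seq(48, 48.0001, length.out = 10))
  steps <- classify_and_georeference(g$recording, fixes, model, scaler)
  w <- segment_steps(detect_step_events(g$recording), g$recording$timestamps)
  in_span <- sum(w$start_time >= dur / 3 & w$start_time <= 2 * dur / 3)
  expect_equal(nrow(steps), in_span)
  # flat recording -> no steps -> empty result
  flat <- make_recording(rep(0.5, 100))
  expect_equal(nrow(classify_and_georeference(flat, fixes, model, scaler)), 0L)
})

test_that("classified steps export as a GeoJSON point layer with style hints", {
  steps <- data.frame(time = c(1, 2), lon = c(10, 10.1), lat = c(48, 48.1),
                      activity = factor(c("walk", "stairs_up"),
                                        levels = activity_classes()))
  f <- withr::local_tempfile(fileext = ".geojson")
  write_steps_geojson(steps, f)
  gj <- jsonlite::read_json(f)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 2L)
  expect_equal(gj$features[[1L]]$properties$`marker-color`, "#ff0000")
  expect_equal(gj$features[[2L]]$properties$`marker-color`, "#00aa00")
  expect_equal(gj$features[[1L]]$geometry$coordinates[[1L]], 10)
})
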