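test_that("noise-free generation yields exactly one event per stride", {
  p0 <- gait_generator_params(noise_sd = 0, subject_sd = 0)
  g <- generate_gait_recording(data.frame(activity = "walk", n_strides = 10L), p0)
  expect_length(detect_step_events(g$recording), 10L)
  # ground-truth windows line up with the generated strides
  expect_equal(nrow(g$truth), 9L)
  expect_true(all(g$truth$pure))
  expect_equal(diff(g$truth$start_time), rep(1.1, 8), tolerance = 1e-9)
})

test_that("generation is a pure function of parameters and seed", {
  sched <- data.frame(activity = c("walk", "stairs_up"), n_strides = c(5L, 5L))
  p <- gait_generator_params(seed = 7)
  g1 <- generate_gait_recording(sched, p, "S1", "T1")
  g2 <- generate_gait_recording(sched, p, "S1", "T1")
  expect_identical(g1$recording$thigh$incl, g2$recording$thigh$incl)
  g3 <- generate_gait_recording(sched, gait_generator_params(seed = 8), "S1", "T1")
  expect_false(identical(g1$recording$thigh$incl, g3$recording$thigh$incl))
  # different subjects get different amplitude draws
  g4 <- generate_gait_recording(sched, p, "S2", "T1")
  expect_false(identical(g1$recording$thigh$incl, g4$recording$thigh$incl))
})

test_that("stair ascent has a larger thigh range than walking", {
  p <- gait_generator_params(seed = 21)
  rng <- function(cls) {
    g <- generate_gait_recording(
      data.frame(activity = cls, n_strides = 100L), p, "S1", "T1")
    w <- segment_steps(detect_step_events(g$recording), g$recording$timestamps)
    mean(extract_feature_matrix(g$recording, w)[, "thigh_range"])
  }
  expect_gt(rng("stairs_up"), rng("walk"))
})

test_that("trial CSV files round-trip a generated recording", {
  g <- generate_gait_recording(data.frame(activity = "walk", n_strides = 5L),
                               gait_generator_params(seed = 2), "S5", "T2")
  f <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(g$recording, f)
  back <- read_trial_csv(f, subject_id = "S5", trial_id = "T2")
  expect_equal(back$timestamps, g$recording$timestamps, tolerance = 1e-9)
  expect_equal(back$thigh$incl, g$recording$thigh$incl, tolerance = 1e-9)
  expect_equal(unname(back$shank$gyro), unname(g$recording$shank$gyro),
               tolerance = 1e-9)
})

test_that("truth networks match their template definitions", {
  cor <- generate_truth_network("corridor_with_stairs")
  expect_length(cor$paths, 3L)
  expect_length(cor$crossings, 2L)
  types <- sort(vapply(cor$paths, `[[`, character(1), "path_type"))
  expect_equal(types, c("stairs_up", "stairs_up", "walk"), ignore_attr = TRUE)
  stair_counts <- unlist(lapply(cor$paths, function(p) p$properties$stair_count))
  expect_equal(unname(stair_counts), c(21L, 21L))
  hall <- Filter(function(p) p$path_type == "walk", cor$paths)[[1L]]
  expect_equal(path_length(hall), 46, tolerance = 0.1)
  expect_consistent(cor)

  grid <- generate_truth_network("campus_grid", n = 2L)
  expect_length(grid$paths, 12L)
  expect_length(grid$crossings, 9L)
  expect_consistent(grid)
  expect_error(generate_truth_network("atlantis"), "arg")
})

test_that("GPS traces follow the route within their noise budget", {
  net <- generate_truth_network("campus_grid", n = 1L)
  route <- names(net$paths)[1L]
  proj <- stridemap:::store_projection(net)
  route_xy <- proj$project(store_get_path(net, route)$geometry)
  # zero noise: every fix on the polyline
  clean <- generate_gps_trace(net, route, trace_generator_params(
    noise_sd = 0, reflection_prob = 0, seed = 1))
  d0 <- stridemap:::points_to_polyline(proj$project(cbind(clean$lon, clean$lat)),
                                       route_xy)$dist
  expect_lt(max(d0), 0.1)
  expect_equal(clean$time[1L], 0)
  expect_true(all(diff(clean$time) > 0))
  # sigma = 2 m: about 95% of fixes within 4 m (2 sigma of the radial error
  # is looser than 2 sigma per axis; allow a binomial margin)
  noisy <- do.call(rbind, lapply(1:4, function(k) {
    generate_gps_trace(net, route, trace_generator_params(
      noise_sd = 2, reflection_prob = 0, seed = k))
  }))
  dn <- stridemap:::points_to_polyline(proj$project(cbind(noisy$lon, noisy$lat)),
                                       route_xy)$dist
  expect_gt(mean(dn <= 4), 0.85)
  # forced reflection: a run of fixes lands far off the route
  refl <- generate_gps_trace(net, route, trace_generator_params(
    noise_sd = 0, reflection_prob = 1, reflection_offset = 25, seed = 5))
  dr <- stridemap:::points_to_polyline(proj$project(cbind(refl$lon, refl$lat)),
                                       route_xy)$dist
  runs <- rle(dr >= 20)
  expect_true(any(runs$values & runs$lengths >= 2))
})

test_that("routes must be connected walks through the network", {
  net <- generate_truth_network("campus_grid", n = 2L)
  # find two edges that do not share an endpoint
  ids <- names(net$paths)
  ends <- lapply(ids, function(id) {
    g <- store_get_path(net, id)$geometry
    rbind(g[1L, ], g[nrow(g), ])
  })
  disjoint <- NULL
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      dmin <- min(geosphere::distGeo(
        ends[[i]][rep(1:2, each = 2), ], ends[[j]][rep(1:2, 2), ]))
      if (dmin > 5) { disjoint <- c(ids[i], ids[j]); break }
    }
    if (!is.null(disjoint)) break
  }
  expect_error(generate_gps_trace(net, disjoint, trace_generator_params(seed = 1)),
               "not connected")
  # connected two-edge route works and is longer than either edge
  cr <- net$crossings[[which(vapply(net$crossings, function(x)
    nrow(x$connections), integer(1)) >= 2)[1L]]]
  pair <- cr$connections$path_id[1:2]
  tr <- generate_gps_trace(net, pair, trace_generator_params(
    noise_sd = 0, reflection_prob = 0, seed = 1))
  expect_gt(nrow(tr), 50) # two 50 m edges at 1.3 m/s, 1 s fixes
})
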