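test_that("simplification cuts a figure-eight at its waist into two loops", {
  # two diamond loops sharing the origin; the polyline revisits (0,0)
  # halfway through, which is the self-intersection
  loop1 <- rbind(c(0, 0), c(5, 5), c(10, 0), c(5, -5), c(0, 0))
  loop2 <- rbind(c(-5, 5), c(-10, 0), c(-5, -5), c(0, 0))
  fig8 <- mpath(rbind(loop1, loop2))
  pieces <- simplify_path(fig8, builder_config())
  expect_length(pieces, 2L)
  for (p in pieces) {
    expect_length(stridemap:::self_intersection_arcs(
      fix_proj$project(p$geometry)), 0L)
  }
  # proper edge crossing: X-shaped polyline splits at the crossing point
  xshape <- mpath(rbind(c(0, 0), c(10, 10), c(0, 10), c(10, 0)))
  pieces_x <- simplify_path(xshape, builder_config())
  expect_gt(length(pieces_x), 1L)
  total <- sum(vapply(pieces_x, path_length, numeric(1)))
  expect_equal(total, path_length(xshape), tolerance = 1e-6)
})

test_that("simplification thins dense vertices within the tolerance", {
  dense <- mpath(line_xy(0, 0, 100, 0, n = 1001)) # a vertex every 0.1 m
  out <- simplify_path(dense, builder_config())
  expect_length(out, 1L)
  g <- fix_proj$project(out[[1L]]$geometry)
  expect_lt(nrow(g), 50L)
  expect_equal(unname(g[1, ]), c(0, 0), tolerance = 1e-6)
  expect_equal(unname(g[nrow(g), ]), c(100, 0), tolerance = 1e-6)
  # deviation oracle: every input vertex within tolerance of the output
  dev <- stridemap:::points_to_polyline(
    fix_proj$project(dense$geometry), g)$dist
  expect_lte(max(dev), builder_config()$simplify_tolerance + 1e-9)
  # already-simple path passes through unchanged
  simple <- mpath(rbind(c(0, 0), c(50, 10), c(100, 0)))
  out2 <- simplify_path(simple, builder_config())
  expect_length(out2, 1L)
  expect_equal(out2[[1L]]$geometry, simple$geometry)
})

test_that("path matching finds the coincident stretch and nothing else", {
  cfg <- builder_config()
  a <- mpath(line_xy(0, 0, 90, 0))
  # identical geometry: full-length match
  mr <- match_paths(mpath(line_xy(0, 0, 90, 0)), a, cfg)
  expect_equal(nrow(mr$matched), 1L)
  expect_equal(nrow(mr$unmatched), 0L)
  expect_equal(mr$matched$new_end - mr$matched$new_start, path_length(a),
               tolerance = 0.01)
  # parallel but 50 m apart: no match
  mr2 <- match_paths(mpath(line_xy(0, 50, 90, 50)), a, cfg)
  expect_equal(nrow(mr2$matched), 0L)
  expect_equal(sum(mr2$unmatched$end - mr2$unmatched$start), path_length(a),
               tolerance = 0.5)
  # coincident only on the middle 30 m (1 m offset there), perpendicular
  # approach arms; tolerance = 2 * resample_spacing for run boundaries plus
  # heading_window / 2 attenuation per side where the corner smears headings
  b <- mpath(rbind(c(30, 28), c(30, 1), c(60, 1), c(60, 28)))
  mr3 <- match_paths(b, a, cfg)
  expect_equal(nrow(mr3$matched), 1L)
  tol <- 2 * cfg$resample_spacing + cfg$heading_window
  expect_lt(abs((mr3$matched$new_end - mr3$matched$new_start) - 30), tol)
  expect_lt(abs(abs(mr3$matched$cand_end - mr3$matched$cand_start) - 30), tol)
  # matched and unmatched intervals partition the new path
  covered <- sum(mr3$matched$new_end - mr3$matched$new_start) +
    sum(mr3$unmatched$end - mr3$unmatched$start)
  L <- stridemap:::planar_length(fix_proj$project(b$geometry))
  expect_equal(covered, L, tolerance = 1e-6)
})

test_that("matching respects bidirectionality and perpendicularity", {
  cfg <- builder_config()
  a <- mpath(line_xy(0, 0, 90, 0))
  # anti-parallel retracing still matches (mod 180 degrees)
  rev_b <- mpath(line_xy(90, 0.5, 0, 0.5))
  mr <- match_paths(rev_b, a, cfg)
  expect_equal(nrow(mr$matched), 1L)
  expect_gt(mr$matched$cand_start, mr$matched$cand_end) # candidate arc reversed
  # perpendicular crossing does not match even where distances are small
  cross <- mpath(line_xy(45, -40, 45, 40))
  mr2 <- match_paths(cross, a, cfg)
  expect_equal(nrow(mr2$matched), 0L)
})

test_that("splitting conserves length and redistributes stair counts", {
  stairs <- mpath(line_xy(0, 0, 100, 0), "stairs_up",
                  properties = list(stair_count = 20L))
  L <- path_length(stairs)
  parts <- split_path(stairs, L / 2)
  expect_equal(parts[[1L]]$properties$stair_count, 10L)
  expect_equal(parts[[2L]]$properties$stair_count, 10L)
  expect_equal(path_length(parts[[1L]]) + path_length(parts[[2L]]), L,
               tolerance = 0.01)
  # asymmetric split of a 100 m path at 25 m
  trail <- mpath(line_xy(0, 0, 100, 0))
  Lt <- path_length(trail)
  p25 <- split_path(trail, 25)
  expect_equal(path_length(p25[[1L]]), 25, tolerance = 0.01)
  expect_equal(path_length(p25[[2L]]), Lt - 25, tolerance = 0.01)
  # stair integers always sum exactly, whatever the cut
  for (at in c(17.3, 50.01, 88.8)) {
    ps <- split_path(stairs, at)
    expect_equal(ps[[1L]]$properties$stair_count + ps[[2L]]$properties$stair_count, 20L)
    expect_equal(path_length(ps[[1L]]) + path_length(ps[[2L]]), L, tolerance = 0.01)
  }
  expect_error(split_path(trail, 0), "strictly inside")
  expect_error(split_path(trail, Lt + 5), "strictly inside")
  # merge_count is copied, not divided
  both <- split_path(mpath(line_xy(0, 0, 40, 0), merge_count = 4L), 20)
  expect_equal(both[[1L]]$merge_count, 4L)
  expect_equal(both[[2L]]$merge_count, 4L)
})

test_that("merging averages geometry and properties by merge count", {
  cfg <- builder_config()
  # identical copy: geometry unchanged, counts add
  a <- mpath(line_xy(0, 0, 90, 0))
  m0 <- merge_paths(a, mpath(line_xy(0, 0, 90, 0)), cfg)
  expect_equal(m0$merge_count, 2L)
  d <- stridemap:::points_to_polyline(fix_proj$project(m0$geometry),
                                      fix_proj$project(a$geometry))$dist
  expect_lt(max(d), 0.01)
  # lateral offset 4 m, weights 3:1 -> merged line at offset 1 m
  heavy <- mpath(line_xy(0, 0, 90, 0), merge_count = 3L)
  light <- mpath(line_xy(0, 4, 90, 4), merge_count = 1L)
  m1 <- merge_paths(heavy, light, cfg)
  y <- fix_proj$project(m1$geometry)[, 2L]
  expect_equal(range(y), c(1, 1), tolerance = 1e-3)
  expect_equal(m1$merge_count, 4L)
  # stair counts: weighted mean, equal weights -> plain mean
  s1 <- mpath(line_xy(0, 0, 30, 0), "stairs_up", properties = list(stair_count = 10L))
  s2 <- mpath(line_xy(0, 1, 30, 1), "stairs_up", properties = list(stair_count = 12L))
  expect_equal(merge_paths(s1, s2, cfg)$properties$stair_count, 11L)
  # anti-parallel partner is re-oriented before averaging
  m2 <- merge_paths(a, mpath(line_xy(90, 2, 0, 2)), cfg)
  y2 <- fix_proj$project(m2$geometry)[, 2L]
  expect_equal(range(y2), c(1, 1), tolerance = 1e-3)
  # different types refuse to merge under type-aware matching
  walk <- mpath(line_xy(0, 0, 30, 0), "walk")
  expect_error(merge_paths(walk, s1, cfg), class = "stridemap_merge_refused")
  # untyped mode merges them
  m3 <- merge_paths(walk, mpath(line_xy(0, 1, 30, 1)),
                    builder_config(type_aware = FALSE))
  expect_equal(m3$merge_count, 2L)
})

test_that("merge order barely matters for full-length matches", {
  cfg <- builder_config()
  a <- mpath(line_xy(0, 0, 60, 0))
  b <- mpath(line_xy(0, 2, 60, 2))
  c_ <- mpath(line_xy(0, 4, 60, 4))
  ab_c <- merge_paths(merge_paths(a, b, cfg), c_, cfg)
  ac_b <- merge_paths(merge_paths(a, c_, cfg), b, cfg)
  d <- stridemap:::points_to_polyline(fix_proj$project(ab_c$geometry),
                                      fix_proj$project(ac_b$geometry))$dist
  expect_lt(max(d), cfg$resample_spacing)
  expect_equal(ab_c$merge_count, ac_b$merge_count)
})

test_that("connectors snap to nearby crossings instead of multiplying", {
  store <- map_store()
  id1 <- store_insert_path(store, mpath(line_xy(0, 0, 30, 0)))
  id2 <- store_insert_path(store, mpath(line_xy(30, 0, 60, 0)))
  id3 <- store_insert_path(store, mpath(line_xy(30.5, 0.3, 30, 40)))
  c1 <- insert_connector(store, fix_proj$unproject(cbind(30, 0))[1, ],
                         data.frame(path_id = c(id1, id2), end = c("end", "start")))
  # second boundary point 0.5 m away: same crossing is reused
  c2 <- insert_connector(store, fix_proj$unproject(cbind(30.5, 0.3))[1, ],
                         data.frame(path_id = id3, end = "start"))
  expect_equal(c1, c2)
  expect_equal(nrow(store_get_crossing(store, c1)$connections), 3L)
  expect_consistent(store)
  expect_error(insert_connector(store, c(10, 48),
                                data.frame(path_id = "nope", end = "start")),
               "dangling")
})

test_that("inserting into an empty store adds one path and no crossings", {
  store <- map_store()
  rep_ <- insert_path(store, mpath(line_xy(0, 0, 100, 0)), builder_config())
  expect_length(store$paths, 1L)
  expect_length(store$crossings, 0L)
  expect_equal(store$paths[[1L]]$merge_count, 1L)
  expect_length(rep_$created, 1L)
  expect_consistent(store)
})

test_that("re-inserting the same trace merges instead of duplicating", {
  store <- map_store()
  cfg <- builder_config()
  insert_path(store, mpath(line_xy(0, 0, 100, 0)), cfg)
  rep2 <- insert_path(store, mpath(line_xy(0, 0, 100, 0)), cfg)
  expect_length(store$paths, 1L)
  expect_equal(store$paths[[1L]]$merge_count, 2L)
  expect_length(store$crossings, 0L) # no interior crossings
  expect_length(rep2$merged, 1L)
  expect_consistent(store)
})

test_that("a branching trace splits the stored path at a three-way crossing", {
  store <- map_store()
  cfg <- builder_config()
  insert_path(store, mpath(line_xy(0, 0, 100, 0)), cfg)
  branch <- mpath(rbind(line_xy(0, 0, 50, 0), line_xy(51, 1, 80, 30)[-1, ]))
  insert_path(store, branch, cfg)
  expect_length(store$paths, 3L)
  expect_length(store$crossings, 1L)
  expect_equal(nrow(store$crossings[[1L]]$connections), 3L)
  # the shared first half aggregated two traversals, the tails one each
  counts <- vapply(store$paths, `[[`, integer(1), "merge_count")
  expect_equal(sort(unname(counts)), c(1L, 1L, 2L))
  expect_consistent(store)
})

test_that("paths of different types are never merged when typing is on", {
  store <- map_store()
  cfg <- builder_config()
  insert_path(store, mpath(line_xy(0, 0, 50, 0), "walk"), cfg)
  insert_path(store, mpath(line_xy(0, 0.5, 50, 0.5), "stairs_up",
                           properties = list(stair_count = 10L)), cfg)
  expect_length(store$paths, 2L)
  expect_true(all(vapply(store$paths, `[[`, integer(1), "merge_count") == 1L))
  # untyped mode merges the same pair
  store2 <- map_store()
  untyped <- builder_config(type_aware = FALSE)
  insert_path(store2, mpath(line_xy(0, 0, 50, 0), "walk"), untyped)
  insert_path(store2, mpath(line_xy(0, 0.5, 50, 0.5)), untyped)
  expect_length(store2$paths, 1L)
  expect_equal(store2$paths[[1L]]$merge_count, 2L)
})

test_that("failed insertions leave the store untouched", {
  store <- map_store()
  insert_path(store, mpath(line_xy(0, 0, 100, 0)), builder_config())
  snapshot <- store_clone(store)
  bad <- mpath(line_xy(0, 0, 50, 0))
  bad$geometry <- NULL # corrupt the record to force a failure downstream
  expect_error(insert_path(store, bad, builder_config()))
  expect_equal(store$paths, snapshot$paths)
  expect_equal(store$crossings, snapshot$crossings)
})

test_that("pruning removes unconfirmed paths and their orphan crossings", {
  store <- map_store()
  cfg <- builder_config()
  insert_path(store, mpath(line_xy(0, 0, 100, 0)), cfg)
  branch <- mpath(rbind(line_xy(0, 0, 50, 0), line_xy(51, 1, 80, 30)[-1, ]))
  insert_path(store, branch, cfg)
  # min_merges 1 removes nothing
  expect_length(prune_unmerged(store_clone(store), 1L), 0L)
  # min_merges 2 keeps only the twice-walked stretch
  pruned <- store_clone(store)
  removed <- prune_unmerged(pruned, 2L)
  expect_equal(length(pruned$paths), 1L)
  expect_equal(pruned$paths[[1L]]$merge_count, 2L)
  expect_length(removed, 2L)
  expect_consistent(pruned)
  # a store of single-visit paths empties entirely
  lone <- map_store()
  insert_path(lone, mpath(line_xy(0, 50, 60, 50)), cfg)
  prune_unmerged(lone, 2L)
  expect_length(lone$paths, 0L)
  expect_length(lone$crossings, 0L)
})

test_that("map scoring measures buffer overlap and junction recovery", {
  truth <- map_store()
  store_insert_path(truth, mpath(line_xy(0, 0, 50, 0)))
  # identical map scores perfectly
  same <- map_store()
  store_insert_path(same, mpath(line_xy(0, 0, 50, 0)))
  res <- evaluate_map(same, truth, buffer = 5)
  expect_equal(res$geometric, 1.0)
  expect_equal(res$topological, 1.0) # no truth crossings: vacuous
  # everything far away scores zero
  off <- map_store()
  store_insert_path(off, mpath(line_xy(0, 100, 50, 100)))
  expect_equal(evaluate_map(off, truth, buffer = 5)$geometric, 0.0)
  # two equal-length constructed segments, one on and one off the truth
  half <- map_store()
  store_insert_path(half, mpath(line_xy(0, 0, 50, 0)))
  store_insert_path(half, mpath(line_xy(0, 100, 50, 100)))
  expect_equal(evaluate_map(half, truth, buffer = 5)$geometric, 0.5,
               tolerance = 0.02)
  expect_error(evaluate_map(half, map_store(), buffer = 5), "empty")
})
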