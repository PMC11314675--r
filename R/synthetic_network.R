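#' Parameters of the synthetic GPS trace generator
#'
#' Emulates the smartphone traces the map layer ingests: fixes sampled at
#' walking speed along a route through a known network, with isotropic
#' Gaussian position noise and, occasionally, a contiguous run of fixes
#' displaced sideways by a constant offset — the signature of a multipath
#' reflection off a building facade.
#'
#' @param fix_interval Seconds between fixes.
#' @param noise_sd Isotropic position noise, metres.
#' @param reflection_prob Probability that a trace contains one reflected
#'   run.
#' @param reflection_offset Displacement of the reflected run, metres.
#' @param speed Walking speed, m/s.
#' @param seed Integer seed.
#' @return An object of class `trace_generator_params`.
#' @export
trace_generator_params <- function(fix_interval = 1, noise_sd = 2,
                                   reflection_prob = 0.05,
                                   reflection_offset = 25,
                                   speed = 1.3, seed = 1L) {
  stopifnot(fix_interval > 0, noise_sd >= 0, reflection_prob >= 0,
            reflection_prob <= 1, reflection_offset >= 0, speed > 0)
  structure(list(fix_interval = fix_interval, noise_sd = noise_sd,
                 reflection_prob = reflection_prob,
                 reflection_offset = reflection_offset,
                 speed = speed, seed = as.integer(seed)),
            class = "trace_generator_params")
}

# Reference origin of the synthetic world (mid-latitude Central Europe).
truth_origin <- function() c(lon = 10.0, lat = 48.0)

# Build a path_record from local metric coordinates relative to the origin.
metric_path <- function(xy_m, path_type, properties = list()) {
  proj <- local_projection(truth_origin())
  path_record(proj$unproject(rbind(xy_m)), path_type = path_type,
              properties = properties)
}

#' Generate a known ground-truth path network
#'
#' Two templates are available. `corridor_with_stairs` mirrors an indoor
#' acquisition track: a 46 m hallway flanked by two staircases of 21 steps
#' each, i.e. 3 typed paths joined by 2 crossings. `campus_grid` is an
#' `n` by `n` block grid of plain trails (`(n+1)^2` crossings,
#' `2 n (n+1)` edge paths, 50 m blocks), emulating an outdoor campus walk.
#'
#' @param template `"corridor_with_stairs"` or `"campus_grid"`.
#' @param n Grid size for `campus_grid` (default 2).
#' @return A consistent [map_store()].
#' @export
generate_truth_network <- function(template = c("corridor_with_stairs",
                                                "campus_grid"), n = 2L) {
  template <- match.arg(template)
  store <- map_store()
  add_crossing_between <- function(loc, refs) {
    cid <- store_insert_crossing(store, crossing(loc, refs))
    for (k in seq_len(nrow(refs))) {
      p <- store$paths[[refs$path_id[k]]]
      p[[paste0(refs$end[k], "_crossing")]] <- cid
      store$paths[[refs$path_id[k]]] <- p
    }
    cid
  }
  if (template == "corridor_with_stairs") {
    s1 <- store_insert_path(store, metric_path(
      cbind(c(0, 10), c(0, 0)), "stairs_up", list(stair_count = 21L)))
    hall <- store_insert_path(store, metric_path(
      cbind(c(10, 56), c(0, 0)), "walk"))
    s2 <- store_insert_path(store, metric_path(
      cbind(c(56, 66), c(0, 0)), "stairs_up", list(stair_count = 21L)))
    proj <- local_projection(truth_origin())
    add_crossing_between(proj$unproject(cbind(10, 0))[1L, ],
                         data.frame(path_id = c(s1, hall), end = c("end", "start")))
    add_crossing_between(proj$unproject(cbind(56, 0))[1L, ],
                         data.frame(path_id = c(hall, s2), end = c("end", "start")))
  } else {
    spacing <- 50
    proj <- local_projection(truth_origin())
    node_xy <- function(i, j) c(i * spacing, j * spacing)
    ids <- list() # edge ids with their node endpoints
    for (j in 0:n) for (i in 0:n) {
      if (i < n) {
        id <- store_insert_path(store, metric_path(
          rbind(node_xy(i, j), node_xy(i + 1L, j)), "trail"))
        ids[[length(ids) + 1L]] <- list(id = id, from = c(i, j), to = c(i + 1L, j))
      }
      if (j < n) {
        id <- store_insert_path(store, metric_path(
          rbind(node_xy(i, j), node_xy(i, j + 1L)), "trail"))
        ids[[length(ids) + 1L]] <- list(id = id, from = c(i, j), to = c(i, j + 1L))
      }
    }
    for (j in 0:n) for (i in 0:n) {
      refs <- data.frame(path_id = character(0), end = character(0))
      for (e in ids) {
        if (all(e$from == c(i, j))) refs <- rbind(refs, data.frame(path_id = e$id, end = "start"))
        if (all(e$to == c(i, j))) refs <- rbind(refs, data.frame(path_id = e$id, end = "end"))
      }
      add_crossing_between(proj$unproject(rbind(node_xy(i, j)))[1L, ], refs)
    }
  }
  stopifnot(length(audit_consistency(store)) == 0L)
  store
}

#' Generate a noisy GPS trace along a route through a network
#'
#' The route (a connected sequence of path ids) is concatenated into one
#' polyline, sampled at `speed * fix_interval` metre steps, and perturbed
#' with isotropic Gaussian noise. With probability `reflection_prob` one
#' contiguous run of fixes (about 15% of the trace) is additionally
#' displaced sideways by `reflection_offset` metres.
#'
#' @param network A [map_store()], e.g. from [generate_truth_network()].
#' @param route Character vector of path ids forming a connected walk
#'   (consecutive paths must share an endpoint).
#' @param params A [trace_generator_params()].
#' @param start_time Epoch seconds of the first fix.
#' @return A [geo_fixes()] table.
#' @export
generate_gps_trace <- function(network, route,
                               params = trace_generator_params(),
                               start_time = 0) {
  stopifnot(length(route) >= 1L)
  proj <- store_projection(network)
  geoms <- lapply(route, function(id) proj$project(store_get_path(network, id)$geometry))
  line <- geoms[[1L]]
  if (length(geoms) > 1L) {
    for (k in 2:length(geoms)) {
      g <- geoms[[k]]
      tail_pt <- line[nrow(line), ]
      d_start <- sqrt(sum((g[1L, ] - tail_pt)^2))
      d_end <- sqrt(sum((g[nrow(g), ] - tail_pt)^2))
      if (min(d_start, d_end) > 1) {
        # maybe the previous path needed flipping (first pair only)
        if (k == 2L) {
          line <- line[rev(seq_len(nrow(line))), , drop = FALSE]
          tail_pt <- line[nrow(line), ]
          d_start <- sqrt(sum((g[1L, ] - tail_pt)^2))
          d_end <- sqrt(sum((g[nrow(g), ] - tail_pt)^2))
        }
        if (min(d_start, d_end) > 1) {
          stop("generate_gps_trace: route is not connected at path ", route[k])
        }
      }
      if (d_end < d_start) g <- g[rev(seq_len(nrow(g))), , drop = FALSE]
      line <- rbind(line, g[-1L, , drop = FALSE])
    }
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed %% 2000000000L)
  spacing <- params$speed * params$fix_interval
  rs <- resample_polyline(line, spacing)
  n <- nrow(rs$xy)
  pts <- rs$xy + matrix(stats::rnorm(2L * n, sd = params$noise_sd), ncol = 2L)
  if (stats::runif(1) < params$reflection_prob && n >= 4L) {
    run_len <- max(2L, round(0.15 * n))
    start <- sample.int(n - run_len + 1L, 1L)
    idx <- start:(start + run_len - 1L)
    # a multipath reflection displaces the run sideways off the route
    # (a shift along the walking direction would hide inside the path)
    h <- headings_at_arcs(line, rs$arc[start + run_len %/% 2L], 10)
    side <- sample(c(-1, 1), 1L)
    shift <- side * params$reflection_offset * c(-sin(h), cos(h))
    pts[idx, ] <- pts[idx, ] + rep(shift, each = length(idx))
  }
  lonlat <- proj$unproject(pts)
  geo_fixes(start_time + rs$arc / params$speed, lonlat[, 1L], lonlat[, 2L])
}
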