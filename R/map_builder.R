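#' Map builder configuration
#'
#' Tolerances of the iterative insertion algorithm. All distances are in
#' metres, angles in degrees.
#'
#' @param match_distance Max lateral distance for a point of a new trace to
#'   match a stored path.
#' @param match_angle Max local heading difference (modulo 180 degrees;
#'   paths are bidirectional) for a match.
#' @param resample_spacing Arc-length spacing used when scanning for matches
#'   and when pairing vertices for weighted merging.
#' @param crossing_snap Radius within which boundary points reuse an
#'   existing crossing instead of spawning a new one, and within which free
#'   path endpoints are joined into a crossing.
#' @param simplify_tolerance Max deviation allowed when thinning vertices.
#' @param min_match_length Matched runs shorter than this are demoted to
#'   unmatched; unmatched gaps shorter than this between two matched runs
#'   against the same candidate are bridged.
#' @param heading_window Half-window of arc length over which local headings
#'   are estimated (GPS jitter makes per-segment headings meaningless).
#' @param type_aware When TRUE, paths of different types never match; when
#'   FALSE every path is treated as a plain trail (untyped mode).
#' @return An object of class `builder_config`.
#' @export
builder_config <- function(match_distance = 5, match_angle = 45,
                           resample_spacing = 1, crossing_snap = 2,
                           simplify_tolerance = 0.5, min_match_length = 3,
                           heading_window = 5, type_aware = TRUE) {
  vals <- c(match_distance, match_angle, resample_spacing, crossing_snap,
            simplify_tolerance, min_match_length, heading_window)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("builder_config: all tolerances must be strictly positive")
  }
  structure(list(match_distance = match_distance, match_angle = match_angle,
                 resample_spacing = resample_spacing,
                 crossing_snap = crossing_snap,
                 simplify_tolerance = simplify_tolerance,
                 min_match_length = min_match_length,
                 heading_window = heading_window,
                 type_aware = isTRUE(type_aware)),
            class = "builder_config")
}

# Split planar props proportionally to the length fraction. stair_count is
# rounded to integers that sum to the original; other numeric scalars are
# split proportionally as-is.
split_properties <- function(properties, frac) {
  a <- properties; b <- properties
  for (k in names(properties)) {
    v <- properties[[k]]
    if (is.numeric(v) && length(v) == 1L) {
      if (k == "stair_count") {
        a[[k]] <- as.integer(round(v * frac))
        b[[k]] <- as.integer(v) - a[[k]]
      } else {
        a[[k]] <- v * frac
        b[[k]] <- v * (1 - frac)
      }
    }
  }
  list(a, b)
}

#' Split a path at an arc-length position
#'
#' Pure geometric split: the cut point is interpolated between the
#' bracketing vertices, numeric properties are redistributed proportionally
#' to arc length (`stair_count` as integers summing to the original), and
#' the merge count is copied to both parts. Crossing links stay with the
#' endpoint they belong to; the caller wires up a crossing at the cut.
#'
#' @param path A [path_record()].
#' @param arc_position Metres from the path's first vertex, strictly inside
#'   `(0, length)`.
#' @return List of two `path_record`s (no ids).
#' @export
split_path <- function(path, arc_position) {
  g <- path$geometry
  n <- nrow(g)
  seglen <- geosphere::distGeo(g[-n, , drop = FALSE], g[-1L, , drop = FALSE])
  cs <- c(0, cumsum(seglen))
  L <- cs[n]
  if (!is.finite(arc_position) || arc_position <= 0 || arc_position >= L) {
    stop("split_path: arc_position must lie strictly inside (0, ",
         format(L), ")")
  }
  i <- min(max(findInterval(arc_position, cs, rightmost.closed = TRUE), 1L), n - 1L)
  f <- if (seglen[i] > 0) (arc_position - cs[i]) / seglen[i] else 0
  p <- g[i, ] + f * (g[i + 1L, ] - g[i, ])
  a <- g[seq_len(i), , drop = FALSE]
  b <- g[seq.int(i + 1L, n), , drop = FALSE]
  if (max(abs(a[nrow(a), ] - p)) > 1e-12) a <- rbind(a, p)
  if (max(abs(b[1L, ] - p)) > 1e-12) b <- rbind(p, b)
  props <- split_properties(path$properties, arc_position / L)
  list(
    path_record(a, path_type = path$path_type,
                properties = props[[1L]], merge_count = path$merge_count,
                start_crossing = path$start_crossing),
    path_record(b, path_type = path$path_type,
                properties = props[[2L]], merge_count = path$merge_count,
                end_crossing = path$end_crossing))
}

#' Simplify a path into non-self-intersecting pieces
#'
#' Thins excess vertices (no removed vertex deviates more than
#' `simplify_tolerance` from the result) and cuts the polyline at every
#' self-intersection, so each returned piece is loop-free. Endpoints are
#' preserved and the pieces concatenate to cover the input. Numeric
#' properties are redistributed over the pieces proportionally to length.
#'
#' @param path A [path_record()].
#' @param config A [builder_config()].
#' @return List of `path_record`s (>= 1).
#' @export
simplify_path <- function(path, config = builder_config()) {
  proj <- local_projection(path_centroid(path))
  # loops are removed before downsampling: vertex thinning can straighten
  # out the very vertex at which the polyline revisits itself
  pieces <- list(proj$project(path$geometry))
  # cut at self-intersections until every piece is simple
  for (pass in 1:10) {
    out <- list(); clean <- TRUE
    for (g in pieces) {
      arcs <- self_intersection_arcs(g)
      if (length(arcs) == 0L) { out <- c(out, list(g)); next }
      clean <- FALSE
      rest <- g; consumed <- 0
      for (s in arcs) {
        rel <- s - consumed
        if (rel <= 1e-6 || rel >= planar_length(rest) - 1e-6) next
        halves <- cut_polyline(rest, rel)
        out <- c(out, list(halves[[1L]]))
        rest <- halves[[2L]]
        consumed <- s
      }
      out <- c(out, list(rest))
    }
    pieces <- out
    if (clean) break
  }
  pieces <- lapply(pieces, douglas_peucker, tol = config$simplify_tolerance)
  pieces <- Filter(function(g) nrow(g) >= 2L && planar_length(g) > 1e-9, pieces)
  total <- sum(vapply(pieces, planar_length, numeric(1)))
  result <- list(); remaining <- path$properties
  for (i in seq_along(pieces)) {
    frac <- planar_length(pieces[[i]]) / total
    if (i < length(pieces)) {
      sp <- split_properties(remaining, frac / sum(vapply(
        pieces[i:length(pieces)], planar_length, numeric(1))) * total)
      props <- sp[[1L]]; remaining <- sp[[2L]]
    } else {
      props <- remaining
    }
    result[[i]] <- path_record(
      proj$unproject(pieces[[i]]), path_type = path$path_type,
      properties = props, merge_count = path$merge_count,
      start_crossing = if (i == 1L) path$start_crossing,
      end_crossing = if (i == length(pieces)) path$end_crossing)
  }
  result
}

# Per-sample match scan of a resampled new geometry against one candidate.
# `new_head` holds the new path's precomputed local headings per sample.
# Returns list(dist, cand_arc, ok) over the sample points.
scan_candidate <- function(new_xy, new_arc, new_head, cand_xy, config) {
  hit <- points_to_polyline(cbind(new_xy), cand_xy)
  ok <- hit$dist <= config$match_distance
  idx <- which(ok)
  if (length(idx)) {
    h_cand <- headings_at_arcs(cand_xy, hit$arc[idx], config$heading_window)
    d <- abs(new_head[idx] - h_cand) %% pi
    d <- pmin(d, pi - d) * 180 / pi
    ok[idx] <- d <= config$match_angle
  }
  list(dist = hit$dist, cand_arc = hit$arc, ok = ok)
}

# Demote short matched runs, then bridge short unmatched gaps flanked by
# the same candidate. `assign` is a character vector (NA = unmatched).
clean_runs <- function(assign, arc, min_len) {
  runs <- rle(ifelse(is.na(assign), "<na>", assign))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  extent <- arc[ends] - arc[starts]
  for (r in seq_along(runs$values)) {
    if (runs$values[r] != "<na>" && extent[r] < min_len) {
      assign[starts[r]:ends[r]] <- NA
    }
  }
  runs <- rle(ifelse(is.na(assign), "<na>", assign))
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  extent <- arc[ends] - arc[starts]
  for (r in seq_along(runs$values)) {
    if (runs$values[r] == "<na>" && extent[r] < min_len &&
        r > 1L && r < length(runs$values) &&
        runs$values[r - 1L] == runs$values[r + 1L]) {
      assign[starts[r]:ends[r]] <- runs$values[r - 1L]
    }
  }
  assign
}

#' Match a new path against a candidate path
#'
#' A point of the new path matches the candidate when it lies within
#' `match_distance` of it *and* the local headings differ by at most
#' `match_angle` (modulo 180 degrees — paths are bidirectional, so an
#' anti-parallel retracing matches, while a perpendicular crossing does
#' not). Matching is evaluated at `resample_spacing` steps; maximal runs
#' shorter than `min_match_length` are demoted to unmatched and short
#' unmatched gaps between matched runs are bridged. The interval endpoints
#' are where matching starts and stops.
#'
#' @param new_path,candidate [path_record()]s (or lon/lat matrices).
#' @param config A [builder_config()].
#' @return List with data.frames `matched` (`new_start`, `new_end`,
#'   `cand_start`, `cand_end`; candidate arcs may decrease when the match is
#'   anti-parallel) and `unmatched` (`start`, `end` on the new path), whose
#'   intervals partition the new path's arc length.
#' @export
match_paths <- function(new_path, candidate, config = builder_config()) {
  new_g <- if (inherits(new_path, "path_record")) new_path$geometry else rbind(new_path)
  cand_g <- if (inherits(candidate, "path_record")) candidate$geometry else rbind(candidate)
  if (config$type_aware &&
      inherits(new_path, "path_record") && inherits(candidate, "path_record") &&
      new_path$path_type != candidate$path_type) {
    L <- path_length(new_path)
    return(list(matched = data.frame(new_start = numeric(0), new_end = numeric(0),
                                     cand_start = numeric(0), cand_end = numeric(0)),
                unmatched = data.frame(start = 0, end = L)))
  }
  proj <- local_projection(path_centroid(new_g))
  new_xy <- proj$project(new_g)
  cand_xy <- proj$project(cand_g)
  rs <- resample_polyline(new_xy, config$resample_spacing)
  new_head <- headings_at_arcs(new_xy, rs$arc, config$heading_window)
  scan <- scan_candidate(rs$xy, rs$arc, new_head, cand_xy, config)
  assign <- ifelse(scan$ok, "cand", NA_character_)
  assign <- clean_runs(assign, rs$arc, config$min_match_length)
  runs <- rle(ifelse(is.na(assign), "<na>", assign))
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  n <- length(rs$arc)
  boundary <- function(i_last, i_next) (rs$arc[i_last] + rs$arc[i_next]) / 2
  matched <- data.frame(new_start = numeric(0), new_end = numeric(0),
                        cand_start = numeric(0), cand_end = numeric(0))
  unmatched <- data.frame(start = numeric(0), end = numeric(0))
  for (r in seq_along(runs$values)) {
    lo <- if (starts[r] == 1L) 0 else boundary(starts[r] - 1L, starts[r])
    hi <- if (ends[r] == n) rs$arc[n] else boundary(ends[r], ends[r] + 1L)
    if (runs$values[r] == "<na>") {
      unmatched <- rbind(unmatched, data.frame(start = lo, end = hi))
    } else {
      matched <- rbind(matched, data.frame(
        new_start = lo, new_end = hi,
        cand_start = scan$cand_arc[starts[r]],
        cand_end = scan$cand_arc[ends[r]]))
    }
  }
  list(matched = matched, unmatched = unmatched)
}

#' Merge two matching paths by merge-count-weighted averaging
#'
#' Both geometries (or the matched stretches of them) are resampled at
#' `resample_spacing`, paired by arc-length fraction (the second path is
#' re-oriented if the match is anti-parallel), and averaged vertex-wise
#' with weights equal to the merge counts:
#' `v = (m_a * v_a + m_b * v_b) / (m_a + m_b)`. Numeric properties are
#' averaged with the same weights (`stair_count` rounded); the merged
#' merge count is the sum. Paths of different types refuse to merge when
#' the configuration is type-aware.
#'
#' @param path_a,path_b [path_record()]s assumed to match over their full
#'   given geometry (split first if only a stretch matches).
#' @param config A [builder_config()].
#' @return A merged `path_record` (no id, no crossing links).
#' @export
merge_paths <- function(path_a, path_b, config = builder_config()) {
  if (config$type_aware && path_a$path_type != path_b$path_type) {
    stop(structure(class = c("stridemap_merge_refused", "error", "condition"),
                   list(message = sprintf("merge refused: type %s vs %s",
                                          path_a$path_type, path_b$path_type),
                        call = sys.call())))
  }
  proj <- local_projection(path_centroid(path_a))
  xa <- proj$project(path_a$geometry)
  xb <- proj$project(path_b$geometry)
  # orient b along a: compare endpoint pairing straight vs crossed
  straight <- sum((xa[1L, ] - xb[1L, ])^2) + sum((xa[nrow(xa), ] - xb[nrow(xb), ])^2)
  crossed <- sum((xa[1L, ] - xb[nrow(xb), ])^2) + sum((xa[nrow(xa), ] - xb[1L, ])^2)
  if (crossed < straight) xb <- xb[rev(seq_len(nrow(xb))), , drop = FALSE]
  n <- max(2L, ceiling(max(planar_length(xa), planar_length(xb)) /
                         config$resample_spacing) + 1L)
  fr <- seq(0, 1, length.out = n)
  pa <- points_at_arcs(xa, fr * planar_length(xa))
  pb <- points_at_arcs(xb, fr * planar_length(xb))
  ma <- path_a$merge_count; mb <- path_b$merge_count
  merged_xy <- (ma * pa + mb * pb) / (ma + mb)
  props <- path_a$properties
  for (k in union(names(path_a$properties), names(path_b$properties))) {
    va <- path_a$properties[[k]]; vb <- path_b$properties[[k]]
    if (is.numeric(va) && is.numeric(vb)) {
      w <- (ma * va + mb * vb) / (ma + mb)
      props[[k]] <- if (k == "stair_count") as.integer(round(w)) else w
    } else if (is.null(va)) props[[k]] <- vb
  }
  path_record(proj$unproject(merged_xy), path_type = path_a$path_type,
              properties = props, merge_count = ma + mb)
}

#' Split a stored path, wiring a crossing at the cut
#'
#' Store-level counterpart of [split_path()]: the original path is replaced
#' by its two parts, existing crossing links are transferred to the outer
#' endpoints, and a new (or snapped-to existing) crossing joins the two
#' parts at the cut point.
#'
#' @param store A [map_store()].
#' @param id Id of the path to split.
#' @param arc_position Metres along the stored geometry.
#' @param config A [builder_config()].
#' @return List with `first_id`, `second_id`, `crossing_id`.
#' @export
store_split_path <- function(store, id, arc_position, config = builder_config()) {
  p <- store_get_path(store, id)
  parts <- split_path(p, arc_position)
  # drop the original, rewriting crossing references onto the parts
  store$paths[[id]] <- NULL
  a_id <- store_insert_path(store, parts[[1L]])
  b_id <- store_insert_path(store, parts[[2L]])
  rewire <- function(cid, old_end, new_id) {
    if (is.null(cid)) return()
    cr <- store$crossings[[cid]]
    sel <- cr$connections$path_id == id & cr$connections$end == old_end
    cr$connections$path_id[sel] <- new_id
    store$crossings[[cid]] <- cr
  }
  rewire(p$start_crossing, "start", a_id)
  rewire(p$end_crossing, "end", b_id)
  cut_point <- parts[[1L]]$geometry[nrow(parts[[1L]]$geometry), ]
  cid <- insert_connector(store, cut_point,
                          data.frame(path_id = c(a_id, b_id),
                                     end = c("end", "start")),
                          config)
  list(first_id = a_id, second_id = b_id, crossing_id = cid)
}

#' Insert (or reuse) a connector crossing
#'
#' If a crossing already exists within `crossing_snap` of the boundary
#' point it is reused, otherwise a new crossing is created there. All given
#' path ends are registered with it; a path end already attached to a
#' different crossing is re-pointed (and the old connection dropped) so
#' referential symmetry always holds afterwards.
#'
#' @param store A [map_store()].
#' @param boundary_point `c(lon, lat)`.
#' @param path_end_refs Data.frame with columns `path_id`, `end`.
#' @param config A [builder_config()].
#' @return The crossing id.
#' @export
insert_connector <- function(store, boundary_point, path_end_refs,
                             config = builder_config()) {
  for (pid in path_end_refs$path_id) {
    if (is.null(store$paths[[pid]])) {
      stop("insert_connector: dangling path reference ", pid)
    }
  }
  cid <- NULL
  if (length(store$crossings)) {
    locs <- do.call(rbind, lapply(store$crossings, `[[`, "location"))
    d <- geosphere::distGeo(matrix(boundary_point, ncol = 2L), locs)
    if (min(d) <= config$crossing_snap) {
      cid <- names(store$crossings)[which.min(d)]
    }
  }
  if (is.null(cid)) {
    cid <- store_insert_crossing(store, crossing(boundary_point))
  }
  cr <- store$crossings[[cid]]
  for (k in seq_len(nrow(path_end_refs))) {
    pid <- path_end_refs$path_id[k]; end <- path_end_refs$end[k]
    p <- store$paths[[pid]]
    field <- paste0(end, "_crossing")
    old <- p[[field]]
    if (!is.null(old) && old != cid && !is.null(store$crossings[[old]])) {
      oc <- store$crossings[[old]]
      oc$connections <- oc$connections[!(oc$connections$path_id == pid &
                                           oc$connections$end == end), , drop = FALSE]
      if (nrow(oc$connections) == 0L) store$crossings[[old]] <- NULL
      else store$crossings[[old]] <- oc
    }
    p[[field]] <- cid
    store$paths[[pid]] <- p
    if (!any(cr$connections$path_id == pid & cr$connections$end == end)) {
      cr$connections <- rbind(cr$connections,
                              data.frame(path_id = pid, end = end))
    }
  }
  store$crossings[[cid]] <- cr
  cid
}

# Join free path endpoints that lie within crossing_snap of an existing
# crossing or of each other. A crossing is only materialised where at least
# two path ends meet; a lone trace terminus stays bare.
connect_free_endpoints <- function(store, config) {
  repeat {
    ends <- list()
    for (p in store$paths) {
      if (is.null(p$start_crossing)) {
        ends[[length(ends) + 1L]] <- list(id = p$id, end = "start",
                                          pt = p$geometry[1L, ])
      }
      if (is.null(p$end_crossing)) {
        ends[[length(ends) + 1L]] <- list(id = p$id, end = "end",
                                          pt = p$geometry[nrow(p$geometry), ])
      }
    }
    if (length(ends) == 0L) return(invisible())
    progress <- FALSE
    for (e in ends) {
      p <- store$paths[[e$id]]
      if (is.null(p) || !is.null(p[[paste0(e$end, "_crossing")]])) next
      # existing crossing nearby?
      near_cross <- FALSE
      if (length(store$crossings)) {
        locs <- do.call(rbind, lapply(store$crossings, `[[`, "location"))
        near_cross <- min(geosphere::distGeo(matrix(e$pt, ncol = 2L), locs)) <=
          config$crossing_snap
      }
      partners <- Filter(function(o) {
        !(o$id == e$id && o$end == e$end) &&
          geosphere::distGeo(matrix(e$pt, ncol = 2L),
                             matrix(o$pt, ncol = 2L)) <= config$crossing_snap
      }, ends)
      partners <- Filter(function(o) {
        op <- store$paths[[o$id]]
        !is.null(op) && is.null(op[[paste0(o$end, "_crossing")]])
      }, partners)
      if (near_cross || length(partners)) {
        refs <- data.frame(
          path_id = c(e$id, vapply(partners, `[[`, character(1), "id")),
          end = c(e$end, vapply(partners, `[[`, character(1), "end")))
        cid <- insert_connector(store, e$pt, refs, config)
        # a crossing needs >= 2 ends; lone attach only allowed on reuse
        if (nrow(store$crossings[[cid]]$connections) >= 2L) progress <- TRUE
        else {
          # undo a 1-connection crossing we just created
          store$paths[[e$id]][[paste0(e$end, "_crossing")]] <- NULL
          store$crossings[[cid]] <- NULL
        }
      }
    }
    if (!progress) return(invisible())
  }
}

# Extract the sub-polyline of planar geometry xy between arc positions.
sub_polyline <- function(xy, s0, s1) {
  cs <- cum_arclength(xy)
  L <- cs[length(cs)]
  s0 <- max(0, s0); s1 <- min(L, s1)
  p0 <- point_at_arc(xy, s0); p1 <- point_at_arc(xy, s1)
  inner <- xy[cs > s0 + 1e-9 & cs < s1 - 1e-9, , drop = FALSE]
  out <- rbind(p0, inner, p1)
  out[c(TRUE, rowSums(abs(diff(out))) > 1e-12), , drop = FALSE]
}

#' Insert a path into the map with matching, splitting and merging
#'
#' The iterative construction step. The new path is simplified into
#' loop-free pieces; for each piece, candidate paths are looked up by
#' bounding box and scanned for matches. Matching stretches are merged into
#' the corresponding stretch of the stored path (splitting it first where
#' the match starts or stops) using merge-count-weighted averaging;
#' non-matching stretches enter the map as new paths. Connectors are placed
#' at every boundary between matching and non-matching stretches, and free
#' endpoints that meet within the snap radius are joined. The insertion is
#' atomic: on any error the store is left untouched.
#'
#' @param store A [map_store()].
#' @param path A [path_record()] (a raw trace, typically `merge_count` 1).
#' @param config A [builder_config()].
#' @return Insertion report: list with `created`, `merged`, `deleted`
#'   (path ids) and `crossings` (crossing ids touched).
#' @export
insert_path <- function(store, path, config = builder_config()) {
  work <- store_clone(store)
  report <- new.env(parent = emptyenv())
  report$created <- character(0); report$merged <- character(0)
  report$deleted <- character(0); report$crossings <- character(0)
  segments <- simplify_path(path, config)
  # candidate lookup is snapshotted before any piece is stored: a trace
  # must never match pieces of itself inserted moments earlier (a merge
  # count records independent traversals)
  preexisting <- names(work$paths)
  for (seg in segments) insert_segment(work, seg, config, report, preexisting)
  connect_free_endpoints(work, config)
  problems <- audit_consistency(work)
  if (length(problems)) {
    stop("insert_path: store inconsistent after insertion (aborted): ",
         paste(problems, collapse = "; "))
  }
  store_assign(store, work)
  list(created = report$created, merged = report$merged,
       deleted = report$deleted, crossings = unique(report$crossings))
}

# Insert one simplified, loop-free segment (used by insert_path).
insert_segment <- function(work, seg, config, report, preexisting) {
  cands <- query_candidates(work, seg, margin_m = config$match_distance * 2)
  cands <- Filter(function(p) p$id %in% preexisting, cands)
  if (config$type_aware) {
    cands <- Filter(function(p) p$path_type == seg$path_type, cands)
  }
  # deterministic candidate priority: descending merge count, ascending id
  if (length(cands)) {
    ord <- order(-vapply(cands, `[[`, integer(1), "merge_count"),
                 vapply(cands, `[[`, character(1), "id"))
    cands <- cands[ord]
  }
  proj <- local_projection(path_centroid(seg))
  seg_xy <- proj$project(seg$geometry)
  rs <- resample_polyline(seg_xy, config$resample_spacing)
  npts <- nrow(rs$xy)
  new_head <- headings_at_arcs(seg_xy, rs$arc, config$heading_window)
  cand_xy_by_id <- list()
  scans <- list()
  for (cand in cands) {
    cxy <- proj$project(cand$geometry)
    cand_xy_by_id[[cand$id]] <- cxy
    scans[[cand$id]] <- scan_candidate(rs$xy, rs$arc, new_head, cxy, config)
  }
  # per-sample candidate assignment with hysteresis: stay with the current
  # candidate while it keeps matching, otherwise switch to the closest
  # matching one — overlapping stored fragments would otherwise make the
  # assignment flicker and shred the trace into slivers
  assign <- rep(NA_character_, npts)
  cand_ids <- names(scans)
  cur <- NA_character_
  for (i in seq_len(npts)) {
    if (!is.na(cur) && scans[[cur]]$ok[i]) {
      assign[i] <- cur
      next
    }
    best_id <- NA_character_; best_d <- Inf
    for (id in cand_ids) {
      if (scans[[id]]$ok[i] && scans[[id]]$dist[i] < best_d) {
        best_d <- scans[[id]]$dist[i]; best_id <- id
      }
    }
    assign[i] <- best_id
    cur <- best_id
  }
  assign <- clean_runs(assign, rs$arc, config$min_match_length)
  runs <- rle(ifelse(is.na(assign), "<na>", assign))
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  snap <- config$crossing_snap
  piece_refs <- vector("list", length(runs$values)) # (path_id, end) per side
  boundary_pts <- vector("list", length(runs$values))
  for (r in seq_along(runs$values)) {
    lo <- if (starts[r] == 1L) 0 else (rs$arc[starts[r] - 1L] + rs$arc[starts[r]]) / 2
    hi <- if (ends[r] == length(rs$arc)) rs$arc[length(rs$arc)] else
      (rs$arc[ends[r]] + rs$arc[ends[r] + 1L]) / 2
    piece_xy <- sub_polyline(seg_xy, lo, hi)
    boundary_pts[[r]] <- list(lo = proj$unproject(piece_xy[1L, , drop = FALSE])[1L, ],
                              hi = proj$unproject(piece_xy[nrow(piece_xy), , drop = FALSE])[1L, ])
    insert_new_piece <- function() {
      # unmatched slivers shorter than the minimum meaningful match are
      # noise overhangs (e.g. a trace running a couple of metres past the
      # stored backbone); inserting them would litter the map
      if (planar_length(piece_xy) < config$min_match_length) {
        return(NULL)
      }
      frac <- (hi - lo) / rs$arc[length(rs$arc)]
      props <- split_properties(seg$properties, frac)[[1L]]
      new_id <- store_insert_path(work, path_record(
        proj$unproject(piece_xy), path_type = seg$path_type,
        properties = props, merge_count = seg$merge_count))
      report$created <- c(report$created, new_id)
      list(lo = c(new_id, "start"), hi = c(new_id, "end"))
    }
    if (runs$values[r] == "<na>") {
      ref <- insert_new_piece()
    } else {
      ref <- merge_piece(work, runs$values[r], piece_xy, lo, hi, seg,
                         cand_xy_by_id[[runs$values[r]]], config, report)
      if (is.null(ref)) ref <- insert_new_piece() # degenerate match footprint
    }
    if (!is.null(ref)) piece_refs[[r]] <- ref
  }
  # connectors at every boundary between consecutive pieces; when the
  # stored candidate was split at this boundary, the split's crossing is
  # the connector (anchor there, not at the trace-side boundary point)
  linked_crossing_loc <- function(ref) {
    p <- work$paths[[ref[1L]]]
    cid <- p[[paste0(ref[2L], "_crossing")]]
    if (!is.null(cid) && !is.null(work$crossings[[cid]])) {
      work$crossings[[cid]]$location
    } else NULL
  }
  for (r in seq_len(length(runs$values) - 1L)) {
    a <- piece_refs[[r]]; b <- piece_refs[[r + 1L]]
    if (is.null(a) || is.null(b)) next
    refs <- data.frame(path_id = c(a$hi[1L], b$lo[1L]),
                       end = c(a$hi[2L], b$lo[2L]))
    refs <- refs[!is.na(refs$path_id), , drop = FALSE]
    if (nrow(refs) < 2L) next
    pt <- linked_crossing_loc(a$hi)
    if (is.null(pt)) pt <- linked_crossing_loc(b$lo)
    if (is.null(pt)) pt <- (boundary_pts[[r]]$hi + boundary_pts[[r + 1L]]$lo) / 2
    cid <- insert_connector(work, pt, refs, config)
    report$crossings <- c(report$crossings, cid)
  }
  invisible()
}

# Merge one matched piece of the incoming segment into the stored candidate,
# splitting the candidate where the match starts/stops. `cand_xy` is the
# candidate geometry in the same projection as `piece_xy`; the split
# positions come from projecting the piece's endpoints onto it, so the
# candidate's cut points coincide with the piece boundaries. Returns NULL
# when the piece's footprint on the candidate is degenerate (e.g. the
# match hugs the candidate's very end) and no merge is meaningful.
merge_piece <- function(work, cand_id, piece_xy, lo, hi, seg, cand_xy, config, report) {
  ends_hit <- points_to_polyline(
    rbind(piece_xy[1L, ], piece_xy[nrow(piece_xy), ]), cand_xy)
  c_lo <- ends_hit$arc[1L]; c_hi <- ends_hit$arc[2L]
  reversed <- c_lo > c_hi
  snap <- config$crossing_snap
  cand <- work$paths[[cand_id]]
  # the candidate may have been consumed (split/merged) by an earlier run
  # of this same insertion; the piece then falls back to a fresh insert
  if (is.null(cand)) return(NULL)
  planar_L <- planar_length(cand_xy)
  geo_L <- path_length(cand)
  # planar arcs -> geodesic arcs by proportional rescaling (split_path cuts
  # in geodesic metres)
  span <- sort(c(c_lo, c_hi)) / max(planar_L, 1e-9) * geo_L
  span <- pmin(pmax(span, 0), geo_L)
  if (span[2L] - span[1L] <= max(snap, config$resample_spacing)) {
    return(NULL)
  }
  middle_id <- cand_id
  # split off the stretch of the candidate before the match
  if (span[1L] > snap) {
    res <- store_split_path(work, middle_id, span[1L], config)
    report$crossings <- c(report$crossings, res$crossing_id)
    middle_id <- res$second_id
    span <- span - span[1L]
  } else {
    span <- span - span[1L]
  }
  # split off the stretch after the match
  mid_L <- path_length(store_get_path(work, middle_id))
  if (span[2L] > snap && span[2L] < mid_L - snap) {
    res <- store_split_path(work, middle_id, span[2L], config)
    report$crossings <- c(report$crossings, res$crossing_id)
    middle_id <- res$first_id
  }
  mid <- store_get_path(work, middle_id)
  proj <- local_projection(path_centroid(seg))
  piece <- path_record(proj$unproject(piece_xy), path_type = seg$path_type,
                       properties = split_properties(
                         seg$properties,
                         (hi - lo) / max(planar_length(proj$project(seg$geometry)), 1e-9))[[1L]],
                       merge_count = seg$merge_count)
  merged <- merge_paths(mid, piece, config)
  merged$id <- mid$id
  merged$start_crossing <- mid$start_crossing
  merged$end_crossing <- mid$end_crossing
  store_update_path(work, merged)
  report$merged <- c(report$merged, mid$id)
  # orient the merged path's ends along the incoming segment
  if (reversed) list(lo = c(mid$id, "end"), hi = c(mid$id, "start"))
  else list(lo = c(mid$id, "start"), hi = c(mid$id, "end"))
}

#' Remove paths that never merged
#'
#' A trace that was inserted but never confirmed by a later merge is likely
#' a spurious measurement (for example a GPS reflection off a building
#' facade). Paths with `merge_count` below the threshold are removed, and
#' crossings left without connections disappear with them.
#'
#' @param store A [map_store()].
#' @param min_merges Keep only paths with `merge_count >= min_merges`.
#' @return Character vector of removed path ids.
#' @export
prune_unmerged <- function(store, min_merges) {
  stopifnot(min_merges >= 1L)
  doomed <- names(Filter(function(p) p$merge_count < min_merges, store$paths))
  for (id in doomed) store_delete_path(store, id)
  doomed
}

#' Score a constructed map against a reference network
#'
#' Geometric correctness is the fraction of the constructed network's
#' length lying within `buffer` metres of the reference network's paths;
#' topological correctness is the fraction of reference crossings that have
#' a constructed crossing within `buffer` metres.
#'
#' @param constructed,truth [map_store()]s; `truth` must contain paths.
#' @param buffer Tolerance corridor in metres.
#' @return Named list `geometric` and `topological`, both in `[0, 1]`
#'   (`topological` is 1 when the reference has no crossings).
#' @export
evaluate_map <- function(constructed, truth, buffer) {
  if (length(truth$paths) == 0L) stop("evaluate_map: empty reference map")
  if (length(constructed$paths) == 0L) stop("evaluate_map: empty constructed map")
  proj <- store_projection(truth)
  truth_xy <- lapply(truth$paths, function(p) proj$project(p$geometry))
  step <- 0.5
  total <- 0; inside <- 0
  for (p in constructed$paths) {
    rs <- resample_polyline(proj$project(p$geometry), step)
    d <- rep(Inf, nrow(rs$xy))
    for (t_xy in truth_xy) {
      d <- pmin(d, points_to_polyline(rs$xy, t_xy)$dist)
    }
    L <- planar_length(proj$project(p$geometry))
    total <- total + L
    inside <- inside + L * mean(d <= buffer)
  }
  topo <- 1
  if (length(truth$crossings)) {
    t_locs <- do.call(rbind, lapply(truth$crossings, `[[`, "location"))
    if (length(constructed$crossings)) {
      c_locs <- do.call(rbind, lapply(constructed$crossings, `[[`, "location"))
      hits <- vapply(seq_len(nrow(t_locs)), function(i) {
        any(geosphere::distGeo(t_locs[i, , drop = FALSE], c_locs) <= buffer)
      }, logical(1))
      topo <- mean(hits)
    } else topo <- 0
  }
  list(geometric = if (total > 0) inside / total else 0, topological = topo)
}
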