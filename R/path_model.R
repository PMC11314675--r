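#' Path types recognised by the map layer
#'
#' The activity classes plus a generic `trail` used when activity typing is
#' switched off (untyped mode treats every inserted trace as a plain trail).
#'
#' @return Character vector.
#' @export
path_types <- function() c("trail", "walk", "stairs_up", "stairs_down")

#' Create a path record
#'
#' A typed geographic polyline: the atomic unit of the map layer. Paths are
#' edges of a bidirectional graph whose nodes are crossings; `merge_count`
#' records how many traces the path aggregates and acts as the weight in
#' merge averaging.
#'
#' @param geometry n x 2 matrix of WGS84 (longitude, latitude), n >= 2.
#' @param path_type One of [path_types()].
#' @param properties Named list of extra properties. Stairs-typed paths must
#'   carry a non-negative integer `stair_count`; other types must not.
#' @param merge_count Positive integer, number of aggregated traces.
#' @param id Optional identifier (assigned by the store on insert).
#' @param start_crossing,end_crossing Optional crossing ids this path's
#'   first/last vertex is connected to.
#' @return An object of class `path_record`.
#' @export
path_record <- function(geometry, path_type = "trail", properties = list(),
                        merge_count = 1L, id = NULL,
                        start_crossing = NULL, end_crossing = NULL) {
  geometry <- rbind(geometry)
  if (nrow(geometry) < 2L) stop("path_record: geometry needs at least 2 points")
  if (!path_type %in% path_types()) stop("path_record: unknown path_type ", path_type)
  if (any(abs(geometry[, 2L]) > 90) || any(abs(geometry[, 1L]) > 180)) {
    stop("path_record: coordinates outside WGS84 bounds (expected lon, lat order)")
  }
  stairs <- path_type %in% c("stairs_up", "stairs_down")
  if (stairs && is.null(properties$stair_count)) {
    stop("path_record: stairs-typed path requires a stair_count property")
  }
  if (!stairs) properties$stair_count <- NULL
  if (merge_count < 1L) stop("path_record: merge_count must be >= 1")
  structure(list(id = id, geometry = unname(geometry), path_type = path_type,
                 properties = properties, merge_count = as.integer(merge_count),
                 start_crossing = start_crossing, end_crossing = end_crossing),
            class = "path_record")
}

#' Create a crossing
#'
#' A graph node joining path ends. `connections` lists which end (`"start"`
#' or `"end"`) of which path meets here; the referenced path's
#' `start_crossing`/`end_crossing` field must point back (referential
#' symmetry, enforced by the store audit).
#'
#' @param location `c(lon, lat)` of the node.
#' @param connections Data.frame with columns `path_id`, `end`.
#' @param id Optional identifier.
#' @return An object of class `crossing`.
#' @export
crossing <- function(location, connections = NULL, id = NULL) {
  if (is.null(connections)) {
    connections <- data.frame(path_id = character(0), end = character(0))
  }
  stopifnot(all(connections$end %in% c("start", "end")))
  structure(list(id = id, location = as.numeric(location),
                 connections = connections),
            class = "crossing")
}

#' Create an empty in-memory map store
#'
#' Holds the path and crossing collections with insert/delete/update/get and
#' bounding-box query operations. The store has reference semantics (it is
#' an environment), mirroring a database connection; persistence goes
#' through GeoJSON ([write_map_geojson()] / [read_map_geojson()]).
#'
#' @return An object of class `map_store`.
#' @export
map_store <- function() {
  store <- new.env(parent = emptyenv())
  store$paths <- list()
  store$crossings <- list()
  store$next_path <- 1L
  store$next_crossing <- 1L
  class(store) <- "map_store"
  store
}

#' @export
print.map_store <- function(x, ...) {
  cat(sprintf("<map_store> %d paths, %d crossings\n",
              length(x$paths), length(x$crossings)))
  invisible(x)
}

#' Deep-copy a map store
#'
#' @param store A [map_store()].
#' @return An independent copy; mutations to one do not affect the other.
#' @export
store_clone <- function(store) {
  copy <- map_store()
  copy$paths <- store$paths
  copy$crossings <- store$crossings
  copy$next_path <- store$next_path
  copy$next_crossing <- store$next_crossing
  copy
}

# Overwrite the contents of `store` with those of `other` (atomic commit).
store_assign <- function(store, other) {
  store$paths <- other$paths
  store$crossings <- other$crossings
  store$next_path <- other$next_path
  store$next_crossing <- other$next_crossing
  invisible(store)
}

#' Insert a path into the store
#'
#' @param store A [map_store()].
#' @param path A [path_record()]; if it has no id one is assigned.
#' @return The stored path's id.
#' @export
store_insert_path <- function(store, path) {
  stopifnot(inherits(path, "path_record"))
  if (is.null(path$id)) {
    path$id <- sprintf("p%04d", store$next_path)
    store$next_path <- store$next_path + 1L
  }
  store$paths[[path$id]] <- path
  path$id
}

#' @rdname store_insert_path
#' @param crossing_obj A [crossing()]; if it has no id one is assigned.
#' @export
store_insert_crossing <- function(store, crossing_obj) {
  stopifnot(inherits(crossing_obj, "crossing"))
  if (is.null(crossing_obj$id)) {
    crossing_obj$id <- sprintf("c%04d", store$next_crossing)
    store$next_crossing <- store$next_crossing + 1L
  }
  store$crossings[[crossing_obj$id]] <- crossing_obj
  crossing_obj$id
}

#' Fetch a path or crossing by id
#'
#' @param store A [map_store()].
#' @param id Identifier.
#' @return The record, or an error if absent.
#' @export
store_get_path <- function(store, id) {
  p <- store$paths[[id]]
  if (is.null(p)) stop("store_get_path: no path with id ", id)
  p
}

#' @rdname store_get_path
#' @export
store_get_crossing <- function(store, id) {
  cr <- store$crossings[[id]]
  if (is.null(cr)) stop("store_get_crossing: no crossing with id ", id)
  cr
}

#' Replace a stored path (same id)
#'
#' @param store A [map_store()].
#' @param path A [path_record()] with a non-NULL id already in the store.
#' @return The id, invisibly.
#' @export
store_update_path <- function(store, path) {
  if (is.null(path$id) || is.null(store$paths[[path$id]])) {
    stop("store_update_path: path not in store")
  }
  store$paths[[path$id]] <- path
  invisible(path$id)
}

#' Delete a path, detaching it from its crossings
#'
#' Connections referencing the path are removed from crossings; crossings
#' left with no connections are deleted too.
#'
#' @param store A [map_store()].
#' @param id Path id.
#' @return Invisibly, the id.
#' @export
store_delete_path <- function(store, id) {
  if (is.null(store$paths[[id]])) stop("store_delete_path: no path with id ", id)
  store$paths[[id]] <- NULL
  for (cid in names(store$crossings)) {
    cr <- store$crossings[[cid]]
    keep <- cr$connections$path_id != id
    if (!all(keep)) {
      cr$connections <- cr$connections[keep, , drop = FALSE]
      if (nrow(cr$connections) == 0L) store$crossings[[cid]] <- NULL
      else store$crossings[[cid]] <- cr
    }
  }
  invisible(id)
}

#' Geodesic length of a path
#'
#' Sum of WGS84 geodesic segment lengths along the polyline.
#'
#' @param path A [path_record()] (or a bare lon/lat matrix).
#' @return Length in metres.
#' @export
path_length <- function(path) {
  g <- if (inherits(path, "path_record")) path$geometry else rbind(path)
  if (nrow(g) < 2L) return(0)
  sum(geosphere::distGeo(g[-nrow(g), , drop = FALSE], g[-1L, , drop = FALSE]))
}

#' Centroid of a path
#'
#' Arc-length-weighted centroid of the polyline: segment midpoints averaged
#' with weights proportional to segment length (a zero-length path falls
#' back to the plain vertex mean).
#'
#' @param path A [path_record()] or lon/lat matrix.
#' @return `c(lon, lat)`.
#' @export
path_centroid <- function(path) {
  g <- if (inherits(path, "path_record")) path$geometry else rbind(path)
  if (nrow(g) == 1L) return(g[1L, ])
  w <- geosphere::distGeo(g[-nrow(g), , drop = FALSE], g[-1L, , drop = FALSE])
  mid <- (g[-nrow(g), , drop = FALSE] + g[-1L, , drop = FALSE]) / 2
  if (sum(w) == 0) return(colMeans(g))
  colSums(mid * w) / sum(w)
}

#' Bounding box of a path
#'
#' @param path A [path_record()] or lon/lat matrix.
#' @return Named numeric `c(min_lon, min_lat, max_lon, max_lat)`.
#' @export
path_bbox <- function(path) {
  g <- if (inherits(path, "path_record")) path$geometry else rbind(path)
  c(min_lon = min(g[, 1L]), min_lat = min(g[, 2L]),
    max_lon = max(g[, 1L]), max_lat = max(g[, 2L]))
}

bbox_intersects <- function(a, b, margin_deg = 0) {
  !(a["max_lon"] + margin_deg < b["min_lon"] ||
      b["max_lon"] + margin_deg < a["min_lon"] ||
      a["max_lat"] + margin_deg < b["min_lat"] ||
      b["max_lat"] + margin_deg < a["min_lat"])
}

#' Query stored paths by bounding-box overlap
#'
#' Returns every stored path whose bounding box intersects the query path's
#' bounding box (optionally padded by `margin_m` metres) — a superset of the
#' paths that can geometrically match, never a false negative.
#'
#' @param store A [map_store()].
#' @param path A [path_record()] or lon/lat matrix (the query geometry).
#' @param margin_m Padding added around the query box, metres.
#' @return List of `path_record`s.
#' @export
query_candidates <- function(store, path, margin_m = 0) {
  if (length(store$paths) == 0L) return(list())
  qb <- path_bbox(path)
  lat0 <- (qb["min_lat"] + qb["max_lat"]) / 2
  margin_deg <- margin_m / (EARTH_RADIUS_M * pi / 180) / max(cos(lat0 * pi / 180), 0.1)
  hits <- Filter(function(p) bbox_intersects(qb, path_bbox(p), margin_deg),
                 store$paths)
  unname(hits)
}

#' Audit the store's structural invariants
#'
#' Checks referential symmetry between paths and crossings, that no path
#' has degenerate (zero-length or < 2 point) geometry or a merge count
#' below 1, and that no crossing is orphaned (zero connections or dangling
#' path references).
#'
#' @param store A [map_store()].
#' @return Character vector of problems; empty when the store is consistent.
#' @export
audit_consistency <- function(store) {
  problems <- character(0)
  note <- function(...) problems <<- c(problems, sprintf(...))
  for (p in store$paths) {
    if (nrow(p$geometry) < 2L) note("path %s: fewer than 2 points", p$id)
    else if (path_length(p) <= 0) note("path %s: zero length", p$id)
    if (p$merge_count < 1L) note("path %s: merge_count < 1", p$id)
    for (end in c("start", "end")) {
      cid <- p[[paste0(end, "_crossing")]]
      if (is.null(cid)) next
      cr <- store$crossings[[cid]]
      if (is.null(cr)) {
        note("path %s: %s_crossing %s does not exist", p$id, end, cid)
      } else if (!any(cr$connections$path_id == p$id & cr$connections$end == end)) {
        note("path %s: crossing %s lacks the back-reference (%s)", p$id, cid, end)
      }
    }
  }
  for (cr in store$crossings) {
    if (nrow(cr$connections) < 1L) note("crossing %s: no connections", cr$id)
    for (k in seq_len(nrow(cr$connections))) {
      pid <- cr$connections$path_id[k]
      end <- cr$connections$end[k]
      p <- store$paths[[pid]]
      if (is.null(p)) note("crossing %s: dangling path reference %s", cr$id, pid)
      else if (!identical(p[[paste0(end, "_crossing")]], cr$id)) {
        note("crossing %s: path %s does not point back via %s_crossing",
             cr$id, pid, end)
      }
    }
  }
  problems
}

# Projection centred on the store's (or a set of geometries') centroid.
store_projection <- function(store, extra = NULL) {
  pts <- do.call(rbind, c(lapply(store$paths, `[[`, "geometry"), list(extra)))
  if (is.null(pts) || nrow(pts) == 0L) stop("store_projection: no geometry")
  local_projection(colMeans(pts))
}

#' Write a map store as a GeoJSON FeatureCollection
#'
#' Paths become LineString features (properties: `kind`, `path_type`,
#' `merge_count`, `stair_count` where applicable, `start_crossing`,
#' `end_crossing`); crossings become Point features with their connection
#' list. Coordinates are (longitude, latitude) per RFC 7946. The file loads
#' directly in GIS tools.
#'
#' @param store A [map_store()].
#' @param file Path to write.
#' @return `file`, invisibly.
#' @export
write_map_geojson <- function(store, file) {
  feats <- list()
  for (p in store$paths) {
    props <- c(list(kind = "path", id = p$id, path_type = p$path_type,
                    merge_count = p$merge_count,
                    start_crossing = p$start_crossing,
                    end_crossing = p$end_crossing),
               p$properties)
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "LineString",
                      coordinates = lapply(seq_len(nrow(p$geometry)),
                                           function(i) as.numeric(p$geometry[i, ]))),
      properties = props[!vapply(props, is.null, logical(1))])
  }
  for (cr in store$crossings) {
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = as.numeric(cr$location)),
      properties = list(kind = "crossing", id = cr$id,
                        connections = lapply(seq_len(nrow(cr$connections)),
                                             function(k) list(
                                               path_id = cr$connections$path_id[k],
                                               end = cr$connections$end[k]))))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' Read a map store from GeoJSON
#'
#' Inverse of [write_map_geojson()].
#'
#' @param file GeoJSON FeatureCollection path.
#' @return A [map_store()].
#' @export
read_map_geojson <- function(file) {
  doc <- jsonlite::read_json(file)
  if (!identical(doc$type, "FeatureCollection")) {
    stop("read_map_geojson: not a FeatureCollection")
  }
  store <- map_store()
  max_id <- function(ids, prefix) {
    nums <- suppressWarnings(as.integer(sub(prefix, "", ids[grepl(paste0("^", prefix), ids)])))
    if (length(nums) && any(!is.na(nums))) max(nums, na.rm = TRUE) else 0L
  }
  for (f in doc$features) {
    pr <- f$properties
    if (identical(pr$kind, "path")) {
      geom <- do.call(rbind, lapply(f$geometry$coordinates, as.numeric))
      extra <- pr[setdiff(names(pr), c("kind", "id", "path_type", "merge_count",
                                       "start_crossing", "end_crossing"))]
      store$paths[[pr$id]] <- path_record(
        geom, path_type = pr$path_type, properties = extra,
        merge_count = pr$merge_count, id = pr$id,
        start_crossing = pr$start_crossing, end_crossing = pr$end_crossing)
    } else if (identical(pr$kind, "crossing")) {
      conns <- data.frame(
        path_id = vapply(pr$connections, `[[`, character(1), "path_id"),
        end = vapply(pr$connections, `[[`, character(1), "end"))
      store$crossings[[pr$id]] <- crossing(as.numeric(f$geometry$coordinates),
                                           conns, id = pr$id)
    }
  }
  store$next_path <- max_id(names(store$paths), "p") + 1L
  store$next_crossing <- max_id(names(store$crossings), "c") + 1L
  store
}
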