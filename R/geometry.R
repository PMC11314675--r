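# Planar geometry on polylines.
#
# Coordinates at rest are WGS84 (longitude, latitude) degrees. All metric
# work happens in a local tangent-plane (equirectangular) projection centred
# on the data: x = R cos(lat0) dlon, y = R dlat, in metres. Over the
# sub-kilometre extents of a pedestrian path network the distortion of this
# projection is negligible and it is exactly invertible, which matters
# because merged/averaged geometry must be mapped back to WGS84.
#
# Polylines are n x 2 matrices. Arc positions are metres from the first
# vertex, measured in the projection.

EARTH_RADIUS_M <- 6378137

#' Local tangent-plane projection
#'
#' Builds a pair of functions mapping WGS84 (lon, lat) degree matrices to
#' local metric (x, y) coordinates and back, centred on a reference point.
#'
#' @param origin Numeric `c(lon, lat)` centre of the projection.
#' @return List with functions `project(lonlat)` and `unproject(xy)`, both
#'   accepting and returning 2-column matrices, plus the `origin`.
#' @export
local_projection <- function(origin) {
  lon0 <- origin[1L]; lat0 <- origin[2L]
  kx <- EARTH_RADIUS_M * cos(lat0 * pi / 180) * pi / 180
  ky <- EARTH_RADIUS_M * pi / 180
  list(
    origin = c(lon0, lat0),
    project = function(lonlat) {
      m <- rbind(lonlat)
      cbind((m[, 1L] - lon0) * kx, (m[, 2L] - lat0) * ky)
    },
    unproject = function(xy) {
      m <- rbind(xy)
      cbind(m[, 1L] / kx + lon0, m[, 2L] / ky + lat0)
    })
}

# Cumulative planar arc length of an n x 2 matrix: numeric vector length n.
cum_arclength <- function(xy) {
  if (nrow(xy) < 2L) return(rep(0, nrow(xy)))
  c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
}

planar_length <- function(xy) {
  s <- cum_arclength(xy)
  s[length(s)]
}

# Point at arc position s (clamped to [0, L]) on a planar polyline.
point_at_arc <- function(xy, s) {
  cs <- cum_arclength(xy)
  L <- cs[length(cs)]
  s <- min(max(s, 0), L)
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(xy) - 1L)
  seg <- cs[i + 1L] - cs[i]
  f <- if (seg > 0) (s - cs[i]) / seg else 0
  xy[i, ] + f * (xy[i + 1L, ] - xy[i, ])
}

# Vectorised interpolation: points at several arc positions (clamped).
points_at_arcs <- function(xy, s) {
  cs <- cum_arclength(xy)
  L <- cs[length(cs)]
  s <- pmin(pmax(s, 0), L)
  i <- pmin(pmax(findInterval(s, cs, rightmost.closed = TRUE), 1L), nrow(xy) - 1L)
  seg <- cs[i + 1L] - cs[i]
  f <- ifelse(seg > 0, (s - cs[i]) / seg, 0)
  xy[i, , drop = FALSE] + f * (xy[i + 1L, , drop = FALSE] - xy[i, , drop = FALSE])
}

# Resample a planar polyline at (approximately) `spacing` metres: points at
# arc positions 0, d, 2d, ..., L with d chosen so the last point lands
# exactly on L. Returns list(xy, arc).
resample_polyline <- function(xy, spacing) {
  L <- planar_length(xy)
  n <- max(2L, ceiling(L / spacing) + 1L)
  arc <- seq(0, L, length.out = n)
  list(xy = points_at_arcs(xy, arc), arc = arc)
}

# Vectorised local headings (radians) at arc positions, estimated over a
# +/- window of arc length.
headings_at_arcs <- function(xy, s, window) {
  L <- planar_length(xy)
  p0 <- points_at_arcs(xy, pmax(0, s - window))
  p1 <- points_at_arcs(xy, pmin(L, s + window))
  atan2(p1[, 2L] - p0[, 2L], p1[, 1L] - p0[, 1L])
}

# Cut a planar polyline at arc position s: list of two polylines that share
# the interpolated cut point. s must be strictly inside (0, L).
cut_polyline <- function(xy, s) {
  cs <- cum_arclength(xy)
  L <- cs[length(cs)]
  if (s <= 0 || s >= L) stop("cut_polyline: cut position must be strictly inside the path")
  p <- point_at_arc(xy, s)
  i <- findInterval(s, cs, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(xy) - 1L)
  a <- xy[seq_len(i), , drop = FALSE]
  b <- xy[seq.int(i + 1L, nrow(xy)), , drop = FALSE]
  eps <- 1e-9 * max(L, 1)
  if (sqrt(sum((a[nrow(a), ] - p)^2)) > eps) a <- rbind(a, p)
  if (sqrt(sum((b[1L, ] - p)^2)) > eps) b <- rbind(p, b)
  list(a, b)
}

# Distances from M query points to a planar polyline. Returns list of
# vectors: dist (metres), arc (arc position of nearest point on polyline).
points_to_polyline <- function(pts, xy) {
  pts <- rbind(pts)
  nseg <- nrow(xy) - 1L
  cs <- cum_arclength(xy)
  a <- xy[seq_len(nseg), , drop = FALSE]
  d <- xy[seq.int(2L, nrow(xy)), , drop = FALSE] - a
  len2 <- rowSums(d^2)
  best_d2 <- rep(Inf, nrow(pts)); best_arc <- numeric(nrow(pts))
  for (j in seq_len(nseg)) {
    wx <- pts[, 1L] - a[j, 1L]; wy <- pts[, 2L] - a[j, 2L]
    t <- if (len2[j] > 0) pmin(pmax((wx * d[j, 1L] + wy * d[j, 2L]) / len2[j], 0), 1) else 0
    dx <- wx - t * d[j, 1L]; dy <- wy - t * d[j, 2L]
    d2 <- dx * dx + dy * dy
    better <- d2 < best_d2
    best_d2[better] <- d2[better]
    best_arc[better] <- cs[j] + t[better] * sqrt(len2[j])
  }
  list(dist = sqrt(best_d2), arc = best_arc)
}

# Douglas-Peucker simplification with planar tolerance (metres). Keeps
# endpoints; no removed vertex lies further than tol from the result.
douglas_peucker <- function(xy, tol) {
  n <- nrow(xy)
  if (n <= 2L) return(xy)
  keep <- logical(n); keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    rng <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i0 <- rng[1L]; i1 <- rng[2L]
    if (i1 - i0 < 2L) next
    mid <- seq.int(i0 + 1L, i1 - 1L)
    seg <- rbind(xy[i0, ], xy[i1, ])
    d <- points_to_polyline(xy[mid, , drop = FALSE], seg)$dist
    k <- which.max(d)
    if (d[k] > tol) {
      idx <- mid[k]
      keep[idx] <- TRUE
      stack <- c(stack, list(c(i0, idx)), list(c(idx, i1)))
    }
  }
  xy[keep, , drop = FALSE]
}

# Proper intersection point of segments p1-p2 and p3-p4, or NULL. Touching
# at shared endpoints does not count (adjacent segments always touch).
segment_intersection <- function(p1, p2, p3, p4, eps = 1e-12) {
  r <- p2 - p1; s <- p4 - p3
  denom <- r[1L] * s[2L] - r[2L] * s[1L]
  if (abs(denom) < eps) return(NULL) # parallel or collinear: no single crossing point
  q <- p3 - p1
  t <- (q[1L] * s[2L] - q[2L] * s[1L]) / denom
  u <- (q[1L] * r[2L] - q[2L] * r[1L]) / denom
  tol <- 1e-9
  if (t <= tol || t >= 1 - tol || u <= tol || u >= 1 - tol) return(NULL)
  p1 + t * r
}

# Arc positions (strictly inside (0, L)) at which a planar polyline crosses
# itself, sorted. Each crossing contributes both of its traversal positions.
self_intersection_arcs <- function(xy) {
  n <- nrow(xy)
  if (n < 4L) return(numeric(0))
  cs <- cum_arclength(xy)
  arcs <- numeric(0)
  for (i in seq_len(n - 3L)) {
    for (j in seq.int(i + 2L, n - 1L)) {
      p <- segment_intersection(xy[i, ], xy[i + 1L, ], xy[j, ], xy[j + 1L, ])
      if (!is.null(p)) {
        arcs <- c(arcs,
                  cs[i] + sqrt(sum((p - xy[i, ])^2)),
                  cs[j] + sqrt(sum((p - xy[j, ])^2)))
      }
    }
  }
  # revisited vertices (e.g. a figure-eight anchored at its waist) are
  # crossings too, even though no two edges properly intersect there
  for (i in seq_len(n - 2L)) {
    for (j in seq.int(i + 2L, n)) {
      if (max(abs(xy[i, ] - xy[j, ])) < 1e-6) arcs <- c(arcs, cs[i], cs[j])
    }
  }
  L <- cs[n]
  arcs <- arcs[arcs > 1e-9 & arcs < L - 1e-9]
  sort(unique(round(arcs, 9)))
}
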