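#' Build a table of GPS fixes
#'
#' @param time Numeric seconds (same clock as the IMU timestamps).
#' @param lon,lat WGS84 degrees.
#' @param accuracy Optional accuracy estimate, metres.
#' @return Data.frame of class `geo_fixes`, time-ordered.
#' @export
geo_fixes <- function(time, lon, lat, accuracy = NA_real_) {
  stopifnot(length(time) == length(lon), length(lon) == length(lat))
  if (any(abs(lat) > 90) || any(abs(lon) > 180)) {
    stop("geo_fixes: coordinates outside WGS84 bounds")
  }
  if (is.unsorted(time)) stop("geo_fixes: fixes must be time-ordered")
  structure(data.frame(time = as.numeric(time), lon = as.numeric(lon),
                       lat = as.numeric(lat), accuracy = accuracy),
            class = c("geo_fixes", "data.frame"))
}

#' Interpolate GPS fixes to step timepoints
#'
#' The phone delivers fixes at a lower, irregular rate than steps occur, so
#' each step's position is linearly interpolated in time between the two
#' bracketing fixes, per coordinate. Step times outside the fix span are an
#' error: extrapolating positions would invent geometry.
#'
#' @param fixes A [geo_fixes()] table with at least 2 rows.
#' @param step_times Sorted numeric seconds.
#' @return Data.frame with columns `lon`, `lat`, one row per step time.
#' @export
interpolate_fixes <- function(fixes, step_times) {
  if (nrow(fixes) < 2L) stop("interpolate_fixes: need at least 2 fixes")
  if (is.unsorted(step_times)) stop("interpolate_fixes: step_times must be sorted")
  out_of_range <- step_times < fixes$time[1L] |
    step_times > fixes$time[nrow(fixes)]
  if (any(out_of_range)) {
    stop("interpolate_fixes: step times outside the fix span: ",
         paste(format(step_times[out_of_range]), collapse = ", "))
  }
  data.frame(
    lon = stats::approx(fixes$time, fixes$lon, xout = step_times, ties = "ordered")$y,
    lat = stats::approx(fixes$time, fixes$lat, xout = step_times, ties = "ordered")$y)
}

gpx_time_format <- "%Y-%m-%dT%H:%M:%OSZ"

#' Read GPX 1.1 tracks
#'
#' Each `<trk>` becomes one trace; `<trkseg>` segments within a track are
#' concatenated in document order. `<time>` stamps are converted to numeric
#' seconds (UTC epoch).
#'
#' @param file GPX file path.
#' @return List of [geo_fixes()] tables, one per track.
#' @export
read_gpx <- function(file) {
  doc <- xml2::read_xml(file)
  xml2::xml_ns_strip(doc)
  tracks <- xml2::xml_find_all(doc, ".//trk")
  lapply(tracks, function(trk) {
    pts <- xml2::xml_find_all(trk, ".//trkseg/trkpt")
    if (length(pts) == 0L) return(geo_fixes(numeric(0), numeric(0), numeric(0)))
    times <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
    if (anyNA(times)) stop("read_gpx: track point without a <time> stamp")
    t <- as.POSIXct(times, format = gpx_time_format, tz = "UTC")
    if (anyNA(t)) stop("read_gpx: unparseable <time> stamp")
    geo_fixes(as.numeric(t),
              as.numeric(xml2::xml_attr(pts, "lon")),
              as.numeric(xml2::xml_attr(pts, "lat")))
  })
}

#' Write traces as a GPX 1.1 file
#'
#' @param traces List of [geo_fixes()] tables (or a single table).
#' @param file Path to write.
#' @return `file`, invisibly.
#' @export
write_gpx <- function(traces, file) {
  if (inherits(traces, "data.frame")) traces <- list(traces)
  doc <- xml2::xml_new_root("gpx", version = "1.1", creator = "stridemap",
                            xmlns = "http://www.topografix.com/GPX/1/1")
  for (trace in traces) {
    trk <- xml2::xml_add_child(doc, "trk")
    seg <- xml2::xml_add_child(trk, "trkseg")
    for (i in seq_len(nrow(trace))) {
      pt <- xml2::xml_add_child(seg, "trkpt",
                                lat = sprintf("%.8f", trace$lat[i]),
                                lon = sprintf("%.8f", trace$lon[i]))
      xml2::xml_add_child(pt, "time",
                          format(as.POSIXct(trace$time[i], origin = "1970-01-01",
                                            tz = "UTC"),
                                 gpx_time_format))
    }
  }
  xml2::write_xml(doc, file)
  invisible(file)
}

#' Classify strides and attach positions
#'
#' Runs the full per-trial pipeline: heel-strike detection, stride
#' segmentation, feature extraction, scaling, activity prediction, and GPS
#' interpolation. Each retained stride is positioned at its *start* time
#' (the heel strike opening the stride); strides whose start time falls
#' outside the GPS fix span are dropped.
#'
#' @param recording An [inertial_recording()].
#' @param fixes A [geo_fixes()] table sharing the recording's clock.
#' @param model A trained `har_model`.
#' @param scaler The [fit_scaler()] parameters the model was trained with.
#' @param config A [step_detector_config()].
#' @param time_offset Constant seconds added to IMU times to align clocks.
#' @return Data.frame of classified steps: `time`, `lon`, `lat`, `activity`.
#' @export
classify_and_georeference <- function(recording, fixes, model, scaler,
                                      config = step_detector_config(),
                                      time_offset = 0) {
  events <- detect_step_events(recording, config)
  windows <- segment_steps(events, recording$timestamps, config)
  empty <- data.frame(time = numeric(0), lon = numeric(0), lat = numeric(0),
                      activity = factor(character(0), levels = activity_classes()))
  if (nrow(windows) == 0L) return(empty)
  feats <- extract_feature_matrix(recording, windows)
  pred <- predict(model, apply_scaler(scaler, feats))
  t_step <- windows$start_time + time_offset
  keep <- t_step >= fixes$time[1L] & t_step <= fixes$time[nrow(fixes)]
  if (!any(keep)) return(empty)
  pos <- interpolate_fixes(fixes, t_step[keep])
  data.frame(time = t_step[keep], lon = pos$lon, lat = pos$lat,
             activity = pred[keep])
}

#' Export classified steps as a GeoJSON point layer
#'
#' One Point feature per step with properties `time`, `activity` and a
#' rendering hint `marker-color` (walking red, stair activity green).
#'
#' @param steps Data.frame from [classify_and_georeference()].
#' @param file Path to write.
#' @return `file`, invisibly.
#' @export
write_steps_geojson <- function(steps, file) {
  color <- ifelse(steps$activity == "walk", "#ff0000", "#00aa00")
  feats <- lapply(seq_len(nrow(steps)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(steps$lon[i], steps$lat[i])),
         properties = list(time = steps$time[i],
                           activity = as.character(steps$activity[i]),
                           `marker-color` = color[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}
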