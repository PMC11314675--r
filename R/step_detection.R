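#' Step detector configuration
#'
#' Thresholds for heel-strike detection on the thigh pitch angle. At the
#' moment of heel strike the thigh inclination is near its per-cycle maximum,
#' so strides are delimited by filtered local maxima of that one signal.
#'
#' @param prominence Minimum topographic prominence of a peak, radians.
#' @param min_height Minimum absolute peak height, radians. The mounting
#'   convention of the thigh sensor puts the heel-strike pitch well above
#'   1.6 rad, so this doubles as a stance/noise rejector.
#' @param min_separation Minimum distance between retained peaks, in samples
#'   (not seconds): 16 samples is about 0.53 s at the nominal 30 Hz rate.
#' @param max_cycle_duration Maximum duration of one gait cycle, seconds.
#'   Peak-to-peak intervals at least this long are treated as standing
#'   periods and produce no stride window.
#' @return An object of class `step_detector_config`.
#' @export
step_detector_config <- function(prominence = 0.2, min_height = 1.6,
                                 min_separation = 16, max_cycle_duration = 2.0) {
  vals <- c(prominence, min_height, min_separation, max_cycle_duration)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("step_detector_config: all parameters must be strictly positive")
  }
  structure(list(prominence = prominence, min_height = min_height,
                 min_separation = as.integer(min_separation),
                 max_cycle_duration = max_cycle_duration),
            class = "step_detector_config")
}

# Local maxima of a numeric vector with plateau handling: a plateau of equal
# values flanked by strictly lower samples counts as one peak, anchored at
# the plateau's first sample. Returns integer indices.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  peaks <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      # climb: find end of any plateau at this level
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) peaks <- c(peaks, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  peaks
}

# Topographic prominence of each peak: drop from the peak to the higher of
# the two minima separating it from the nearest higher terrain (or the
# signal edge) on either side.
peak_prominences <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1L)]
    higher_l <- which(left > h)
    lo_l <- min(x[(if (length(higher_l)) max(higher_l) else 1L):p])
    right_idx <- seq.int(p + 1L, length(x))
    right <- x[right_idx]
    higher_r <- which(right > h)
    hi_r <- if (length(higher_r)) right_idx[min(higher_r)] else length(x)
    lo_r <- min(x[p:hi_r])
    h - max(lo_l, lo_r)
  }, numeric(1))
}

# Greedy distance filter, highest peaks first (ties: earlier index wins).
enforce_separation <- function(x, peaks, min_sep) {
  if (length(peaks) < 2L) return(peaks)
  ord <- order(-x[peaks], peaks)
  keep <- logical(length(peaks))
  for (k in ord) {
    if (!any(keep & abs(peaks - peaks[k]) < min_sep)) keep[k] <- TRUE
  }
  sort(peaks[keep])
}

#' Detect heel-strike events on the thigh pitch angle
#'
#' Finds local maxima of the thigh sagittal inclination and filters them by
#' prominence, absolute height, and pairwise sample separation. Only the
#' thigh inclination channel is consulted; all other channels are ignored.
#'
#' @param recording An [inertial_recording()].
#' @param config A [step_detector_config()].
#' @return Strictly increasing integer vector of sample indices, one per
#'   detected heel strike.
#' @export
detect_step_events <- function(recording, config = step_detector_config()) {
  stopifnot(inherits(recording, "inertial_recording"),
            inherits(config, "step_detector_config"))
  x <- recording$thigh$incl
  peaks <- local_maxima(x)
  peaks <- peaks[x[peaks] >= config$min_height]
  if (length(peaks)) {
    peaks <- peaks[peak_prominences(x, peaks) >= config$prominence]
  }
  enforce_separation(x, peaks, config$min_separation)
}

#' Cut detected events into per-stride time windows
#'
#' Every interval between two consecutive heel strikes shorter than the
#' maximum gait-cycle duration becomes one stride window (a full stride of
#' the instrumented leg, heel strike to next heel strike). Longer intervals
#' are standing periods and are discarded.
#'
#' @param events Sorted integer sample indices from [detect_step_events()].
#' @param timestamps Sample times of the recording, seconds.
#' @param config A [step_detector_config()].
#' @return A data.frame with one row per window: `start_index`, `end_index`
#'   (half-open `[start, end)`), `start_time`, `end_time`.
#' @export
segment_steps <- function(events, timestamps, config = step_detector_config()) {
  stopifnot(inherits(config, "step_detector_config"))
  if (is.unsorted(events, strictly = TRUE)) {
    stop("segment_steps: events must be strictly increasing")
  }
  if (length(events) && (min(events) < 1L || max(events) > length(timestamps))) {
    stop("segment_steps: event index out of range")
  }
  empty <- data.frame(start_index = integer(0), end_index = integer(0),
                      start_time = numeric(0), end_time = numeric(0))
  if (length(events) < 2L) return(empty)
  a <- events[-length(events)]
  b <- events[-1L]
  ok <- (timestamps[b] - timestamps[a]) < config$max_cycle_duration
  data.frame(start_index = as.integer(a[ok]), end_index = as.integer(b[ok]),
             start_time = timestamps[a[ok]], end_time = timestamps[b[ok]])
}
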