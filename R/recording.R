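#' Two-sensor inertial recording for one trial
#'
#' Bundles the synchronised channels of a thigh- and shank-mounted IMU:
#' sagittal-plane inclination (radians), three-axis angular velocity (rad/s)
#' and three-axis acceleration (m/s^2), sampled at a nominal ~30 Hz. Only the
#' two inclination channels feed the downstream stride features; the remaining
#' channels are carried so that a full trial round-trips through the CSV trial
#' format unchanged.
#'
#' @param timestamps Numeric vector of sample times in seconds, strictly
#'   increasing, length >= 2.
#' @param thigh,shank Lists with elements `incl` (numeric), `gyro` (n x 3
#'   matrix) and `accel` (n x 3 matrix), each matching `timestamps` in length.
#' @param subject_id,trial_id Identifiers carried through to labeled samples.
#' @return An object of class `inertial_recording`.
#' @export
inertial_recording <- function(timestamps, thigh, shank,
                               subject_id = "S1", trial_id = "T1") {
  n <- length(timestamps)
  if (n < 2L) {
    stop("inertial_recording: need at least 2 samples, got ", n)
  }
  if (any(diff(timestamps) <= 0)) {
    stop("inertial_recording: timestamps must be strictly increasing")
  }
  for (side in list(thigh = thigh, shank = shank)) {
    stopifnot(length(side$incl) == n,
              nrow(side$gyro) == n, ncol(side$gyro) == 3L,
              nrow(side$accel) == n, ncol(side$accel) == 3L)
  }
  structure(
    list(timestamps = as.numeric(timestamps),
         thigh = thigh, shank = shank,
         subject_id = subject_id, trial_id = trial_id),
    class = "inertial_recording")
}

#' @export
print.inertial_recording <- function(x, ...) {
  dur <- diff(range(x$timestamps))
  cat(sprintf(
    "<inertial_recording> subject=%s trial=%s  %d samples, %.1f s (~%.1f Hz)\n",
    x$subject_id, x$trial_id, length(x$timestamps),
    dur, (length(x$timestamps) - 1) / dur))
  invisible(x)
}

# Column layout of the CSV trial format, fixed order.
trial_csv_columns <- function() {
  c("time_s",
    "thigh_incl", "thigh_gx", "thigh_gy", "thigh_gz",
    "thigh_ax", "thigh_ay", "thigh_az",
    "shank_incl", "shank_gx", "shank_gy", "shank_gz",
    "shank_ax", "shank_ay", "shank_az")
}

#' Write a trial to the CSV trial format
#'
#' One file per trial; columns `time_s`, then thigh inclination, gyro (x,y,z)
#' and accelerometer (x,y,z), then the same block for the shank. UTF-8 with
#' `.` decimal separator.
#'
#' @param recording An [inertial_recording()].
#' @param file Path to write.
#' @return `file`, invisibly.
#' @export
write_trial_csv <- function(recording, file) {
  df <- data.frame(
    time_s = recording$timestamps,
    thigh_incl = recording$thigh$incl,
    recording$thigh$gyro, recording$thigh$accel,
    shank_incl = recording$shank$incl,
    recording$shank$gyro, recording$shank$accel)
  names(df) <- trial_csv_columns()
  utils::write.csv(df, file, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}

#' Read a trial from the CSV trial format
#'
#' @param file Path to a trial CSV written in the package's trial layout.
#' @param subject_id,trial_id Identifiers to attach (the format itself does
#'   not carry them; they live in the file name or an external manifest).
#' @return An [inertial_recording()].
#' @export
read_trial_csv <- function(file, subject_id = "S1", trial_id = "T1") {
  df <- utils::read.csv(file, fileEncoding = "UTF-8")
  missing <- setdiff(trial_csv_columns(), names(df))
  if (length(missing)) {
    stop("read_trial_csv: missing columns: ", paste(missing, collapse = ", "))
  }
  side <- function(prefix) {
    list(incl = df[[paste0(prefix, "_incl")]],
         gyro = as.matrix(df[paste0(prefix, c("_gx", "_gy", "_gz"))]),
         accel = as.matrix(df[paste0(prefix, c("_ax", "_ay", "_az"))]))
  }
  inertial_recording(df$time_s, side("thigh"), side("shank"),
                     subject_id = subject_id, trial_id = trial_id)
}
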