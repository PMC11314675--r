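#' Parameters of the synthetic gait generator
#'
#' The generator emulates the ~30 Hz two-IMU recordings the pipeline
#' ingests: piecewise-periodic thigh and shank sagittal inclination whose
#' amplitude, period and shank phase depend on the activity class, with
#' additive Gaussian sensor noise and multiplicative per-subject amplitude
#' variability. Thigh peak amplitudes sit above the 1.6 rad heel-strike
#' detection threshold for every class so that stride detection is
#' well-posed by construction.
#'
#' @param sampling_rate Hz.
#' @param stride_period Seconds per stride, named by class.
#' @param thigh_amplitude Thigh inclination peak, radians, named by class.
#' @param shank_amplitude,shank_offset,shank_phase Shank waveform shape per
#'   class (amplitude rad, baseline offset rad, phase shift rad); ascent
#'   and descent differ in phase and offset so the classes are separable.
#' @param noise_sd Additive Gaussian noise on the inclination channels, rad.
#' @param subject_sd Standard deviation of the per-subject multiplicative
#'   amplitude factor (mean 1).
#' @param seed Integer seed; generation is a pure function of parameters,
#'   identifiers and this seed.
#' @return An object of class `gait_generator_params`.
#' @export
gait_generator_params <- function(
    sampling_rate = 30,
    stride_period = c(walk = 1.1, stairs_up = 1.4, stairs_down = 1.2),
    thigh_amplitude = c(walk = 1.8, stairs_up = 2.1, stairs_down = 1.9),
    shank_amplitude = c(walk = 0.9, stairs_up = 1.3, stairs_down = 1.15),
    shank_offset = c(walk = 0.20, stairs_up = 0.50, stairs_down = -0.15),
    shank_phase = c(walk = 0, stairs_up = 0.9, stairs_down = -0.9),
    noise_sd = 0.05, subject_sd = 0.08, seed = 1L) {
  stopifnot(sampling_rate > 0, all(stride_period > 0), all(thigh_amplitude > 0),
            noise_sd >= 0, subject_sd >= 0)
  structure(list(sampling_rate = sampling_rate, stride_period = stride_period,
                 thigh_amplitude = thigh_amplitude,
                 shank_amplitude = shank_amplitude,
                 shank_offset = shank_offset, shank_phase = shank_phase,
                 noise_sd = noise_sd, subject_sd = subject_sd,
                 seed = as.integer(seed)),
            class = "gait_generator_params")
}

# Deterministic small integer derived from a string, for folding
# identifiers into the seed. Kept well below 2^31.
id_hash <- function(s) {
  h <- 0L
  for (ch in utf8ToInt(as.character(s))) h <- (h * 31L + ch) %% 1000003L
  h
}

#' Generate a labeled synthetic gait recording
#'
#' Produces one trial: an [inertial_recording()] whose thigh inclination is
#' a rectified sinusoid peaking once per stride (the synthetic heel
#' strike), plus ground-truth stride windows. Gyroscope channels carry the
#' waveform's first derivative and accelerometer channels its second
#' derivative (plus gravity on the vertical axis), so the full CSV schema
#' is exercised even though only the inclinations feed the features.
#'
#' @param schedule Data.frame with columns `activity` and `n_strides`, in
#'   execution order (e.g. 20 walking strides, then 10 stair-ascent).
#' @param params A [gait_generator_params()].
#' @param subject_id,trial_id Identifiers; the subject id also selects the
#'   subject's amplitude factor, the pair selects the noise stream.
#' @return List with `recording` and `truth` (data.frame of ground-truth
#'   windows: `start_time`, `end_time`, `start_index`, `end_index`,
#'   `label`).
#' @export
generate_gait_recording <- function(schedule, params = gait_generator_params(),
                                    subject_id = "S1", trial_id = "T1") {
  stopifnot(nrow(schedule) >= 1L,
            all(schedule$activity %in% activity_classes()),
            all(schedule$n_strides >= 1L))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  # per-subject amplitude factor (one draw per sensor), then trial noise
  set.seed((params$seed * 7L + id_hash(subject_id)) %% 2000000000L)
  fac <- stats::rnorm(2L, mean = 1, sd = params$subject_sd)
  set.seed((params$seed * 13L + id_hash(subject_id) * 5L +
              id_hash(trial_id)) %% 2000000000L)

  # stride timeline: start time, duration and class of every stride
  classes <- rep(as.character(schedule$activity), schedule$n_strides)
  durs <- params$stride_period[classes]
  starts <- c(0, cumsum(durs))[seq_along(durs)]
  total <- sum(durs)

  dt <- 1 / params$sampling_rate
  t <- seq(0, total - dt / 2, by = dt)
  stride_of <- findInterval(t, c(starts, total), rightmost.closed = TRUE)
  stride_of <- pmin(pmax(stride_of, 1L), length(classes))
  u <- (t - starts[stride_of]) / durs[stride_of] # phase in [0, 1)
  cls <- classes[stride_of]

  # detection threshold floor keeps every subject's peaks detectable
  floor_amp <- 1.6 + 3 * params$noise_sd + 0.02
  thigh_amp <- pmax(params$thigh_amplitude[cls] * fac[1L], floor_amp)
  thigh <- unname(thigh_amp * abs(sin(pi * u)))
  shank_amp <- pmax(params$shank_amplitude[cls] * fac[2L], 0.05)
  shank <- unname(params$shank_offset[cls] +
                    shank_amp * abs(sin(pi * u + params$shank_phase[cls])))

  n <- length(t)
  noisy <- function(x) x + stats::rnorm(n, sd = params$noise_sd)
  thigh_n <- noisy(thigh); shank_n <- noisy(shank)
  deriv <- function(x) c(diff(x) / dt, 0)
  channels <- function(incl) {
    g <- cbind(deriv(incl), stats::rnorm(n, sd = 0.1), stats::rnorm(n, sd = 0.1))
    a <- cbind(deriv(deriv(incl)) * 0.05, stats::rnorm(n, sd = 0.2),
               9.81 + stats::rnorm(n, sd = 0.2))
    list(gyro = g, accel = a)
  }
  th_ch <- channels(thigh_n); sh_ch <- channels(shank_n)
  rec <- inertial_recording(
    t,
    thigh = list(incl = thigh_n, gyro = th_ch$gyro, accel = th_ch$accel),
    shank = list(incl = shank_n, gyro = sh_ch$gyro, accel = sh_ch$accel),
    subject_id = subject_id, trial_id = trial_id)

  # ground truth: heel-strike peaks at mid-stride, windows between them
  peak_times <- starts + durs / 2
  k <- length(peak_times)
  w_start <- peak_times[-k]; w_end <- peak_times[-1L]
  lab <- classes[-k]
  # a window straddling two activity bouts has mixed-class content; it is
  # flagged so dataset assembly can skip it (activity spans are labeled,
  # transitions between spans are not)
  pure <- classes[-k] == classes[-1L]
  truth <- data.frame(
    start_time = w_start, end_time = w_end,
    start_index = findInterval(w_start, t), end_index = findInterval(w_end, t),
    label = factor(lab, levels = activity_classes()), pure = pure)
  list(recording = rec, truth = truth)
}

#' Generate a multi-subject labeled sample set
#'
#' Runs the synthetic generator and the real segmentation/feature pipeline
#' for several subjects and trials, returning the labeled samples the
#' evaluation protocols consume. Window labels come from the generator's
#' ground truth (nearest window by start time).
#'
#' @param n_subjects,trials_per_subject Cohort size.
#' @param schedule Per-trial activity schedule (see
#'   [generate_gait_recording()]); the default mixes walking with both
#'   stair classes, walking represented about twice as often.
#' @param params A [gait_generator_params()].
#' @param config A [step_detector_config()].
#' @return Labeled sample data.frame (raw features).
#' @export
generate_har_dataset <- function(n_subjects, trials_per_subject = 1L,
                                 schedule = NULL,
                                 params = gait_generator_params(),
                                 config = step_detector_config()) {
  if (is.null(schedule)) {
    schedule <- data.frame(
      activity = c("walk", "stairs_up", "walk", "stairs_down"),
      n_strides = c(12L, 11L, 12L, 11L))
  }
  out <- list()
  for (s in seq_len(n_subjects)) {
    for (tr in seq_len(trials_per_subject)) {
      sid <- sprintf("S%02d", s); tid <- sprintf("T%02d", tr)
      gen <- generate_gait_recording(schedule, params, sid, tid)
      events <- detect_step_events(gen$recording, config)
      windows <- segment_steps(events, gen$recording$timestamps, config)
      if (nrow(windows) == 0L) next
      nearest <- vapply(windows$start_time, function(ts) {
        which.min(abs(gen$truth$start_time - ts))
      }, integer(1L))
      keep <- gen$truth$pure[nearest]
      if (!any(keep)) next
      labels <- gen$truth$label[nearest[keep]]
      out[[length(out) + 1L]] <- make_labeled_samples(
        gen$recording, windows[keep, , drop = FALSE], labels)
    }
  }
  do.call(rbind, out)
}

#' Write ground-truth stride windows as a sidecar CSV
#'
#' @param truth Truth table from [generate_gait_recording()].
#' @param file Path to write.
#' @return `file`, invisibly.
#' @export
write_truth_csv <- function(truth, file) {
  utils::write.csv(truth, file, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}
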