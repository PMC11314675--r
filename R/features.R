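#' @keywords internal
feature_names <- function() {
  as.vector(t(outer(c("shank", "thigh"),
                    c("min", "max", "mean", "sd", "range"),
                    paste, sep = "_")))
}

# Population standard deviation (divide by n, not n - 1); the per-stride
# window is treated as the complete cycle, not a sample from one.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Per-stride inclination feature vector
#'
#' Computes the 10-element stride descriptor: minimum, maximum, mean,
#' standard deviation and range of the shank and thigh sagittal inclination
#' over one stride window, in the fixed order
#' `shank_{min,max,mean,sd,range}, thigh_{min,max,mean,sd,range}`.
#' Gyroscope and accelerometer channels are deliberately not used: the
#' inclination statistics carry the class signal for walking versus stair
#' ascent/descent.
#'
#' @param recording An [inertial_recording()].
#' @param window One row of the data.frame from [segment_steps()] (or any
#'   list with `start_index` and `end_index`, half-open).
#' @return Named numeric vector of length 10.
#' @export
extract_features <- function(recording, window) {
  i0 <- window$start_index
  i1 <- window$end_index
  n <- length(recording$timestamps)
  if (is.null(i0) || is.null(i1) || i0 < 1L || i1 > n + 1L || i1 - i0 < 2L) {
    stop("extract_features: window must cover at least 2 samples inside the recording")
  }
  idx <- seq.int(i0, i1 - 1L)
  stats_of <- function(x) {
    c(min(x), max(x), mean(x), sd_pop(x), max(x) - min(x))
  }
  out <- c(stats_of(recording$shank$incl[idx]),
           stats_of(recording$thigh$incl[idx]))
  names(out) <- feature_names()
  out
}

#' Extract the feature matrix for all windows of a recording
#'
#' @param recording An [inertial_recording()].
#' @param windows Data.frame from [segment_steps()].
#' @return Numeric matrix, one row per window, 10 named columns.
#' @export
extract_feature_matrix <- function(recording, windows) {
  m <- t(vapply(seq_len(nrow(windows)),
                function(i) extract_features(recording, windows[i, ]),
                numeric(10L)))
  colnames(m) <- feature_names()
  m
}

#' Fit a min-max scaler on a training feature matrix
#'
#' Records the column-wise minimum and maximum so features can be mapped
#' onto the unit interval. Fit on training folds only and applied unchanged
#' to test folds, so no information leaks across a cross-validation split.
#'
#' @param training_features Numeric matrix (rows = samples).
#' @return An object of class `scaler_params` with fields `min` and `max`.
#' @export
fit_scaler <- function(training_features) {
  m <- as.matrix(training_features)
  if (nrow(m) < 1L) stop("fit_scaler: need at least one training sample")
  structure(list(min = apply(m, 2L, min), max = apply(m, 2L, max)),
            class = "scaler_params")
}

#' Scale features onto the unit interval
#'
#' Applies `(x - min) / (max - min)` per column. Values outside the training
#' range map outside `[0, 1]` (no clipping, so ordering is preserved);
#' degenerate zero-range columns map to 0.
#'
#' @param params A fitted [fit_scaler()] result.
#' @param features Numeric vector (one sample) or matrix (rows = samples).
#' @return Scaled object of the same shape.
#' @export
apply_scaler <- function(params, features) {
  stopifnot(inherits(params, "scaler_params"))
  one <- is.null(dim(features))
  m <- if (one) matrix(features, nrow = 1L) else as.matrix(features)
  rng <- params$max - params$min
  scaled <- sweep(m, 2L, params$min, "-")
  scaled <- sweep(scaled, 2L, ifelse(rng > 0, rng, 1), "/")
  scaled[, rng == 0] <- 0
  colnames(scaled) <- names(params$min)
  if (one) scaled[1L, ] else scaled
}

#' Write a labeled feature table as CSV
#'
#' Serialises the 10 feature columns plus `label`, `subject_id`, `trial_id`.
#'
#' @param samples A labeled sample table (see [make_labeled_samples()]).
#' @param file Path to write.
#' @return `file`, invisibly.
#' @export
write_feature_csv <- function(samples, file) {
  utils::write.csv(samples[c(feature_names(), "label", "subject_id", "trial_id")],
                   file, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}

#' Read a labeled feature table from CSV
#'
#' @param file Path to a CSV written by [write_feature_csv()].
#' @return Data.frame of labeled samples.
#' @export
read_feature_csv <- function(file) {
  df <- utils::read.csv(file, fileEncoding = "UTF-8")
  missing <- setdiff(c(feature_names(), "label", "subject_id", "trial_id"), names(df))
  if (length(missing)) {
    stop("read_feature_csv: missing columns: ", paste(missing, collapse = ", "))
  }
  df$label <- factor(df$label, levels = activity_classes())
  df
}
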