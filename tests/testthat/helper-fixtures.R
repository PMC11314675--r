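# Shared fixture builders. All geometric fixtures live on a local metric
# plane anchored at (lon 10, lat 48) and are converted to WGS84 through the
# same projection the package uses.

fix_proj <- local_projection(c(10, 48))

# path_record from local metric coordinates
mpath <- function(xy, type = "trail", ...) {
  path_record(fix_proj$unproject(rbind(xy)), path_type = type, ...)
}

# straight metric line with n vertices
line_xy <- function(x0, y0, x1, y1, n = 50) {
  cbind(seq(x0, x1, length.out = n), seq(y0, y1, length.out = n))
}

# minimal recording with a given thigh inclination signal (shank mirrors it
# unless given); other channels are zeros
make_recording <- function(thigh_incl, rate = 30, shank_incl = NULL,
                           subject_id = "S1", trial_id = "T1") {
  n <- length(thigh_incl)
  if (is.null(shank_incl)) shank_incl <- thigh_incl
  zeros <- matrix(0, n, 3L)
  inertial_recording(
    timestamps = seq(0, by = 1 / rate, length.out = n),
    thigh = list(incl = thigh_incl, gyro = zeros, accel = zeros),
    shank = list(incl = shank_incl, gyro = zeros, accel = zeros),
    subject_id = subject_id, trial_id = trial_id)
}

# well-separated three-class Gaussian feature clusters (already "scaled")
cluster_samples <- function(n_per_class = 10, sep = 5, sd = 0.05, seed = 42) {
  set.seed(seed)
  centers <- list(walk = rep(0.2, 10), stairs_up = rep(0.2, 10) + sep * 0.1,
                  stairs_down = rep(0.2, 10) - sep * 0.1)
  rows <- lapply(names(centers), function(cls) {
    m <- matrix(rnorm(n_per_class * 10, sd = sd), ncol = 10, byrow = TRUE)
    m <- sweep(m, 2L, centers[[cls]], "+")
    df <- as.data.frame(m)
    names(df) <- stridemap:::feature_names()
    df$label <- cls
    df
  })
  out <- do.call(rbind, rows)
  out$label <- factor(out$label, levels = activity_classes())
  out$subject_id <- rep(sprintf("S%02d", seq_len(n_per_class)), times = 3)
  out$trial_id <- "T01"
  out$start_time <- seq_len(nrow(out))
  out
}

expect_consistent <- function(store) {
  expect_length(audit_consistency(store), 0L)
}
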