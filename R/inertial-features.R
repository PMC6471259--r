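#' Windowed statistical features for the inertial modalities
#'
#' The fused segment is divided into M equal-duration windows (default
#' M = 6). For each window, sensor site, and axis, the per-axis mean,
#' population standard deviation, and variance of the raw in-window
#' samples are computed, for the gyroscope and accelerometer channels
#' separately. Stacking the four sites (order EL, ER, AL, AR) gives an
#' `M x 4 x 9` feature array per channel, the statistics ordered
#' `(mu_x, mu_y, mu_z, sd_x, sd_y, sd_z, var_x, var_y, var_z)`.
#'
#' @name inertial-features
NULL

.STAT_NAMES <- c("mu_x", "mu_y", "mu_z", "sd_x", "sd_y", "sd_z",
                 "var_x", "var_y", "var_z")

#' @describeIn inertial-features Split a fused segment into M equal,
#'   contiguous, half-open windows `[a, b)`; the last window is closed at
#'   the segment end so the union is exactly the segment.
#' @param segment a `fused_segment` (or any list with `t_start`,
#'   `t_end`).
#' @param M number of windows (>= 1).
#' @return `window_bounds`: an `M x 2` matrix with columns `start`,
#'   `end`.
#' @export
window_bounds <- function(segment, M = 6L) {
  if (M < 1L) {
    stop("M must be at least 1")
  }
  if (!(segment$t_end > segment$t_start)) {
    stop("segment duration must be positive")
  }
  edges <- seq(segment$t_start, segment$t_end, length.out = M + 1L)
  cbind(start = edges[-(M + 1L)], end = edges[-1L])
}

#' @describeIn inertial-features Windowed statistics of one stream's
#'   3-axis channel: an `M x 9` matrix, row w holding the in-window mean,
#'   population standard deviation, and variance per axis. A window
#'   containing no samples (possible only at degraded sampling rates)
#'   carries the previous window's statistics forward; an empty first
#'   window is an error.
#' @param stream an [imu_stream()].
#' @param channel `"gyro"` or `"accel"`.
#' @param config a [windowing_config()].
#' @export
windowed_stats <- function(stream, channel = c("gyro", "accel"),
                           segment, config = windowing_config()) {
  stopifnot(inherits(stream, "imu_stream"))
  channel <- match.arg(channel)
  M <- config$M
  bounds <- window_bounds(segment, M)
  x <- stream[[channel]]
  out <- matrix(NA_real_, nrow = M, ncol = 9L,
                dimnames = list(NULL, .STAT_NAMES))
  for (w in seq_len(M)) {
    if (w < M) {
      inw <- stream$time >= bounds[w, 1] & stream$time < bounds[w, 2]
    } else {
      inw <- stream$time >= bounds[w, 1] & stream$time <= bounds[w, 2]
    }
    n <- sum(inw)
    if (n == 0L) {
      if (w == 1L) {
        stop("first window of segment contains no ", channel,
             " samples (site ", stream$site, ")")
      }
      out[w, ] <- out[w - 1L, ]
      next
    }
    xs <- x[inw, , drop = FALSE]
    mu <- colMeans(xs)
    v <- colMeans(xs^2) - mu^2
    v[v < 0] <- 0  # guard tiny negative from cancellation
    out[w, ] <- c(mu, sqrt(v), v)
  }
  out
}

#' Windowing configuration
#'
#' @param M number of equal time partitions of the fused segment
#'   (default 6).
#' @export
windowing_config <- function(M = 6L) {
  if (M < 1L) {
    stop("M must be at least 1")
  }
  structure(list(M = as.integer(M)), class = "windowing_config")
}

#' @describeIn inertial-features Full inertial feature arrays of a trial:
#'   for each channel, the four sites' windowed statistics stacked in
#'   fixed order EL, ER, AL, AR into an `M x 4 x 9` array.
#' @param trial a [trial()].
#' @param segment the trial's `fused_segment`.
#' @return `inertial_features`: list with elements `gyro` and `accel`,
#'   each an `M x 4 x 9` array (window x site x statistic).
#' @export
inertial_features <- function(trial, segment, config = windowing_config()) {
  stopifnot(inherits(trial, "trial"))
  M <- config$M
  build <- function(channel) {
    arr <- array(NA_real_, dim = c(M, 4L, 9L),
                 dimnames = list(NULL, sensor_sites(), .STAT_NAMES))
    for (s in sensor_sites()) {
      arr[, s, ] <- windowed_stats(trial$imu[[s]], channel, segment, config)
    }
    arr
  }
  list(gyro = build("gyro"), accel = build("accel"))
}

#' @describeIn inertial-features Flatten an `M x 4 x 9` feature array to
#'   an `M x 36` matrix: per window, the four sites' 9 statistics are
#'   concatenated in site order. Each row is one step of the inertial
#'   input sequence for the sequence classifier;
#'   `as.vector(t(flatten_inertial(arr)))` is the window-major
#'   concatenation used by the SVM baseline.
#' @param arr an `M x 4 x 9` array from [inertial_features()].
#' @export
flatten_inertial <- function(arr) {
  stopifnot(length(dim(arr)) == 3L, dim(arr)[2] == 4L, dim(arr)[3] == 9L)
  M <- dim(arr)[1]
  out <- matrix(aperm(arr, c(3L, 2L, 1L)), nrow = M, byrow = TRUE)
  colnames(out) <- paste0(rep(sensor_sites(), each = 9L), ".",
                          rep(.STAT_NAMES, times = 4L))
  out
}

#' @describeIn inertial-features Inverse of [flatten_inertial()].
#' @param mat an `M x 36` matrix.
#' @export
unflatten_inertial <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) == 36L)
  arr <- aperm(array(t(mat), dim = c(9L, 4L, nrow(mat))), c(3L, 2L, 1L))
  dimnames(arr) <- list(NULL, sensor_sites(), .STAT_NAMES)
  arr
}
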