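#' Activity segmentation by relative difference thresholds
#'
#' Each modality yields a nonnegative per-step difference signal: the
#' Euclidean distance between consecutive skeleton centroids for the depth
#' camera, and the Euclidean norm of consecutive-sample differences for
#' each gyroscope and accelerometer. Steps whose difference exceeds a
#' fixed fraction (default 5%) of that signal's own maximum are treated as
#' movement; the per-sensor spans are fused by taking the earliest start
#' and the latest end.
#'
#' @name segmentation
NULL

#' @describeIn segmentation Component-wise mean of the 25 joint positions
#'   of one frame.
#' @param frame a named 25 x 3 joint matrix (see [skeleton_frame()]).
#' @return `compute_centroid`: numeric 3-vector.
#' @export
compute_centroid <- function(frame) {
  stopifnot(is.matrix(frame), nrow(frame) == 25L, ncol(frame) == 3L)
  colMeans(frame)
}

#' @describeIn segmentation Construct a difference series directly (values
#'   must be nonnegative; one timestamp per value).
#' @param time,values,source series timestamps, nonnegative magnitudes,
#'   and a modality tag such as `"depth"` or `"gyro@EL"`.
#' @export
difference_series <- function(time, values, source) {
  stopifnot(length(time) == length(values), all(values >= 0))
  structure(list(t = as.numeric(time), values = as.numeric(values),
                 source = source),
            class = "difference_series")
}

.difference_series <- function(time, values, source) {
  structure(list(t = time, values = values, source = source),
            class = "difference_series")
}

#' @describeIn segmentation Per-step centroid displacement of a skeleton
#'   sequence. The value at output position `t` is the distance between
#'   the centroids of frames `t` and `t + 1`, timestamped at the later
#'   frame; length is `frames - 1`.
#' @param seq a [skeleton_sequence()].
#' @return a `difference_series`: list with `t`, nonnegative `values`,
#'   and a `source` tag.
#' @export
centroid_difference_series <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  cent <- apply(seq$joints, c(1L, 3L), mean)      # T x 3
  d <- diff(cent)
  .difference_series(seq$time[-1], sqrt(rowSums(d^2)), "depth")
}

#' @describeIn segmentation Per-step difference magnitude of one 3-axis
#'   IMU channel.
#' @param stream an [imu_stream()].
#' @param channel `"gyro"` or `"accel"`.
#' @export
imu_difference_series <- function(stream, channel = c("gyro", "accel")) {
  stopifnot(inherits(stream, "imu_stream"))
  channel <- match.arg(channel)
  d <- diff(stream[[channel]])
  .difference_series(stream$time[-1], sqrt(rowSums(d^2)),
                     paste0(channel, "@", stream$site))
}

#' Segmentation configuration
#'
#' @param threshold_fraction fraction of a difference signal's maximum
#'   above which a step counts as movement (default 0.05, i.e. the 5%
#'   level). Must lie strictly between 0 and 1.
#' @param resample_points number of points all modality signals are
#'   resampled to on the fused segment (default 60, about two seconds of
#'   skeleton frames at 30 Hz).
#' @return a `segmentation_config` list.
#' @export
segmentation_config <- function(threshold_fraction = 0.05,
                                resample_points = 60L) {
  if (!(threshold_fraction > 0 && threshold_fraction < 1)) {
    stop("threshold_fraction must be in (0, 1)")
  }
  if (resample_points < 2L) {
    stop("resample_points must be at least 2")
  }
  structure(list(threshold_fraction = threshold_fraction,
                 resample_points = as.integer(resample_points)),
            class = "segmentation_config")
}

#' @describeIn segmentation Detect the active span of one difference
#'   series: from the first to the last value strictly above
#'   `threshold_fraction * max(values)`. Returns `NULL` when the series
#'   is identically zero (no movement). Ties at exactly the threshold are
#'   excluded.
#' @param series a `difference_series`.
#' @param config a [segmentation_config()].
#' @return `detect_span`: a `span` (list `t_start`, `t_end`, `source`)
#'   or `NULL`.
#' @export
detect_span <- function(series, config = segmentation_config()) {
  stopifnot(inherits(series, "difference_series"),
            length(series$values) > 0L)
  mx <- max(series$values)
  if (mx == 0) {
    return(NULL)
  }
  above <- which(series$values > config$threshold_fraction * mx)
  structure(list(t_start = series$t[above[1]],
                 t_end = series$t[above[length(above)]],
                 source = series$source),
            class = "span")
}

#' @describeIn segmentation Fuse per-sensor spans: earliest start, latest
#'   end. Spans that were `NULL` (static sensors) should be dropped by the
#'   caller; an empty input means no sensor saw movement and is an error.
#' @param spans nonempty list of `span` objects.
#' @return `fuse_spans`: a `fused_segment` (list `t_start`, `t_end`,
#'   `contributing`).
#' @export
fuse_spans <- function(spans) {
  spans <- Filter(Negate(is.null), spans)
  if (length(spans) == 0L) {
    stop("no activity detected: every difference signal was static")
  }
  starts <- vapply(spans, `[[`, numeric(1), "t_start")
  ends <- vapply(spans, `[[`, numeric(1), "t_end")
  structure(list(t_start = min(starts), t_end = max(ends),
                 contributing = spans),
            class = "fused_segment")
}

#' @describeIn segmentation Segment a whole trial: one centroid series,
#'   four gyroscope series, and four accelerometer series are thresholded
#'   and their nine spans fused. Downstream feature extraction consumes
#'   only data inside the fused segment.
#' @param trial a [trial()].
#' @export
segment_trial <- function(trial, config = segmentation_config()) {
  stopifnot(inherits(trial, "trial"))
  series <- c(list(centroid_difference_series(trial$skeleton)),
              lapply(trial$imu, imu_difference_series, channel = "gyro"),
              lapply(trial$imu, imu_difference_series, channel = "accel"))
  fuse_spans(lapply(series, detect_span, config = config))
}

#' Resample a multichannel series to uniformly spaced points
#'
#' Linear interpolation at `n_points` uniformly spaced timestamps spanning
#' the input's time range; the first and last output points equal the
#' first and last input points exactly.
#'
#' @param time numeric timestamps, strictly increasing, length >= 2.
#' @param values numeric vector or `length(time) x d` matrix.
#' @param n_points number of output points (>= 2).
#' @return list with `time` (length `n_points`) and `values`
#'   (`n_points x d` matrix).
#' @export
resample_uniform <- function(time, values, n_points) {
  if (n_points < 2L) {
    stop("n_points must be at least 2")
  }
  if (length(time) < 2L) {
    stop("need at least 2 input points to resample")
  }
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(time))
  t_out <- seq(time[1], time[length(time)], length.out = n_points)
  out <- apply(values, 2L, function(v) {
    stats::approx(time, v, xout = t_out, rule = 2)$y
  })
  dim(out) <- c(n_points, ncol(values))
  # endpoints exact regardless of interpolation rounding
  out[1, ] <- values[1, ]
  out[n_points, ] <- values[nrow(values), ]
  list(time = t_out, values = out)
}
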