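#' Skeleton sequence container
#'
#' A time-ordered sequence of skeleton frames. Joint positions are stored
#' as a `T x 25 x 3` numeric array (frames x joints x xyz, meters), with
#' joints in [kinect_joints()] order and a strictly increasing timestamp
#' vector in seconds relative to trial start.
#'
#' @param time numeric vector of frame timestamps (seconds), strictly
#'   increasing, length >= 2.
#' @param joints numeric array `length(time) x 25 x 3`.
#' @param rate_hz nominal sampling rate (Hz).
#' @return an object of class `skeleton_sequence` with elements `time`,
#'   `joints`, `rate_hz`.
#' @export
skeleton_sequence <- function(time, joints, rate_hz = 30) {
  time <- as.numeric(time)
  if (length(time) < 2L) {
    stop("skeleton_sequence needs at least 2 frames")
  }
  if (any(diff(time) <= 0)) {
    stop("skeleton timestamps must be strictly increasing")
  }
  joints <- unname(joints)
  if (length(dim(joints)) != 3L ||
      dim(joints)[1] != length(time) ||
      dim(joints)[2] != 25L || dim(joints)[3] != 3L) {
    stop("joints must be a T x 25 x 3 array matching length(time)")
  }
  if (!all(is.finite(joints))) {
    stop("skeleton joint coordinates must all be finite")
  }
  dimnames(joints) <- list(NULL, kinect_joints(), c("x", "y", "z"))
  structure(list(time = time, joints = joints, rate_hz = rate_hz),
            class = "skeleton_sequence")
}

#' Extract one frame's joint matrix
#'
#' @param seq a [skeleton_sequence()].
#' @param i frame index.
#' @return a named 25 x 3 matrix of joint positions (meters).
#' @export
skeleton_frame <- function(seq, i) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  m <- seq$joints[i, , , drop = TRUE]
  dim(m) <- c(25L, 3L)
  dimnames(m) <- list(kinect_joints(), c("x", "y", "z"))
  m
}

#' Inertial sensor stream container
#'
#' One body-worn IMU's record: 3-axis gyroscope and 3-axis accelerometer
#' samples with strictly increasing timestamps. Units are whatever the
#' source device delivers; all downstream statistics and thresholds are
#' relative, so no unit conversion is performed.
#'
#' @param time numeric vector of sample timestamps (seconds), strictly
#'   increasing, length >= 2.
#' @param gyro numeric `length(time) x 3` matrix of angular rates.
#' @param accel numeric `length(time) x 3` matrix of accelerations.
#' @param site one of [sensor_sites()].
#' @param rate_hz nominal sampling rate (Hz).
#' @return an object of class `imu_stream`.
#' @export
imu_stream <- function(time, gyro, accel, site, rate_hz = 100) {
  time <- as.numeric(time)
  site <- match.arg(site, sensor_sites())
  if (length(time) < 2L) {
    stop("imu_stream needs at least 2 samples")
  }
  if (any(diff(time) <= 0)) {
    stop("IMU timestamps must be strictly increasing (site ", site, ")")
  }
  gyro <- as.matrix(gyro); accel <- as.matrix(accel)
  dimnames(gyro) <- dimnames(accel) <- NULL
  if (!identical(dim(gyro), c(length(time), 3L)) ||
      !identical(dim(accel), c(length(time), 3L))) {
    stop("gyro and accel must be n x 3 matrices matching length(time)")
  }
  if (!all(is.finite(gyro)) || !all(is.finite(accel))) {
    stop("IMU samples must all be finite (site ", site, ")")
  }
  structure(list(time = time, gyro = gyro, accel = accel,
                 site = site, rate_hz = rate_hz),
            class = "imu_stream")
}

#' Labeled multimodal trial
#'
#' One recorded execution of one behavior by one user: a skeleton sequence
#' plus the four IMU streams. The modality clocks need not share sample
#' instants, but their time ranges must overlap (segment fusion handles
#' alignment).
#'
#' @param trial_id,user_id identifier strings.
#' @param skeleton a [skeleton_sequence()].
#' @param imu named list of the four [imu_stream()]s, names
#'   `r paste(sensor_sites(), collapse = ", ")`.
#' @param label behavior label from [behavior_labels()], or `NA` for an
#'   unlabeled trial awaiting inference.
#' @return an object of class `trial`.
#' @export
trial <- function(trial_id, user_id, skeleton, imu, label = NA_character_) {
  stopifnot(inherits(skeleton, "skeleton_sequence"))
  if (!is.na(label)) {
    label <- match.arg(label, behavior_labels())
  }
  missing_sites <- setdiff(sensor_sites(), names(imu))
  if (length(missing_sites) > 0L) {
    stop("trial ", trial_id, " is missing IMU site(s): ",
         paste(missing_sites, collapse = ", "))
  }
  imu <- imu[sensor_sites()]
  for (s in sensor_sites()) {
    if (!inherits(imu[[s]], "imu_stream")) {
      stop("imu[[\"", s, "\"]] is not an imu_stream")
    }
    if (imu[[s]]$site != s) {
      stop("imu list name ", s, " does not match stream site ",
           imu[[s]]$site)
    }
  }
  skel_rng <- range(skeleton$time)
  for (s in sensor_sites()) {
    rng <- range(imu[[s]]$time)
    if (rng[1] > skel_rng[2] || rng[2] < skel_rng[1]) {
      stop("trial ", trial_id, ": time range of IMU ", s,
           " does not overlap the skeleton sequence")
    }
  }
  structure(list(trial_id = as.character(trial_id),
                 user_id = as.character(user_id),
                 label = label, skeleton = skeleton, imu = imu),
            class = "trial")
}

#' @export
print.trial <- function(x, ...) {
  cat("<trial ", x$trial_id, "> user=", x$user_id,
      " label=", ifelse(is.na(x$label), "<none>", x$label),
      " frames=", length(x$skeleton$time),
      " imu_samples=", length(x$imu[[1]]$time), "\n", sep = "")
  invisible(x)
}
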