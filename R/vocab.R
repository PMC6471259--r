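#' Fixed vocabularies: joints, sensor sites, behavior labels, modalities
#'
#' The skeleton model is the 25-joint Kinect-V2 body, indexed 0-24 in the
#' SDK order. Inertial sensors are worn at four sites: left/right elbow and
#' left/right ankle. Behaviors come from a fixed 10-class vocabulary.
#'
#' @name vocab
NULL

.KINECT_JOINTS <- c(
  "SPINE_BASE", "SPINE_MID", "NECK", "HEAD",
  "SHOULDER_LEFT", "ELBOW_LEFT", "WRIST_LEFT", "HAND_LEFT",
  "SHOULDER_RIGHT", "ELBOW_RIGHT", "WRIST_RIGHT", "HAND_RIGHT",
  "HIP_LEFT", "KNEE_LEFT", "ANKLE_LEFT", "FOOT_LEFT",
  "HIP_RIGHT", "KNEE_RIGHT", "ANKLE_RIGHT", "FOOT_RIGHT",
  "SPINE_SHOULDER", "HAND_TIP_LEFT", "THUMB_LEFT",
  "HAND_TIP_RIGHT", "THUMB_RIGHT"
)

.SENSOR_SITES <- c("EL", "ER", "AL", "AR")

.BEHAVIOR_LABELS <- c("BP", "BB", "LS", "RS", "DS",
                      "LL", "RL", "NW", "AW", "CP")

.MODALITIES <- c("DEPTH", "GYRO", "ACCEL")

#' @describeIn vocab The 25 Kinect-V2 joint names, in SDK index order
#'   (stable index 0-24 given by `position - 1`).
#' @export
kinect_joints <- function() .KINECT_JOINTS

#' @describeIn vocab The 4 inertial sensor sites, in fixed order
#'   left elbow, right elbow, left ankle, right ankle (k = 1..4).
#' @export
sensor_sites <- function() .SENSOR_SITES

#' @describeIn vocab The 10 behavior classes: baseball pitch (BP), baseball
#'   bat (BB), left/right stretch (LS/RS), deep squat (DS), left/right lunge
#'   (LL/RL), normal/abnormal walking (NW/AW), coffee pouring (CP).
#' @export
behavior_labels <- function() .BEHAVIOR_LABELS

#' @describeIn vocab The 3 sensing modalities entering decision fusion.
#' @export
modalities <- function() .MODALITIES

#' @describeIn vocab 0-based stable index of a joint name.
#' @param joint character vector of joint names.
#' @export
joint_index <- function(joint) {
  idx <- match(joint, .KINECT_JOINTS)
  if (anyNA(idx)) {
    stop("unknown joint name(s): ",
         paste(joint[is.na(idx)], collapse = ", "))
  }
  idx - 1L
}
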