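#' Synthetic multimodal recording generator
#'
#' Generates labeled trials with the statistical structure the pipeline
#' consumes: a 25-joint skeleton stream and four IMU streams at different
#' native rates, idle outside a known active window and animated inside
#' it by smooth class-dependent waveforms. Each behavior class has a
#' distinct motion template (dominant limbs, waveform frequency,
#' envelope, per-site amplitude pattern); users differ by body height.
#' The generator makes no biomechanical realism claim - it provides
#' class-separable, segmentable signals with known ground truth.
#'
#' @name synthetic
NULL

#' Generator configuration
#'
#' Defaults emulate the structure of the 1000-trial study design:
#' 10 behaviors x 10 users x 10 repetitions, body heights uniform in
#' 1.29-1.80 m, a 30 Hz skeleton stream and 100 Hz IMU streams over a
#' 10 s recording whose active movement occupies 2-6 s.
#'
#' @param n_users,n_repetitions users and repetitions per behavior.
#' @param behaviors behavior subset (default all 10).
#' @param height_range_m body-height sampling range (meters).
#' @param skeleton_rate_hz,imu_rate_hz native sampling rates.
#' @param trial_duration_s recording length (seconds).
#' @param active_window_s start/end of the true active span (seconds).
#' @param noise_sd named noise scales: `DEPTH` is the per-joint idle
#'   tracking jitter SD in meters, `GYRO`/`ACCEL` are additive sample
#'   noise SDs in signal units. Defaults keep the sensor noise floor far
#'   below the motion signal, as on real recordings, so the relative
#'   difference threshold separates idle from active cleanly.
#' @param signal_scale global multiplier on all motion templates
#'   (0 produces zero-signal recordings, pure noise).
#' @param amplitude_jitter per-trial uniform amplitude variation
#'   (fraction; default 0.1 means x U(0.9, 1.1)).
#' @param seed integer seed making the whole dataset reproducible.
#' @export
generator_config <- function(n_users = 10L, n_repetitions = 10L,
                             behaviors = behavior_labels(),
                             height_range_m = c(1.29, 1.80),
                             skeleton_rate_hz = 30, imu_rate_hz = 100,
                             trial_duration_s = 10,
                             active_window_s = c(2, 6),
                             noise_sd = c(DEPTH = 5e-4, GYRO = 1e-4,
                                          ACCEL = 1e-4),
                             signal_scale = 1, amplitude_jitter = 0.1,
                             seed = 1L) {
  stopifnot(n_users >= 1L, n_repetitions >= 1L,
            all(behaviors %in% behavior_labels()),
            length(height_range_m) == 2L, height_range_m[1] > 0,
            height_range_m[2] >= height_range_m[1],
            skeleton_rate_hz > 0, imu_rate_hz > 0,
            active_window_s[1] >= 0,
            active_window_s[2] > active_window_s[1],
            active_window_s[2] <= trial_duration_s,
            all(c("DEPTH", "GYRO", "ACCEL") %in% names(noise_sd)),
            signal_scale >= 0)
  structure(list(n_users = as.integer(n_users),
                 n_repetitions = as.integer(n_repetitions),
                 behaviors = behaviors, height_range_m = height_range_m,
                 skeleton_rate_hz = skeleton_rate_hz,
                 imu_rate_hz = imu_rate_hz,
                 trial_duration_s = trial_duration_s,
                 active_window_s = active_window_s,
                 noise_sd = noise_sd, signal_scale = signal_scale,
                 amplitude_jitter = amplitude_jitter,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Standing pose in body units (height 1 after rescale): x lateral
# (+left), y up, z forward.
.base_pose <- function() {
  p <- rbind(
    SPINE_BASE = c(0, 0.55, 0), SPINE_MID = c(0, 0.68, 0),
    NECK = c(0, 0.86, 0), HEAD = c(0, 1.00, 0),
    SHOULDER_LEFT = c(0.11, 0.82, 0), ELBOW_LEFT = c(0.19, 0.65, 0),
    WRIST_LEFT = c(0.22, 0.48, 0), HAND_LEFT = c(0.23, 0.43, 0),
    SHOULDER_RIGHT = c(-0.11, 0.82, 0), ELBOW_RIGHT = c(-0.19, 0.65, 0),
    WRIST_RIGHT = c(-0.22, 0.48, 0), HAND_RIGHT = c(-0.23, 0.43, 0),
    HIP_LEFT = c(0.06, 0.52, 0), KNEE_LEFT = c(0.07, 0.28, 0),
    ANKLE_LEFT = c(0.08, 0.04, 0), FOOT_LEFT = c(0.08, 0, 0.05),
    HIP_RIGHT = c(-0.06, 0.52, 0), KNEE_RIGHT = c(-0.07, 0.28, 0),
    ANKLE_RIGHT = c(-0.08, 0.04, 0), FOOT_RIGHT = c(-0.08, 0, 0.05),
    SPINE_SHOULDER = c(0, 0.80, 0), HAND_TIP_LEFT = c(0.24, 0.38, 0),
    THUMB_LEFT = c(0.21, 0.42, 0.02), HAND_TIP_RIGHT = c(-0.24, 0.38, 0),
    THUMB_RIGHT = c(-0.21, 0.42, 0.02))
  p[kinect_joints(), ]
}

.ARM_L <- c("ELBOW_LEFT", "WRIST_LEFT", "HAND_LEFT", "HAND_TIP_LEFT",
            "THUMB_LEFT")
.ARM_R <- c("ELBOW_RIGHT", "WRIST_RIGHT", "HAND_RIGHT", "HAND_TIP_RIGHT",
            "THUMB_RIGHT")
.LEG_L <- c("KNEE_LEFT", "ANKLE_LEFT")
.LEG_R <- c("KNEE_RIGHT", "ANKLE_RIGHT")
.TORSO <- c("SPINE_BASE", "SPINE_MID", "SPINE_SHOULDER", "NECK",
            "HIP_LEFT", "HIP_RIGHT")
# HEAD and the FOOT joints are never animated or jittered, so the body
# height (head to foot midpoint) stays exactly at the drawn user height.
.STATIC_JOINTS <- c("HEAD", "FOOT_LEFT", "FOOT_RIGHT")

.motion <- function(joints, dir, amp, phase = 0) {
  dir <- dir / sqrt(sum(dir^2))
  list(joints = joints, dir = dir, amp = amp, phase = phase)
}

#' Motion template of one behavior class
#'
#' @param behavior one of [behavior_labels()].
#' @return a list describing the class waveform: cycle count over the
#'   active window, envelope type, whole-body sway direction, skeleton
#'   joint-group motions (body units), and per-site gyroscope and
#'   accelerometer amplitudes with per-site phases.
#' @export
behavior_template <- function(behavior) {
  behavior <- match.arg(behavior, behavior_labels())
  tpl <- switch(behavior,
    BP = list(cycles = 6, env = "bump", sway = c(0, 0, 1),
              motions = list(.motion(.ARM_R, c(-0.5, 0.3, 0.8), 0.25)),
              gyro = c(EL = 1.4, ER = 3.5, AL = 1.2, AR = 1.2),
              accel = c(EL = 1.3, ER = 3.0, AL = 1.2, AR = 1.2),
              site_phase = c(EL = 0, ER = 0, AL = 0, AR = 0),
              gyro_offset = c(EL = 0, ER = 0, AL = 0, AR = 0)),
    BB = list(cycles = 4, env = "bump", sway = c(1, 0, 0),
              motions = list(.motion(.ARM_L, c(0.6, 0.1, 0.8), 0.22),
                             .motion(.ARM_R, c(0.6, 0.1, 0.8), 0.22)),
              gyro = c(EL = 3.0, ER = 3.2, AL = 1.2, AR = 1.2),
              accel = c(EL = 2.5, ER = 2.8, AL = 1.2, AR = 1.2),
              site_phase = c(EL = 0, ER = 0, AL = 0, AR = 0),
              gyro_offset = c(EL = 0, ER = 0, AL = 0, AR = 0)),
    LS = list(cycles = 2, env = "const", sway = c(1, 0, 0.3),
              motions = list(.motion(.ARM_L, c(0.2, 0.9, 0), 0.20)),
              gyro = c(EL = 2.5, ER = 1.2, AL = 1.2, AR = 1.2),
              accel = c(EL = 2.0, ER = 1.2, AL = 1.2, AR = 1.2),
              site_phase = c(EL = 0, ER = 0, AL = 0, AR = 0),
              gyro_offset = c(EL = 0, ER = 0, AL = 0, AR = 0)),
    RS = list(cycles = 2, env = "const", sway = c(-1, 0, 0.3),
              motions = list(.motion(.ARM_R, c(-0.2, 0.9, 0), 0.20)),
              gyro = c(EL = 1.2, ER = 2.5, AL = 1.2, AR = 1.2),
              accel = c(EL = 1.2, ER = 2.0, AL = 1.2, AR = 1.2),
              site_phase = c(EL = 0, ER = 0, AL = 0, AR = 0),
              gyro_offset = c(EL = 0, ER = 0, AL = 0, AR = 0)),
    DS = list(cycles = 3, env = "const", sway = c(0, 1, 0),
              motions = list(.motion(.TORSO, c(0, -1, 0), 0.18),
                             .motion(.LEG_L, c(0, -0.5, 0.8), 0.08),
                             .motion(.LEG_R, c(0, -0.5, 0.8), 0.08)),
              gyro = c(EL = 1.2, ER = 1.2, AL = 1.8, AR = 1.8),
              accel = c(EL = 1.4, ER = 1.4, AL = 2.2, AR = 2.2),
              site_phase = c(EL = 0, ER = 0, AL = 0, AR = 0),
              gyro_offset = c(EL = 0, ER = 0, AL = 0, AR = 0)),
    LL = list(cycles = 3, env = "const", sway = c(0, 0.4, 1),
              motions = list(.motion(.LEG_L, c(0, -0.2, 1), 0.20),
                             .motion(.TORSO, c(0, -1, 0), 0.06)),
              gyro = c(EL = 1.2, ER = 1.2, AL = 3.0, AR = 1.3),
              accel = c(EL = 1.2, ER = 1.2, AL = 2.6, AR = 1.3),
              site_phase = c(EL = 0, ER = 0, AL = 0, AR = 0),
              gyro_offset = c(EL = 0, ER = 0, AL = 0, AR = 0)),
    RL = list(cycles = 3, env = "const", sway = c(0, 0.4, -1),
              motions = list(.motion(.LEG_R, c(0, -0.2, 1), 0.20),
                             .motion(.TORSO, c(0, -1, 0), 0.06)),
              gyro = c(EL = 1.2, ER = 1.2, AL = 1.3, AR = 3.0),
              accel = c(EL = 1.2, ER = 1.2, AL = 1.3, AR = 2.6),
              site_phase = c(EL = 0, ER = 0, AL = 0, AR = 0),
              gyro_offset = c(EL = 0, ER = 0, AL = 0, AR = 0)),
    NW = list(cycles = 8, env = "const", sway = c(0, 0, 1),
              motions = list(.motion(.LEG_L, c(0, 0.1, 1), 0.12),
                             .motion(.LEG_R, c(0, 0.1, 1), 0.12, pi),
                             .motion(.ARM_L, c(0, 0, 1), 0.08, pi),
                             .motion(.ARM_R, c(0, 0, 1), 0.08)),
              gyro = c(EL = 1.4, ER = 1.4, AL = 2.2, AR = 2.2),
              accel = c(EL = 1.3, ER = 1.3, AL = 2.0, AR = 2.0),
              site_phase = c(EL = 0, ER = pi, AL = 0, AR = pi),
              gyro_offset = c(EL = 0, ER = 0, AL = 0, AR = 0)),
    AW = list(cycles = 8, env = "const", sway = c(0.3, 0, 1),
              motions = list(.motion(.LEG_L, c(0, 0.15, 1), 0.18),
                             .motion(.LEG_R, c(0, 0.05, 1), 0.06, pi),
                             .motion(.ARM_L, c(0, 0, 1), 0.05, pi),
                             .motion(.ARM_R, c(0, 0, 1), 0.10)),
              gyro = c(EL = 1.4, ER = 1.4, AL = 3.2, AR = 1.3),
              accel = c(EL = 1.3, ER = 1.3, AL = 2.9, AR = 1.3),
              site_phase = c(EL = 0, ER = pi, AL = 0, AR = pi),
              gyro_offset = c(EL = 0, ER = 0, AL = 0, AR = 0)),
    CP = list(cycles = 2, env = "const", sway = c(0.5, 0, -1),
              motions = list(.motion(.ARM_R, c(-0.3, 0.4, 0.6), 0.08)),
              gyro = c(EL = 1.2, ER = 1.6, AL = 1.2, AR = 1.2),
              accel = c(EL = 1.2, ER = 1.4, AL = 1.2, AR = 1.2),
              site_phase = c(EL = 0, ER = 0, AL = 0, AR = 0),
              gyro_offset = c(EL = 0, ER = 1.0, AL = 0, AR = 0)))
  tpl$behavior <- behavior
  tpl$sway <- tpl$sway / sqrt(sum(tpl$sway^2))
  tpl$sway_amp <- 0.10
  tpl
}

.envelope <- function(tau, kind) {
  if (kind == "bump") sin(pi * tau) else rep(1, length(tau))
}

# axis shaping shared by all templates: relative weight and phase of the
# x, y, z axes of every IMU waveform
.AXIS_W <- c(1, 0.7, 0.5)
.AXIS_PH <- c(0, 1.1, 2.2)

#' Generate one synthetic trial
#'
#' The skeleton idles at a standing pose (plus small tracking jitter)
#' outside the active window; inside it, the whole body sways along a
#' class-dependent direction (driving the centroid difference signal)
#' and class-dependent joint groups move along smooth sinusoids. IMU
#' signals are class-dependent sinusoids per site plus additive Gaussian
#' noise. The head and foot joints are anchored so the measured body
#' height equals `user_height` in every frame.
#'
#' @param behavior one of [behavior_labels()].
#' @param user_height body height in meters.
#' @param config a [generator_config()].
#' @param seed integer seed for this trial's random elements.
#' @param trial_id,user_id identifiers for the returned trial.
#' @return a [trial()], with the true active window (seconds, length-2
#'   vector) attached as attribute `"active_window"`.
#' @export
generate_trial <- function(behavior, user_height,
                           config = generator_config(), seed = 1L,
                           trial_id = "t1", user_id = "u1") {
  if (!is.finite(user_height) || user_height <= 0) {
    stop("user_height must be a positive number")
  }
  tpl <- behavior_template(behavior)
  set.seed(as.integer(seed))
  aj <- config$amplitude_jitter
  amp_scale <- config$signal_scale * stats::runif(1, 1 - aj, 1 + aj)
  w0 <- config$active_window_s[1]
  w1 <- config$active_window_s[2]
  dur <- w1 - w0

  # --- skeleton stream ---
  ts <- seq(0, config$trial_duration_s - 1 / config$skeleton_rate_hz,
            by = 1 / config$skeleton_rate_hz)
  nT <- length(ts)
  pose <- .base_pose()
  base_h <- sqrt(sum((pose["HEAD", ] -
                        (pose["FOOT_LEFT", ] + pose["FOOT_RIGHT", ]) / 2)^2))
  pose <- pose * (user_height / base_h)
  joints <- array(rep(pose, each = nT), dim = c(nT, 25L, 3L))
  tau <- pmin(pmax((ts - w0) / dur, 0), 1)
  active <- ts >= w0 & ts <= w1
  env <- .envelope(tau, tpl$env) * active
  sway <- amp_scale * tpl$sway_amp *
    sin(2 * pi * 4 * tau) * active  # 4 cycles, zero at both boundaries
  for (a in 1:3) {
    joints[, , a] <- joints[, , a] + sway * tpl$sway[a]
  }
  for (mo in tpl$motions) {
    disp <- amp_scale * mo$amp * user_height * env *
      sin(2 * pi * tpl$cycles * tau + mo$phase)
    ji <- match(mo$joints, kinect_joints())
    for (a in 1:3) {
      joints[, ji, a] <- joints[, ji, a] + disp * mo$dir[a]
    }
  }
  jitter_idx <- which(!(kinect_joints() %in% .STATIC_JOINTS))
  joints[, jitter_idx, ] <- joints[, jitter_idx, ] +
    stats::rnorm(nT * length(jitter_idx) * 3L, sd = config$noise_sd[["DEPTH"]])
  skel <- skeleton_sequence(ts, joints, rate_hz = config$skeleton_rate_hz)

  # --- IMU streams ---
  ti <- seq(0, config$trial_duration_s - 1 / config$imu_rate_hz,
            by = 1 / config$imu_rate_hz)
  ni <- length(ti)
  taui <- pmin(pmax((ti - w0) / dur, 0), 1)
  activei <- ti >= w0 & ti <= w1
  envi <- .envelope(taui, tpl$env) * activei
  imu <- lapply(sensor_sites(), function(s) {
    mk <- function(channel) {
      amp <- amp_scale * tpl[[channel]][[s]]
      ph <- tpl$site_phase[[s]]
      sig <- vapply(1:3, function(a) {
        amp * .AXIS_W[a] * envi *
          sin(2 * pi * tpl$cycles * taui + .AXIS_PH[a] + ph)
      }, numeric(ni))
      if (channel == "gyro" && tpl$gyro_offset[[s]] != 0) {
        sig[, 1] <- sig[, 1] + amp_scale * tpl$gyro_offset[[s]] * activei
      }
      sig + stats::rnorm(ni * 3L,
                         sd = config$noise_sd[[toupper(channel)]])
    }
    imu_stream(ti, mk("gyro"), mk("accel"), site = s,
               rate_hz = config$imu_rate_hz)
  })
  names(imu) <- sensor_sites()

  tr <- trial(trial_id, user_id, skel, imu, label = behavior)
  attr(tr, "active_window") <- c(w0, w1)
  tr
}

#' Generate a full labeled dataset
#'
#' Produces `n_users x n_repetitions x length(behaviors)` trials (1000
#' under the defaults). User heights are drawn uniformly from
#' `height_range_m`; every trial gets an independently derived seed, so
#' the whole dataset is reproducible from `config$seed`.
#'
#' @param config a [generator_config()].
#' @return list of [trial()] objects with `"active_window"` attributes.
#' @export
generate_dataset <- function(config = generator_config()) {
  set.seed(config$seed)
  heights <- stats::runif(config$n_users, config$height_range_m[1],
                          config$height_range_m[2])
  n_total <- config$n_users * config$n_repetitions *
    length(config$behaviors)
  trial_seeds <- sample.int(.Machine$integer.max, n_total)
  trials <- vector("list", n_total)
  i <- 0L
  for (u in seq_len(config$n_users)) {
    for (b in config$behaviors) {
      for (r in seq_len(config$n_repetitions)) {
        i <- i + 1L
        trials[[i]] <- generate_trial(
          b, heights[u], config, seed = trial_seeds[i],
          trial_id = sprintf("u%02d_%s_r%02d", u, b, r),
          user_id = sprintf("u%02d", u))
      }
    }
  }
  trials
}

#' Degrade one modality of a dataset with extra noise
#'
#' Adds independent Gaussian noise to the chosen modality's raw signals
#' only (skeleton joints for `DEPTH`, all four gyroscopes for `GYRO`,
#' all four accelerometers for `ACCEL`); labels and the other modalities
#' are untouched. With `extra_noise_sd = 0` the dataset is returned
#' unchanged.
#'
#' @param trials list of [trial()] objects.
#' @param modality one of [modalities()].
#' @param extra_noise_sd standard deviation of the added noise.
#' @param seed integer seed.
#' @return the degraded trial list.
#' @export
degrade_modality <- function(trials, modality, extra_noise_sd,
                             seed = 1L) {
  modality <- match.arg(modality, modalities())
  stopifnot(extra_noise_sd >= 0)
  if (extra_noise_sd == 0) {
    return(trials)
  }
  set.seed(as.integer(seed))
  lapply(trials, function(tr) {
    if (modality == "DEPTH") {
      tr$skeleton$joints <- tr$skeleton$joints +
        stats::rnorm(length(tr$skeleton$joints), sd = extra_noise_sd)
    } else {
      ch <- if (modality == "GYRO") "gyro" else "accel"
      for (s in sensor_sites()) {
        tr$imu[[s]][[ch]] <- tr$imu[[s]][[ch]] +
          stats::rnorm(length(tr$imu[[s]][[ch]]), sd = extra_noise_sd)
      }
    }
    tr
  })
}
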