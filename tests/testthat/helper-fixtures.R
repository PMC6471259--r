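# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# A random non-degenerate skeleton frame: standing-like pose plus noise.
random_frame <- function(seed = NULL, noise = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  base <- mmhar:::.base_pose() * 1.6
  m <- base + matrix(rnorm(75, sd = noise), 25, 3)
  dimnames(m) <- list(kinect_joints(), c("x", "y", "z"))
  m
}

frames_to_sequence <- function(frames, dt = 1 / 30, rate_hz = 30) {
  arr <- array(NA_real_, dim = c(length(frames), 25L, 3L))
  for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
  skeleton_sequence(seq_along(frames) * dt, arr, rate_hz = rate_hz)
}

random_imu_stream <- function(n = 50, site = "EL", seed = NULL,
                              rate_hz = 100) {
  if (!is.null(seed)) set.seed(seed)
  imu_stream(seq_len(n) / rate_hz,
             matrix(rnorm(n * 3), n, 3), matrix(rnorm(n * 3), n, 3),
             site = site, rate_hz = rate_hz)
}

# Small labeled synthetic dataset for classifier tests.
small_dataset <- function(behaviors, n_users = 2, n_reps = 3, seed = 1,
                          ...) {
  generate_dataset(generator_config(n_users = n_users,
                                    n_repetitions = n_reps,
                                    behaviors = behaviors, seed = seed,
                                    ...))
}

trial_labels <- function(trials) {
  vapply(trials, `[[`, character(1), "label")
}

# A minimal hand-built valid trial (not generator-based).
tiny_trial <- function(seed = 1) {
  set.seed(seed)
  frames <- lapply(1:10, function(i) random_frame(noise = 0.01))
  skel <- frames_to_sequence(frames)
  imu <- lapply(sensor_sites(), function(s)
    random_imu_stream(30, site = s))
  names(imu) <- sensor_sites()
  trial("tiny", "u0", skel, imu, label = "BP")
}
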