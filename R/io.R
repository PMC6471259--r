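#' Read and write trials as delimited text
#'
#' File formats are plain comma-delimited text with fixed, schema-checked
#' column orders:
#' * skeleton file: one row per frame, `t, x_0, y_0, z_0, ..., x_24, y_24,
#'   z_24` (76 columns), joints in [kinect_joints()] index order;
#' * IMU file (one per sensor site): one row per sample,
#'   `t, gx, gy, gz, ax, ay, az` (7 columns).
#'
#' Values round-trip at full double precision (15 significant digits).
#'
#' @param skeleton_path path to the skeleton file.
#' @param imu_paths named character vector/list of the four IMU file paths,
#'   names `EL, ER, AL, AR`.
#' @param trial_id,user_id,label metadata attached to the returned trial.
#' @param skeleton_rate_hz,imu_rate_hz nominal rates attached to streams.
#' @return a validated [trial()].
#' @export
read_trial <- function(skeleton_path, imu_paths,
                       trial_id = "trial", user_id = "user",
                       label = NA_character_,
                       skeleton_rate_hz = 30, imu_rate_hz = 100) {
  missing_sites <- setdiff(sensor_sites(), names(imu_paths))
  if (length(missing_sites) > 0L) {
    stop("imu_paths is missing site(s): ",
         paste(missing_sites, collapse = ", "))
  }
  skel <- .read_delim_checked(skeleton_path, 76L, "skeleton")
  n <- nrow(skel)
  joints <- array(as.matrix(skel[, -1, drop = FALSE]), dim = c(n, 3L, 25L))
  joints <- aperm(joints, c(1L, 3L, 2L))
  seq <- skeleton_sequence(skel[[1]], joints, rate_hz = skeleton_rate_hz)
  imu <- lapply(sensor_sites(), function(s) {
    d <- .read_delim_checked(imu_paths[[s]], 7L, paste0("IMU ", s))
    imu_stream(d[[1]], as.matrix(d[, 2:4]), as.matrix(d[, 5:7]),
               site = s, rate_hz = imu_rate_hz)
  })
  names(imu) <- sensor_sites()
  trial(trial_id, user_id, seq, imu, label = label)
}

.read_delim_checked <- function(path, ncol_expected, what) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  d <- tryCatch(
    data.table::fread(path, header = FALSE, sep = ",",
                      colClasses = "numeric", data.table = FALSE),
    error = function(e) stop("parse error in ", what, " file ", path,
                             ": ", conditionMessage(e)))
  if (ncol(d) != ncol_expected) {
    stop(what, " file ", path, " has ", ncol(d),
         " columns; expected ", ncol_expected)
  }
  bad <- which(!stats::complete.cases(d))
  if (length(bad) > 0L) {
    stop("parse error in ", what, " file ", path,
         ": non-numeric or missing value at line ", bad[1])
  }
  d
}

#' @rdname read_trial
#' @param trial a valid [trial()].
#' @param out_dir directory to write into (created if needed).
#' @return `write_trial` returns (invisibly) a named character vector of
#'   the files written: `skeleton` plus one entry per sensor site.
#' @export
write_trial <- function(trial, out_dir) {
  stopifnot(inherits(trial, "trial"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir)
  }
  id <- trial$trial_id
  skel_path <- file.path(out_dir, paste0(id, "_skeleton.csv"))
  jt <- aperm(trial$skeleton$joints, c(1L, 3L, 2L))  # T x 3 x 25
  dim(jt) <- c(dim(jt)[1], 75L)
  data.table::fwrite(data.table::as.data.table(cbind(trial$skeleton$time, jt)),
                     skel_path, col.names = FALSE)
  paths <- c(skeleton = skel_path)
  for (s in sensor_sites()) {
    p <- file.path(out_dir, paste0(id, "_imu_", s, ".csv"))
    st <- trial$imu[[s]]
    data.table::fwrite(
      data.table::as.data.table(cbind(st$time, st$gyro, st$accel)),
      p, col.names = FALSE)
    paths[[s]] <- p
  }
  invisible(paths)
}

#' Write and read a dataset manifest
#'
#' The manifest is a tab-separated record-per-line file with columns
#' `trial_id`, `user_id`, `label`, then relative paths `skeleton`,
#' `imu_EL`, `imu_ER`, `imu_AL`, `imu_AR`.
#'
#' @param trials list of [trial()] objects.
#' @param out_dir directory receiving the per-trial files and
#'   `manifest.tsv`.
#' @return `write_dataset` returns the manifest path invisibly;
#'   `read_dataset` returns the list of trials.
#' @export
write_dataset <- function(trials, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(trials, function(tr) {
    paths <- write_trial(tr, out_dir)
    data.frame(trial_id = tr$trial_id, user_id = tr$user_id,
               label = ifelse(is.na(tr$label), "", tr$label),
               skeleton = basename(paths[["skeleton"]]),
               imu_EL = basename(paths[["EL"]]),
               imu_ER = basename(paths[["ER"]]),
               imu_AL = basename(paths[["AL"]]),
               imu_AR = basename(paths[["AR"]]))
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(out_dir, "manifest.tsv")
  data.table::fwrite(manifest, path, sep = "\t")
  invisible(path)
}

#' @rdname write_dataset
#' @param manifest_path path to a `manifest.tsv` written by
#'   [write_dataset()].
#' @export
read_dataset <- function(manifest_path,
                         skeleton_rate_hz = 30, imu_rate_hz = 100) {
  root <- dirname(manifest_path)
  m <- data.table::fread(manifest_path, sep = "\t", data.table = FALSE,
                         colClasses = "character")
  needed <- c("trial_id", "user_id", "label", "skeleton",
              paste0("imu_", sensor_sites()))
  if (!all(needed %in% names(m))) {
    stop("manifest ", manifest_path, " lacks column(s): ",
         paste(setdiff(needed, names(m)), collapse = ", "))
  }
  lapply(seq_len(nrow(m)), function(i) {
    imu_paths <- as.list(file.path(root, unlist(m[i, paste0("imu_", sensor_sites())])))
    names(imu_paths) <- sensor_sites()
    lab <- m$label[i]
    read_trial(file.path(root, m$skeleton[i]), imu_paths,
               trial_id = m$trial_id[i], user_id = m$user_id[i],
               label = ifelse(is.na(lab) || lab == "", NA_character_, lab),
               skeleton_rate_hz = skeleton_rate_hz,
               imu_rate_hz = imu_rate_hz)
  })
}

#' @rdname read_trial
#' @param imu_rate_hz nominal IMU rate attached on read.
#' @name io-params
NULL
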