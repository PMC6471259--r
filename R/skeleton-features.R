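#' Time-variant skeleton vector-projection features
#'
#' Per frame, joint positions are expressed relative to the SHOULDER_RIGHT
#' joint and normalized by the body height (head to foot-midpoint
#' distance), then projected onto a body-attached basis: the shoulder
#' vector S (right shoulder to left shoulder), the foot vector F (right
#' shoulder to foot midpoint), and their cross product N = S x F. The
#' per-frame 25 x 3 projection matrices, stacked over a common resampled
#' time axis, form a T x 25 x 3 spatio-temporal feature cube.
#'
#' With unit-normalized basis vectors (the default) the features are
#' invariant to global translation, global rotation, and uniform scaling
#' of the skeleton, i.e. user-invariant across body sizes.
#'
#' @name skeleton-features
NULL

.DEGENERATE_EPS <- 1e-6

#' @describeIn skeleton-features Body height of one frame: Euclidean
#'   distance from HEAD to the midpoint of FOOT_LEFT and FOOT_RIGHT
#'   (meters). Errors on degenerate (near-zero height) skeletons, which
#'   would break the normalization.
#' @param frame a named 25 x 3 joint matrix ([skeleton_frame()]).
#' @export
body_height <- function(frame) {
  foot_mid <- (frame["FOOT_LEFT", ] + frame["FOOT_RIGHT", ]) / 2
  h <- sqrt(sum((frame["HEAD", ] - foot_mid)^2))
  if (h < .DEGENERATE_EPS) {
    stop("degenerate skeleton: body height below ", .DEGENERATE_EPS, " m")
  }
  h
}

#' @describeIn skeleton-features Normalized relative joint positions:
#'   row i is `(joint_i - SHOULDER_RIGHT) / body_height`; the
#'   SHOULDER_RIGHT row is exactly zero.
#' @export
normalize_joints <- function(frame) {
  h <- body_height(frame)
  origin <- frame["SHOULDER_RIGHT", ]
  sweep(frame, 2L, origin, "-") / h
}

#' @describeIn skeleton-features Body-attached basis of one frame:
#'   shoulder vector `S`, foot vector `F`, and normal `N = S x F`.
#'   Errors when S and F are (near-)parallel, leaving the normal
#'   undefined.
#' @param unit if `TRUE` (default) the basis vectors are returned
#'   unit-normalized, which makes the downstream projections scale-free.
#' @return `body_basis`: list with unit (or raw) 3-vectors `S`, `F`, `N`.
#' @export
body_basis <- function(frame, unit = TRUE) {
  S <- frame["SHOULDER_LEFT", ] - frame["SHOULDER_RIGHT", ]
  foot_mid <- (frame["FOOT_LEFT", ] + frame["FOOT_RIGHT", ]) / 2
  F <- foot_mid - frame["SHOULDER_RIGHT", ]
  N <- c(S[2] * F[3] - S[3] * F[2],
         S[3] * F[1] - S[1] * F[3],
         S[1] * F[2] - S[2] * F[1])
  nn <- sqrt(sum(N^2))
  if (nn < .DEGENERATE_EPS^2) {
    stop("degenerate pose: shoulder and foot vectors are parallel")
  }
  if (unit) {
    S <- S / sqrt(sum(S^2))
    F <- F / sqrt(sum(F^2))
    N <- N / nn
  }
  names(S) <- names(F) <- names(N) <- c("x", "y", "z")
  list(S = S, F = F, N = N)
}

#' @describeIn skeleton-features One frame's 25 x 3 projection feature:
#'   row i holds the inner products of the normalized relative joint
#'   vector with the basis, in column order `(N, F, S)`.
#' @param unit_basis project onto unit-normalized basis vectors (default
#'   `TRUE`; see [body_basis()]).
#' @export
frame_feature <- function(frame, unit_basis = TRUE) {
  jp <- normalize_joints(frame)
  b <- body_basis(frame, unit = unit_basis)
  out <- jp %*% cbind(N = b$N, F = b$F, S = b$S)
  rownames(out) <- kinect_joints()
  out
}

#' @describeIn skeleton-features Spatio-temporal feature cube: restrict
#'   the sequence to the fused segment, linearly resample every joint
#'   coordinate to `n_points` common time steps, then compute the frame
#'   feature of each resampled pose and stack along time.
#' @param seq a [skeleton_sequence()].
#' @param segment a `fused_segment` from [segment_trial()].
#' @param n_points resampled frame count T (default 60).
#' @return `feature_cube`: numeric `n_points x 25 x 3` array
#'   (time x joint x projection), projections ordered `(N, F, S)`.
#' @export
feature_cube <- function(seq, segment, n_points = 60L,
                         unit_basis = TRUE) {
  stopifnot(inherits(seq, "skeleton_sequence"),
            inherits(segment, "fused_segment"))
  keep <- which(seq$time >= segment$t_start & seq$time <= segment$t_end)
  if (length(keep) < 2L) {
    stop("fewer than 2 skeleton frames inside the fused segment")
  }
  flat <- seq$joints[keep, , , drop = FALSE]
  dim(flat) <- c(length(keep), 75L)
  rs <- resample_uniform(seq$time[keep], flat, n_points)
  cube <- array(NA_real_, dim = c(n_points, 25L, 3L),
                dimnames = list(NULL, kinect_joints(), c("N", "F", "S")))
  pose <- rs$values
  dim(pose) <- c(n_points, 25L, 3L)
  for (t in seq_len(n_points)) {
    fr <- pose[t, , ]
    dim(fr) <- c(25L, 3L)
    rownames(fr) <- kinect_joints()
    cube[t, , ] <- frame_feature(fr, unit_basis = unit_basis)
  }
  cube
}

#' @describeIn skeleton-features Flatten a feature cube to a T x 75
#'   matrix: per time step, joints are laid out in index order with their
#'   three projections contiguous, i.e. `(N_1, F_1, S_1, N_2, ..., S_25)`.
#'   Each row is one step of the camera-modality input sequence for the
#'   sequence classifier; `as.vector(t(flatten_skeleton(cube)))` is the
#'   full time-major concatenation used by the SVM baseline.
#' @param cube a `feature_cube()` result.
#' @export
flatten_skeleton <- function(cube) {
  stopifnot(length(dim(cube)) == 3L, dim(cube)[2] == 25L,
            dim(cube)[3] == 3L)
  T <- dim(cube)[1]
  out <- matrix(aperm(cube, c(3L, 2L, 1L)), nrow = T, byrow = TRUE)
  colnames(out) <- paste0(rep(kinect_joints(), each = 3L),
                          ".", rep(c("N", "F", "S"), times = 25L))
  out
}

#' @describeIn skeleton-features Inverse of [flatten_skeleton()]:
#'   reshape a T x 75 matrix back into the T x 25 x 3 cube.
#' @param mat a T x 75 matrix.
#' @export
unflatten_skeleton <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) == 75L)
  cube <- aperm(array(t(mat), dim = c(3L, 25L, nrow(mat))),
                c(3L, 2L, 1L))
  dimnames(cube) <- list(NULL, kinect_joints(), c("N", "F", "S"))
  cube
}
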