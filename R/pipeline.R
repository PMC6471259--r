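#' End-to-end pipeline: segment, featurize, train, fuse, evaluate
#'
#' @name pipeline
NULL

#' Extract all three modality feature sequences of one trial
#'
#' Segments the trial, computes the skeleton projection feature cube on
#' the fused segment (resampled to `seg_config$resample_points` steps),
#' and the windowed inertial statistics (M windows), returning flattened
#' per-step sequences ready for the classifiers.
#'
#' @param trial a [trial()].
#' @param seg_config a [segmentation_config()].
#' @param win_config a [windowing_config()].
#' @param unit_basis see [body_basis()].
#' @return list with `DEPTH` (T x 75), `GYRO` (M x 36), `ACCEL`
#'   (M x 36) matrices and the `segment` used.
#' @export
extract_trial_features <- function(trial,
                                   seg_config = segmentation_config(),
                                   win_config = windowing_config(),
                                   unit_basis = TRUE) {
  seg <- segment_trial(trial, seg_config)
  cube <- feature_cube(trial$skeleton, seg,
                       n_points = seg_config$resample_points,
                       unit_basis = unit_basis)
  inert <- inertial_features(trial, seg, win_config)
  list(DEPTH = flatten_skeleton(cube),
       GYRO = flatten_inertial(inert$gyro),
       ACCEL = flatten_inertial(inert$accel),
       segment = seg)
}

#' Evaluate the full multimodal pipeline on labeled trials
#'
#' Runs segmentation and feature extraction on every trial, splits the
#' dataset with a stratified hold-out ([split_trials()]), trains one
#' classifier per modality, predicts the held-out trials, fuses the
#' decisions by [majority_vote()], and reports one confusion matrix per
#' modality plus one for the fusion.
#'
#' @param trials list of labeled [trial()] objects.
#' @param config a [classifier_config()] applied to all three
#'   modalities, or a named list with elements `DEPTH`, `GYRO`, `ACCEL`.
#' @param test_fraction hold-out fraction (default 0.3).
#' @param seed integer seed for the split (classifier training follows
#'   `config$seed`).
#' @param seg_config,win_config,unit_basis feature-stage settings.
#' @param features optional precomputed output of
#'   [extract_trial_features()] per trial (skips re-extraction).
#' @return list with elements `DEPTH`, `GYRO`, `ACCEL`, `FUSED` (each an
#'   [evaluation_report()]), plus `split`, `predictions` and
#'   `tiebreak_rate`.
#' @export
evaluate_dataset <- function(trials, config = classifier_config(),
                             test_fraction = 0.3, seed = 1L,
                             seg_config = segmentation_config(),
                             win_config = windowing_config(),
                             unit_basis = TRUE, features = NULL) {
  labels <- vapply(trials, `[[`, character(1), "label")
  if (anyNA(labels)) {
    stop("all trials must be labeled for evaluation")
  }
  if (is.null(features)) {
    features <- lapply(trials, extract_trial_features,
                       seg_config = seg_config, win_config = win_config,
                       unit_basis = unit_basis)
  }
  if (inherits(config, "classifier_config")) {
    config <- list(DEPTH = config, GYRO = config, ACCEL = config)
  }
  split <- split_trials(labels, test_fraction, seed)
  preds <- list()
  for (m in modalities()) {
    feats <- lapply(features, `[[`, m)
    clf <- train_modality_classifier(feats[split$train],
                                     labels[split$train], config[[m]])
    preds[[m]] <- predict_modality(clf, feats[split$test])
  }
  n_test <- length(split$test)
  fused_labels <- character(n_test)
  tiebreaks <- logical(n_test)
  for (i in seq_len(n_test)) {
    pp <- lapply(modalities(), function(m) {
      list(label = preds[[m]]$labels[i], scores = preds[[m]]$scores[i, ])
    })
    names(pp) <- modalities()
    fr <- majority_vote(pp)
    fused_labels[i] <- fr$label
    tiebreaks[i] <- fr$tiebreak_used
  }
  true <- labels[split$test]
  out <- lapply(modalities(), function(m) {
    evaluation_report(true, preds[[m]]$labels)
  })
  names(out) <- modalities()
  out$FUSED <- evaluation_report(true, fused_labels)
  out$split <- split
  out$predictions <- list(per_modality = preds, fused = fused_labels,
                          true = true)
  out$tiebreak_rate <- mean(tiebreaks)
  out
}
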