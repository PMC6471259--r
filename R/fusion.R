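#' Decision-level fusion by majority vote
#'
#' The three per-modality decisions are fused at the decision level: a
#' label carried by at least two modalities wins. When all three
#' disagree, the tie is broken by the modality with the largest top-1
#' score margin (best minus second-best score); should margins tie
#' exactly, a fixed fallback priority ACCEL > DEPTH > GYRO applies,
#' ordered by typical single-modality reliability.
#'
#' @param preds named list with elements `DEPTH`, `GYRO`, `ACCEL`, each a
#'   list with `label` (one of [behavior_labels()]) and `scores` (named
#'   numeric vector of class scores in `[0, 1]`).
#' @return a `fusion_result`: list with `label`, `votes` (named count
#'   vector over the voted labels), and `tiebreak_used` flag.
#' @export
majority_vote <- function(preds) {
  missing <- setdiff(modalities(), names(preds))
  if (length(missing) > 0L) {
    stop("missing modality prediction(s): ",
         paste(missing, collapse = ", "))
  }
  labels <- vapply(modalities(), function(m) preds[[m]]$label,
                   character(1))
  votes <- table(factor(labels, levels = behavior_labels()))
  votes <- votes[votes > 0]
  if (max(votes) >= 2L) {
    return(structure(list(label = names(votes)[which.max(votes)],
                          votes = c(votes), tiebreak_used = FALSE),
                     class = "fusion_result"))
  }
  fallback <- c("ACCEL", "DEPTH", "GYRO")
  margins <- vapply(fallback, function(m) {
    s <- sort(preds[[m]]$scores, decreasing = TRUE)
    s[1] - s[2]
  }, numeric(1))
  winner <- fallback[which.max(margins)]  # ties -> first in priority order
  structure(list(label = preds[[winner]]$label, votes = c(votes),
                 tiebreak_used = TRUE),
            class = "fusion_result")
}

#' Stratified train/test split of labeled trials
#'
#' Per behavior class, `round(test_fraction * n_class)` trials go to the
#' test set; the split is disjoint, exhaustive, and reproducible by
#' `seed`. With 100 trials per class and the default fraction 0.3 this
#' gives 30 test and 70 training trials per class.
#'
#' @param labels character vector of behavior labels, one per trial.
#' @param test_fraction fraction held out for testing (default 0.3).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_trials <- function(labels, test_fraction = 0.3, seed = 1L) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop("test_fraction must be in (0, 1)")
  }
  set.seed(seed)
  test <- integer(0)
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < 2L) {
      stop("class ", cls, " has fewer than 2 trials; cannot split")
    }
    n_test <- round(test_fraction * length(idx))
    n_test <- max(1L, min(length(idx) - 1L, n_test))
    test <- c(test, sample(idx, n_test))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Build an evaluation report from true and predicted labels
#'
#' @param true,predicted character vectors of behavior labels.
#' @return an `evaluation_report`: 10 x 10 confusion matrix (rows true,
#'   columns predicted), per-class accuracy vector, `average_accuracy`
#'   (mean of per-class accuracies, percent), and `overall_accuracy`
#'   (fraction correct, percent).
#' @export
evaluation_report <- function(true, predicted) {
  lv <- behavior_labels()
  confusion <- table(factor(true, levels = lv),
                     factor(predicted, levels = lv))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("true", "predicted")
  row_n <- rowSums(confusion)
  per_class <- ifelse(row_n > 0, diag(confusion) / row_n, NA_real_)
  structure(list(confusion = confusion,
                 per_class_accuracy = 100 * per_class,
                 average_accuracy = 100 * mean(per_class, na.rm = TRUE),
                 overall_accuracy = 100 * sum(diag(confusion)) /
                   sum(confusion)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> average accuracy ",
      sprintf("%.2f%%", x$average_accuracy),
      " (overall ", sprintf("%.2f%%", x$overall_accuracy),
      ", n = ", sum(x$confusion), ")\n", sep = "")
  invisible(x)
}
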