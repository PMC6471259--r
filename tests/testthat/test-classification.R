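# brute-force reference implementation of the fusion rule
brute_vote <- function(preds) {
  labs <- vapply(c("DEPTH", "GYRO", "ACCEL"), function(m)
    preds[[m]]$label, character(1))
  counts <- table(labs)
  if (max(counts) >= 2) {
    return(names(counts)[which.max(counts)])
  }
  margins <- vapply(c("ACCEL", "DEPTH", "GYRO"), function(m) {
    s <- sort(preds[[m]]$scores, decreasing = TRUE)
    s[1] - s[2]
  }, numeric(1))
  preds[[names(margins)[which.max(margins)]]]$label
}

mk_pred <- function(label, margin = 0.5) {
  scores <- stats::setNames(rep(0.1, 10), behavior_labels())
  scores[label] <- 0.1 + margin
  list(label = label, scores = scores)
}

test_that("majority vote agrees with brute force on all 1000 label triples", {
  lv <- behavior_labels()
  margins <- c(DEPTH = 0.30, GYRO = 0.20, ACCEL = 0.25)
  n_tie <- 0
  for (a in lv) for (b in lv) for (c0 in lv) {
    preds <- list(DEPTH = mk_pred(a, margins["DEPTH"]),
                  GYRO = mk_pred(b, margins["GYRO"]),
                  ACCEL = mk_pred(c0, margins["ACCEL"]))
    got <- majority_vote(preds)
    expect_identical(got$label, brute_vote(preds))
    if (got$tiebreak_used) n_tie <- n_tie + 1
    if (length(unique(c(a, b, c0))) < 3) {
      expect_false(got$tiebreak_used)
    }
  }
  expect_equal(n_tie, 10 * 9 * 8)  # exactly the all-distinct triples
})

test_that("three-way disagreement is resolved by top-score margin, then fixed priority", {
  preds <- list(DEPTH = mk_pred("BP", 0.4), GYRO = mk_pred("BB", 0.3),
                ACCEL = mk_pred("CP", 0.6))
  v <- majority_vote(preds)
  expect_identical(v$label, "CP")
  expect_true(v$tiebreak_used)
  # equal margins fall back to ACCEL > DEPTH > GYRO
  preds2 <- list(DEPTH = mk_pred("BP", 0.4), GYRO = mk_pred("BB", 0.4),
                 ACCEL = mk_pred("CP", 0.4))
  expect_identical(majority_vote(preds2)$label, "CP")
  preds3 <- list(DEPTH = mk_pred("BP", 0.5), GYRO = mk_pred("BB", 0.4),
                 ACCEL = mk_pred("CP", 0.4))
  expect_identical(majority_vote(preds3)$label, "BP")
  expect_error(majority_vote(preds3[c("DEPTH", "GYRO")]),
               "missing modality")
})

test_that("stratified split has exact per-class arithmetic and is seeded", {
  labels <- rep(behavior_labels(), each = 100)
  sp <- split_trials(labels, 0.3, seed = 4)
  expect_length(sp$test, 300)
  expect_length(sp$train, 700)
  per_class <- table(labels[sp$test])
  expect_true(all(per_class == 30))
  # disjoint and exhaustive
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  sp2 <- split_trials(labels, 0.3, seed = 4)
  expect_identical(sp, sp2)
  sp3 <- split_trials(labels, 0.3, seed = 5)
  expect_false(identical(sp$test, sp3$test))
  expect_error(split_trials(c("BP", "BB"), 0.3), "fewer than 2")
  expect_error(split_trials(labels, 1.2), "must be in")
})

test_that("the LSTM analytic gradient matches a numerical gradient", {
  set.seed(10)
  n <- 6; d <- 4; steps <- 5; h <- 3; nc <- 3
  X <- array(rnorm(n * d * steps), dim = c(n, d, steps))
  y <- sample(0:(nc - 1), n, replace = TRUE)
  w <- mmhar:::.init_lstm_weights(d, h, nc)
  eps <- 1e-6
  for (pool in c(TRUE, FALSE)) {
    res <- mmhar:::.lstm_loss_grad_cpp(X, y, nc, w, pool)
    for (nm in names(w)) {
      idx <- sample(length(w[[nm]]), min(5, length(w[[nm]])))
      for (j in idx) {
        wp <- w; wp[[nm]][j] <- wp[[nm]][j] + eps
        wm <- w; wm[[nm]][j] <- wm[[nm]][j] - eps
        lp <- mmhar:::.lstm_loss_grad_cpp(X, y, nc, wp, pool)$loss
        lm <- mmhar:::.lstm_loss_grad_cpp(X, y, nc, wm, pool)$loss
        num <- (lp - lm) / (2 * eps)
        expect_equal(res$grad[[nm]][j], num, tolerance = 1e-4)
      }
    }
  }
})

# deterministic two-class sequences separated by the sign of one channel
separable_sequences <- function(n_per_class, steps = 8, d = 6, seed = 1) {
  set.seed(seed)
  feats <- list(); labels <- character(0)
  for (cls in c("BP", "DS")) {
    mu <- if (cls == "BP") 1.5 else -1.5
    for (i in seq_len(n_per_class)) {
      m <- matrix(rnorm(steps * d), steps, d)
      m[, 1] <- m[, 1] + mu
      feats <- c(feats, list(m))
      labels <- c(labels, cls)
    }
  }
  list(features = feats, labels = labels)
}

test_that("separable two-class data is learned by both model kinds", {
  tr <- separable_sequences(50, seed = 2)
  te <- separable_sequences(20, seed = 3)

  svm_cfg <- classifier_config("SVM", seed = 11)
  svm_fit <- train_modality_classifier(tr$features, tr$labels, svm_cfg)
  svm_tr <- predict_modality(svm_fit, tr$features)
  expect_equal(mean(svm_tr$labels == tr$labels), 1.0)
  svm_te <- predict_modality(svm_fit, te$features)
  expect_gte(mean(svm_te$labels == te$labels), 0.98)

  lstm_cfg <- classifier_config("LSTM", hidden_units = 8, epochs = 50,
                                seed = 11)
  lstm_fit <- train_modality_classifier(tr$features, tr$labels, lstm_cfg)
  lstm_tr <- predict_modality(lstm_fit, tr$features)
  expect_gte(mean(lstm_tr$labels == tr$labels), 0.98)

  # same data, same seed: identical held-out predictions
  lstm_fit2 <- train_modality_classifier(tr$features, tr$labels, lstm_cfg)
  p1 <- predict_modality(lstm_fit, te$features)
  p2 <- predict_modality(lstm_fit2, te$features)
  expect_identical(p1$scores, p2$scores)

  expect_error(train_modality_classifier(tr$features,
                                         rep("BP", length(tr$features)),
                                         lstm_cfg), "at least 2 classes")
  bad <- tr$features
  bad[[3]] <- bad[[3]][, 1:4]
  expect_error(train_modality_classifier(bad, tr$labels, lstm_cfg),
               "same steps x dim")
})

test_that("score invariants hold for modality predictions", {
  tr <- separable_sequences(20, seed = 4)
  fit <- train_modality_classifier(
    tr$features, tr$labels,
    classifier_config("LSTM", hidden_units = 4, epochs = 10, seed = 2))
  pr <- predict_modality(fit, tr$features)
  expect_true(all(pr$scores >= 0 & pr$scores <= 1))
  # decoded label is the argmax of the scores
  expect_identical(pr$labels,
                   colnames(pr$scores)[max.col(pr$scores, "first")])
})

test_that("evaluation reports have coherent confusion-matrix totals", {
  set.seed(12)
  true <- sample(behavior_labels(), 200, replace = TRUE)
  pred <- true
  flip <- sample(200, 40)
  pred[flip] <- sample(behavior_labels(), 40, replace = TRUE)
  rep_ <- evaluation_report(true, pred)
  expect_equal(sum(rep_$confusion), 200)
  expect_equal(rowSums(rep_$confusion), c(table(factor(true, behavior_labels()))),
               ignore_attr = TRUE)
  expect_equal(rep_$overall_accuracy, 100 * mean(true == pred))
  expect_true(rep_$average_accuracy >= 0 && rep_$average_accuracy <= 100)
})

test_that("the end-to-end pipeline separates behaviors and fusion is deterministic", {
  ds <- small_dataset(c("BP", "DS", "NW", "CP"), n_users = 3, n_reps = 4,
                      seed = 6)
  cc <- classifier_config("LSTM", epochs = 40, seed = 9)
  res <- evaluate_dataset(ds, cc, test_fraction = 0.3, seed = 2)
  expect_equal(sum(res$FUSED$confusion), length(res$split$test))
  expect_gte(res$FUSED$average_accuracy,
             max(res$DEPTH$average_accuracy, res$GYRO$average_accuracy,
                 res$ACCEL$average_accuracy) - 1)
  res2 <- evaluate_dataset(ds, cc, test_fraction = 0.3, seed = 2)
  expect_identical(res$FUSED$confusion, res2$FUSED$confusion)
  expect_identical(res$predictions$fused, res2$predictions$fused)

  # SVM baseline on the same small dataset also separates the classes
  res_svm <- evaluate_dataset(ds, classifier_config("SVM", seed = 9),
                              test_fraction = 0.3, seed = 2)
  expect_gte(res_svm$FUSED$average_accuracy, 95)
})
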