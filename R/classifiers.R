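#' Classifier configuration
#'
#' @param model_kind `"LSTM"` (sequence model) or `"SVM"` (baseline on
#'   the full concatenated feature vector).
#' @param hidden_units LSTM hidden state size (default 32).
#' @param n_classes number of behavior classes (default 10).
#' @param epochs training epochs (default 500).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size minibatch size (default 32).
#' @param seed integer seed controlling weight initialization and batch
#'   shuffling; fixes training exactly.
#' @param output_head `"sigmoid"` (default) or `"softmax"`; the decoded
#'   label is the argmax either way.
#' @param svm_kernel kernel for the SVM baseline (default `"linear"`).
#' @param clip_norm global gradient-norm clip (default 5).
#' @param readout `"mean"` (default) reads the class logits off the
#'   time-mean of the hidden states; `"last"` uses only the final hidden
#'   state. Mean pooling is robust when the informative frames sit in
#'   the middle of the sequence (e.g. wide fused segments with idle
#'   margins).
#' @export
classifier_config <- function(model_kind = c("LSTM", "SVM"),
                              hidden_units = 32L, n_classes = 10L,
                              epochs = 500L, learning_rate = 1e-3,
                              batch_size = 32L, seed = 1L,
                              output_head = c("sigmoid", "softmax"),
                              svm_kernel = "linear", clip_norm = 5,
                              readout = c("mean", "last")) {
  model_kind <- match.arg(model_kind)
  output_head <- match.arg(output_head)
  readout <- match.arg(readout)
  stopifnot(hidden_units >= 1L, n_classes >= 2L, epochs >= 1L,
            learning_rate > 0, batch_size >= 1L)
  structure(list(model_kind = model_kind,
                 hidden_units = as.integer(hidden_units),
                 n_classes = as.integer(n_classes),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), output_head = output_head,
                 svm_kernel = svm_kernel, clip_norm = clip_norm,
                 readout = readout),
            class = "classifier_config")
}

.stack_sequences <- function(features) {
  dims <- vapply(features, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all feature sequences must share the same steps x dim shape")
  }
  steps <- dims[1, 1]; d <- dims[2, 1]
  X <- array(NA_real_, dim = c(length(features), d, steps))
  for (i in seq_along(features)) {
    X[i, , ] <- t(features[[i]])
  }
  X
}

.standardizer <- function(X) {
  # X: N x d x T; per-feature-dimension center/scale pooled over time
  mu <- apply(X, 2L, mean)
  sd <- apply(X, 2L, stats::sd)
  sd[sd < 1e-12] <- 1
  list(mu = mu, sd = sd)
}

.apply_standardizer <- function(X, st) {
  for (j in seq_len(dim(X)[2])) {
    X[, j, ] <- (X[, j, ] - st$mu[j]) / st$sd[j]
  }
  X
}

#' Train a per-modality behavior classifier
#'
#' Trains either the single-layer LSTM sequence classifier (hidden state
#' of `hidden_units`, dense + sigmoid output of dimension `n_classes`,
#' decoded by argmax) or the linear one-vs-rest SVM baseline, which
#' consumes the time-major concatenation of the sequence into a single
#' vector. Features are standardized per dimension using training-set
#' statistics stored in the model. Training is exactly reproducible for
#' a fixed `config$seed`.
#'
#' @param features list of per-trial feature sequences, each a
#'   `steps x dim` matrix (75-dim steps for the depth modality, 36-dim
#'   for gyro/accel).
#' @param labels character vector of behavior labels, one per trial.
#' @param config a [classifier_config()].
#' @return a `modality_classifier` object; use [predict_modality()] to
#'   obtain per-trial scores and labels.
#' @export
train_modality_classifier <- function(features, labels, config) {
  stopifnot(inherits(config, "classifier_config"),
            length(features) == length(labels))
  classes <- behavior_labels()[behavior_labels() %in% unique(labels)]
  if (length(classes) < 2L) {
    stop("training data must contain at least 2 classes")
  }
  if (!all(labels %in% behavior_labels())) {
    stop("unknown behavior label(s) in training data")
  }
  y <- match(labels, classes) - 1L
  X <- .stack_sequences(features)
  st <- .standardizer(X)
  X <- .apply_standardizer(X, st)
  model <- if (config$model_kind == "LSTM") {
    .train_lstm(X, y, length(classes), config)
  } else {
    .train_svm_ovr(X, y, length(classes), config)
  }
  structure(list(kind = config$model_kind, classes = classes,
                 standardizer = st, model = model, config = config,
                 input_dim = dim(X)[2], steps = dim(X)[3]),
            class = "modality_classifier")
}

.init_lstm_weights <- function(d, h, c) {
  r_in <- 1 / sqrt(d + h)
  w <- list(Wx = matrix(stats::runif(d * 4 * h, -r_in, r_in), d, 4 * h),
            Wh = matrix(stats::runif(h * 4 * h, -r_in, r_in), h, 4 * h),
            Wy = matrix(stats::runif(h * c, -1 / sqrt(h), 1 / sqrt(h)),
                        h, c),
            b = rep(0, 4 * h), by = rep(0, c))
  w$b[(h + 1):(2 * h)] <- 1  # forget-gate bias starts open
  w
}

.train_lstm <- function(X, y, n_class, config) {
  n <- dim(X)[1]
  set.seed(config$seed)
  init <- .init_lstm_weights(dim(X)[2], config$hidden_units, n_class)
  order <- t(replicate(config$epochs, sample.int(n))) - 1L
  if (config$epochs == 1L) {
    order <- matrix(order, nrow = 1L)
  }
  fit <- .lstm_train_cpp(X, y, n_class, init, order,
                         config$batch_size, config$learning_rate,
                         config$clip_norm, config$readout == "mean")
  fit
}

.train_svm_ovr <- function(X, y, n_class, config) {
  # time-major concatenation of each sequence into one vector
  V <- .flatten_for_svm(X)
  set.seed(config$seed)
  fits <- lapply(seq_len(n_class) - 1L, function(cls) {
    yy <- factor(ifelse(y == cls, "pos", "neg"), levels = c("pos", "neg"))
    e1071::svm(x = V, y = yy, kernel = config$svm_kernel,
               scale = FALSE, cost = 1)
  })
  list(fits = fits)
}

.flatten_for_svm <- function(X) {
  # X: N x d x T -> N x (T*d), step-major (step 1's dims, step 2's, ...)
  n <- dim(X)[1]
  V <- matrix(NA_real_, n, dim(X)[2] * dim(X)[3])
  for (i in seq_len(n)) {
    V[i, ] <- as.vector(X[i, , ])
  }
  V
}

#' Predict behavior scores for new trials
#'
#' @param object a `modality_classifier`.
#' @param features list of `steps x dim` feature sequences.
#' @return list with `labels` (character) and `scores` (matrix
#'   `n x n_classes`, columns named by class, values in `[0, 1]`).
#' @export
predict_modality <- function(object, features) {
  stopifnot(inherits(object, "modality_classifier"))
  X <- .stack_sequences(features)
  if (dim(X)[2] != object$input_dim || dim(X)[3] != object$steps) {
    stop("feature shape ", dim(X)[2], " x ", dim(X)[3],
         " does not match the trained model (", object$input_dim,
         " x ", object$steps, ")")
  }
  X <- .apply_standardizer(X, object$standardizer)
  scores <- if (object$kind == "LSTM") {
    s <- .lstm_scores_cpp(X, object$model$weights,
                          object$config$readout == "mean")
    if (object$config$output_head == "softmax") {
      e <- exp(s - apply(s, 1L, max))
      s <- e / rowSums(e)
    }
    s
  } else {
    V <- .flatten_for_svm(X)
    dv <- vapply(object$model$fits, function(f) {
      pr <- attr(stats::predict(f, V, decision.values = TRUE),
                 "decision.values")
      d <- as.numeric(pr[, 1])
      # decision values are signed toward the first factor level ("pos")
      if (!grepl("^pos", colnames(pr)[1])) d <- -d
      d
    }, numeric(nrow(V)))
    dim(dv) <- c(nrow(V), length(object$model$fits))
    1 / (1 + exp(-dv))
  }
  colnames(scores) <- object$classes
  list(labels = object$classes[max.col(scores, ties.method = "first")],
       scores = scores)
}
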