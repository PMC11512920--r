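#' CNN + LSTM classifier configuration
#'
#' Architecture of the two-stage sequence classifier: a convolutional frame
#' encoder (two 3x3 convolution layers with batch normalisation and ReLU,
#' the second with stride 2 to bound the flattened feature size) feeding a
#' two-layer LSTM with hidden size 20, dropout on the concatenated hidden
#' states, and two fully-connected layers ending in two class logits.
#'
#' @param mesh frame side length in pixels.
#' @param in_ch image channels (3 band-pair layers).
#' @param filters two conv filter counts.
#' @param kernel convolution kernel size.
#' @param stride2 stride of the second convolution.
#' @param frames sequence length (temporal segments per subject).
#' @param hidden LSTM hidden size.
#' @param fc1 width of the first fully-connected layer.
#' @param dropout dropout probability applied after the LSTM during
#'   training.
#' @return list of class `cnn_lstm_config`.
#' @export
cnn_lstm_config <- function(mesh = 32, in_ch = 3, filters = c(8, 16),
                            kernel = 3, stride2 = 2, frames = 30,
                            hidden = 20, fc1 = 16, dropout = 0.5) {
  out2 <- (mesh + 2 - kernel) %/% stride2 + 1
  structure(list(mesh = mesh, in_ch = in_ch, f1 = filters[1], f2 = filters[2],
                 k = kernel, stride2 = stride2, T = frames, hidden = hidden,
                 fc1 = fc1, dropout = dropout,
                 flat_size = filters[2] * out2 * out2),
            class = "cnn_lstm_config")
}

# concatenate image sequences (mesh x mesh x C x T arrays) for the C++ core
seqs_to_vec <- function(sequences, cfg) {
  want <- c(cfg$mesh, cfg$mesh, cfg$in_ch, cfg$T)
  for (s in sequences) {
    if (!identical(dim(s)[1:4], as.integer(want)))
      stop(sprintf("sequence dims (%s) do not match config (%s)",
                   paste(dim(s), collapse = "x"), paste(want, collapse = "x")))
  }
  unlist(lapply(sequences, as.numeric), use.names = FALSE)
}

label_to_int <- function(labels) {
  lv <- c("control", "dyslexic")
  y <- match(labels, lv) - 1L
  if (anyNA(y)) stop("labels must be 'control' or 'dyslexic'")
  y
}

#' Initialise classifier parameters
#'
#' @param cfg a [cnn_lstm_config()].
#' @param seed integer seed (He-uniform weights, forget-gate bias 1).
#' @return named list of parameter matrices/vectors.
#' @export
init_classifier <- function(cfg, seed = 1) {
  nn_init_params_cpp(unclass(cfg), as.integer(seed))
}

#' Convolutional frame features
#'
#' Runs the convolutional encoder (conv - batch-norm - ReLU twice, then
#' flatten) over a batch of frames; deterministic in eval mode.
#'
#' @param frames array `mesh x mesh x in_ch x n` (or a single frame without
#'   the batch axis).
#' @param model a fitted `cnn_lstm_model` (or list with `params` + `cfg`).
#' @param train use batch statistics instead of running statistics.
#' @return matrix `n x flat_size` of feature vectors.
#' @export
cnn_features <- function(frames, model, train = FALSE) {
  cfg <- model$cfg
  d <- dim(frames)
  if (length(d) == 3) { dim(frames) <- c(d, 1L); d <- dim(frames) }
  if (d[1] != cfg$mesh || d[2] != cfg$mesh || d[3] != cfg$in_ch)
    stop("frame dims do not match the model configuration")
  t(nn_cnn_features_cpp(model$params, unclass(cfg), as.numeric(frames),
                        d[4], train))
}

#' Train the CNN + LSTM classifier
#'
#' Minimises (optionally class-weighted) softmax cross-entropy with Adam on
#' minibatches of whole subject sequences. Reproducible for a fixed seed:
#' initialisation, shuffling and dropout masks all derive from it.
#'
#' @param sequences list of `mesh x mesh x in_ch x T` arrays (one per
#'   subject); `cfs_image_sequence` objects are accepted.
#' @param labels character vector, `"control"` / `"dyslexic"`.
#' @param cfg a [cnn_lstm_config()].
#' @param epochs maximum training epochs.
#' @param lr Adam learning rate.
#' @param batch_size subjects per minibatch.
#' @param seed integer seed.
#' @param class_weights `"balanced"` (inverse class frequency), `"none"`, or
#'   a numeric length-2 vector (control, dyslexic).
#' @param stop_loss early-stopping threshold on the epoch-mean training
#'   loss.
#' @return object of class `cnn_lstm_model` with elements `params`, `cfg`,
#'   `loss_trace`, `classes`.
#' @export
train_classifier <- function(sequences, labels, cfg = cnn_lstm_config(),
                             epochs = 40, lr = 1e-3, batch_size = 8,
                             seed = 1, class_weights = "balanced",
                             stop_loss = 0.03) {
  y <- label_to_int(labels)
  if (length(unique(y)) < 2)
    stop("training set must contain both classes")
  cw <- c(1, 1)
  if (identical(class_weights, "balanced")) {
    n <- length(y)
    cw <- c(n / (2 * sum(y == 0)), n / (2 * sum(y == 1)))
  } else if (is.numeric(class_weights)) cw <- class_weights
  params <- init_classifier(cfg, seed)
  sv <- seqs_to_vec(sequences, cfg)
  fit <- nn_train_cpp(params, unclass(cfg), sv,
                      as.integer(y), cw, as.integer(epochs), lr,
                      as.integer(batch_size), cfg$dropout,
                      as.integer(seed), stop_loss)
  # replace momentum-averaged batch-norm statistics by exact training-set
  # statistics under the final weights (eval-mode calibration)
  fit$params <- nn_bn_recalibrate_cpp(fit$params, unclass(cfg), sv,
                                      length(sequences), 8L)
  structure(list(params = fit$params, cfg = cfg,
                 loss_trace = as.numeric(fit$loss_trace),
                 classes = c("control", "dyslexic")),
            class = "cnn_lstm_model")
}

#' @export
print.cnn_lstm_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<cnn_lstm_model> %d parameters, %d epochs trained, final loss %.4f\n",
              np, length(x$loss_trace),
              if (length(x$loss_trace)) utils::tail(x$loss_trace, 1) else NA))
  invisible(x)
}

#' Class scores for image sequences
#'
#' `sequence_logits` returns the two class logits for one sequence;
#' `predict` scores a list of sequences and returns logits or class
#' probabilities (softmax). Eval mode: dropout disabled, batch-norm running
#' statistics - deterministic.
#'
#' @param sequence one `mesh x mesh x in_ch x T` array.
#' @param model a `cnn_lstm_model`.
#' @return `sequence_logits`: numeric length-2 vector (control, dyslexic).
#' @export
sequence_logits <- function(sequence, model) {
  out <- predict(model, list(sequence), type = "logits")
  stats::setNames(out[1, ], model$classes)
}

#' @rdname sequence_logits
#' @param object a `cnn_lstm_model`.
#' @param sequences list of sequences.
#' @param type `"logits"` or `"prob"`.
#' @param ... unused.
#' @export
predict.cnn_lstm_model <- function(object, sequences, type = c("prob", "logits"),
                                   ...) {
  type <- match.arg(type)
  cfg <- object$cfg
  logits <- nn_predict_cpp(object$params, unclass(cfg),
                           seqs_to_vec(sequences, cfg), length(sequences))
  colnames(logits) <- object$classes
  if (type == "logits") return(logits)
  e <- exp(logits - apply(logits, 1, max))
  e / rowSums(e)
}

#' Classification metrics for one evaluation fold
#'
#' Confusion counts at the argmax decision (positive class: dyslexic),
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, balanced accuracy
#' (their mean) and AUC computed as the normalised rank statistic of the
#' positive-class score (probability of a random positive scoring above a
#' random negative, ties counted half).
#'
#' @param scores matrix `n x 2` of class scores (logits or probabilities)
#'   with the positive class in column 2, or a vector of positive-class
#'   scores (then decisions use `score > 0.5`).
#' @param labels character vector of true labels.
#' @return list of class `fold_metrics`: counts and the four measures.
#' @export
evaluate <- function(scores, labels) {
  y <- label_to_int(labels)
  if (is.matrix(scores)) {
    pred <- max.col(scores, ties.method = "first") - 1L
    pos <- scores[, 2]
  } else {
    pred <- as.integer(scores > 0.5)
    pos <- scores
  }
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  if (length(unique(y)) < 2)
    stop("AUC undefined: evaluation set contains a single class")
  auc <- auc_score(pos, y)
  structure(list(n_TP = tp, n_TN = tn, n_FP = fp, n_FN = fn,
                 sensitivity = sens, specificity = spec,
                 balanced_accuracy = mean(c(sens, spec)), auc = auc,
                 correct = pred == y),
            class = "fold_metrics")
}

#' @rdname evaluate
#' @param pos_scores positive-class scores.
#' @param y 0/1 truth vector.
#' @export
auc_score <- function(pos_scores, y) {
  r <- rank(pos_scores, ties.method = "average")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.fold_metrics <- function(x, ...) {
  cat(sprintf("sens %.3f  spec %.3f  bal.acc %.3f  AUC %.3f  (TP %d FN %d TN %d FP %d)\n",
              x$sensitivity, x$specificity, x$balanced_accuracy, x$auc,
              x$n_TP, x$n_FN, x$n_TN, x$n_FP))
  invisible(x)
}

# stratified fold assignment: round-robin within each shuffled class
stratified_folds <- function(labels, k, seed) {
  y <- label_to_int(labels)
  if (min(table(y)) < k)
    stop(sprintf("each class needs at least k = %d subjects for %d-fold CV",
                 k, k))
  fold <- integer(length(y))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Splits subjects (one sequence per subject, so no leakage across folds)
#' into k stratified folds, trains a freshly initialised model per fold and
#' evaluates on the held-out fold.
#'
#' @inheritParams train_classifier
#' @param k number of folds (k = number of subjects gives leave-one-out).
#' @param seed seed controlling fold assignment and per-fold model seeds.
#' @param ... further arguments for [train_classifier()].
#' @return list of class `cv_result`: `folds` (per-fold `fold_metrics`),
#'   `summary` (mean and sd per metric), `assignments`, `correct` (per
#'   subject, in input order).
#' @export
cross_validate <- function(sequences, labels, k = 5, cfg = cnn_lstm_config(),
                           seed = 1, ...) {
  fold <- stratified_folds(labels, k, seed)
  metrics <- vector("list", k)
  correct <- logical(length(labels))
  for (f in seq_len(k)) {
    te <- which(fold == f); tr <- which(fold != f)
    model <- train_classifier(sequences[tr], labels[tr], cfg,
                              seed = seed + f, ...)
    sc <- predict(model, sequences[te], type = "prob")
    metrics[[f]] <- evaluate(sc, labels[te])
    correct[te] <- metrics[[f]]$correct
  }
  msel <- c("sensitivity", "specificity", "balanced_accuracy", "auc")
  tab <- sapply(msel, function(m) vapply(metrics, `[[`, 0, m))
  structure(list(folds = metrics,
                 summary = data.frame(metric = msel,
                                      mean = colMeans(tab),
                                      sd = apply(tab, 2, stats::sd)),
                 assignments = fold, correct = correct, k = k),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold stratified cross-validation\n", x$k))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-18s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Write cross-validation metrics as CSV
#'
#' One row per metric with mean and standard deviation over folds, plus
#' per-fold columns.
#'
#' @param cv a `cv_result`.
#' @param path output file.
#' @param run_label optional label column (e.g. band-pair triplet and
#'   stimulus).
#' @return `path`, invisibly.
#' @export
write_cv_csv <- function(cv, path, run_label = "") {
  s <- cv$summary
  per_fold <- sapply(seq_along(cv$folds), function(f)
    vapply(s$metric, function(m) cv$folds[[f]][[m]], 0))
  colnames(per_fold) <- paste0("fold", seq_along(cv$folds))
  df <- cbind(data.frame(run = run_label), s, per_fold)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
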