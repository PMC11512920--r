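test_that("convolution matches the brute-force double sum", {
  set.seed(61)
  for (case in list(c(k = 3, stride = 1, pad = 1, cin = 2, f = 3, n = 6),
                    c(k = 3, stride = 2, pad = 1, cin = 3, f = 2, n = 8))) {
    X <- array(rnorm(case["n"]^2 * case["cin"]),
               dim = c(case["n"], case["n"], case["cin"]))
    W <- matrix(rnorm(case["f"] * case["cin"] * case["k"]^2), case["f"])
    b <- rnorm(case["f"])
    got <- eegcfs:::nn_conv2d_cpp(as.numeric(X), case["n"], case["cin"], W, b,
                                  case["k"], case["stride"], case["pad"])
    want <- conv2d_brute(X, W, b, case["k"], case["stride"], case["pad"])
    expect_lt(max(abs(got - want)), 1e-10)
  }
})

test_that("hand-checkable convolution cases", {
  # 1x1 identity filter reproduces the input map
  X <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3)
  got <- eegcfs:::nn_conv2d_cpp(as.numeric(X), 3, 1,
                                matrix(1, 1, 1), 0, 1, 1, 0)
  expect_equal(got[, , 1], X, tolerance = 1e-12)
  # all-zero input with zero bias gives all-zero pre-activations
  z <- eegcfs:::nn_conv2d_cpp(numeric(25), 5, 1, matrix(rnorm(9), 1), 0,
                              3, 1, 1)
  expect_true(all(z == 0))
})

test_that("LSTM cell equals hand-computed gate arithmetic", {
  set.seed(62)
  H <- 1
  Wx <- matrix(rnorm(4), 4, 1); Wh <- matrix(rnorm(4), 4, 1)
  b <- rnorm(4)
  h <- matrix(0.3); cc <- matrix(-0.2)
  xs <- c(0.7, -1.1)                                 # scalar length-2 sequence
  for (x in xs) {
    got <- eegcfs:::nn_lstm_cell_cpp(matrix(x), h, cc, Wx, Wh, b)
    want <- lstm_cell_hand(x, as.numeric(h), as.numeric(cc), Wx, Wh, b)
    expect_lt(abs(got$h - want$h), 1e-10)
    expect_lt(abs(got$c - want$c), 1e-10)
    h <- got$h; cc <- got$c
  }
})

test_that("cnn_features and sequence scores satisfy their shape contracts", {
  cfg <- tiny_cfg()
  model <- structure(list(params = init_classifier(cfg, 1), cfg = cfg,
                          classes = c("control", "dyslexic")),
                     class = "cnn_lstm_model")
  fr <- array(runif(8 * 8 * 2 * 5), dim = c(8, 8, 2, 5))
  ft <- cnn_features(fr, model)
  expect_identical(dim(ft), c(5L, as.integer(cfg$flat_size)))
  expect_error(cnn_features(array(0, c(4, 4, 2, 1)), model), "dims")
  sq <- array(runif(8 * 8 * 2 * 3), dim = c(8, 8, 2, 3))
  lg <- sequence_logits(sq, model)
  expect_length(lg, 2)
  expect_true(all(is.finite(lg)))
  expect_identical(lg, sequence_logits(sq, model))   # eval determinism
  expect_error(sequence_logits(array(0, c(8, 8, 2, 4)), model), "dims")
})

test_that("training separates a planted two-class problem and is reproducible", {
  d <- tiny_sequences()
  m1 <- train_classifier(d$seqs, d$labels, tiny_cfg(), epochs = 40,
                         seed = 9, batch_size = 4)
  pr <- predict(m1, d$seqs)
  met <- evaluate(pr, d$labels)
  expect_gte(met$balanced_accuracy, 0.95)
  m2 <- train_classifier(d$seqs, d$labels, tiny_cfg(), epochs = 40,
                         seed = 9, batch_size = 4)
  expect_identical(m1$params$W1, m2$params$W1)
  expect_identical(m1$params$lstm2_Wx, m2$params$lstm2_Wx)
  expect_identical(m1$loss_trace, m2$loss_trace)
  # smoothed loss decreases on a separable problem
  sm <- stats::filter(m1$loss_trace, rep(1 / 3, 3), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1])
  expect_error(train_classifier(d$seqs[1:6], d$labels[1:6], tiny_cfg()),
               "both classes")
})

test_that("parameter count is architecture-derived and scales with hidden size", {
  count <- function(hidden) {
    cfg <- cnn_lstm_config(mesh = 8, in_ch = 2, filters = c(2, 3), frames = 3,
                           hidden = hidden, fc1 = 4)
    sum(vapply(init_classifier(cfg, 1), length, 0L))
  }
  expected <- function(H) {
    D <- 3 * 4 * 4
    conv <- (2 * 9 * 2 + 2 + 4 * 2) + (3 * 9 * 2 + 3 + 4 * 3)
    lstm <- (4 * H * D + 4 * H * H + 4 * H) + (4 * H * H + 4 * H * H + 4 * H)
    fc <- (4 * 3 * H + 4) + (2 * 4 + 2)
    conv + lstm + fc
  }
  expect_equal(count(4L), expected(4L))
  expect_equal(count(6L), expected(6L))
  expect_gt(count(6L), count(4L))
})

test_that("metrics follow the standard confusion definitions", {
  perfect <- evaluate(cbind(c(rep(1, 5), rep(0, 3)), c(rep(0, 5), rep(1, 3))),
                      c(rep("control", 5), rep("dyslexic", 3)))
  expect_identical(c(perfect$n_TP, perfect$n_TN, perfect$n_FP, perfect$n_FN),
                   c(3L, 5L, 0L, 0L))
  expect_equal(perfect$balanced_accuracy, 1.0)
  # TP=2 FN=1 TN=4 FP=1 -> sens 2/3, spec 4/5, bal.acc 11/15
  y <- c(rep("dyslexic", 3), rep("control", 5))
  pos <- c(0.9, 0.8, 0.2, 0.7, 0.1, 0.2, 0.3, 0.4)
  m <- evaluate(cbind(1 - pos, pos), y)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 4 / 5)
  expect_equal(m$balanced_accuracy, 11 / 15)
  expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2,
               tolerance = 1e-12)
  expect_error(evaluate(cbind(0.1, 0.9), "dyslexic"), "single class")
})

test_that("AUC is the rank statistic: perfect, reversed, and Mann-Whitney", {
  y <- c(0, 0, 0, 1, 1)
  expect_equal(auc_score(c(1, 2, 3, 4, 5), y), 1.0)
  expect_equal(auc_score(c(5, 4, 3, 2, 1), y), 0.0)
  set.seed(63)
  for (i in 1:5) {
    yy <- rep(c(0, 1), c(12, 8))
    s <- rnorm(20)
    W <- suppressWarnings(stats::wilcox.test(s[yy == 1], s[yy == 0]))$statistic
    expect_equal(auc_score(s, yy), unname(W) / (8 * 12), tolerance = 1e-12)
  }
})

test_that("stratified folds keep class ratios and honour degenerate k", {
  labs <- rep(c("control", "dyslexic"), c(33, 15))
  f <- eegcfs:::stratified_folds(labs, 5, seed = 1)
  for (k in 1:5) {
    expect_true(abs(sum(f == k & labs == "control") - 33 / 5) < 1)
    expect_true(abs(sum(f == k & labs == "dyslexic") - 15 / 5) < 1)
  }
  expect_identical(f, eegcfs:::stratified_folds(labs, 5, seed = 1))
  expect_false(identical(f, eegcfs:::stratified_folds(labs, 5, seed = 2)))
  # k = per-class count: every fold holds one subject of each class
  small <- rep(c("control", "dyslexic"), each = 4)
  loo <- eegcfs:::stratified_folds(small, 4, seed = 1)
  expect_true(all(table(loo) == 2))
  expect_error(eegcfs:::stratified_folds(small, 5, seed = 1), "at least")
})

test_that("cross-validation returns per-fold metrics and a mean/sd summary", {
  d <- tiny_sequences(n_per_class = 4)
  cv <- cross_validate(d$seqs, d$labels, k = 2, cfg = tiny_cfg(), seed = 3,
                       epochs = 15, batch_size = 4)
  expect_length(cv$folds, 2)
  expect_identical(dim(cv$summary), c(4L, 3L))
  expect_true(all(is.finite(cv$summary$mean)))
  expect_length(cv$correct, 8)
  f <- tempfile(fileext = ".csv")
  write_cv_csv(cv, f, run_label = "tiny")
  expect_identical(nrow(read.csv(f)), 4L)
})
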