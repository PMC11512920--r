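geom_e <- topo_geometry(project_montage(montage_standard32()))
mask_e <- build_feature_mask(geom_e)

test_that("kernel weight is exponential in squared Euclidean distance", {
  x <- array(0, dim = c(4, 4, 1))
  expect_equal(kernel_weight(x, x, 1), 1.0)
  z1 <- x; z1[1, 1, 1] <- 1
  z2 <- x; z2[1, 1, 1] <- 2
  expect_gt(kernel_weight(x, z1, 1), kernel_weight(x, z2, 1))
  zd <- x; zd[2, 2, 1] <- 0.6                       # D = width -> e^-1
  expect_equal(kernel_weight(x, zd, 0.6), exp(-1), tolerance = 1e-12)
  expect_error(kernel_weight(x, x, 0), "positive")
})

test_that("frame perturbation switches super-pixels off and keeps all-ones intact", {
  set.seed(71)
  sq <- random_sequence(T_ = 4)
  p <- perturb_frame(sq, 2, mask_e, N = 50, seed = 5)
  expect_identical(dim(p$designs), c(50L, 31L))
  expect_true(all(p$designs %in% 0:1))
  expect_identical(p$designs[1, ], rep(1L, 31L))     # all-ones always first
  expect_equal(p$frames[, , , 1], sq[, , , 2], tolerance = 1e-12)
  # explicit all-zeros design: in-hull pixels zeroed, out-of-hull untouched
  labs <- 1:31
  z0 <- matrix(0L, 1, 31)
  fr <- eegcfs:::apply_designs(sq[, , , 2, drop = FALSE], mask_e, z0, labs)
  inh <- unclass(geom_e$inhull)
  for (ch in 1:3) {
    expect_true(all(fr[, , ch, 1][inh] == 0))
    expect_equal(fr[, , ch, 1][!inh], sq[, , ch, 2][!inh], tolerance = 1e-12)
  }
  expect_error(perturb_frame(sq, 9, mask_e, 10), "out of range")
  expect_error(perturb_frame(sq, 1, mask_e, 1), "N >= 2")
})

test_that("a constant-score model gets all-zero coefficients", {
  sq <- random_sequence(T_ = 3, seed = 72)
  const_model <- function(frames, frame_idx) rep(0.42, dim(frames)[4])
  b <- explain_frame(const_model, sq, 1, mask_e, N = 200, seed = 1)
  expect_true(all(b == 0))
})

test_that("the lasso surrogate recovers a planted super-pixel model", {
  sq <- random_sequence(T_ = 3, seed = 73)
  s_lab <- match("FC5", attr(mask_e, "labels"))
  sel <- unclass(mask_e) == s_lab
  oracle <- function(frames, frame_idx) {
    apply(frames, 4, function(fr) mean(fr[, , 1][sel]))
  }
  b <- explain_frame(oracle, sq, 2, mask_e, N = 600, seed = 2,
                     lasso_penalty = 1e-4)
  expect_identical(names(which.max(abs(b))), "FC5")
  expect_gt(abs(b["FC5"]), 5 * max(abs(b[names(b) != "FC5"])))
  expect_gte(attr(b, "fidelity"), 0.99)              # surrogate fidelity
  b2 <- explain_frame(oracle, sq, 2, mask_e, N = 600, seed = 2,
                      lasso_penalty = 1e-4)
  expect_identical(as.numeric(b), as.numeric(b2))    # fixed-seed determinism
})

test_that("explain_sequence produces a frames x super-pixels map", {
  sq <- random_sequence(T_ = 4, seed = 74)
  s_lab <- match("Oz", attr(mask_e, "labels"))
  sel <- unclass(mask_e) == s_lab
  scorer <- function(frames, frame_idx) {
    if (frame_idx == 3) return(rep(0.5, dim(frames)[4]))  # insensitive frame
    apply(frames, 4, function(fr) mean(fr[, , 2][sel]))
  }
  m <- explain_sequence(scorer, sq, mask_e, N = 250, seed = 1)
  expect_identical(dim(unclass(m)), c(4L, 31L))
  expect_identical(colnames(m), attr(mask_e, "labels"))
  expect_true(all(m[3, ] == 0))                      # zero row where constant
  expect_identical(names(which.max(abs(m[1, ]))), "Oz")
})

test_that("shrinking the penalty converges to weighted least squares", {
  set.seed(75)
  n <- 300; d <- 31
  Z <- matrix(rbinom(n * d, 1, 0.5), n, d)
  beta_true <- rnorm(d, sd = 0.3)
  y <- as.numeric(Z %*% beta_true) + rnorm(n, sd = 0.01)
  w <- runif(n, 0.2, 1)
  fit <- glmnet::glmnet(Z, y, weights = w, alpha = 1, lambda = 1e-10,
                        standardize = FALSE, thresh = 1e-14)
  X1 <- cbind(1, Z)
  wls <- solve(t(X1) %*% (w * X1), t(X1) %*% (w * y))
  expect_lt(max(abs(as.numeric(fit$beta) - wls[-1])), 1e-6)
})

test_that("aggregation ranks by mean |coefficient| and respects selection", {
  mk <- function(v) {
    m <- matrix(rep(v, each = 2), 2, 31)
    colnames(m) <- attr(mask_e, "labels")
    structure(m, class = "explanation_map", frames = 1:2)
  }
  set.seed(76)
  v <- rnorm(31)
  one <- top_superpixels(list(mk(v)), k = 31)
  expect_identical(one$ranking[[1]],
                   attr(mask_e, "labels")[order(abs(v), decreasing = TRUE)])
  expect_identical(top_superpixels(list(mk(v)))$k, 5L)   # default k
  # opposite-signed subjects cancel
  two <- top_superpixels(list(mk(v), mk(-v)), k = 5)
  expect_lt(max(abs(two$average)), 1e-12)
  # permutation of subjects leaves the average unchanged
  maps <- list(mk(v), mk(2 * v), mk(-0.5 * v))
  expect_equal(top_superpixels(maps, k = 5)$average,
               top_superpixels(rev(maps), k = 5)$average, tolerance = 1e-12)
  # correctness filter
  flt <- top_superpixels(list(mk(v), mk(100 * v)), correct = c(TRUE, FALSE),
                         k = 31)
  expect_equal(unname(flt$average[1, ]), v, tolerance = 1e-12)
  expect_error(top_superpixels(list(mk(v)), correct = logical(0)), "one correctness")
  expect_error(top_superpixels(list(mk(v))[0]), "no subjects")
})

test_that("relevance rendering paints each super-pixel with its value", {
  v <- stats::setNames(numeric(31), attr(mask_e, "labels"))
  v["FC5"] <- 0.8; v["P4"] <- -0.5
  img <- render_relevance(v, mask_e)
  m <- unclass(mask_e)
  expect_true(all(img[m == match("FC5", attr(mask_e, "labels"))] == 0.8))
  expect_true(all(img[m == match("P4", attr(mask_e, "labels"))] == -0.5))
  expect_true(all(img[m == 0] == 0))
  top1 <- render_relevance(v, mask_e, top_k = 1)
  expect_true(all(top1[m == match("P4", attr(mask_e, "labels"))] == 0))
})
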