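test_that("Bessel-ratio inversion hits its calibration targets", {
  expect_identical(coupling_to_concentration(0), 0)
  k9 <- coupling_to_concentration(0.9)
  expect_equal(vm_resultant(k9), 0.9, tolerance = 1e-7)
  set.seed(21)
  r <- Mod(mean(exp(1i * rvonmises(1e6, k9))))    # Monte-Carlo resultant
  expect_equal(r, 0.9, tolerance = 0.005)
  k5 <- coupling_to_concentration(0.5)
  set.seed(22)
  phi <- runif(1e5, -pi, pi)
  expect_equal(cfs_value(phi, phi + rvonmises(1e5, k5)), 0.5,
               tolerance = 0.01)
  expect_error(coupling_to_concentration(-0.1), "\\[0, 1\\]")
  expect_error(coupling_to_concentration(1.2), "\\[0, 1\\]")
  expect_warning(kinf <- coupling_to_concentration(1), "degenerate")
  expect_identical(kinf, Inf)
  expect_identical(rvonmises(5, Inf), rep(0, 5))
})

test_that("estimator recovers every jitter target within Monte-Carlo error", {
  set.seed(23)
  n <- 2500; reps <- 200
  for (t in seq(0.1, 0.9, by = 0.2)) {
    kap <- coupling_to_concentration(t)
    vals <- vapply(seq_len(reps), function(r) {
      phi <- runif(n, -pi, pi)
      cfs_value(phi, phi + rvonmises(n, kap))
    }, 0)
    se <- stats::sd(vals) / sqrt(reps)
    expect_lt(abs(mean(vals) - t), 3 * se + 2e-3)
  }
})

test_that("generated recordings have the contracted geometry and are reproducible", {
  tpl <- default_templates()$control
  rec <- generate_subject(tpl, duration_s = 20, sfreq = 500, seed = 31)
  expect_s3_class(rec, "eeg_recording")
  expect_identical(nrow(rec$data), 31L)              # Cz-referenced channels
  expect_identical(ncol(rec$data), 10000L)           # duration x rate
  expect_true(all(is.finite(rec$data)))
  expect_equal(max(abs(rowMeans(rec$data))), 0, tolerance = 1e-10)
  expect_equal(max(abs(sqrt(rowMeans(rec$data^2)) - 1)), 0, tolerance = 1e-10)
  rec2 <- generate_subject(tpl, duration_s = 20, sfreq = 500, seed = 31)
  expect_identical(rec$data, rec2$data)
  expect_error(generate_subject(tpl, duration_s = 2, sfreq = 500, seed = 1),
               "segment")
  bad <- class_template("control",
                        list(coupling_spec("XX", c("Alpha", "Beta"), 0.5)))
  expect_error(generate_subject(bad, 20, 500, 1), "montage")
})

test_that("injected coupling is recovered by the pipeline estimator", {
  tpl <- class_template("control",
                        list(coupling_spec("FC5", c("Alpha", "Beta"), 0.95)))
  rec <- generate_subject(tpl, duration_s = 30, sfreq = 500, seed = 7)
  cm <- cfs_matrix(extract_phases(rec))
  expect_gte(min(cm["FC5", "Alpha-Beta", ]), 0.9)
  others <- cm[rownames(cm) != "FC5", , ]
  expect_lt(max(others), 0.2)
})

test_that("couplings between spectrally disjoint bands are rejected", {
  expect_error(
    generate_subject(class_template("control",
                                    list(coupling_spec("FC5",
                                                       c("Theta", "Gamma"),
                                                       0.9))),
                     20, 500, 1),
    "boundary")
})

test_that("coupling respects its segment span and other electrodes' baseline", {
  tpl <- class_template("control",
                        list(coupling_spec("TP9", c("Beta", "Gamma"), 0.8,
                                           onset_segment = 2,
                                           offset_segment = 3)))
  rec <- generate_subject(tpl, duration_s = 25, sfreq = 500, seed = 41)
  cm <- cfs_matrix(extract_phases(rec))
  v <- cm["TP9", "Beta-Gamma", ]
  expect_gt(min(v[2:3]), 0.6)
  expect_lt(max(v[c(1, 4, 5)]), 0.2)
  # baseline distribution at uncoupled electrodes matches a couplings-free
  # cohort (two-sample check over seeds)
  plain <- class_template("control",
                          list(coupling_spec("FC5", c("Alpha", "Beta"), 0)))
  base <- unlist(lapply(1:2, function(s) {
    r <- generate_subject(plain, 20, 500, seed = 100 + s)
    cfs_matrix(extract_phases(r))[, "Beta-Gamma", ]
  }))
  coupled_others <- cm[rownames(cm) != "TP9", "Beta-Gamma", ]
  expect_lt(abs(mean(coupled_others) - mean(base)), 0.03)
  expect_lt(max(coupled_others), max(base) + 0.1)
})

test_that("cohorts carry study-sized labelling and per-subject seeds", {
  co <- make_cohort(33, 15, duration_s = 5, sfreq = 100, seed = 1)
  expect_length(co, 48)
  labs <- attr(co, "labels")
  expect_identical(sum(labs == "control"), 33L)
  expect_identical(sum(labs == "dyslexic"), 15L)
  expect_identical(vapply(co, function(r) r$label, ""), labs)
  two <- make_cohort(1, 1, duration_s = 5, sfreq = 100, seed = 1)
  expect_false(identical(two[[1]]$data, two[[2]]$data))
  expect_error(make_cohort(0, 1), ">= 1")
})

test_that("coupling_spec and class_template enforce their invariants", {
  expect_error(coupling_spec("FC5", c("Alpha", "Beta"), 1.5), "\\[0, 1\\]")
  expect_error(coupling_spec("FC5", c("Alpha", "Alpha"), 0.5), "distinct")
  expect_error(coupling_spec("FC5", c("Alpha", "Beta"), 0.5, 5, 2), "onset")
  expect_error(class_template("control", list()), "at least one")
  tpls <- default_templates()
  expect_false(identical(tpls$control$couplings, tpls$dyslexic$couplings))
})
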