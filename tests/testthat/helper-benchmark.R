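# Shared heavy fixtures for the acceptance suite, computed once per test run.
# Study-condition sizes: 33 control + 15 dyslexic subjects, 150 s at 500 Hz,
# 30 five-second segments, default class templates. The permutation-null
# cohort uses identical templates for both classes at a reduced sequence
# length (50 s -> 10 frames), which leaves the chance level untouched while
# keeping >= 20 permutation refits tractable.

.bench <- new.env(parent = emptyenv())

benchmark_geometry <- function() {
  if (is.null(.bench$geom)) {
    proj <- project_montage(montage_standard32())
    .bench$geom <- topo_geometry(proj)
    .bench$mask <- build_feature_mask(.bench$geom)
  }
  list(geom = .bench$geom, mask = .bench$mask)
}

cohort_to_sequences <- function(cohort, geom) {
  lapply(cohort, function(rec)
    unclass(stack_frames(cfs_matrix(extract_phases(rec)), geom = geom)))
}

benchmark_data <- function(seed = 101) {
  if (!is.null(.bench$data)) return(.bench$data)
  g <- benchmark_geometry()
  cohort <- make_cohort(33, 15, seed = seed)
  .bench$data <- list(seqs = cohort_to_sequences(cohort, g$geom),
                      labels = attr(cohort, "labels"),
                      cfs = lapply(cohort, function(rec)
                        cfs_matrix(extract_phases(rec))))
  .bench$data
}

benchmark_cv <- function(seed = 101) {
  if (!is.null(.bench$cv)) return(.bench$cv)
  d <- benchmark_data(seed)
  cfg <- cnn_lstm_config(frames = 30)
  .bench$cv <- cross_validate(d$seqs, d$labels, k = 5, cfg = cfg,
                              seed = seed, epochs = 40, batch_size = 8)
  .bench$cv
}

null_permutation_bal_acc <- function(n_perm = 20, seed = 202) {
  if (!is.null(.bench$null_ba)) return(.bench$null_ba)
  g <- benchmark_geometry()
  tpl <- default_templates()
  null_templates <- list(control = tpl$control,
                        dyslexic = tpl$control)  # identical generative law
  null_templates$dyslexic$name <- "dyslexic"
  cohort <- make_cohort(6, 6, templates = null_templates, seed = seed,
                        duration_s = 50)
  seqs <- cohort_to_sequences(cohort, g$geom)
  labels <- attr(cohort, "labels")
  cfg <- cnn_lstm_config(frames = 10)
  ba <- vapply(seq_len(n_perm), function(p) {
    set.seed(seed + p)
    perm <- sample(labels)
    cv <- cross_validate(seqs, perm, k = 5, cfg = cfg, seed = seed + p,
                         epochs = 10, batch_size = 4)
    cv$summary$mean[cv$summary$metric == "balanced_accuracy"]
  }, 0)
  .bench$null_ba <- ba
  ba
}
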