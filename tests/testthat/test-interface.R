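test_that("matrix + sidecar round trip preserves the recording", {
  set.seed(81)
  rec <- recording(matrix(rnorm(3 * 1000), 3), 250, c("C3", "C4", "Pz"),
                   subject_id = "S001", label = "control")
  f <- file.path(tempdir(), "S001.tsv")
  write_recording_matrix(rec, f)
  back <- read_eeg(f, format = "matrix", standardize = FALSE)
  expect_equal(back$data, rec$data, tolerance = 1e-6)
  expect_identical(back$sfreq, 250)
  expect_identical(back$channel_names, rec$channel_names)
  expect_identical(back$label, "control")
  # 500 Hz x 150 s bookkeeping
  expect_identical(eegcfs::n_samples(recording(matrix(0, 1, 75000), 500, "X")),
                   75000L)
  unlink(c(f, eegcfs:::sidecar_path(f)))
})

test_that("matrix format without a sidecar is an explicit error", {
  f <- tempfile(fileext = ".tsv")
  write.table(matrix(rnorm(20), 2), f, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  expect_error(read_eeg(f, format = "matrix"), "sidecar")
  sc <- eegcfs:::sidecar_path(f)
  yaml::write_yaml(list(channel_names = c("A", "B")), sc)
  expect_error(read_eeg(f, format = "matrix"), "sfreq")
  unlink(c(f, sc))
})

test_that("EDF round trip agrees to 16-bit quantisation", {
  set.seed(82)
  rec <- recording(matrix(rnorm(2 * 1000), 2), 100, c("Fp1", "Oz"),
                   subject_id = "edf01", label = "dyslexic")
  f <- tempfile(fileext = ".edf")
  write_edf(rec, f)
  back <- read_eeg(f, standardize = FALSE)
  expect_identical(dim(back$data), dim(rec$data))
  expect_identical(back$channel_names, rec$channel_names)
  expect_identical(back$label, "dyslexic")
  expect_identical(back$sfreq, 100)
  tol <- max(apply(rec$data, 1, function(r) diff(range(r)))) / 65535 * 2
  expect_lt(max(abs(back$data - rec$data)), tol)
  expect_warning(write_edf(recording(matrix(rnorm(150), 1), 100, "X"),
                           tempfile(fileext = ".edf")), "partial")
  unlink(f)
})

test_that("BrainVision triplets are parsed with scaling", {
  dir <- tempdir()
  set.seed(83)
  X <- matrix(rnorm(2 * 400), 2)
  eeg <- file.path(dir, "t.eeg")
  con <- file(eeg, "wb")
  writeBin(as.numeric(X), con, size = 4, endian = "little")
  close(con)
  vhdr <- file.path(dir, "t.vhdr")
  writeLines(c("Brain Vision Data Exchange Header File Version 1.0",
               "[Common Infos]", "DataFile=t.eeg", "DataFormat=BINARY",
               "DataOrientation=MULTIPLEXED", "NumberOfChannels=2",
               "SamplingInterval=2000",
               "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
               "[Channel Infos]", "Ch1=C3,,1,uV", "Ch2=C4,,1,uV"), vhdr)
  rec <- read_eeg(vhdr, standardize = FALSE)
  expect_identical(rec$sfreq, 500)
  expect_identical(rec$channel_names, c("C3", "C4"))
  # multiplexed: sample-major interleaving
  expect_equal(rec$data[1, 1:3], X[1, 1:3], tolerance = 1e-6)
  unlink(c(eeg, vhdr))
})

test_that("read_eeg z-scores channels by default", {
  rec <- recording(matrix(c(rnorm(500, 5, 2), rnorm(500, -3, 0.5)), 2,
                          byrow = TRUE), 100, c("A", "B"))
  f <- file.path(tempdir(), "z.tsv")
  write_recording_matrix(rec, f)
  z <- read_eeg(f, format = "matrix")
  expect_equal(max(abs(rowMeans(z$data))), 0, tolerance = 1e-9)
  expect_equal(unname(sqrt(rowMeans(z$data^2))), c(1, 1), tolerance = 1e-6)
  unlink(c(f, eegcfs:::sidecar_path(f)))
})

test_that("cohort export/import is inverse and manifest-driven", {
  co <- make_cohort(2, 1, duration_s = 5, sfreq = 100, seed = 9)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort_matrix(co, dir)
  manifest <- read.csv(file.path(dir, "manifest.csv"))
  expect_identical(manifest$label, c("control", "control", "dyslexic"))
  back <- read_cohort(dir, standardize = FALSE)
  expect_length(back, 3)
  expect_equal(back[[1]]$data, co[[1]]$data, tolerance = 1e-5)
  unlink(dir, recursive = TRUE)
})

test_that("pipeline config validates fast and hashes its content", {
  cfg <- pipeline_config(n_control = 4, n_dyslexic = 4, folds = 5)
  expect_error(run_pipeline(cfg), "exceeds")          # before any computation
  h1 <- eegcfs:::config_hash(pipeline_config(seed = 1, output_dir = "o"))
  h2 <- eegcfs:::config_hash(pipeline_config(seed = 2, output_dir = "o"))
  expect_identical(h1, eegcfs:::config_hash(pipeline_config(seed = 1,
                                                            output_dir = "o")))
  expect_false(identical(h1, h2))
  expect_error(pipeline_config(band_pairs = list(c("Alpha", "Beta"))) |>
                 run_pipeline(), "3 pairs")
})

test_that("small synthetic pipeline runs end to end, deterministically", {
  out1 <- file.path(tempdir(), "run1")
  out2 <- file.path(tempdir(), "run2")
  base <- list(n_control = 4, n_dyslexic = 4, duration_s = 20, folds = 2,
               epochs = 8, seed = 11, explain_subjects = 0)
  r1 <- run_pipeline(do.call(pipeline_config, c(base, output_dir = out1)),
                     quiet = TRUE)
  expect_s3_class(r1$cv, "cv_result")
  expect_true(file.exists(file.path(out1, "metrics.csv")))
  prov <- jsonlite::read_json(file.path(out1, "provenance.json"))
  expect_identical(prov$seed, 11L)
  expect_match(prov$config_hash, "^[0-9a-f]{32}$")
  r2 <- run_pipeline(do.call(pipeline_config, c(base, output_dir = out2)),
                     quiet = TRUE)
  m1 <- read.csv(file.path(out1, "metrics.csv"))
  m2 <- read.csv(file.path(out2, "metrics.csv"))
  expect_identical(m1, m2)                            # identical config+seed
  unlink(c(out1, out2), recursive = TRUE)
})
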