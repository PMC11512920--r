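#' Read an EEG recording
#'
#' Supported formats: plain numeric matrix with a YAML sidecar
#' (`format = "matrix"`), European Data Format (`"edf"`), and BrainVision
#' (`"brainvision"`, the `.vhdr` of the triplet). Channels are z-scored at
#' read time (zero mean, unit variance per channel) unless
#' `standardize = FALSE`, mirroring the acquisition-side preprocessing.
#'
#' @param path input file (`.tsv`/`.txt`, `.edf`, or `.vhdr`).
#' @param format one of `"auto"`, `"matrix"`, `"edf"`, `"brainvision"`.
#' @param standardize z-score channels after reading.
#' @param label optional class label override.
#' @return an `eeg_recording`.
#' @export
read_eeg <- function(path, format = c("auto", "matrix", "edf", "brainvision"),
                     standardize = TRUE, label = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", vhdr = "brainvision",
                     tsv = "matrix", txt = "matrix", dat = "matrix",
                     stop(sprintf("cannot infer format from '%s'", path)))
  }
  rec <- switch(format,
                matrix = read_recording_matrix(path),
                edf = read_edf(path),
                brainvision = read_brainvision(path))
  if (!is.null(label)) rec$label <- label
  if (standardize) rec <- standardize_recording(rec)
  rec
}

#' Plain-matrix recording files
#'
#' `write_recording_matrix` writes a channels x samples tab-separated matrix
#' plus a YAML sidecar (same stem, `.yaml`) carrying `sfreq`,
#' `channel_names`, `subject_id`, `label` and `montage`.
#' `read_recording_matrix` reads the pair back; a missing or sfreq-less
#' sidecar is an explicit format error.
#'
#' @param rec an `eeg_recording`.
#' @param path the data file path.
#' @param digits significant digits for the text export.
#' @return the path (write) / an `eeg_recording` (read).
#' @export
write_recording_matrix <- function(rec, path, digits = 7) {
  utils::write.table(signif(rec$data, digits), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(sfreq = rec$sfreq, channel_names = rec$channel_names,
               subject_id = rec$subject_id, label = rec$label,
               montage = "standard_1020_32")
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".yaml")

#' @rdname write_recording_matrix
#' @export
read_recording_matrix <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop(sprintf("matrix format requires sidecar '%s' (sfreq, channels)", sc))
  meta <- yaml::read_yaml(sc)
  if (is.null(meta$sfreq))
    stop(sprintf("sidecar '%s' lacks the sampling rate (sfreq)", sc))
  x <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(x) <- NULL
  recording(x, meta$sfreq, meta$channel_names,
            subject_id = meta$subject_id %||% tools::file_path_sans_ext(basename(path)),
            label = meta$label %||% "unknown")
}

# --- EDF ---------------------------------------------------------------

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  sprintf(paste0("%-", width, "s"), s)
}

#' European Data Format I/O
#'
#' Minimal EDF writer/reader for continuous recordings: 16-bit samples,
#' one-second data records, per-channel physical scaling from the data
#' range. Samples beyond the last whole second are dropped on write (EDF
#' stores whole records); round trips agree to the 16-bit quantisation of
#' each channel's range.
#'
#' @param rec an `eeg_recording` (integer `sfreq`).
#' @param path `.edf` file path.
#' @return the path (write) / an `eeg_recording` (read).
#' @export
write_edf <- function(rec, path) {
  ns <- nrow(rec$data)
  sf <- rec$sfreq
  if (abs(sf - round(sf)) > 1e-9) stop("EDF export needs an integer sampling rate")
  sf <- as.integer(round(sf))
  n_rec <- ncol(rec$data) %/% sf
  if (n_rec < 1) stop("recording shorter than one EDF record (1 s)")
  if (n_rec * sf < ncol(rec$data))
    warning("trailing partial second dropped in EDF export")
  pmin_ <- apply(rec$data, 1, min)
  pmax_ <- apply(rec$data, 1, max)
  span <- pmax_ - pmin_
  pmin_[span == 0] <- pmin_[span == 0] - 1
  pmax_[span == 0] <- pmax_[span == 0] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad_field("0", 8),
    pad_field(rec$subject_id, 80),
    pad_field(paste("label:", rec$label), 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 + ns * 256, 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field(1, 8),
    pad_field(ns, 4)), con, eos = NULL)
  fields <- list(c(16, rec$channel_names), c(80, rep("", ns)),
                 c(8, rep("uV", ns)),
                 c(8, formatC(pmin_, digits = 6, format = "g")),
                 c(8, formatC(pmax_, digits = 6, format = "g")),
                 c(8, rep("-32768", ns)), c(8, rep("32767", ns)),
                 c(80, rep("", ns)), c(8, rep(sf, ns)), c(32, rep("", ns)))
  for (f in fields) {
    w <- as.integer(f[1])
    for (v in f[-1]) writeChar(pad_field(v, w), con, eos = NULL)
  }
  # re-read header scaling (8-char ASCII) so writer and reader quantise alike
  pmin_r <- as.numeric(formatC(pmin_, digits = 6, format = "g"))
  pmax_r <- as.numeric(formatC(pmax_, digits = 6, format = "g"))
  scale <- (pmax_r - pmin_r) / 65535
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * sf + 1):(r * sf)
    for (ch in seq_len(ns)) {
      dig <- round((rec$data[ch, idx] - pmin_r[ch]) / scale[ch]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)
  subject_id <- rd(80)
  recinfo <- rd(80)
  rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labs <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-channel sampling rates not supported")
  sf <- spr[1] / dur
  X <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      X[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <-
        (raw - dmin[ch]) * scale[ch] + pmin_[ch]
    }
  }
  label <- if (grepl("label: ", recinfo)) sub("^label: ", "", recinfo) else "unknown"
  if (!label %in% c("control", "dyslexic")) label <- "unknown"
  recording(X, sf, labs, subject_id = subject_id, label = label)
}

# --- BrainVision -------------------------------------------------------

parse_vhdr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  section <- ""
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln) && nzchar(section)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

#' @rdname read_eeg
#' @export
read_brainvision <- function(path) {
  hdr <- parse_vhdr(path)
  ci <- hdr[["Common Infos"]]
  if (is.null(ci$SamplingInterval))
    stop(sprintf("'%s' lacks SamplingInterval", path))
  sf <- 1e6 / as.numeric(ci$SamplingInterval)
  nch <- as.integer(ci$NumberOfChannels)
  if (!identical(toupper(ci$DataOrientation %||% "MULTIPLEXED"), "MULTIPLEXED"))
    stop("only multiplexed BrainVision data supported")
  chinfo <- hdr[["Channel Infos"]]
  labs <- character(nch); res <- rep(1, nch)
  for (i in seq_len(nch)) {
    parts <- strsplit(chinfo[[paste0("Ch", i)]], ",")[[1]]
    labs[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) res[i] <- as.numeric(parts[3])
  }
  bf <- toupper(hdr[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")
  datafile <- file.path(dirname(path), ci$DataFile)
  sz <- file.info(datafile)$size
  con <- file(datafile, "rb")
  on.exit(close(con))
  if (bf == "IEEE_FLOAT_32") {
    n <- sz %/% 4
    raw <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  } else if (bf == "INT_16") {
    n <- sz %/% 2
    raw <- readBin(con, "integer", n = n, size = 2, endian = "little")
  } else stop(sprintf("unsupported BinaryFormat '%s'", bf))
  ns <- length(raw) %/% nch
  X <- matrix(raw[seq_len(ns * nch)], nrow = nch)
  X <- X * res
  recording(X, sf, labs, subject_id = tools::file_path_sans_ext(basename(path)))
}

# --- pipeline ----------------------------------------------------------

#' Pipeline configuration
#'
#' Referentially complete configuration for [run_pipeline()]: every stage
#' parameter with its default. Serialises cleanly to YAML and back.
#'
#' @param n_control,n_dyslexic synthetic cohort sizes (study sizes 33/15).
#' @param duration_s,sfreq recording geometry.
#' @param seed master seed; stage seeds derive from it.
#' @param band_pairs three band pairs forming the image layers.
#' @param window_s segmentation window (s).
#' @param mesh image mesh size.
#' @param folds cross-validation folds.
#' @param epochs,lr,batch_size,dropout,hidden,filters,fc1 training
#'   hyper-parameters.
#' @param explain_N LIME perturbation samples.
#' @param explain_subjects how many correctly classified subjects to
#'   explain (0 disables the explanation stage).
#' @param output_dir where artefacts are written.
#' @param input_dir read recordings from a manifest directory instead of
#'   simulating (`NULL` = simulate).
#' @param templates synthetic class templates.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_control = 33, n_dyslexic = 15,
                            duration_s = 150, sfreq = 500, seed = 1,
                            band_pairs = default_band_pairs(),
                            window_s = 5, mesh = 32, folds = 5,
                            epochs = 40, lr = 1e-3, batch_size = 8,
                            dropout = 0.5, hidden = 20, filters = c(8, 16),
                            fc1 = 16, explain_N = 1000,
                            explain_subjects = 0,
                            output_dir = tempfile("eegcfs_run_"),
                            input_dir = NULL,
                            templates = default_templates()) {
  cfgl <- as.list(environment())
  structure(cfgl, class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(lapply(unclass(config), unclass), tmp, compress = FALSE)
  unname(tools::md5sum(tmp))
}

validate_config <- function(config) {
  with(config, {
    if (folds > min(n_control, n_dyslexic))
      stop(sprintf("folds (%d) exceeds the smaller class count (%d)",
                   folds, min(n_control, n_dyslexic)))
    if (length(band_pairs) != 3) stop("band_pairs must list 3 pairs")
    if (duration_s < window_s) stop("duration shorter than one segment")
  })
  invisible(config)
}

#' Run the full pipeline
#'
#' Simulate (or read) the cohort, extract band phases, compute CFS
#' matrices, build image sequences, run stratified cross-validation, and
#' (optionally) explain correctly classified subjects. Artefacts (metrics
#' CSV, per-subject CFS CSVs, explanation CSVs, provenance JSON carrying
#' the config hash, seeds and timings) are written to
#' `config$output_dir`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list of class `pipeline_result`: `cv`, `sequences` metadata,
#'   `explanations`, `top`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  validate_config(config)
  t_start <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0, nm) {
    timings[[nm]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  }

  t0 <- tic()
  if (is.null(config$input_dir)) {
    say("simulating %d + %d subjects", config$n_control, config$n_dyslexic)
    cohort <- make_cohort(config$n_control, config$n_dyslexic,
                          templates = config$templates, seed = config$seed,
                          duration_s = config$duration_s, sfreq = config$sfreq)
  } else {
    cohort <- read_cohort(config$input_dir)
  }
  labels <- vapply(cohort, function(r) r$label, "")
  toc(t0, "cohort")

  t0 <- tic()
  mon <- default_montage()
  proj <- project_montage(mon)
  geom <- topo_geometry(proj, mesh = config$mesh)
  mask <- build_feature_mask(geom)
  spec <- segmentation_spec(config$window_s)
  say("transforming %d recordings into CFS image sequences", length(cohort))
  cfs_list <- lapply(cohort, function(rec) {
    tryCatch(cfs_matrix(extract_phases(rec), pairs = config$band_pairs,
                        spec = spec),
             error = function(e) stop(sprintf("CFS stage failed for %s: %s",
                                              rec$subject_id,
                                              conditionMessage(e))))
  })
  seqs <- lapply(cfs_list, function(cm) stack_frames(cm, geom = geom))
  toc(t0, "transform")

  n_frames <- dim(seqs[[1]])[4]
  cfg <- cnn_lstm_config(mesh = config$mesh, frames = n_frames,
                         hidden = config$hidden, filters = config$filters,
                         fc1 = config$fc1, dropout = config$dropout)
  t0 <- tic()
  say("cross-validating (%d folds)", config$folds)
  cv <- cross_validate(lapply(seqs, unclass), labels, k = config$folds,
                       cfg = cfg, seed = config$seed,
                       epochs = config$epochs, lr = config$lr,
                       batch_size = config$batch_size)
  write_cv_csv(cv, file.path(config$output_dir, "metrics.csv"),
               run_label = paste(vapply(config$band_pairs, paste, "",
                                        collapse = "-"), collapse = "_"))
  toc(t0, "cross_validation")

  explanations <- NULL; top <- NULL
  if (config$explain_subjects > 0) {
    t0 <- tic()
    model <- train_classifier(lapply(seqs, unclass), labels, cfg,
                              seed = config$seed, epochs = config$epochs,
                              lr = config$lr, batch_size = config$batch_size)
    pr <- predict(model, lapply(seqs, unclass))
    correct <- (max.col(pr) - 1L) == label_to_int(labels)
    sel <- which(correct)[seq_len(min(config$explain_subjects, sum(correct)))]
    say("explaining %d correctly classified subjects", length(sel))
    explanations <- lapply(sel, function(i)
      explain_sequence(model, unclass(seqs[[i]]), mask, N = config$explain_N,
                       seed = config$seed + i))
    top <- top_superpixels(explanations)
    for (j in seq_along(sel))
      write_explanation_csv(explanations[[j]],
                            file.path(config$output_dir,
                                      sprintf("explanation_%s.csv",
                                              cohort[[sel[j]]]$subject_id)))
    toc(t0, "explain")
  }

  prov <- list(config_hash = config_hash(config),
               seed = config$seed,
               package_version = as.character(utils::packageVersion("eegcfs")),
               r_version = R.version.string,
               timings_s = as.list(timings),
               started = format(t_start), finished = format(Sys.time()))
  jsonlite::write_json(prov, file.path(config$output_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(list(cv = cv, labels = labels, explanations = explanations,
                 top = top, provenance = prov,
                 output_dir = config$output_dir),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$cv)
  cat(sprintf("  artefacts: %s (config %s)\n", x$output_dir,
              substr(x$provenance$config_hash, 1, 8)))
  invisible(x)
}

#' Read a cohort exported by [write_cohort_matrix()]
#'
#' @param dir directory with `manifest.csv` and per-subject matrix files.
#' @param standardize z-score channels on read.
#' @return list of `eeg_recording`s with a `labels` attribute.
#' @export
read_cohort <- function(dir, standardize = TRUE) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    rec <- read_eeg(file.path(dir, paste0(manifest$subject[i], ".tsv")),
                    format = "matrix", standardize = standardize)
    rec$label <- manifest$label[i]
    rec
  })
  attr(out, "labels") <- manifest$label
  out
}
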