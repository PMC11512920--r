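#' EEG recordings
#'
#' An `eeg_recording` is a channels x samples numeric matrix with a sampling
#' rate, ordered channel labels (the montage minus the reference for
#' Cz-referenced data), a subject identifier and a class label.
#'
#' @param data numeric matrix, channels in rows.
#' @param sfreq sampling frequency in Hz.
#' @param channel_names character vector, one per row of `data`.
#' @param subject_id subject identifier string.
#' @param label class label: `"control"`, `"dyslexic"` or `"unknown"`.
#' @return object of class `eeg_recording`.
#' @export
recording <- function(data, sfreq, channel_names,
                      subject_id = "s01", label = "unknown") {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data)))
    stop("recording data must be finite numeric")
  if (sfreq <= 0) stop("sfreq must be positive")
  if (length(channel_names) != nrow(data))
    stop("channel_names must match the number of data rows")
  label <- match.arg(label, c("control", "dyslexic", "unknown"))
  structure(list(data = data, sfreq = sfreq,
                 channel_names = as.character(channel_names),
                 subject_id = as.character(subject_id), label = label),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$label, nrow(x$data), ncol(x$data), x$sfreq,
              ncol(x$data) / x$sfreq))
  invisible(x)
}

#' @rdname recording
#' @param rec an `eeg_recording`.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Z-score each channel (zero mean, unit variance)
#'
#' Mirrors the acquisition-side preprocessing convention: every channel is
#' normalised to zero mean and unit variance. Constant channels are left at
#' zero mean with unit scale.
#'
#' @param rec an `eeg_recording`.
#' @return the standardised `eeg_recording`.
#' @export
standardize_recording <- function(rec) {
  mu <- rowMeans(rec$data)
  x <- rec$data - mu
  s <- sqrt(rowMeans(x^2))
  s[s < 1e-12] <- 1
  rec$data <- x / s
  rec
}
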