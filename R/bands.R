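#' Canonical EEG frequency bands
#'
#' The five canonical bands with their band-pass cut-offs. Filter lengths are
#' derived from the sampling rate by [fir_length()] unless overridden; at
#' 500 Hz the derived lengths are 3301 (Delta), 825 (Theta), 825 (Alpha),
#' 551 (Beta) and 221 (Gamma) samples.
#'
#' @param name,f_low,f_high,filter_length band definition fields;
#'   `filter_length` may be `NA` to derive it from the sampling rate.
#' @return `band_definition` returns a one-row data.frame of class
#'   `band_definition`; `canonical_bands` the five-band table.
#' @export
canonical_bands <- function() {
  out <- data.frame(
    name = c("Delta", "Theta", "Alpha", "Beta", "Gamma"),
    f_low = c(0.5, 4, 8, 12, 30),
    f_high = c(4, 8, 12, 30, 80),
    filter_length = NA_integer_,
    stringsAsFactors = FALSE)
  class(out) <- c("band_table", "data.frame")
  out
}

#' @rdname canonical_bands
#' @export
band_definition <- function(name, f_low, f_high, filter_length = NA_integer_) {
  if (!(f_low > 0 && f_low < f_high)) stop("need 0 < f_low < f_high")
  if (!is.na(filter_length) && filter_length %% 2 == 0)
    stop("filter_length must be odd (linear-phase type I)")
  out <- data.frame(name = name, f_low = f_low, f_high = f_high,
                    filter_length = as.integer(filter_length),
                    stringsAsFactors = FALSE)
  class(out) <- c("band_definition", "data.frame")
  out
}

#' Derived FIR band-pass filter length
#'
#' Hamming-windowed design rule: the transition bandwidth is
#' `df = min(max(0.25 * f_low, 2), f_low)` Hz and the length is
#' `ceil(3.3 / df * sfreq)` rounded up to the next odd integer. At 500 Hz
#' this reproduces the lengths 3301/825/825/551/221 for the canonical bands.
#'
#' @param f_low lower band edge in Hz.
#' @param sfreq sampling frequency in Hz.
#' @return odd integer filter length in samples.
#' @export
fir_length <- function(f_low, sfreq) {
  df <- min(max(0.25 * f_low, 2), f_low)
  L <- ceiling(3.3 / df * sfreq)
  if (L %% 2 == 0) L <- L + 1
  as.integer(L)
}

#' Design a linear-phase band-pass FIR filter
#'
#' Hamming-windowed time-domain design (via [signal::fir1]). The filter is
#' symmetric (type I linear phase) with group delay `(length - 1) / 2`
#' samples.
#'
#' @param band a `band_definition` or one row of [canonical_bands()].
#' @param sfreq sampling frequency in Hz.
#' @param filter_length optional odd length; defaults to the band's
#'   `filter_length` or, when that is `NA`, to [fir_length()].
#' @return list of class `fir_filter` with elements `h` (coefficients),
#'   `delay` (group delay in samples), `band`, `sfreq`.
#' @export
design_fir <- function(band, sfreq, filter_length = NULL) {
  if (band$f_high >= sfreq / 2)
    stop(sprintf("band %s: f_high (%g Hz) must be below Nyquist (%g Hz)",
                 band$name, band$f_high, sfreq / 2))
  L <- filter_length
  if (is.null(L)) L <- band$filter_length
  if (is.null(L) || is.na(L)) L <- fir_length(band$f_low, sfreq)
  L <- as.integer(L)
  if (L %% 2 == 0) stop("filter length must be odd")
  h <- as.numeric(signal::fir1(L - 1L, c(band$f_low, band$f_high) / (sfreq / 2),
                               type = "pass"))
  structure(list(h = h, delay = (L - 1L) %/% 2L,
                 band = band$name, sfreq = sfreq),
            class = "fir_filter")
}

#' Frequency response magnitude of an FIR filter
#'
#' @param filt a `fir_filter` (or coefficient vector).
#' @param freqs frequencies in Hz.
#' @param sfreq sampling rate (taken from the filter when omitted).
#' @return magnitude response at `freqs`.
#' @export
fir_response <- function(filt, freqs, sfreq = NULL) {
  if (inherits(filt, "fir_filter")) {
    h <- filt$h
    if (is.null(sfreq)) sfreq <- filt$sfreq
  } else h <- as.numeric(filt)
  k <- seq_along(h) - 1
  vapply(freqs, function(f) Mod(sum(h * exp(-2i * pi * f * k / sfreq))), 0)
}

# Zero-phase transfer function of a linear-phase FIR on an FFT grid of
# length nfft: A(f) = H(f) * exp(+i w delay), real-valued.
fir_zero_phase_tf <- function(h, delay, nfft) {
  H <- stats::fft(c(h, rep(0, nfft - length(h))))
  w <- 2 * pi * (seq_len(nfft) - 1) / nfft
  Re(H * exp(1i * w * delay))
}

#' Band-pass filter a recording with delay compensation
#'
#' Filters every channel with the band's linear-phase FIR and shifts the
#' output by the constant group delay `(length - 1) / 2` samples, so in-band
#' components are time-aligned with the input (zero-phase equivalent).
#' Output length equals input length; the first and last `delay` samples are
#' computed against implicit zero padding and are flagged via the
#' `edge_samples` attribute.
#'
#' @param rec an `eeg_recording`.
#' @param band a band definition row.
#' @param filter_length optional odd FIR length override.
#' @return filtered `eeg_recording` with attribute `edge_samples`.
#' @export
bandpass <- function(rec, band, filter_length = NULL) {
  filt <- design_fir(band, rec$sfreq, filter_length)
  n <- ncol(rec$data)
  if (n <= length(filt$h))
    stop(sprintf("recording (%d samples) shorter than %s filter (%d samples)",
                 n, band$name, length(filt$h)))
  nfft <- stats::nextn(n + length(filt$h), c(2, 3, 5))
  A <- fir_zero_phase_tf(filt$h, filt$delay, nfft)
  out <- rec
  out$data <- t(apply(rec$data, 1, function(x) {
    X <- stats::fft(c(x, rep(0, nfft - n)))
    Re(stats::fft(X * A, inverse = TRUE))[seq_len(n)] / nfft
  }))
  attr(out, "edge_samples") <- filt$delay
  attr(out, "band") <- band$name
  out
}

#' Instantaneous phase via the analytic signal
#'
#' Builds the analytic signal `z(t) = x(t) + j H[x(t)]` by zeroing negative
#' frequencies in the DFT and returns its angle. The wrapped phase lies in
#' (-pi, pi]; `unwrap = TRUE` returns the cumulative (unwrapped) phase. The
#' phase-difference resultant used downstream is invariant to wrapping.
#'
#' @param x numeric time series.
#' @param unwrap return the unwrapped phase?
#' @return phase in radians, same length as `x`.
#' @export
analytic_phase <- function(x, unwrap = FALSE) {
  if (length(x) < 2) stop("need at least 2 samples")
  if (anyNA(x) || any(!is.finite(x))) stop("input must be finite")
  if (all(x == 0)) {
    warning("all-zero input: phase undefined, returning zeros")
    return(numeric(length(x)))
  }
  z <- analytic_signal(x)
  ph <- Arg(z)
  if (unwrap) ph <- unwrap_phase(ph)
  ph
}

# Analytic signal via the frequency-domain construction.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  mask <- numeric(n)
  mask[1] <- 1
  if (n %% 2 == 0) {
    mask[2:(n / 2)] <- 2
    mask[n / 2 + 1] <- 1
  } else {
    mask[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * mask, inverse = TRUE) / n
}

#' @rdname analytic_phase
#' @param ph wrapped phase in radians.
#' @export
unwrap_phase <- function(ph) {
  d <- diff(ph)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(ph[1], ph[1] + cumsum(d))
}

#' Instantaneous band phases for all channels
#'
#' Band-pass filters every channel in each requested band (delay-compensated
#' linear-phase FIR) and computes the instantaneous phase of the analytic
#' signal, on the full-length signal before any segmentation. The filter and
#' Hilbert steps are fused in the frequency domain: one forward FFT per
#' channel, then one inverse FFT per (channel, band).
#'
#' @param rec an `eeg_recording`.
#' @param bands band table (default [canonical_bands()]).
#' @return object of class `phase_tensor`: array channels x bands x samples
#'   (radians) with attributes `sfreq`, `band_names`, `channel_names`,
#'   `edge_samples` (per band).
#' @export
extract_phases <- function(rec, bands = canonical_bands()) {
  n <- ncol(rec$data)
  nch <- nrow(rec$data)
  nb <- nrow(bands)
  filts <- lapply(seq_len(nb), function(i) design_fir(bands[i, ], rec$sfreq))
  maxlen <- max(vapply(filts, function(f) length(f$h), 0L))
  if (n <= maxlen)
    stop("recording shorter than the longest band filter")
  nfft <- stats::nextn(n + maxlen, c(2, 3, 5))
  # analytic-signal mask on the padded grid
  mask <- numeric(nfft)
  mask[1] <- 1
  if (nfft %% 2 == 0) { mask[2:(nfft / 2)] <- 2; mask[nfft / 2 + 1] <- 1
  } else mask[2:((nfft + 1) / 2)] <- 2
  tfs <- lapply(filts, function(f) fir_zero_phase_tf(f$h, f$delay, nfft) * mask)
  ph <- array(NA_real_, dim = c(nch, nb, n))
  pad <- rep(0, nfft - n)
  for (ci in seq_len(nch)) {
    X <- stats::fft(c(rec$data[ci, ], pad))
    for (bi in seq_len(nb)) {
      z <- stats::fft(X * tfs[[bi]], inverse = TRUE)[seq_len(n)] / nfft
      ph[ci, bi, ] <- Arg(z)
    }
  }
  structure(ph, class = "phase_tensor", sfreq = rec$sfreq,
            band_names = bands$name, channel_names = rec$channel_names,
            edge_samples = vapply(filts, function(f) f$delay, 0L),
            subject_id = rec$subject_id, label = rec$label)
}

#' @export
print.phase_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<phase_tensor> %d channels x %d bands x %d samples @ %g Hz\n",
              d[1], d[2], d[3], attr(x, "sfreq")))
  cat(" bands:", paste(attr(x, "band_names"), collapse = ", "), "\n")
  invisible(x)
}
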