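#' Temporal segmentation
#'
#' Non-overlapping rectangular windows (default 5 s); a trailing partial
#' window is discarded, so a 150 s recording yields 30 segments.
#'
#' @param window_s window length in seconds (> 0).
#' @param overlap overlap in seconds (0 <= overlap < window_s; default 0).
#' @return object of class `segmentation_spec`.
#' @export
segmentation_spec <- function(window_s = 5, overlap = 0) {
  if (window_s <= 0) stop("window_s must be positive")
  if (overlap < 0 || overlap >= window_s) stop("need 0 <= overlap < window_s")
  structure(list(window_s = window_s, overlap = overlap),
            class = "segmentation_spec")
}

#' Split a phase series into segments
#'
#' @param phase numeric vector (instantaneous phase or any series).
#' @param spec a [segmentation_spec()].
#' @param sfreq sampling rate in Hz.
#' @return list of numeric vectors, one per complete window.
#' @export
segment_phase <- function(phase, spec = segmentation_spec(), sfreq) {
  win <- round(spec$window_s * sfreq)
  step <- round((spec$window_s - spec$overlap) * sfreq)
  n <- length(phase)
  if (n < win) stop("series shorter than one segmentation window")
  starts <- seq(1L, n - win + 1L, by = step)
  lapply(starts, function(s) phase[s:(s + win - 1L)])
}

# Number of non-overlapping complete windows.
segment_count <- function(n_samples, spec, sfreq) {
  win <- round(spec$window_s * sfreq)
  step <- round((spec$window_s - spec$overlap) * sfreq)
  if (n_samples < win) 0L else as.integer((n_samples - win) %/% step + 1L)
}

#' Cross-frequency phase-synchronisation value
#'
#' The modulus of the time-averaged unit phasor of the phase differences
#' between two bands at one site:
#' `S_CF = | 1/n * sum_t exp(i (phi_A(t) - phi_B(t))) |`.
#' The value lies in \[0, 1\], is invariant to adding a constant to either
#' series and to wrapping, and equals 1 iff the phase difference is constant.
#' For independent uniform phases its expectation is the Rayleigh resultant
#' `~ sqrt(pi / (4 n))`.
#'
#' `ratio` optionally generalises to n:m locking, replacing the difference by
#' `n * phi_A - m * phi_B`; the default `c(1, 1)` matches the plain
#' phase-difference definition used throughout this package.
#'
#' @param phi_a,phi_b equal-length phase vectors in radians.
#' @param ratio integer pair `(n, m)` for n:m locking; default `c(1, 1)`.
#' @return scalar in \[0, 1\].
#' @export
cfs_value <- function(phi_a, phi_b, ratio = c(1, 1)) {
  if (length(phi_a) != length(phi_b)) stop("phase series lengths differ")
  n <- length(phi_a)
  if (n < 1) stop("empty phase series")
  d <- ratio[1] * phi_a - ratio[2] * phi_b
  Mod(mean(exp(1i * d)))
}

#' CFS matrix: electrodes x band pairs x segments
#'
#' Applies [cfs_value()] to every electrode, requested band pair and
#' temporal segment of a phase tensor.
#'
#' @param phases a `phase_tensor` from [extract_phases()].
#' @param pairs list of 2-element character vectors (band name pairs), or a
#'   2-column character matrix. Default: [default_band_pairs()].
#' @param spec a [segmentation_spec()].
#' @return object of class `cfs_matrix`: numeric array electrodes x pairs x
#'   segments with dimnames, and attributes `band_pairs`, `subject_id`,
#'   `label`.
#' @export
cfs_matrix <- function(phases, pairs = default_band_pairs(),
                       spec = segmentation_spec()) {
  stopifnot(inherits(phases, "phase_tensor"))
  bn <- attr(phases, "band_names")
  pairs <- normalize_pairs(pairs)
  for (p in pairs) {
    if (!all(p %in% bn))
      stop(sprintf("unknown band in pair %s-%s (have: %s)",
                   p[1], p[2], paste(bn, collapse = ", ")))
  }
  sfreq <- attr(phases, "sfreq")
  d <- dim(phases)
  win <- round(spec$window_s * sfreq)
  ns <- segment_count(d[3], spec, sfreq)
  if (ns < 1) stop("recording shorter than one segmentation window")
  step <- round((spec$window_s - spec$overlap) * sfreq)
  starts <- seq(1L, by = step, length.out = ns)
  pair_names <- vapply(pairs, function(p) paste0(p[1], "-", p[2]), "")
  out <- array(NA_real_, dim = c(d[1], length(pairs), ns),
               dimnames = list(attr(phases, "channel_names"), pair_names, NULL))
  for (pi in seq_along(pairs)) {
    ia <- match(pairs[[pi]][1], bn)
    ib <- match(pairs[[pi]][2], bn)
    # vectorised over channels and segments
    dphi <- exp(1i * (phases[, ia, , drop = FALSE] - phases[, ib, , drop = FALSE]))
    dim(dphi) <- c(d[1], d[3])
    for (si in seq_len(ns)) {
      idx <- starts[si]:(starts[si] + win - 1L)
      out[, pi, si] <- Mod(rowMeans(dphi[, idx, drop = FALSE]))
    }
  }
  structure(out, class = "cfs_matrix", band_pairs = pairs,
            subject_id = attr(phases, "subject_id"),
            label = attr(phases, "label"),
            window_s = spec$window_s)
}

#' @rdname cfs_matrix
#' @export
default_band_pairs <- function() {
  list(c("Theta", "Gamma"), c("Alpha", "Beta"), c("Beta", "Gamma"))
}

normalize_pairs <- function(pairs) {
  if (is.matrix(pairs)) pairs <- lapply(seq_len(nrow(pairs)), function(i) pairs[i, ])
  if (is.character(pairs) && length(pairs) == 2) pairs <- list(pairs)
  lapply(pairs, function(p) {
    if (length(p) != 2 || p[1] == p[2])
      stop("each band pair must be two distinct band names")
    as.character(p)
  })
}

#' @export
print.cfs_matrix <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<cfs_matrix> %s [%s]: %d electrodes x %d pairs x %d segments\n",
              attr(x, "subject_id"), attr(x, "label"), d[1], d[2], d[3]))
  cat(" pairs:", paste(dimnames(x)[[2]], collapse = ", "), "\n")
  invisible(x)
}

#' Write a CFS matrix as tidy CSV
#'
#' One row per (electrode, band pair, segment); segments are reported
#' 1-based.
#'
#' @param cfs a `cfs_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cfs_csv <- function(cfs, path) {
  d <- dim(cfs)
  df <- expand.grid(electrode = dimnames(cfs)[[1]],
                    pair = dimnames(cfs)[[2]],
                    segment = seq_len(d[3]),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$subject <- attr(cfs, "subject_id")
  df$label <- attr(cfs, "label")
  df$value <- as.vector(cfs)
  utils::write.csv(df[, c("subject", "label", "electrode", "pair",
                          "segment", "value")], path, row.names = FALSE)
  invisible(path)
}
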