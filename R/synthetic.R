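#' Von Mises resultant length and its inversion
#'
#' `vm_resultant` computes the mean resultant length `A(kappa) =
#' I1(kappa) / I0(kappa)` of a von Mises distribution with concentration
#' `kappa`. `coupling_to_concentration` inverts it by monotone bisection:
#' given a target phase-synchronisation value in \[0, 1) it returns the
#' concentration whose expected resultant equals the target, the analytic
#' calibration used by the synthetic generator and the estimator tests.
#'
#' @param kappa concentration parameter (>= 0).
#' @param target_cfs target resultant length in \[0, 1).
#' @param tol bisection tolerance.
#' @return `vm_resultant`: value in \[0, 1). `coupling_to_concentration`:
#'   concentration `kappa >= 0`; exactly 0 for target 0; `Inf` (with a
#'   warning) as the degenerate zero-jitter sentinel for target 1.
#' @export
vm_resultant <- function(kappa) {
  ifelse(kappa <= 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' @rdname vm_resultant
#' @export
coupling_to_concentration <- function(target_cfs, tol = 1e-8) {
  if (!is.finite(target_cfs) || target_cfs < 0 || target_cfs > 1)
    stop("target_cfs must lie in [0, 1]")
  if (target_cfs == 1) {
    warning("degenerate target_cfs = 1: use zero jitter")
    return(Inf)
  }
  if (target_cfs == 0) return(0)
  hi <- 1
  while (vm_resultant(hi) < target_cfs) hi <- hi * 2
  lo <- 0
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (vm_resultant(mid) < target_cfs) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Draw von Mises variates
#'
#' Best-Fisher (1979) rejection sampler; uses R's RNG stream.
#'
#' @param n number of draws.
#' @param kappa concentration (>= 0); 0 gives uniform angles; `Inf` gives
#'   zeros.
#' @param mu mean direction in radians.
#' @return angles in (-pi, pi\].
#' @export
rvonmises <- function(n, kappa, mu = 0) {
  if (!is.finite(kappa)) return(rep(mu, n))
  if (kappa < 1e-9) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    z <- cos(pi * stats::runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    acc <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(acc)
    if (k > 0) {
      th <- sign(stats::runif(k) - 0.5) * acos(pmax(-1, pmin(1, f[acc])))
      out[(got + 1L):(got + k)] <- th
      got <- got + k
    }
  }
  wrap_pi(out + mu)
}

wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Coupling specifications and class templates
#'
#' A `coupling_spec` injects elevated cross-frequency phase synchronisation
#' at one electrode for one ordered band pair over a span of temporal
#' segments. Couplings are realised as coherent bursts of a shared carrier
#' at the pair's common band boundary (e.g. 12 Hz for Alpha-Beta): both
#' band-pass filters pass the same boundary component, so their
#' instantaneous phases lock, and the within-segment duty cycle of the
#' bursts sets the segment CFS to `target_cfs`. Band pairs without a shared
#' boundary are rejected: the 1:1 phase-difference resultant between
#' spectrally disjoint bands is pinned near the Rayleigh floor for any
#' waveform, because a band-limited signal's phase must advance at an
#' in-band rate (see the methods vignette).
#'
#' @param electrode montage label.
#' @param band_pair two distinct canonical band names whose ranges share a
#'   boundary frequency.
#' @param target_cfs target segment CFS in \[0, 1\].
#' @param onset_segment,offset_segment 1-based segment span the coupling
#'   covers (default: all segments).
#' @return `coupling_spec` object.
#' @export
coupling_spec <- function(electrode, band_pair, target_cfs,
                          onset_segment = 1L, offset_segment = Inf) {
  if (!is.finite(target_cfs) || target_cfs < 0 || target_cfs > 1)
    stop("target_cfs must lie in [0, 1]")
  band_pair <- as.character(band_pair)
  if (length(band_pair) != 2 || band_pair[1] == band_pair[2])
    stop("band_pair must be two distinct band names")
  if (onset_segment > offset_segment) stop("onset_segment must be <= offset_segment")
  structure(list(electrode = electrode, band_pair = band_pair,
                 target_cfs = target_cfs,
                 onset_segment = onset_segment,
                 offset_segment = offset_segment),
            class = "coupling_spec")
}

#' @rdname coupling_spec
#' @param name class name, `"control"` or `"dyslexic"`.
#' @param couplings list of `coupling_spec`s (at least one).
#' @param noise_exponent 1/f^a background-noise power exponent (default 1).
#' @param band_amplitudes named non-negative amplitudes per canonical band.
#' @param noise_scale standard deviation of the background noise relative to
#'   a unit-amplitude band oscillation.
#' @export
class_template <- function(name, couplings, noise_exponent = 1,
                           band_amplitudes = c(Delta = 1.2, Theta = 1,
                                               Alpha = 1, Beta = 0.8,
                                               Gamma = 0.5),
                           noise_scale = 0.35) {
  if (length(couplings) < 1) stop("need at least one coupling_spec")
  if (inherits(couplings, "coupling_spec")) couplings <- list(couplings)
  stopifnot(all(vapply(couplings, inherits, TRUE, "coupling_spec")))
  if (any(band_amplitudes < 0)) stop("band amplitudes must be >= 0")
  structure(list(name = name, couplings = couplings,
                 noise_exponent = noise_exponent,
                 band_amplitudes = band_amplitudes,
                 noise_scale = noise_scale),
            class = "class_template")
}

#' Default benchmark class templates
#'
#' Control and dyslexic templates differing in three electrode/band-pair
#' couplings, the synthetic analogue of the group-difference topographies
#' reported for the syllable-rate stimulus: dyslexic recordings carry a
#' raised temporo-parietal (TP9) Alpha-Beta coupling and an extra right
#' frontal (F4) Beta-Gamma coupling, control recordings a left fronto-central
#' (FC5) Alpha-Beta coupling; both share a CP1 Beta-Gamma coupling. Effect
#' sizes are fixture choices, not measured quantities.
#'
#' @return named list of two `class_template`s.
#' @export
default_templates <- function() {
  list(
    control = class_template("control", list(
      coupling_spec("FC5", c("Alpha", "Beta"), 0.85),
      coupling_spec("CP1", c("Beta", "Gamma"), 0.75))),
    dyslexic = class_template("dyslexic", list(
      coupling_spec("TP9", c("Alpha", "Beta"), 0.85),
      coupling_spec("CP1", c("Beta", "Gamma"), 0.75),
      coupling_spec("F4", c("Beta", "Gamma"), 0.6))))
}

# Shared boundary frequency of a band pair, or stop.
pair_boundary <- function(band_pair, bands) {
  i <- match(band_pair, bands$name)
  if (anyNA(i)) stop(sprintf("unknown band in pair %s-%s",
                             band_pair[1], band_pair[2]))
  a <- bands[i[1], ]; b <- bands[i[2], ]
  if (isTRUE(all.equal(a$f_high, b$f_low))) return(a$f_high)
  if (isTRUE(all.equal(b$f_high, a$f_low))) return(b$f_high)
  stop(sprintf(paste0(
    "bands %s and %s share no boundary frequency: a 1:1 phase-difference ",
    "coupling between spectrally disjoint bands cannot survive band-pass ",
    "filtering (phase winding); use an adjacent pair"),
    band_pair[1], band_pair[2]))
}

# 1/f^a noise via spectral shaping of white noise, unit variance.
pink_noise <- function(n, exponent, f_floor = 0.5, sfreq = 500) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, sfreq, length.out = n + 1)[seq_len(n)]
  f[f > sfreq / 2] <- sfreq - f[f > sfreq / 2]
  shape <- pmax(f, f_floor)^(-exponent / 2)
  shape[1] <- 0
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Smooth burst window: fraction `duty` of each covered segment, with
# raised-cosine ramps, evaluated on the full sample grid.
burst_window <- function(n, sfreq, window_s, segments, duty, ramp_s = 0.05) {
  w <- numeric(n)
  win <- round(window_s * sfreq)
  ramp <- round(ramp_s * sfreq)
  for (s in segments) {
    s0 <- (s - 1L) * win + 1L
    if (s0 > n) next
    len <- max(2L * ramp + 2L, round(duty * win) + ramp)
    len <- min(len, win)
    idx <- s0:(min(s0 + len - 1L, n))
    env <- rep(1, length(idx))
    r <- min(ramp, floor(length(idx) / 2))
    if (r > 0) {
      up <- 0.5 * (1 - cos(pi * seq_len(r) / r))
      env[seq_len(r)] <- up
      env[(length(idx) - r + 1L):length(idx)] <- rev(up)
    }
    w[idx] <- env
  }
  w
}

#' Generate one synthetic EEG recording
#'
#' Each channel is the sum of amplitude-weighted narrowband oscillations
#' (one per canonical band, carrier at the band's geometric mid-frequency
#' with slow phase diffusion) and 1/f background noise. For every coupling
#' in the template, coherent bursts of a shared carrier at the band pair's
#' boundary frequency replace the two bands' own oscillations at the named
#' electrode during the covered segments; the within-segment duty cycle
#' equals `target_cfs`, so the pipeline's segment CFS at that electrode
#' approaches the target. Channels are z-scored before return.
#'
#' @param template a [class_template()].
#' @param duration_s recording length in seconds (>= 5).
#' @param sfreq sampling rate in Hz.
#' @param seed integer seed; the same call with the same seed is bitwise
#'   reproducible.
#' @param mon montage (default bundled 32-electrode 10-20 cap); the
#'   reference electrode is omitted from the generated channels.
#' @param bands band table.
#' @param subject_id,segment_window_s bookkeeping fields.
#' @return an `eeg_recording` with `label = template$name`.
#' @export
generate_subject <- function(template, duration_s = 150, sfreq = 500, seed = 1,
                             mon = default_montage(),
                             bands = canonical_bands(),
                             subject_id = sprintf("sim%04d", seed),
                             segment_window_s = 5) {
  if (duration_s < segment_window_s)
    stop("duration_s must cover at least one segment window")
  stopifnot(inherits(template, "class_template"))
  chan <- setdiff(mon$label, attr(mon, "reference"))
  for (cp in template$couplings) {
    if (!cp$electrode %in% chan)
      stop(sprintf("coupling electrode '%s' not in montage", cp$electrode))
    pair_boundary(cp$band_pair, bands)  # validates adjacency
  }
  n <- round(duration_s * sfreq)
  n_seg <- floor(duration_s / segment_window_s)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  amps <- template$band_amplitudes[bands$name]
  amps[is.na(amps)] <- 0
  tvec <- (seq_len(n) - 1) / sfreq
  X <- matrix(0, length(chan), n)
  for (ci in seq_along(chan)) {
    couplings <- Filter(function(cp) cp$electrode == chan[ci],
                        template$couplings)
    gate <- matrix(0, nrow(bands), n)  # per-band suppression weight
    sig <- numeric(n)
    for (cp in couplings) {
      f_edge <- pair_boundary(cp$band_pair, bands)
      segs <- seq(max(1L, cp$onset_segment), min(n_seg, cp$offset_segment))
      # duty cycle calibrated for the in-burst coherence factor: band-edge
      # filter dynamics smear the burst boundaries and background noise
      # jitters the phases, so a fully covered segment yields ~0.93, not 1
      duty <- min(1, cp$target_cfs / 0.93)
      w <- burst_window(n, sfreq, segment_window_s, segs, duty)
      theta <- 2 * pi * f_edge * tvec + stats::runif(1, -pi, pi) +
        cumsum(stats::rnorm(n, 0, 0.005))
      # strong carrier keeps the burst's in-band SNR high enough that
      # background-noise phase jitter costs only a few percent of resultant
      a_c <- 3 * max(amps[match(cp$band_pair, bands$name)], 0.5)
      sig <- sig + w * a_c * cos(theta)
      bi <- match(cp$band_pair, bands$name)
      gate[bi[1], ] <- pmax(gate[bi[1], ], w)
      gate[bi[2], ] <- pmax(gate[bi[2], ], w)
    }
    for (bi in seq_len(nrow(bands))) {
      if (amps[bi] <= 0) next
      f_c <- sqrt(bands$f_low[bi] * bands$f_high[bi])
      theta <- 2 * pi * f_c * tvec + stats::runif(1, -pi, pi) +
        cumsum(stats::rnorm(n, 0, 0.02))
      sig <- sig + (1 - gate[bi, ]) * amps[bi] * cos(theta)
    }
    sig <- sig + template$noise_scale *
      sqrt(sum(amps^2)) * pink_noise(n, template$noise_exponent, sfreq = sfreq)
    X[ci, ] <- sig
  }
  rec <- recording(X, sfreq, chan, subject_id = subject_id,
                   label = template$name)
  standardize_recording(rec)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a labelled synthetic cohort
#'
#' Default sizes mirror the study cohort: 33 control and 15 dyslexic
#' subjects. Per-subject seeds are `seed + subject index`, so cohorts are
#' reproducible while subjects stay independent.
#'
#' @param n_control,n_dyslexic subject counts (>= 1).
#' @param templates named list with `control` and `dyslexic`
#'   [class_template()]s.
#' @param duration_s,sfreq,mon,bands passed to [generate_subject()].
#' @param seed base integer seed.
#' @return list of `eeg_recording`s (controls first), with attribute
#'   `labels`.
#' @export
make_cohort <- function(n_control = 33, n_dyslexic = 15,
                        templates = default_templates(), seed = 1,
                        duration_s = 150, sfreq = 500,
                        mon = default_montage(), bands = canonical_bands()) {
  if (n_control < 1 || n_dyslexic < 1) stop("subject counts must be >= 1")
  labels <- c(rep("control", n_control), rep("dyslexic", n_dyslexic))
  out <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    out[[i]] <- generate_subject(
      templates[[labels[i]]], duration_s = duration_s, sfreq = sfreq,
      seed = seed + i, mon = mon, bands = bands,
      subject_id = sprintf("S%03d", i))
  }
  attr(out, "labels") <- labels
  out
}

#' Export a cohort as plain-text matrices with sidecar metadata
#'
#' Writes, per subject, `<id>.tsv` (channels x samples, tab separated) and
#' `<id>.yaml` (sfreq, channel names, label, montage name), plus a
#' `manifest.csv` of subject ids and labels.
#'
#' @param cohort list of `eeg_recording`s.
#' @param dir output directory (created if needed).
#' @param digits signif digits for the text export.
#' @return the manifest path, invisibly.
#' @export
write_cohort_matrix <- function(cohort, dir, digits = 7) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(cohort, function(r) r$subject_id, "")
  labs <- vapply(cohort, function(r) r$label, "")
  for (rec in cohort) {
    write_recording_matrix(rec, file.path(dir, paste0(rec$subject_id, ".tsv")),
                           digits = digits)
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(subject = ids, label = labs), manifest,
                   row.names = FALSE)
  invisible(manifest)
}
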