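---
title: "Cross-frequency synchronisation image sequences: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-frequency synchronisation image sequences: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(eegcfs)
```

## The measure

`eegcfs` studies intra-electrode cross-frequency phase synchronisation (CFS)
in multichannel EEG. For two frequency bands $A$ and $B$ at one electrode,
with instantaneous phases $\phi_A(t)$ and $\phi_B(t)$, the measure is the
resultant length of the phase-difference phasors over a temporal segment of
$n$ samples:

$$S_{\mathrm{CF}} \;=\; \Bigl|\tfrac{1}{n}\sum_{t=1}^{n}
  e^{\,i(\phi_A(t)-\phi_B(t))}\Bigr| \in [0,1].$$

This is the intra-electrode, cross-band variant of intersite phase
clustering. $S_{\mathrm{CF}} = 1$ iff the wrapped phase difference is
constant over the segment; for independent uniform phases its expectation is
the Rayleigh resultant $\sqrt{\pi/(4n)}$ ($\approx 0.0177$ at $n = 2500$),
which is the effective noise floor of every map this package draws.
The difference is strictly 1:1 as the measure is defined; `cfs_value()`
exposes an optional $n{:}m$ ratio for harmonic locking, but every default in
the package uses 1:1.

### A bound worth knowing about

The long-run winding rate of the instantaneous phase of a band-limited
signal lies inside its band: a Hilbert phase that advances at 6 Hz belongs
to a signal with 6 Hz spectral content. Consequently the 1:1 phase
difference between two *spectrally disjoint* bands (Theta 4–8 Hz versus
Gamma 30–80 Hz, say) winds at no less than the gap between the bands, and
$S_{\mathrm{CF}}$ over a 5-s segment is pinned near the Rayleigh floor for
*any* waveform. Elevated 1:1 CFS is physically possible only for band pairs
that share spectral content — in practice, adjacent bands with a common
cut-off (Alpha–Beta at 12 Hz, Beta–Gamma at 30 Hz), where broadband
activity at the boundary is passed by both filters. This is consistent with
what the measure shows on real recordings: Alpha–Beta carries the largest
values, Theta–Gamma sits near the floor. It also dictates how the synthetic
generator injects couplings (below), and why it refuses disjoint pairs.

## From signal to phases

Recordings are z-scored per channel (read-time preprocessing,
`standardize = TRUE`). Each channel is decomposed into the five canonical
bands with Hamming-windowed linear-phase FIR band-pass filters:

| band  | pass band (Hz) | length at 500 Hz |
|-------|----------------|------------------|
| Delta | 0.5–4          | 3301             |
| Theta | 4–8            | 825              |
| Alpha | 8–12           | 825              |
| Beta  | 12–30          | 551              |
| Gamma | 30–80          | 221              |

The lengths derive from the transition-bandwidth rule
$\Delta f = \min(\max(0.25\,f_{\mathrm{low}},\,2\,\mathrm{Hz}),\,f_{\mathrm{low}})$,
$L = \lceil 3.3/\Delta f \cdot f_s\rceil$ rounded up to odd — the standard
Hamming-window design heuristic — and are overridable per band. Linear
phase matters because the phase, not the amplitude, is the signal of
interest here: the constant group delay $(L-1)/2$ is compensated exactly by
a shift, so in-band components are time-aligned with the input. The first
and last $(L-1)/2$ samples are computed against zero padding and flagged
via the `edge_samples` attribute; with 150-s recordings they touch only the
outermost 3 % of the first and last segment, so segments are used in full.

Instantaneous phase is the angle of the analytic signal
$z(t) = x(t) + jH[x(t)]$, built in the frequency domain on the full,
unsegmented band signal (filter → phase → segment, in that order).
`extract_phases()` fuses the filter and the analytic construction: one
forward FFT per channel, one inverse FFT per (channel, band). Phases are
returned wrapped; the resultant is wrap-invariant, and `unwrap_phase()` is
available where a cumulative phase is wanted.

Segmentation uses non-overlapping rectangular 5-s windows; a trailing
partial window is discarded (150 s at 500 Hz → exactly 30 segments of 2500
samples).

## From phases to images

Electrode positions sit on a unit sphere (the bundled 32-electrode 10–20
cap is constructed from the idealized arc-placement rules, not measured
digitisations) and are flattened with the azimuthal equidistant projection
centred on the Cz reference: $\rho = R\,c$ with $c$ the angular distance
from Cz, $x = \rho\sin\theta$, $y = -\rho\cos\theta$, nose up. The
projection preserves radial order exactly, so scalp topography survives
flattening.

Per segment and band pair, the 31 electrode CFS values are interpolated
with a Clough–Tocher $C^1$ piecewise-cubic scheme on the Delaunay
triangulation of the projected electrodes, evaluated on a fixed square
$32\times32$ mesh covering the electrode cloud plus a 5 % margin. The
implementation is self-contained (Bowyer–Watson triangulation; centroid
split; per-vertex gradients by distance-weighted least squares over
triangulation neighbours; mid-edge ordinates from the linear
normal-derivative condition) and reproduces constant and affine fields at
the $10^{-9}$ level, the property the tests pin down. Because the
interpolant is linear in the electrode values, the whole render collapses
into a precomputed $1024\times31$ operator, making frame rendering a
matrix product. Out-of-hull pixels are 0 — zero synchronisation renders
black — and stored frames keep raw CFS values in $[0,1]$ with no per-frame
normalisation (display normalisation is display-only).

Three band pairs form the three layers of each frame; the default triplet
is Theta–Gamma / Alpha–Beta / Beta–Gamma, configurable. A subject thus
becomes a sequence of 30 RGB frames of $32\times32$ pixels.

The **feature mask** assigns every in-hull pixel to its nearest projected
electrode (planar Euclidean distance): a Voronoi partition of the scalp
image into 31 super-pixels, each the "area of influence" of one electrode.
Nearest-electrode assignment is the deterministic realisation of "pixels
most affected by the corresponding electrode"; interpolating a label image
is ill-defined, so this is a design choice, stated as such.

## The synthetic cohort

The study cohort this methodology was developed on is not publicly
deposited, so the package ships a generator whose defaults emulate the
acquisition geometry: 31 Cz-referenced channels, 500 Hz, 150 s per subject,
33 control + 15 dyslexic subjects, per-subject seeds `seed + index`.

Each channel is a sum of per-band narrowband oscillations (carrier at the
band's geometric mid-frequency — a choice that keeps carriers inside the
filter pass-bands — with slow phase diffusion) plus $1/f$ background noise
(spectrally shaped white noise, power exponent 1 by default, overall scale
0.35 relative to the oscillation amplitudes). Default band amplitudes
(Delta 1.2, Theta 1.0, Alpha 1.0, Beta 0.8, Gamma 0.5) follow the usual
decreasing-power profile of scalp EEG.

A `coupling_spec(electrode, band_pair, target_cfs, onset, offset)` injects
elevated CFS as **coherent bursts of a shared carrier at the pair's common
band boundary** (12 Hz for Alpha–Beta, 30 Hz for Beta–Gamma): both filters
pass the same boundary component, their phases lock, and the within-segment
duty cycle of the bursts dials the segment CFS. The duty cycle is
`target_cfs / 0.93`; the fixed 0.93 is the in-burst coherence factor — the
band-edge filter dynamics smear the burst boundaries and in-band background
noise jitters the phases, so a fully covered segment yields about 0.93
rather than 1. The burst carrier is deliberately strong (3× the larger
band amplitude): phase is amplitude-invariant, so carrier strength buys
phase SNR without changing what the estimator sees. Band pairs without a
shared boundary are rejected with an explanatory error — per the bound
above, no waveform can satisfy such a request, and silently producing
floor-level CFS would be worse than refusing.

The von Mises machinery (`coupling_to_concentration()`, `rvonmises()`,
`vm_resultant()`) provides the analytic calibration of the *estimator*: a
target resultant $t$ maps to the concentration $\kappa$ with
$I_1(\kappa)/I_0(\kappa) = t$ (monotone bisection to $10^{-8}$), and the
tests verify that jittered phase pairs recover every target within
Monte-Carlo error. At the waveform level the von Mises jitter cannot be
used directly — the shared boundary carrier is one physical signal, so the
two band paths cannot receive independent phase noise — which is why the
waveform dial is the duty cycle, calibrated as above.

Default class templates differ in three electrode/pair couplings: control
carries FC5 Alpha–Beta 0.85, dyslexic carries TP9 Alpha–Beta 0.85 plus F4
Beta–Gamma 0.6, and both share CP1 Beta–Gamma 0.75. The electrode choices
mirror the qualitative group description the method was reported with
(raised temporo-parietal coupling in dyslexics, left fronto-central
coupling tied to controls, right-hemisphere compensation); the magnitudes
are fixture choices, not measured effect sizes. What passing the benchmark
shows is therefore that the *pipeline* — filters, phases, images,
classifier, explainer — recovers planted, spatially localised coupling
differences end to end. It does not show that real cohorts separate this
cleanly: the generator has no volume conduction, no stimulus-locked
responses, no artefacts, and far larger effects than any real group
difference.

## Classifier

A two-stage model. Per frame, a convolutional encoder: two $3\times3$
convolutions (8 then 16 filters, the second with stride 2 to bound the
flattened size at $16\times16\times16 = 4096$), each followed by batch
normalisation and ReLU, then flattening. Filter counts, kernel and strides
are configurable; the defaults are deliberately small — the images are
$32\times32$ and the planted structure is coarse. Per sequence, a stacked
two-layer LSTM with hidden size 20 consumes the 30 frame features; the
concatenated hidden states pass through dropout (0.5, training only) and
two fully-connected layers ending in two class logits.

The network is implemented in RcppArmadillo (im2col convolutions as BLAS
gemms, full backpropagation through time, Adam with learning rate
$10^{-3}$, minibatches of 8 subjects, inverse-class-frequency loss weights
by default, early stop when the epoch-mean training loss falls below 0.03).
Every random element — initialisation, shuffling, dropout masks — derives
from the caller's seed, so training is bitwise reproducible. The gradient
code is validated in the test suite by finite differences on a small
configuration, and the convolution and LSTM cell against brute-force and
hand-computed oracles at $10^{-10}$.

Evaluation is stratified five-fold cross-validation *by subject* (one
sequence per subject, so no frame leakage across folds), with a freshly
initialised model per fold. Metrics: sensitivity $TP/(TP+FN)$, specificity
$TN/(TN+FP)$, balanced accuracy (their mean — robust to the 33:15
imbalance), and AUC as the normalised rank statistic of the positive-class
score (equal to the Mann–Whitney statistic, which the tests use as the
oracle).

## Explanation

`explain_frame()` is a feature-mask variant of LIME. For one frame, $N$
binary instances $z' \in \{0,1\}^{31}$ are drawn (fair independent coins;
the intact instance is always included); switched-off super-pixels are set
to 0 (absent CFS, matching the imaging zero-fill; a mean-fill alternative
is exposed through `fill`), all other frames stay untouched. The model is
scored on each perturbed sequence — the LSTM is resumed from its cached
state before the perturbed frame, so only that frame re-enters the CNN and
the $N$ sequence evaluations share everything upstream. Samples are
weighted by $\pi_x = \exp(-D^2/w^2)$ with $D$ the Euclidean distance
between the original and perturbed frame in pixel space (the one perturbed
frame, matching the perturbation scheme), and a lasso surrogate is fitted
to design → score. The study default is $N = 10{,}000$ samples per frame.

Two parameters are unavoidably free and fixed once:

* **kernel width** — $0.25\sqrt{d'}$ on the binary design scale, mapped to
  pixel space through the RMS pixel mass of one average super-pixel of the
  explained frame, so that switching off $k$ super-pixels sits at distance
  $\approx\sqrt{k}$ design units;
* **lasso penalty** — a fixed $\lambda = 10^{-3}$ *on the normalised score
  scale* (the effective penalty is $\lambda \cdot \mathrm{sd}(\text{scores})$,
  so explanations behave identically whether the model's output varies by
  0.5 or by $10^{-3}$ — a well-trained softmax saturates and single-frame
  perturbation effects become small), chosen once on surrogate fidelity
  against a planted linear oracle (the tests require weighted
  $R^2 \ge 0.99$ there) rather than re-tuned per frame: determinism beats
  per-frame optimality for comparing maps across frames and subjects.

`explain_sequence()` applies this to all 30 frames (LIME applied 30 times
per subject); `top_superpixels()` averages maps over selected — typically
correctly classified — subjects and keeps the five largest-magnitude
super-pixels per frame, signed (positive toward the explained class, the
green/red encoding of `render_relevance()`/`plot_topo()`). Since which
class's probability is explained is a genuine ambiguity, the explained
class is an argument (`class`, default the positive/dyslexic class), and
both class-conditional aggregations can be produced by calling
`top_superpixels()` on the corresponding subject subsets.

## Numerical choices and degenerate inputs

* `cfs_value` on an empty segment is an error; length mismatches are
  errors, not recycling.
* All-zero signals have undefined phase: `analytic_phase` warns and
  returns zeros.
* `target_cfs = 1` is degenerate for the Bessel-ratio inversion
  ($\kappa \to \infty$); `coupling_to_concentration` warns and returns
  `Inf`, which `rvonmises` treats as zero jitter.
* A frame the model is insensitive to yields an exactly zero coefficient
  row (guarded before the lasso, which cannot fit a constant response).
* Cocircular electrode quadruples (the idealized montage is
  mirror-symmetric) make the Delaunay triangulation non-unique; insertion
  order fixes it deterministically, and every property used downstream
  (hull coverage, affine exactness, $C^1$) holds for either diagonal.
* Ties in the argmax decision rule resolve to the first (control) class;
  AUC handles score ties by mid-ranks.

## Problem sizes used by the shipped checks

The test suite exercises the full study geometry where the quantity under
test needs it and scales down elsewhere: the end-to-end benchmark uses the
complete 33 + 15 cohort at 150 s (30 frames); the permutation-null check
uses 6 + 6 subjects at 50 s (10 frames) and 20 label permutations — chance
level is unaffected by sequence length, and the shorter sequences keep 100
cross-validated refits tractable; explanation recovery uses `N = 1000`
perturbations per frame on 8 correctly classified subjects (4 per class).
Estimator calibrations run at the sizes their error analysis dictates
($n = 10^5$ for the von Mises check, $10^4$ replicates of $n = 2500$ for
the Rayleigh floor).

## Known limitations

* The generator's realism is deliberately limited (no volume conduction,
  no evoked responses, stationary couplings within their segment span);
  it validates the pipeline, not clinical claims.
* The 1:1 measure cannot register cross-frequency relations between
  disjoint bands (see the bound above); $n{:}m$ locking is exposed in
  `cfs_value` but not propagated through the imaging defaults.
* Between-electrode synchronisation and amplitude–phase coupling are out
  of scope.
* The Clough–Tocher gradients are estimated locally; global
  curvature-minimising estimation (as some other implementations use)
  differs at the few-percent level in the interior, which is far below the
  planted effects but visible in direct comparisons.
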