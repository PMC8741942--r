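---
title: "Contactless AF detection from rPPG: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contactless AF detection from rPPG: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rppgaf)
```

## The problem

Atrial fibrillation (AF) is the "irregularly irregular" arrhythmia: beat-to-beat
(RR) intervals fluctuate strongly and without serial correlation. Because the
cardiac pulse modulates skin color by a fraction of a percent, an ordinary
camera pointed at a face can recover the pulse waveform without any body
contact — remote photoplethysmography (rPPG). This package implements a
complete contactless AF-screening pipeline:

1. **Simulate** facial RGB traces whose color is driven by a rhythm-specific
   RR-interval process (plus illumination drift, sensor noise and motion
   artifacts), at 84 samples/s.
2. **Extract** the pulse by chrominance projection and a 4th-order
   Chebyshev type-II 0.5–3 Hz zero-phase bandpass.
3. **Segment** the filtered signal into non-overlapping 30-s clips,
   z-normalized per clip.
4. **Classify** each clip with a sample-level 12-layer 1-D convolutional
   network (11 convolutional layers + a fully-connected head) trained
   in-package.
5. **Vote**: a subject is called AF when strictly more than 50% of their
   clips are called AF; performance is reported from subject-grouped
   10-fold cross-validation with confusion-matrix metrics and ROC/AUC, plus
   a segment-length sensitivity sweep.

Because no clinical recordings are available, the synthetic cohort generator
is a first-class, tested component: it defines the study conditions under
which the pipeline is validated.

## The rhythm simulator

The generator separates *rhythm* (an RR-interval process), *pulse*
(a waveform rendered from the intervals) and *observation* (the camera's
three color channels).

### RR-interval models

No deposited RR statistics exist for the population this emulates, so the
models below are deliberately minimal processes that reproduce the clinical
discriminant — irregular irregularity — without claiming detailed
physiological fidelity. All parameters are exposed as arguments of
`simulate_rr()` rather than hard-coded.

| rhythm | model | defaults |
|---|---|---|
| NSR | base interval $60/\mathrm{HR} \cdot (1 + a\sin 2\pi f_r t)$, multiplicative Gaussian jitter | $a = 0.03$, $f_r = 0.25$ Hz, jitter CV 0.02 |
| AF | i.i.d. Gamma intervals, clipped to [0.3, 2] s | CV 0.24 |
| APC / VPC | NSR with per-beat ectopy: premature beat at 0.6×/0.5× the interval, compensatory pause 1.4×/1.5×, reduced pulse amplitude (0.8/0.5) | ectopy probability 0.1 |
| sinus arrhythmia | NSR with $a = 0.15$ | |
| sinus tachy / brady | NSR at 110 / 50 bpm | |
| flutter | atrial 300/min, ventricular 2:1 ↔ 4:1 block switching every ~20–40 s | 1% jitter |

These choices give a strict variability ordering (AF CV ≈ 0.24 ≫ sinus
arrhythmia ≈ 0.11 ≫ NSR ≈ 0.03, each separated by at least 2×) and
serially independent AF intervals (lag-1 autocorrelation centered on zero),
both asserted by property tests. Every interval is clipped to the
physiological range [0.25, 3] s, and beats are accepted while the cumulative
time fits the requested duration, so generation is bit-reproducible from the
parameters and seed.

Per-subject mean heart rates are drawn from overlapping rhythm-appropriate
ranges (NSR 55–85, AF 70–110, other 55–95 bpm). The overlap is intentional:
rate alone must not separate the classes, so the classifier has to use the
interval structure.

### Pulse and camera model

Each beat contributes a two-Gaussian template — systolic peak at 30% of the
local RR interval (width 0.08 s, unit amplitude) and a dicrotic wave at 55%
(width 0.1 s, amplitude 0.35) — and the summed waveform is normalized to
unit peak. The camera model inverts the rPPG observation:

$$c(t) = B_c\,\bigl(1 + k_c\, s\, p(t) + d(t)\bigr) + \varepsilon_c(t) + m(t)$$

with per-channel baselines $B = (150, 110, 90)$, relative pulsatile
signatures $(k_r, k_g, k_b) = (0.33, 0.77, 0.53)$ (the standard
skin-reflection ratios, green strongest), pulse strength $s = 0.5\%$ of
baseline, a common-mode illumination drift $d$ (0.1-Hz band-limited random
walk, 1% of baseline), per-channel sensor noise $\varepsilon$ (SD 0.2
intensity units) and sparse common-mode motion artifacts $m$ (one 0.5-s,
5-intensity-unit triangular transient per minute on average). The noise
defaults are chosen so the 0.5–3 Hz bandpass is exercised meaningfully:
drift sits below the band, sensor noise is broadband, artifacts are
impulsive. `render_frames()` can optionally expand a trace into flat
synthetic video frames (skin rectangle + constant background + per-pixel
noise) so the ROI-averaging front end is testable end-to-end.

## Pulse extraction

`chrominance_project()` implements the chrominance (CHROM) method as the
default: channels are normalized by their mean inside 1.6-s windows,
combined as $X = 3\hat r - 2\hat g$ and $Y = 1.5\hat r + \hat g - 1.5\hat
b$, and demixed as $S = X - (\sigma_X/\sigma_Y) Y$; windows are blended by
raised-cosine overlap-add at 50% overlap. The fixed coefficients cancel
intensity (motion/illumination) modulation while retaining the pulsatile
component — a property the test suite asserts directly (intensity-only
modulation retains at most 10% of the power of pulsatile modulation of
equal depth). The plane-orthogonal-to-skin (POS) projection and the plain
mean-centered green channel are provided as alternatives; which method the
original clinical system used cannot be determined, so the choice is
config-visible.

The bandpass is a Chebyshev type-II design: flat passband, equiripple
stopband, specified by its stopband edges (0.5 and 3 Hz) and attenuation
(40 dB; the attenuation is a convention of ours, exposed in config). It is
applied forward-backward (`signal::filtfilt`) so beat timing is preserved
exactly; offline processing permits zero-phase filtering. Auto-gain
behavior is deliberately absent: no trace is rescaled unless explicitly
normalized.

`estimate_hr()` reports 60× the argmax of a Welch-averaged periodogram
(Hann windows of 20 s, 50% overlap, 4× zero-padding) over 0.5–3 Hz.
Averaging matters for AF: the full-length periodogram of an irregular pulse
train fragments into narrow lines whose global maximum can sit far from the
mean rate, while the Welch estimate concentrates at the spectral mode. Even
so, the spectral mode of a heavy-tailed interval process is not the mean
rate, so accuracy claims for AF are made on seed ensembles (median error),
not per recording.

`quality_check()` computes an in-band SNR — power within ±0.1 Hz of the
dominant peak and its first harmonic versus the remaining 0.5–3 Hz power —
and excludes recordings below 2 dB. The threshold stands in for the kind
of unreadable-signal exclusion a clinical protocol would apply by eye; at
default noise synthetic subjects pass with several dB of margin while
pure-noise traces land well below zero.

## Segmentation and datasets

Segmentation is non-overlapping, anchored at the first sample, remainder
discarded: a 10-min recording yields exactly 20 thirty-second segments, and
a 484-s one yields 16. Each segment is z-normalized — rPPG amplitude units
are arbitrary, so the classifier must be scale-invariant; a constant
segment becomes all-zeros with an explicit degenerate flag. Three binary
datasets are assembled (AF vs NSR, AF vs Others, AF vs Non-AF); AF maps
to 1 in all of them and every segment inherits its subject's label.

## The classifier

The network follows the sample-level raw-waveform design: kernel size 3
throughout, channel widths (16, 16, 32, 32, 64, 64, 64, 128, 128, 128,
256), max-pool of 3 (floor semantics) after layers 1–5, batch-norm and
ReLU after every convolution, a global pool collapsing the remaining
temporal extent (length 10 at 30 s, i.e. ~3 s per deep position), dropout
0.5, and a single sigmoid output unit — 12 weight layers, 258,513
conv+head parameters. `default_arch()` adapts the pooling depth for other
segment lengths so the schedule never exhausts the signal; the global
pool absorbs the difference (this is what the segment-length sweep relies
on at 15 s).

The global pool is a **mean**, not a max, and this choice is load-bearing.
A max-pool chain collapsing the signal to a single position computes
existence-type statistics ("does any window look irregular?"), which
cannot distinguish atrial fibrillation — where *every* interval is
irregular — from occasional ectopy, where a few premature-beat events
punctuate an otherwise regular rhythm. Averaging the deep feature maps
over time gives the head the *density* of locally detected irregularity,
the discriminating statistic. Empirically the max-pool-to-length-1
variant plateaued near chance on the AF-vs-other-abnormality contrast
while the mean-pool design separates it; the max variant remains
available (`arch_config(global_pool = "max")`).

Everything is implemented in vectorized R on BLAS matrix products (im2col
convolutions): there is no deep-learning framework in the package's
dependency footprint, and training a cohort-scale model takes seconds per
epoch on one CPU. Backpropagation is verified against finite differences
to ~1e-10 in the test suite, and training is bit-deterministic under a
fixed seed (initialization, shuffling, dropout masks, augmentation draws
and the validation split all derive from it).

### Optimization and the rate-shortcut problem

Defaults: Adam (initial lr $10^{-3}$ with a cosine decay to a tenth over
the run), batch 32, binary cross-entropy with optional inverse-frequency
class weights (recommended for the imbalanced AF vs Non-AF task),
decoupled weight decay $10^{-4}$, early stopping on a held-out validation
split with patience 10. The packaged cohort-scale evaluations use lr
$2 \cdot 10^{-3}$, a fixed epoch budget and no validation hold-out (all
training subjects train; the cosine schedule makes the final epoch the
operating point).

Two details matter on small cohorts and were adopted after observing the
failure they prevent:

* **Subject-level validation.** A segment-level validation split shares
  subjects with the training set, so validation loss tracks within-subject
  recall rather than generalization. The validation hold-out therefore
  removes whole subjects (stratified by label).
* **Tempo augmentation.** Each training segment carries its subject's
  nearly constant heart rate, and with few dozen training subjects a
  high-capacity network happily memorizes per-subject spectral signatures
  instead of learning rhythm irregularity: training accuracy reaches 1.0
  while held-out-subject accuracy stalls near chance-plus-rate. Each batch
  is therefore tempo-compressed on the fly: segment $j$ is resampled at a
  random stride $s_j \sim U(0.75, 1)$ from a random offset and
  re-standardized, multiplying the apparent rate by $1/s_j$ while leaving
  interval *structure* untouched. Rate ceases to identify a subject (or a
  class), and the network is forced onto rate-invariant irregularity
  features. Validation and test segments are never augmented. Both
  behaviors are config-visible (`train_config(augment = , val_fraction = )`).

## Evaluation

* `make_folds()` deals shuffled units round-robin per class, so folds are
  stratified and differ by at most one unit. The default grouping is
  subject-level (no subject spans folds — the leakage-safe protocol);
  segment-level partitioning is available as a fidelity mode and the
  report names the mode used.
* `cross_validate()` trains on $k-1$ folds and evaluates the hold-out, so
  every segment receives exactly one out-of-fold probability; per-fold
  metrics are reported as mean ± sample SD (n−1), alongside pooled
  out-of-fold results. Segment probabilities become calls at 0.5 (the
  segment threshold is our convention; ROC curves use the raw
  probabilities).
* `vote_subject()` implements the strict rule: AF if and only if the
  fraction of AF-called segments exceeds 0.5 — a 10/20 tie is non-AF.
* `confusion_metrics()` uses exact count arithmetic and flags undefined
  ratios (e.g. PPV with no positive calls) instead of zeroing them.
* `roc_auc()` sweeps tie-grouped thresholds and integrates trapezoidally,
  so the AUC equals the Mann–Whitney concordance probability to 1e-12
  (asserted against a brute-force pairwise oracle).
* `segment_length_sweep()` re-segments, re-trains and re-votes per window
  length (15–300 s), flagging lengths that exceed the shortest recording.
  A cheaper mode reuses one trained model across lengths (the global pool
  makes the network length-agnostic); it is not faithful to a
  retrain-per-length protocol, but on small cohorts it is the better
  probe of the window-length effect itself, since per-length retraining
  confounds window length with training-set size (a 120-s window cuts the
  number of training segments eightfold versus 15 s).

Whether subject-level metrics should pool out-of-fold votes or average
per-fold subject metrics is ambiguous in such protocols; both are computed
(`subject$pooled`, `subject$per_fold`) and labeled.

## Problem sizes used in the tests

The packaged validation runs at desk scale, chosen to exercise every
mechanism rather than to reproduce clinical effect sizes: the
learning-stack check uses 60 subjects (20 AF / 20 NSR / 20 mixed-other),
5-min recordings at default noise, subject-grouped 10-fold
cross-validation and a reduced epoch budget; the segment-length sweep
compares 15-s and 120-s windows on a smaller cohort over 10 seeds and
checks the median ordering (longer windows average more beats per vote).
Ensemble statistics in the simulator tests use 100 seeds.

## What passing tests do and do not show

The generator reproduces the *discriminative mechanism* — irregular
irregularity expressed through a pulse waveform and a noisy camera — but
real recordings differ in ways the simulator does not model: face motion
and tracking error, illumination spectra and shadows, compression
artifacts, skin-tone diversity beyond fixed baselines, waveform morphology
variation between subjects, and pathologies outside the closed subtype
list. Passing the packaged checks therefore validates the pipeline's
plumbing and its ability to recover rhythm structure from this observation
model; it does not establish clinical accuracy on human data.

## Numerical choices and degenerate inputs

* Batch-norm $\epsilon = 10^{-5}$, running-stat momentum 0.1; evaluation
  always uses running statistics and no dropout.
* Max-pool and global-max ties break toward the earliest position.
* Chrominance windows with zero-variance $Y$ fall back to the $X$
  component alone; constant traces project to exactly zero.
* A segment with SD below $10^{-12}$ z-normalizes to all-zeros and is
  flagged degenerate rather than dividing by ~0.
* Probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ inside the loss.
* An empty RR series renders a zero pulse wave of the requested length
  (not an error); recordings shorter than one segment yield an empty
  segment list.
* Seeds: every subject seed is a deterministic 31-bit mix of the master
  seed and subject index, so cohorts are reproducible and all derived
  seeds remain valid R seeds.

## Known limitations

The 0.5–3 Hz pulse band bounds the temporal resolution of beat timing:
intervals shorter than about 0.33 s cannot be resolved, and the narrowband
filter's ringing both blurs the fast, irregular intervals of atrial
fibrillation at high rates and adds spurious jitter around ectopic beats.
AF-versus-NSR discrimination is therefore much cleaner through this chain
than AF-versus-ectopy, where the margin between "everywhere irregular" and
"occasionally irregular" narrows at the segment level; subject-level
voting recovers much of it by averaging over segments. Training is
CPU-bound at roughly 0.15 s per 32-segment batch at 30-s segments;
cohort-scale tenfold cross-validation is minutes, not seconds. The flutter model switches block ratio abruptly rather than
probabilistically per beat; the ectopy model ignores interpolated (non-
compensatory) beats; no attempt is made to render realistic faces or video
compression. The voting threshold is fixed at the strict 0.5 rule — on
cohorts with different AF prevalence a recalibrated cut point would be
appropriate.
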