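---
title: "Multivariate successive variational mode decomposition: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate successive variational mode decomposition: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvsvmd)
```

## The model

A multi-channel recording `f(t) = [f_1(t), ..., f_C(t)]` is decomposed into
`L` common band-limited intrinsic modes plus a residual,
`f_k = Σ_i u_ik + r_k`. All channels at scale `l` share one center
frequency `ω_l`; what differs per channel is the waveform `u_lk`. Scales
are extracted **successively** — the number of modes is not fixed in
advance — by minimizing three spectral cost terms:

* **L1** — the pooled bandwidth of the current modes: the energy of the
  derivative of each channel's analytic signal demodulated to `ω_l`,
  which in the spectral domain is `Σ_k ∫ (ω − ω_l)² |û_lk(ω)|² dω`.
* **L2** — the energy of everything that is *not* the current mode (the
  unprocessed part plus previously extracted modes) after passing through
  the scale-`l` filter `β̂_l(ω) = 1/(α (ω − ω_l)²)`, which peaks at `ω_l`:
  this forces the new mode to claim all energy near its own center.
* **L3** — the energy of the current mode seen through the filters of the
  `l − 1` previously extracted scales: this keeps the new mode away from
  centers already taken.

subject to exact reconstruction, handled by an augmented Lagrangian and
ADMM. All three terms are available as diagnostics via `cost_terms()`.

Each ADMM iteration alternates, on the one-sided grid `ω ≥ 0`:

1. a per-channel Wiener-type filter update of `û_lk` (`update_modes()`),
   whose gain is exactly 1 at `ω_l` and decays with `(ω − ω_l)²`, with an
   extra pole suppressing bins near prior centers;
2. the pooled power-weighted centroid update of `ω_l`
   (`update_center_frequency()`), evaluated by the trapezoid rule;
3. optional dual ascent on the multipliers (`update_multipliers()`).

Convergence of the inner loop requires the squared relative change of the
mode spectrum to fall below `epsilon1` **in every channel**. The penalty
`α` is then grown as `alpha_min + exp(m)` and the loop restarts from the
converged state (multipliers reset), stopping when the next step would
exceed `alpha_max`: a coarse-to-fine sweep that first locks onto the
strongest residual structure with a wide filter and then narrows it. Two
points are deliberately resolved here because the printed algorithm leaves
them open: `α` grows once per *converged sweep*, not per iteration, and
the prior-mode filters `β̂_i` are always evaluated with the *current* `α`,
exactly as the update formula is written, even though those modes were
extracted at other `α` values.

Extraction of new scales stops when the newest mode's pooled mean energy
`Σ_k ||u_lk||²/T` drops below `epsilon2` — such a mode is regarded as noise,
discarded, and left inside the residual — or when the working residual
itself is already below `epsilon2`, or at the `max_modes` safety cap.
Retained modes are sorted by center frequency ascending, and the residual
is defined by subtraction, so `input = Σ modes + residual` holds to machine
precision by construction.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha_min`, `alpha_max` | 200, 800 | dimensionless (on normalized frequency) | bandwidth-penalty sweep range; 200–800 suits 400 Hz canine iEEG, 200–2000 human iEEG at 500 Hz |
| `epsilon1` | 1e-6 | relative (squared) | inner ADMM convergence tolerance |
| `epsilon2` | 1e-3 | signal-units² | pooled mean-energy noise threshold ending extraction |
| `tau` | 0 | dimensionless | dual-ascent step; 0 disables the multipliers — the noise-robust choice, and the default because recordings are never noise-free |
| `max_modes`, `max_inner_iters` | 15, 300 | — | safety caps (the algorithm itself has none); exceeding the iteration cap raises a typed convergence error carrying diagnostics |
| `mirror` | on | — | reflect the signal at both ends before the transform |

Frequencies are stored normalized (cycles/sample) internally — the
decomposition is rate-agnostic — and exposed in Hz through the signal's
sampling rate.

## Numerical choices

* **One-sided spectra.** All updates operate on `ω ≥ 0` only; real signals
  are reconstructed by conjugate symmetry. This matches the stated domain
  of the update equations and halves the work.
* **Mirror extension.** Signals are reflected at both boundaries (half the
  length on each side) before the transform and trimmed after inversion.
  This is the established boundary treatment for variational
  decompositions; it is flag-controlled for inspection of the raw behavior.
* **Center-frequency initialization.** `ω_l` starts at the frequency of the
  largest peak of the channel-pooled residual power spectrum. This is
  deterministic and follows the univariate convention; it also means the
  first extracted scale is the *strongest* one, not the lowest.
* **Divergent bins.** At a grid frequency exactly equal to a prior center,
  the prior-filter penalty diverges; the mode update returns 0 there (the
  continuous limit), preventing overflow.
* **Degenerate modes.** A zero-energy mode spectrum has no centroid; the
  centroid update raises an error rather than returning NaN. The
  decomposition driver avoids the situation by checking residual energy
  before extracting.
* **Dual-ascent expression.** The multiplier step moves `λ̂_k` along the
  reconstruction violation `f̂_k − (û_lk + f̂_uk + Σ prior modes)`, with the
  unprocessed-part spectrum `f̂_uk` given by its own subproblem's filter
  (numerator evaluated at the pre-update center frequency, denominator at
  the updated one). With the default `tau = 0` this step is inert; it is
  implemented and oracle-tested for completeness.

## Denoising conventions

Removal bands are half-open intervals `[low, high)` in Hz applied to each
mode set's *pooled* center frequency; a mode is removed as a whole across
channels, since the model shares one center per scale. Strict published
inequalities like "between 8 and 15 Hz" are mapped to the same half-open
convention — a center landing exactly on an edge is a measure-zero event
resolved toward removal at the lower edge. The decomposition residual is
excluded from the denoised output: reconstruction sums retained modes
only. Because removal is by frequency band rather than by ordinal scale
index, clips that decompose into different numbers of modes are handled
uniformly. The bands themselves are user-supplied (per subject, via the
YAML config); this package deliberately does not search for the bands that
maximize classification accuracy, which is a study-specific model-selection
exercise.

## Feature protocol

Denoised recordings are cut into 30-s samples sliding every 2 s; each
sample is analyzed with 1-s Hamming windows hopping every 0.25 s (75%
overlap), giving 117 steps per sample. Per window and channel a one-sided
periodogram is computed, truncated below 140 Hz, and averaged (arithmetic
mean of *power* — the estimator works in linear power throughout, no dB
transform) within consecutive 2-Hz bands: 70 bands per channel. Channels
are stacked into one column per time step, so a sample becomes a
`(C·70) × 117` tensor. At a 1-s window the native resolution is 1 Hz, so
each band averages two bins; band-averaging then summing with band widths
conserves the truncated total power, which the tests assert. A Welch
variant (averaged half-length segments) is available behind the same
config switch; the periodogram is the default as the minimal faithful
reading of a generic "spectrum" routine.

Human-rate recordings (e.g. 5 kHz) are brought to 500 Hz beforehand with
polyphase FIR resampling (`resample_signal()`).

## Classifier contract

The published pipeline fine-tunes a pre-trained 12-layer transformer
encoder (hidden size 768, 12 heads, batch 32, 10 epochs) on these tensors.
Reproducing those weights is infeasible and out of scope here; what the
package owns is the *input representation* and the *decision logic*: the
data embedding `E = X ⊙ W + E_p` with seeded normally initialized `W` and
`E_p` (defaults mean 0, sd 0.02 — the initialization distribution's
parameters are not published, so they are configurable, never asserted),
the `fit_classifier()`/`predict()` contract returning a preictal
probability in [0, 1], and strict majority voting across 10 independently
trained trials (preictal only if more than 6 vote preictal). The shipped
baseline is a ridge-regularized linear discriminant on flattened embedded
tensors, solved in the dual; it is deterministic, keeps the pipeline
end-to-end testable, and is *not* claimed to approach transformer
performance. Leave-one-seizure-out splits with class-balanced interictal
subsampling are built by `build_trial_splits()`.

## Alarms and significance

Per-sample labels feed a 10-min sliding window advancing one sample step;
an alarm fires when the preictal fraction strictly exceeds 0.6 ("more than
60%"). After an alarm, no further alarm is raised for a refractory period
defaulting to the SOP: the convention is not published, but without one a
sustained preictal stretch produces an unbounded alarm train and the false
prediction rate loses meaning. A seizure counts as predicted if some alarm
precedes it by at least the SPH (30 min) and at most SPH + SOP (+20 min).
FPR divides false alarms by evaluated interictal hours, excluding the
SPH + SOP stretch before each onset. The random-predictor comparison uses
`P = 1 − exp(−FPR·SOP)` with SOP in *hours* (confirmed by back-computing
the published per-subject p-values with SOP = 1/3 h) and the upper-tail
binomial sum for `p`; both are monotone in the directions the formulas
dictate, which the property tests check.

## The synthetic generator

`generate_recording()` builds signals as amplitude-modulated cosines with
optional slow frequency jitter — the simplest signals satisfying the
narrow-band assumption — plus white Gaussian noise standing in for
broadband background (muscle, ocular and electrode artifacts).
`generate_timeline()` labels 2-s steps preictal between 66 and 5 minutes
before each onset, with seeded label flips modelling classifier error.
What this *does* show: that the decomposition separates genuinely
band-limited common modes (centers recovered within 1 Hz, waveform
correlation ≥ 0.95 at 20 dB SNR on 2-s clips at 400 Hz for 2–4 channels),
that band removal, feature shapes, alarm logic and significance arithmetic
are exactly right. What it does *not* show: performance on real iEEG, whose
modes are nonstationary, non-sinusoidal and cross-contaminated, and whose
preictal signatures are far subtler than a planted label pattern. Headline
clinical numbers (mean sensitivity, FPR across subjects) therefore cannot
be reproduced at desk scale; the package instead reproduces the
significance arithmetic and the published summary-row means from the
printed per-subject values.

## Problem sizes

The test suite and examples run 2-s, 400 Hz clips with 1–4 channels
(decomposition), 30-s samples for features, 1000-stream alarm batches, and
full binomial enumeration up to 12 seizures — sizes chosen so the whole
suite completes in well under a minute on one core while still exercising
every advertised guarantee at the tolerances stated in the tests.

## Known limitations

* The alpha sweep is the published heuristic, not an optimizer; pathological
  inputs (two equal-energy tones closer than the filter bandwidth at
  `alpha_max`) can merge into one mode.
* The filter-bank behavior of successive extraction is not characterized
  here (left open in the underlying method literature).
* EDF support is a minimal 16-bit reader/writer (single sampling rate, no
  annotation channels); it exists for interchange, not archival fidelity.
* Execution is single-threaded by design; per-clip decomposition is
  embarrassingly parallel if a caller wants to shard it.
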