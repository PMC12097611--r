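---
title: "Multimodal EEG-fTCD decoding: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal EEG-fTCD decoding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcifuse)
```

# The decoding problem

A hybrid brain-computer interface records two complementary views of the
same mental act: EEG captures fast oscillatory electrical activity
(sensorimotor mu/beta modulation during motor imagery, steady-state visual
evoked potentials under flickering stimuli), while functional transcranial
Doppler (fTCD) tracks the slower hemodynamic consequence — cerebral blood
flow velocity in the middle cerebral arteries, measured by two 2 MHz
transducers over the temporal windows. `bcifuse` implements a complete
binary intent decoder over such paired trials: per-band spatial filtering
of EEG, maximal-velocity envelope extraction from raw Doppler audio,
per-modality linear evidence scores, and a weighted Bayesian fusion of the
two score streams.

# EEG path: filter-bank common spatial patterns

Each 10 s, 16-channel trial `E` (channels x samples) is band-passed into 9
non-overlapping bands covering 2-60 Hz (6.5 Hz wide; the ninth band is
clipped to [54, 60] Hz so the printed range and the band count can both
hold). Within a band, the trial covariance is trace-normalized,

    C = E E' / trace(E E'),

class means `S(+)`, `S(-)` are averaged over training trials, and CSP
solves the simultaneous diagonalization

    W' S(+) W = L(+),  W' S(-) W = L(-),  L(+) + L(-) = I,

equivalent to the generalized eigenproblem `S(+) w = lambda S(-) w`. The
eigenvalue `lambda_j(+) = w_j' S(+) w_j` in [0, 1] is the fraction of
whitened variance the j-th filter assigns to the positive class; filters
are sorted by decreasing `lambda(+)` and the `Nf` filters from each end
are retained. Features are the log of the power of each projected series;
with 9 bands this yields `9 x 2 Nf` features per trial, `Nf` swept over
1..8.

Numerical choices:

* **Eigensolver.** The pencil is reduced with the Cholesky factor of
  `S(+) + S(-)` followed by a symmetric eigendecomposition, which
  enforces `W'(S(+) + S(-))W = I` at machine precision even for repeated
  eigenvalues. (The test suite checks the eigenvalues against an
  independent symmetric-inverse-square-root whitening oracle.)
* **Regularization.** Shrinkage `S <- (1-g) S + g (tr/n) I`, `g = 1e-6`,
  is applied *lazily*: only when the Cholesky factorization fails or the
  condition number of the sum exceeds 1e10. Unconditional shrinkage would
  perturb the whitening identity by O(1e-6), defeating the 1e-8 tolerance
  the identity is held to; well-conditioned problems are therefore solved
  unregularized.
* **Determinism.** Each filter is sign-fixed so its largest-magnitude
  coefficient is positive; equal eigenvalues keep their original (stable)
  order. Results are then identical across linear-algebra backends.
* **Filter realization.** The band-pass is a 4th-order Butterworth
  magnitude response applied in the frequency domain as `|H(f)|^2` — the
  exact amplitude response of a forward-backward (zero-phase) pass —
  because no IIR design routine is available among the package's
  dependencies and trials are fixed-length. This has no group delay and no
  edge transients; its difference from time-domain filtfilt is confined to
  the filter's transient tails.

# fTCD path: maximal-velocity envelope and feature catalogue

The raw Doppler signal is a superposition of echoes from scatterers moving
at different speeds; a scatterer at velocity `v` shifts the carrier by
`f_d = 2 f_t v cos(theta) / c`. The envelope — the maximal blood flow
velocity — is traced from the short-time spectrum as the highest
significant frequency per frame, converted through the inverse relation
`v = f_d c / (2 f_t cos theta)`.

Parameter choices, with reasons:

* **Speed of sound** defaults to `c = 1540 m/s` (standard soft-tissue
  value), configurable; it only rescales velocities linearly and cannot
  affect classification after standardization.
* **Insonation angle** defaults to `theta = 0`, the TCD convention when
  the angle is unknown.
* **STFT window: 32 ms Hann, 75% overlap.** Longer windows are better in
  frequency resolution but fail during the systolic upstroke: with a
  pulsatile waveform the maximal shift sweeps ~5 kHz/s, so a 128 ms window
  smears the spectral edge across ~80 bins and the edge falls below any
  per-frame threshold (measured mean absolute envelope error 3.5 cm/s). At
  32 ms the one-bin velocity equivalent is ~1.2 cm/s at 2 MHz and the
  measured noiseless recovery error is ~0.8 cm/s with correlation ~0.99
  against ground truth. Clinical spectral Doppler uses comparably short
  windows for the same reason.
* **Edge rule.** Per frame, the trace takes the highest bin with power at
  least 0.1 of the frame peak. A strong lone edge tone pushes its Hann
  mainlobe tail one to two bins past its center, so the detected edge
  snaps down (at most 2 bins) when the bin below is at least 2.5x stronger
  — a pure Hann tail is ~4x — which debiases the lone-tone case without
  disturbing dense scatterer stacks.
* **Noise floor.** Frames whose total power falls below 0.5x the median
  power of the lowest-energy decile of frames are zeroed and flagged. The
  0.5 factor matters: the bare decile median would flag ~5% of frames of a
  perfectly clean recording (half of its own decile), punching spurious
  zeros into the envelope.
* **Smoothing.** A 5-frame running median suppresses single-frame
  dropouts.

Both transducer channels are processed independently and the two per-side
feature vectors are concatenated (left first). The catalogue (version
`v1`, 42 features per side) spans three families: statistical (moments,
dispersion, fixed-bin histogram over 0-160 cm/s, distribution
percentiles), temporal (autocorrelations at lags 1-5, zero crossings,
peak statistics, slope, line length, sample entropy), and spectral
(total power, centroid, spread, 85% roll-off, cardiac-band 0.7-2 Hz
power, 4-level Haar wavelet energies and coefficient statistics).
Degenerate (constant) envelopes yield defined zeros, never NaN. Features
are screened per training fold by a two-sided Wilcoxon rank-sum test at
p < 0.05 (midranks with tie correction; exact when the combined sample is
at most 20); if nothing passes, the single lowest-p feature is kept and
flagged so the fusion stage always has an fTCD evidence stream.

# Evidence projection and weighted Bayesian fusion

Each modality's features are standardized (training mean, training
population variance — the 1/n form keeps the fit exactly invariant to
duplicating the training set) and projected to a scalar score by a linear
maximum-margin discriminant: an L2-regularized squared-hinge SVM solved in
the primal by BFGS, with the loss averaged over trials and the
regularization weight defaulting to 1.0. A Fisher-discriminant backend
(`backend = "lda"`) is available for comparison. Positive scores favor the
positive class; a point on the decision boundary scores exactly 0.

Class-conditional score densities are Gaussian-kernel KDEs with Scott's
bandwidth `h = sd(s) n^(-1/5)`, fitted per fold on training scores only. A
test trial with scores `(e, f)` is assigned to

    argmax_X  alpha * log p(e|X) + (1 - alpha) * log p(f|X) + log prior(X)

with a uniform prior; `alpha` in [0, 1] weights EEG against fTCD and is
chosen on the 101-point grid 0, 0.01, ..., 1. Numerics and tie-breaks:

* densities are evaluated in log space and floored at 1e-300, so far-tail
  test scores never produce 0/0 ratios;
* if a class's training scores have zero spread (a hard-margin projector
  can pin every score to the margin), the KDE falls back to a sharp
  bandwidth derived from the pooled score spread instead of failing;
* exact decision ties go to the first class in tag order; exact accuracy
  ties across the alpha grid go to the smallest alpha. One consequence
  worth knowing: when one modality dominates, validation accuracy
  plateaus in alpha and the reported alpha* is the plateau's left edge —
  alpha* is a sufficient weight, not a unique optimum.

# Cross-validated evaluation

`runCrossValidation()` uses stratified folds with a seeded shuffle
(default 10 folds, reduced with a warning when a class is smaller). All
learned quantities — screening, projectors, CSP filters, KDEs — are fitted
per fold on training trials only. Two selection protocols for `(Nf,
alpha)`:

* **nested** (default, leakage-free): an inner 3-fold cross-validation on
  each training set picks the pair, which is then applied to the untouched
  test fold;
* **posthoc** mode: the pair maximizing pooled cross-validated accuracy is
  reported — the optimistic "maximum accuracy achieved" convention of the
  BCI literature, provided for comparability. Post-hoc accuracy is an
  upper bound on nested accuracy on average.

EEG-only and fTCD-only accuracies in a `CVReport` are the `alpha = 1` and
`alpha = 0` limits of the fused rule, so the fusion-limit identities hold
exactly and the best fused validation accuracy can never fall below either
single modality. Direct SVM-sign accuracies are reported alongside in the
per-fold table. Accuracy comparisons across subjects use the one-sided
paired Wilcoxon signed-rank test, computed exactly for up to 25 nonzero
differences by full sign-flip enumeration over midranks (ties included),
and the per-subject optimal alphas are tested against a median of 0.5 with
the one-sample signed-rank test (a two-sample rank-sum backend is provided
because the reported analysis names that test for this one-sample
question; the one-sample form is the default).

# The synthetic world

Recordings of this kind are rarely shareable, so the package states a
controllable ground-truth world (`generateEEGTrials()`,
`generateFTCDTrials()`, `generatePairedDataset()`):

* **EEG**: four latent sources mixed by a seeded random orthonormal
  16 x 4 matrix. For the flickering paradigm, two sources are 7 Hz and
  17 Hz sinusoids whose power is 4 when attended and 0.05 otherwise —
  SSVEP is stimulus-driven, so the baseline carries essentially none; the
  residual is kept nonzero for the reported attentional leakage from
  nearby flicker. (With a large baseline residual, the per-trial trace
  normalization of the covariance caps the top CSP eigenvalue near 2/3
  regardless of gain — the near-zero residual is what makes a
  discriminable 7 Hz band possible at all.) For motor imagery, two
  lateralized mu/beta band-noise sources are attenuated to 0.25 power
  contralaterally, emulating event-related desynchronization. Two
  broadband (2-45 Hz) background sources are common to all classes; white
  sensor noise is added at a configured SNR (default 10 dB).
* **fTCD**: per trial and side, a pulsatile velocity waveform
  `v(t) = v0 (1 + 0.4 cardiac(t)) + offset(class, side)` with `v0 = 60`
  cm/s, a raised-cosine systolic upstroke (15% of the beat) and
  exponential diastolic decay at 1.2 Hz, and class offsets of +8 cm/s on
  the task-contralateral probe. The raw signal is a sum of 40 randomly
  phased tones at fractions of the instantaneous maximal shift — one tone
  rides exactly at the maximum, the physical carrier of the envelope —
  plus a white noise floor (default -20 dB). The generating `v(t)` is
  recorded and recoverable via `trueVelocity()`.

Determinism is bit-exact under a fixed seed, and the generators leave the
caller's RNG state untouched.

What the simulator does **not** emulate — and what a green test therefore
does not establish: within-session nonstationarity (trials are i.i.d.),
eye-blink/probe-motion artifacts, volume conduction from realistic head
geometry, autoregulatory velocity drift, bidirectional or turbulent flow,
and any correlation between the EEG and fTCD noise processes. Passing
tests certify the algorithms (recovery of injected structure, calibrated
type-I behavior, correct limits and invariances), not human-level
accuracies.

# Known limitations

* The evidence model assumes conditional independence of the two
  modalities given the intent; on simulated data the modalities are
  independent by construction, so this assumption is untested against
  violation.
* `alpha` is only weakly identified when either modality's likelihood
  ratios are well calibrated (the exponent-weighted product is then
  optimized at any alpha on a plateau); its recovery is driven by
  projector overfitting, which is realistic but worth remembering when
  interpreting per-subject alpha values.
* The envelope tracer assumes the maximal-shift line is populated; in
  signals where the fastest scatterers are intermittent the trace falls to
  the next occupied line.
* Multiclass decoding, online operation and cross-subject transfer are out
  of scope.
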