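# bcifuse

Analysis pipeline for **multimodal EEG–fTCD brain–computer interfaces**:
binary decoding of user intent from simultaneously recorded
electroencephalography (16 channels, 256 samples/s) and functional
transcranial Doppler ultrasound (two 2 MHz transducers over the
transtemporal windows). It is written for BCI researchers who want a
tested, reproducible reference implementation of this decoding stack, and
a synthetic paired-data generator with known ground truth to validate it
against.

## What it computes

**EEG — filter-bank common spatial patterns (FBCSP).** Trials are split
into 9 non-overlapping 6.5 Hz bands over 2–60 Hz. Per band, with
trace-normalized trial covariances `C = EEᵀ/tr(EEᵀ)` and class means
`Σ⁺, Σ⁻`, CSP solves the simultaneous diagonalization

    Wᵀ Σ⁺ W = Λ⁺,   Wᵀ Σ⁻ W = Λ⁻,   Λ⁺ + Λ⁻ = I
    (equivalently  Σ⁺ w = λ Σ⁻ w),

retains the `Nf` most discriminative filters from each end of the
eigenvalue spectrum, and emits log-variance features — `9 × 2Nf` per
trial, `Nf ∈ {1,…,8}`.

**fTCD — maximal-velocity envelope features.** The raw Doppler signal is
short-time Fourier transformed; per frame the highest significant
frequency is converted to velocity through the Doppler equation
`v = f_d·c / (2 f_t cos θ)`, giving the cerebral blood-flow-velocity
envelope. A deterministic catalogue of statistical, temporal and spectral
time-series features (42 per probe side) is extracted and screened per
training fold with a two-sided Wilcoxon rank-sum test at p < 0.05.

**Fusion — weighted Bayesian decision.** Each modality's features are
projected to a scalar evidence score by a linear max-margin discriminant;
class-conditional score densities are Gaussian-kernel KDEs with Scott's
bandwidth `h = σ̂ n^(−1/5)`; a test trial with scores `(e, f)` is assigned
to

    argmax_X  p(e|X)^α · p(f|X)^(1−α)      (uniform prior)

with the EEG weight `α` selected on the grid 0, 0.01, …, 1. Everything is
evaluated under stratified 10-fold cross-validation, with `(Nf, α)` chosen
either by nested inner cross-validation (leakage-free default) or post hoc
over the pooled decisions (`mode = "posthoc"`, the literature's
"maximum accuracy achieved" convention). Per-subject accuracy comparisons
use exact paired Wilcoxon signed-rank tests.

## Worked example

Simulate a paired dataset in a deliberately hard regime (SSVEP contrast
1.1 vs 0.5 at −20 dB EEG SNR; ±0.6 cm/s lateralized velocity offsets),
then run the leakage-free cross-validated pipeline:

```r
library(bcifuse)

ds <- generatePairedDataset(
  eegSimConfig(nTrialsPerClass = 20, paradigm = "MRWG", snrDb = -20, seed = 42,
               classBandGains = rbind(mr = c(1.1, 0.5, 1, 1),
                                      wg = c(0.5, 1.1, 1, 1),
                                      baseline = c(0.5, 0.5, 1, 1))),
  ftcdSimConfig(nTrialsPerClass = 20, trialLen = 3, paradigm = "MRWG",
                classVelocityOffsets = rbind(mr = c(0, 0.6), wg = c(0.6, 0),
                                             baseline = c(0, 0)), seed = 43),
  problem = c("mr", "baseline"))

report <- runCrossValidation(ds, nFolds = 5, nPairsGrid = 1:4,
                             mode = "nested", seed = 1)
show(report)
```

```
CVReport (nested mode, 5 folds, seed 1)
  problem: baseline vs mr
  EEG-only :  87.50% +/- 17.68
  fTCD-only:  57.50% +/- 11.18
  Fused    :  92.50% +/- 16.77  (alpha = 0.05, Nf = 3)
```

Reading the numbers: EEG alone decodes mental rotation vs baseline at
87.5%; the Doppler envelope alone is weakly informative (57.5%, its
velocity offset is buried in pulsatile variability at 3 s trials); the
α-weighted fusion still extracts a net gain (92.5%). `alpha = 0.05` is the
*smallest* sufficient EEG weight on the validation-accuracy plateau, and
`Nf = 3` eigenvector pairs per band were selected inside the training
folds. `report@perFold` carries the per-fold table, including direct
SVM-sign accuracies for comparison.

A command-line front-end wraps the same functions:

```sh
inst/cli/bcifuse simulate --config cfg.yaml --out data/
inst/cli/bcifuse run --config cfg.yaml --dataset data/dataset.rds --out run1/
inst/cli/bcifuse report run*/summary.json
```

## Acceptance script

`scripts/acceptance.R` re-runs the package end to end from scratch — it
simulates paired datasets for both paradigms (flickering mental
rotation/word generation, and motor imagery), executes the full
cross-validated FBCSP + envelope + fusion pipeline at the swept `Nf` grid,
logs the resulting accuracies, and writes the results JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
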