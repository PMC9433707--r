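---
title: "Predicting speech intelligibility from EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting speech intelligibility from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Behavioral speech-intelligibility testing — playing sentences and scoring the
fraction of words a listener repeats correctly — is the clinical gold standard
for fitting auditory prostheses, but it requires active cooperation and is
noisy in populations that cannot reliably respond. `csepnet` implements an
objective alternative: predict the behavioral score directly from the
listener's EEG while they passively hear the same sentences.

The pipeline has five stages:

1. **Stimulus degradation** (`noise_vocode()`): natural sentences are passed
   through an *n*-channel noise vocoder (log-spaced filter bank,
   200–5,000 Hz). Band envelopes are kept, spectral fine structure is replaced
   by noise; fewer bands → lower intelligibility. Channel counts 2, 3, 4, 5
   and 8 plus natural speech span the score range.
2. **Stimulus features** (`extract_envelope()`, `onset_impulse_train()`,
   `phenv_product()`): the broadband temporal envelope (ENV: full-wave
   rectification, 30 Hz zero-phase low-pass), the phoneme-onset impulse train
   (PH: unit impulses at annotated onsets), and their product (PHENV), all at
   256 Hz.
3. **EEG preprocessing** (`preprocess_eeg()`, `extract_epochs()`): resample to
   256 Hz, average reference, 1–57 Hz zero-phase Hamming-windowed sinc FIR,
   epoch −0.5..2.5 s around sentence onset (64 × 768 per trial).
4. **Feature images** (`compute_erp()`, `compute_csep()`,
   `bootstrap_dataset()`, `render_image()`): either plain epoch averages
   (ERP) or *continuous speech-evoked potentials* (CSEP) — per-channel,
   per-lag Pearson correlations between an epoch and its sentence's feature,
   averaged over 80 bootstrap-drawn epochs. Panels are rendered to
   299 × 299 × 3 images.
5. **Classification and attribution** (`build_model()`, `train_cnn()`,
   `occlusion_map()`): a small CNN maps each image to one of 38 discrete
   scores (0–100 % in 2.5 % steps; 30.0, 37.5 and 40.0 were never observed),
   and occlusion sensitivity attributes the decision to electrodes.

## The CSEP statistic

For epoch channel $x(t)$ and stimulus feature $s(t)$, both on the 768-sample
epoch grid, the CSEP entry at lag $\ell$ is the Pearson coefficient

$$ r(\ell) = \mathrm{corr}\left(x(t),\, s(t-\ell)\right) $$

computed over the overlapping samples. Positive lags mean the EEG trails the
stimulus, so a cortical tracking response with ~100 ms latency peaks near
$\ell \approx 26$ samples. The lag grid is $\ell \in \{-128, \dots, 639\}$
(−0.5 s to +2.496 s), chosen so CSEP panels share the ERP panels' 64 × 768
geometry; the method's source material does not state its lag window, and
this is the only choice that preserves the printed image size. Overlaps
shorter than 8 samples or with zero variance yield 0 by definition (never
NaN). The implementation computes all lags with FFT cross-products and prefix
sums ($O(N \log N)$); the test suite checks it to $10^{-10}$ against a direct
$O(N^2)$ per-lag oracle.

A note on the delayed-signal convention: with $s$ *delayed* relative to $x$
the peak sits at a negative lag; with the EEG delayed relative to the feature
(the physical situation) it sits at a positive lag.

## Bootstrap dataset construction

Each participant × condition cell contributes a pool of ~1,000 epochs
(10 sentences × 100 repeats). Pools are split 80/20 at the *epoch* level
first; exemplars are then generated by drawing a score class uniformly from
the observed classes, a pool with that label, and 80 epochs with replacement
from the pool's side (train exemplars from train-side epochs only). Defaults
produce 800 training and 200 test exemplars. Because the split is within
participant × condition, train and test share no epoch but do share
participants — a leakage caveat inherent to this design, which the package
documents rather than hides: the alternative (participant-level splitting)
cannot keep all 38 classes on both sides. The split granularity of the
original design is not stated; this reading is recorded explicitly.

Rendering min-max normalizes a panel and bilinearly resizes it to the
network input; the two operations commute up to an affine map, so the package
normalizes after resizing to pin the output range to exactly [0, 1]
(a constant panel maps to 0.5). Grayscale values are replicated onto three
identical channels; a colormap rendering would make results depend on the
colormap choice, which replication avoids.

## Augmentation

Training sets are expanded 10× (800 → 8,000) by keeping every original and
adding nine augmented copies, each produced by exactly one approach chosen
uniformly at random:

* **Gaussian noise** at noise-to-signal RMS ratio 0.6 — the drawn field is
  rescaled so the realized ratio is exactly 0.6, which makes the parameter
  testable deterministically;
* **temporal cutout**: a random 0.625 s window (160 columns, ~20 % of the
  epoch) replaced by Gaussian noise matched to the image's global mean and SD;
* **sensor dropout**: 12 random channels (~20 % of 64) zeroed.

Augmentation operates on the 64 × 768 panels *before* rendering so the
cutout window and dropped sensors keep their stated time/channel meaning.

## The classifier

The fixed stack is conv(32, 16×16) → leakyReLU → conv(8, 8×8) → leakyReLU →
maxpool(2×2) → conv(8, 4×4) → leakyReLU → maxpool(2×2) → conv(3, 3×3) →
leakyReLU → maxpool(2×2) → batch norm → fully-connected(38) → softmax.
Convolutions use same padding; the three pool strides are 2, 1, 1 — the only
assignment consistent with the published intermediate sizes
(299 → 149 → 148 → 147). `build_model()` audits every layer's concrete output
tensor against this table on construction. Batch normalization placed after
the last pool (rather than between convolutions) is unusual but implemented
exactly as specified. The leaky-ReLU negative slope is 0.01 and the loss is
categorical cross-entropy (both conventional; neither is stated in the
source). Training uses Adam (lr 0.001), batch 64, 5 epochs, a randomly
selected 20 % validation split, and pre-epoch shuffling.

No deep-learning framework is available in the target environment, so the
network is implemented in compiled code (RcppArmadillo): im2col + BLAS GEMM
convolutions with hand-written backprop, single-precision throughout, fully
deterministic for a fixed seed (single-threaded, own mt19937).

A reduced profile (`cnn_spec(input_size = 128, filter_scale = 4)`) divides
filter counts by 4 and feeds 128 × 128 inputs; it exists for CPU-scale
experiments and tests and is never used for full-scale reported numbers.

## Occlusion attribution

`occlusion_map()` slides a 5 × 5 occluding patch with stride 5 over the
rendered image (60 × 60 grid for 299-pixel inputs) and records the drop in
the true-class softmax probability; the occluder value is 0.5, the rendered
midpoint (the occluder value is unstated in the source). `map_to_channels()`
partitions image rows into 64 contiguous bands by proportional rounding and
takes the overlap-weighted mean of absolute grid values per band; the
weighting is normalized per grid row so total sensitivity is conserved
exactly. `topk_channels()` ranks electrodes (default k = 10) with ties broken
by montage order. When summarizing a model, maps are averaged over correctly
classified test images selected round-robin across classes: score-0 trials
contain no stimulus-locked response by construction, so a purely sequential
selection could spend the whole budget on uninformative images.

## The synthetic study

The original EEG recordings are not publicly deposited, so a generator
emulates the full experiment, emitting the same objects (WAV + onset TSV +
epoch pools + score CSV) the real-data path consumes.

* **Stimuli**: amplitude-modulated 1/f noise with syllabic (3–6 Hz)
  modulation and a small energy burst at each phoneme onset; duration
  N(1.8, 0.2²) s clipped to 1.2–2.4 s; 17–22 phoneme onsets per sentence
  (mean 18.6, SD 3.9).
* **Scores**: a logistic in log₂(vocoder channels), natural speech entering
  as an effective 16-channel spectrum, anchored to condition means of 7.5 %
  (2-channel) and 99.6 % (natural); a single logistic cannot reproduce all
  six published condition means, so the two extremes are matched and the
  intermediate conditions follow the curve. Subject-level jitter (SD 1.0 on
  the logit) reproduces the observed score spread; scores snap to the
  2.5-step grid with the three unobserved levels mapped to their nearest
  allowed neighbour.
* **EEG**: epoch = s(score) · [g·(kernel ∗ ENV) + g·(kernel ∗ PH)] on 12
  informative channels plus 1/f noise (10 µV RMS) on all 64. The response
  kernel is a biphasic gamma-difference with ~100 ms latency; the
  intelligibility link s(score) = score/100 is the simplest monotone choice
  and suffices for class-separability tests. Tracking gains of 2 µV put
  single-trial feature-tracking correlations near 0.15–0.2, the upper range
  of reported envelope-tracking effect sizes. The informative set is a
  contiguous left temporal/centro-parietal block in montage row order (C1,
  C3, C5, T7, TP7, CP5, CP3, CP1, P1, P3, P5, P7), mimicking the regional
  clustering of real tracking responses and matching the spatial resolution
  of a 5-pixel occlusion grid.

What the generator does *not* emulate: eye/muscle artifacts, inter-subject
response topography differences, channel-specific noise spectra, or any
nonlinearity between features and response. Passing tests therefore
demonstrate that the pipeline recovers what its own forward model puts in —
they do not certify performance on real recordings.

A note on per-lag Pearson correlations with 1/f noise: because both the
envelope and the background noise are dominated by slow components, a single
epoch has few effective degrees of freedom per lag and noise-only channels
show spurious peak correlations of 0.3–0.6. This is why the method averages
80 epochs per exemplar: the noise floor of the averaged CSEP drops by √80
while the stimulus-locked component persists. Single-trial CSEPs are not
interpretable in this regime.

## Problem sizes used by the test suite

The full study (87 subjects × 6 conditions × 1,000 epochs) is far beyond a
desk run, so the end-to-end checks use a scaled profile chosen once: 8
subjects, 20 repeats, 5 conditions pinned to scores {0, 25, 50, 75, 100},
ENV-CSEP exemplars (400 train / 100 test, 80-epoch averages), the reduced
CNN profile, 5 training epochs, and a majority verdict over up to three
training seeds (stopping early once two agree, since a third cannot change
the majority). Occlusion recovery is assessed on the best of those models
with one correctly classified test image per nonzero class.

## Numerical choices and degenerate inputs

* Onset-to-sample rounding is round-half-away-from-zero, stated once and
  used everywhere.
* Zero-phase filtering is one-pass linear-phase FIR with group-delay
  compensation (EEGLAB-style); envelope undershoot is clipped at 0.
* The band-pass FIR uses the Hamming-window heuristic length
  `ceil(3.3/tb · rate)` with tb = 1 Hz, governed by the 1 Hz lower edge (a
  single linear-phase FIR has one transition width, so the stricter edge
  wins).
* The vocoder's band filters are 4th-order Butterworth band-passes applied
  forward-backward; its per-band envelope uses the same 30 Hz definition as
  the ENV feature so one definition serves both.
* Event-index resampling floors after rescaling (±1 sample onset jitter,
  accepted and documented).
* Correlation denominators at or below machine tolerance yield 0; CSEP
  entries are clamped to [−1, 1] against rounding.
* A constant panel renders to all-0.5; an all-zero image rejects
  noise-to-signal scaling with an error rather than dividing by zero.
* Artifact rejection is a simple ±150 µV amplitude threshold standing in for
  interactive component-based cleaning, which needs a human in the loop.

## Known limitations

* Headline full-scale accuracies require the original 87-participant
  recordings, which are not deposited; the package reproduces the method,
  its configuration constants, and desk-scale recovery behavior.
* The within-cell 80/20 split shares participants between train and test
  (see above).
* The compiled CNN is CPU-oriented; no GPU path.
* ENV features are computed from natural (not vocoded) audio by default,
  matching the stated feature definition; a flag allows the alternative.
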