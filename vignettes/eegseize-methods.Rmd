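---
title: "Subband-entropy seizure detection: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subband-entropy seizure detection: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

eegseize classifies epileptic states from single-channel EEG segments by a
four-stage pipeline: preprocessing (band-pass + wavelet denoising), 4-level
db4 wavelet decomposition into the subbands D1--D4 and A4, extraction of 20
amplitude/complexity features (STD, SampEn, ApEn, FuzzyEn per subband),
random-forest permutation-importance selection down to 10 features, and a
compact 1-D convolutional network. This vignette records the models, the
tunable parameters and the design decisions behind each stage, including
the places where the method description leaves genuine freedom and what
this package chose.

## Preprocessing

`bandpass()` designs an order-4 Butterworth filter and applies it
forward--backward (`signal::filtfilt`), so the filter is zero-phase and
entropy features are not distorted by phase shifts. The conventional
analysis band for seizure activity at a 173.61 Hz sampling rate is
0.01--86.8 Hz; since 86.8 Hz *is* the Nyquist frequency, a literal
band-pass design is degenerate there. When the upper edge reaches
0.99 x Nyquist the filter therefore degrades to a high-pass at the lower
edge -- operationally "full band minus drift" -- and says so in a warning.
A zero lower edge likewise yields a low-pass.

`wavelet_denoise()` performs a multilevel DWT, soft-thresholds every detail
level with the universal threshold
$\hat\sigma\sqrt{2\ln N}$, $\hat\sigma = \mathrm{median}(|D_1|)/0.6745$
(the robust noise scale taken from the finest detail coefficients), and
reconstructs. The threshold rule is pluggable (`threshold_rule` may be a
function) because shrinkage variants abound; the universal soft threshold
is the standard default reading.

## The wavelet filter bank

No wavelet package ships with this stack, so the discrete wavelet
transform is implemented in the package itself as the classic cascaded
half-band filter pair (Daubechies orthogonal filters db1--db8, default
db4). Each analysis step convolves with the decomposition low/high-pass
pair and downsamples by two; four levels yield the detail sequences D1--D4
and the approximation A4. Two boundary modes are provided:

* `"symmetric"` (default): half-point symmetric extension, the dominant
  convention for db4 denoising. The transform is slightly redundant at the
  boundary (coefficient counts `floor((n + 7)/2)` per level), and the
  implementation is verified in the test suite against frozen reference
  coefficients from an independent implementation of the same convention.
* `"periodic"`: circular (periodized) convolution, boundary-free and
  exactly orthogonal, requiring the length to be divisible by
  `2^levels`. In this mode the coefficient energies sum exactly to the
  signal energy, which is what the energy-conservation tests exercise;
  the symmetric mode satisfies perfect reconstruction but is redundant at
  the boundary, so exact energy bookkeeping is only meaningful in the
  periodized mode.

`dwt_decompose()` returns either raw coefficient sequences or, by default,
*reconstructed* subband signals: the inverse transform with all other
subbands zeroed. The five reconstructed signals are full-length and sum to
the original segment to machine precision (linearity + perfect
reconstruction). Features are computed on reconstructed subbands by
default -- the time-domain subband waveform is what the method's
subband-figure convention displays -- with `representation =
"coefficients"` available since the method description never states which
was used.

The nominal band of each subband follows the dyadic rule
(`band_edges()`): D1 spans `[fs/4, fs/2)`, each deeper detail halves the
band, A4 spans `[0, fs/32)`. At fs = 173.61 Hz the printed one-decimal
edges are 5.4 / 10.8 / 21.7 / 43.4 / 86.8 Hz; note 173.61/16 =
10.850625, so the printed table corresponds to one-decimal *truncation*
(10.8), which is the convention the acceptance checks use. The function
itself returns exact values.

## Features

Per subband, four features: population standard deviation (divisor $N$)
and three regularity statistics, giving $5 \times 4 = 20$ named columns in
fixed order (all STD, then SampEn, ApEn, FuzzyEn blocks over D1, D2, D3,
D4, A4).

All three entropies use Chebyshev (max-norm) template distance and one
shared `entropy_params()` policy. The method description never states the
estimator parameters; the package defaults to the canonical conventions
$m = 2$, $r = 0.2\,\mathrm{SD}$, $n = 2$:

* **ApEn** (Pincus): $\Phi^m - \Phi^{m+1}$ with self-matches included and
  $N-m+1$ templates at dimension $m$.
* **SampEn** (Richman--Moorman): $-\ln(A/B)$ over template *pairs*,
  self-matches excluded, with the same $N-m$ templates at both dimensions
  so pattern counts are directly comparable. When no pair matches at
  either dimension the statistic is undefined; `sampen()` raises a typed
  condition (`eegseize_sampen_undefined`) and `extract_features()` maps it
  to the conventional cap $\ln(N-m) + \ln(N-m-1) - \ln 2$ (the largest
  expressible value for one matched pair) rather than silently dropping
  segments. The cap is switchable off.
* **FuzzyEn** (Chen): templates are baseline-removed (each vector minus
  its own mean) and the hard match is replaced by the exponential
  membership $e^{-(d/r)^n}$; the statistic is
  $\ln\phi^m - \ln\phi^{m+1}$.

Two deliberate numerical choices:

* $r$ is resolved per subband from that subband's own SD -- each subband
  has its own amplitude scale, and a global $r$ would saturate the deep
  bands.
* A subband whose SD is below $10^{-10}$ of the segment's amplitude is
  treated as constant and its entropies set to 0. The reconstructed detail
  bands of (say) a constant segment carry only $\sim 10^{-15}$
  floating-point residue; "the entropy of rounding noise" is meaningless
  and would otherwise leak into the feature table.

The compiled (Rcpp) estimators are the fast path; the test suite keeps
naive $O(N^2)$ enumeration oracles in plain R and requires agreement to
$10^{-12}$, which is the core correctness surface for this module. One
feature vector is computed per segment; callers wanting shorter analysis
windows slice segments before extraction (the package takes no position on
windowing, which the source method leaves unstated).

## Feature selection

`oob_importance()` grows $K$ CART trees (Gini splits, unlimited depth,
bootstrap size $n$ -- `randomForest` defaults) and computes, for every
tree $k$ and feature $j$, the drop in that tree's out-of-bag accuracy when
column $j$ is permuted within the OOB rows. The importance of feature $j$
is the mean drop $P_j = \frac1K \sum_k (L_k^{OOB} - L_{k,j}^{OOB})$. This
is computed from per-tree predictions by the package itself -- a library's
impurity-based importance is a *different* statistic and would not honor
this definition. Permutations are seeded deterministically from
`(seed, k, j)`, trees with an empty OOB set contribute a zero drop, and
"accuracy" is overall accuracy. The per-tree drop matrix is retained on
request so the bookkeeping identity $\sum_k \Delta_{kj} = K P_j$ is
testable.

`recursive_select()` eliminates exactly one feature per round -- the
lowest $P_j$, ties broken by lexicographically last name and flagged in
the trace -- and *re-grows the forest from scratch on the survivors*
before the next round, until `k_final = 10` remain. Survivors are returned
in final-round importance order with a complete elimination trace.
$K$ defaults to 200 trees.

## The classifier

The network (`cnn_spec()`, `build_cnn()`) is small and fully committed:

```
input 10 -> conv(16 filters, kernel 2, stride 1) -> 9
         -> batch norm -> ReLU -> max pool(2, stride 1) -> 8
         -> conv(32 filters, kernel 2, stride 1) -> 7
         -> batch norm -> ReLU -> max pool(2, stride 1) -> 6
         -> flatten (6 x 32 = 192) -> fc 32 (ReLU) -> fc 2 -> softmax
```

No padding anywhere; the stride-1 size-2 pooling is unusual but
implemented exactly as specified. The hidden fully-connected width (32)
and the ReLU activation are this package's choices where the description
is silent; both are configurable. Training is Adam
(`lr = 1e-3`, $\beta_1 = 0.9$, $\beta_2 = 0.999$) with cross-entropy loss,
batch size 32, 100 epochs by default, on a seeded stratified 3:1
train/test split. Batch-norm running statistics (momentum 0.1) make
prediction deterministic after training.

Because no deep-learning framework is available in this stack, forward
and backward passes are written in base R. Two guards keep that honest:
the first convolution layer is checked against a naive loop oracle, and
every parameter tensor's backpropagated gradient is checked against
central finite differences on a down-scaled spec.

Features are z-scored with training-fold statistics before entering the
network (stored in the model, applied at prediction). Raw subband STD is
tens of microvolts while entropies live in $[0, \sim 2.5]$; without
standardization the optimizer spends its budget rescaling. An RBF-kernel
SVM (`build_svm()`, via e1071) sits behind the same train/predict
contract for comparative reporting only.

## Evaluation protocol

`confusion()`/`metrics()` implement the four standard ratios (accuracy,
sensitivity, specificity, precision) with positive class 1; a zero
denominator yields an explicit `NA` plus an entry in `undefined`, never a
silent zero. `run_case()` runs, per repeat: a fresh seeded stratified 3:1
split, feature selection *fit on the training fold only*, classifier
training, test-fold metrics. Selection and training never see test rows;
an invariant test verifies that permuting test-fold labels (with the split
held fixed) leaves the trained parameters bit-identical. Because single
50-row test folds are noisy, the default protocol is 10 repeats with mean
and SD reported; `selection_scope = "global"` (select once on all rows) is
available for comparison with protocols that selected features globally,
but the leak-proof per-fold scope is the default. The 18 standard
two-class tasks over the Bonn sets (A--E) and New Delhi states are shipped
as a JSON table (`case_spec()`), with deterministic segment ordering (set
order as listed, then lexicographic source id) so splits are reproducible
from a seed alone.

## The synthetic generator

`generate_segment()` emulates the qualitative class contrasts that drive
the real classification problem, not the physiology:

* `background`: band-limited $1/f^\beta$ Gaussian noise ($\beta = 1$,
  pink -- the canonical broadband EEG slope), scaled to a 20 uV SD.
* `interictal_like`: background plus sparse biphasic spikes (0.8
  events/s, amplitude about 4 x background SD).
* `ictal_like`: a 3 Hz sawtooth-plus-Gaussian-spike train (the classic
  spike-and-wave signature, placed inside the A4/D4 analysis bands) with
  reduced-variance noise, at 3 x background amplitude.

Determinism is strict: one segment is a pure function of its
configuration and seed, dataset seeds are derived hierarchically (master
seed, class index, replicate index) so datasets extend without
reshuffling, and the generator restores the caller's RNG state. Fixture
trees can be emitted in the Bonn ASCII dialect or as v5 MAT files (via the
package's own minimal MAT codec) and read back by the io functions.

What the generator does *not* model -- channel cross-talk, line noise,
artifacts, non-stationary seizure evolution, inter-patient variability --
bounds what the end-to-end tests show: they demonstrate that the pipeline
recovers a known amplitude/complexity contrast without leakage, not that
it attains any particular accuracy on clinical recordings.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use segment lengths of
256--1024 samples (512 for the end-to-end runs), 100 segments per class,
3 repeated splits, and forests of 200 trees (30--100 in unit tests).
These sizes were chosen so the complete verification cycle runs in
minutes on one core while every stage still operates far from degenerate
regimes (subband template counts in the hundreds, OOB sets of ~55 rows
per tree). Nominal full-length segments (4097 samples at 173.61 Hz, 1024
at 200 Hz) are supported throughout; entropy cost grows as $N^2$ per
subband, which the compiled kernels keep at roughly a second per
full-length segment.

## Known limitations

* The shuffled-label chance control is tight only in expectation: a
  *fixed* random labeling of strongly clustered data is partially
  learnable (cluster-majority voting), so single shuffled runs can sit
  noticeably above 0.5 on small test folds.
* Symmetric-boundary coefficients are redundant; energy bookkeeping
  across subbands is exact only in the periodized mode.
* SampEn's undefined-case cap is a convention, not an estimate; heavy use
  of the cap (very short windows or tiny $r$) makes the feature
  effectively categorical.
* The MAT codec reads/writes the minimal v5 subset needed here (one
  little-endian numeric array per variable; zlib-compressed elements are
  inflated when the platform supports it). It is not a general MAT
  reader.
* No multi-channel support, EDF/BDF readers, or artifact rejection beyond
  the filtering described above.
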