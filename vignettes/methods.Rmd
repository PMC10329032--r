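---
title: "Methods: transformer-based gesture recognition for HD-sEMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transformer-based gesture recognition for HD-sEMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

High-density surface electromyography (HD-sEMG) records muscle electrical
activity on a two-dimensional electrode grid — here a stacked 16 x 8 layout
sampled at 2,048 Hz — so a recording is a short video-like tensor: time by
horizontal channel by vertical channel. The package classifies hand gestures
from such recordings with a compact class-token vision transformer, and
additionally exposes the "micro" route to the same decision: blind-source
decomposition of the grid signal into motor-unit spike trains, whose
spike-triggered-average (STA) action-potential maps are themselves
discriminative images.

# Preprocessing

The fixed chain is rectification, a low-pass Butterworth envelope, amplitude
companding, rest removal, optional channel decimation, and sliding-window
segmentation.

* **Envelope.** A causal single-pass first-order Butterworth low-pass at
  1 Hz per channel (5 and 10 Hz variants supported). First-order filters
  distort and spread the signal less than sharper ones; the 1 Hz cutoff is
  the conventional envelope choice and corresponds, through the
  moving-average relation `f = 0.443 / T_w`, to an equivalent 443 ms
  averaging window. A zero-phase two-pass variant is available behind
  `norm_config(zero_phase = TRUE)` for offline use; the causal default is
  real-time compatible.
* **Companding.** The mu-law map
  `F(x) = sign(x) log(1 + mu |x|) / log(1 + mu)` with `mu = 255` expands
  small amplitudes so that channels with very different dynamic ranges
  become comparable. The map is only a bijection of `[-1, 1]` onto itself,
  so each channel is first divided by its maximum absolute envelope value
  (per-channel scaling by default; global scaling is available, and the
  scaling maxima can be supplied from a training portion). We treat any
  larger post-companding display scale seen elsewhere as a plotting
  artifact; the package keeps companded signals in `[-1, 1]`.
* **Windowing.** After dropping rest-labelled samples, each contiguous
  (gesture, repetition) run of length `L` yields
  `floor((L - W)/skip) + 1` windows at multiples of the skip step; windows
  never straddle a label boundary. Default skips are 32 samples for
  `W <= 256` and 64 for `W = 512`. Channel decimation keeps every 2nd or
  4th electrode row, reducing the horizontal channel count 16 -> 8 -> 4
  while preserving grid coverage.

# The transformer

The window is tiled into `N = W * N_ch / (H * V)` non-overlapping
`H x V x N_cv` patches (time tile varying fastest), each flattened in
(time, horizontal, vertical) order and projected to the embedding dimension
`d` by a bias-free linear map. A learnable class token is prepended and a
learnable `(N + 1) x d` positional embedding added. Each of the `L` encoder
layers is pre-norm: multi-head self-attention with a residual connection,
then a GELU MLP with a residual connection. A single linear head reads the
final class-token row.

Choices that the parameter-count arithmetic pins down exactly:

* the patch projection has **no bias** and there is **no final layer norm**
  before the head — with either added, the closed-form count no longer
  matches the instantiated model's published sizes (e.g. 46,530 would
  become 46,594 with a projection bias);
* the V2 variant uses `d = 128` with a single MLP hidden layer of 256
  units; this is the only reading of "twice V1" consistent with the
  published counts;
* the head is a single linear layer.

Attention scales scores by `1/sqrt(d/h)` inside each head (the standard
multi-head form); `vit_config(scale = "full_d")` reproduces the literal
single-head formula `1/sqrt(d)`. The scaling choice does not change the
parameter count. The MLP activation is GELU (parameter-free). No dropout is
used, keeping the model exactly its stated size. Initialisation is
truncated normal (sd 0.02, clipped at two standard deviations) for
embeddings and projections, zeros for biases, ones/zeros for norm scale and
shift, all seeded.

The attention forward/backward kernels run in compiled code
(`src/attention.cpp`): at head dimension 8 and sequence lengths 9-65, the
per-call overhead of BLAS dominates actual arithmetic, so the kernels use
explicit loops over per-sample contiguous memory instead.

Training is Adam (`beta1 = 0.9`, `beta2 = 0.999`), learning rate `1e-4`,
weight decay `1e-3` applied uniformly to all parameters (matching the
common deep-learning-framework convention for Adam's `weight_decay`
argument), batch size 128, 20 epochs, cross-entropy loss. The learning rate
is constant for the first 10 epochs and then annealed; the schedule shape
is not uniquely determined by its description, so a linear decay toward
zero is the default (`lr * (E - e + 1)/(E - A + 1)` for epoch `e` past the
annealing point `A`), with a cosine option. No validation split or early
stopping is used: training uses four repetitions and tests on the fifth.

# Evaluation protocols

`crossval_by_repetition()` makes one fold per repetition id; the tested
repetition's windows never appear in training, confusion counts are pooled
over folds and then row-normalised. `shuffled_split_eval()` pools windows
across repetitions before splitting and is therefore optimistic — windows
32 samples apart can land on opposite sides of the split; the package
documents and tests only the direction of this bias. Metrics are per-class
precision/recall/F1, overall accuracy, and the generalised multiclass
Matthews correlation coefficient computed from the pooled count matrix.
Paired model comparisons use the two-sided Wilcoxon signed-rank test with
the conventional `ns`/`*`/`**`/`***`/`****` annotation bins.
`positional_similarity()` returns the cosine-similarity matrix of the
learned positional-embedding rows; the class-token row is excluded because
the quantity of interest is the geometry the model learns over patch
positions.

# The micro path: decomposition, STA, fusion

The multichannel signal is modelled as a convolutive mixture of motor-unit
spike trains. The decomposition stage honours the standard
blind-source-separation contract — delay-extended observations, whitening,
per-source separation vectors, spike detection, a silhouette acceptance
gate at 0.92, at most 7 extraction attempts per window — with the
following concrete algorithm:

1. **Extension and whitening.** Each channel is augmented with `R` delayed
   copies (default `R = 10`; the fusion benchmark uses `R = 4` to keep the
   per-window eigendecomposition small) and the extended covariance is
   eigendecomposed. By default the whitening keeps only eigendirections
   whose eigenvalue exceeds 10 times the median eigenvalue: most directions
   of the extended space carry only sensor noise, and whitening them
   amplifies that noise enough to destroy the repeat structure of the
   motor-unit action potentials. (A full ridge-regularised whitening,
   needed when the caller wants an identity output covariance, remains the
   default of `extend_and_whiten()` itself.)
2. **Source extraction.** Each attempt starts from the whitened
   observation at the highest-energy instant not yet tried or explained,
   is sharpened by three skewness fixed-point updates, and is then refined
   by spike-triggered re-estimation: the separation vector is repeatedly
   replaced by the mean whitened observation over the currently detected
   spikes until the detected set stabilises. The refinement counters the
   known degeneracy of sparseness-seeking contrasts, which otherwise
   converge to single-spike directions. Spikes are detected by peak
   picking on the squared positive source followed by a 2-means split of
   peak amplitudes; the initialisation instant's self-peak is excluded
   from the seed set. Deflation orthogonalises against every attempted
   vector; accepted spikes block nearby instants from later
   initialisations.
3. **Acceptance.** A source is kept when the silhouette of its
   amplitude split reaches the threshold (0.92 on the raw `[-1, 1]`
   silhouette scale, the convention of the decomposition literature),
   carries at least 3 spikes, and does not duplicate an earlier train
   (> 50% spike overlap after alignment over delays — extension makes
   delayed replicas of the same unit equally valid sources).

STA averages 20-sample raw-signal segments centred on each firing (offsets
-10..+9; boundary-clipped segments are dropped); decomposition and STA use
the raw signal, not the envelope, because a 1 Hz envelope would destroy the
action-potential waveform. The per-channel max minus min of the template
gives the non-negative peak-to-peak image, the micro-path input.

The micro classifier (V3) treats one peak-to-peak image as a two-patch
token sequence (`d = 64`, 8 heads, one layer); every accepted unit of a
window is an independent training sample carrying the window's label,
trained with Adam at `3e-4`, weight decay `1e-3`, batch 64, 50 epochs. For
fusion, both backbones are frozen and their heads stripped; the per-window
macro and micro class tokens (micro tokens averaged over the window's
units, zero with a flag when no unit was accepted) are concatenated
(128 dims), expanded by one linear + GELU layer to 1,024 features, and
classified by a final linear layer. Only the fusion head receives
gradients; because the tokens are precomputed from the frozen backbones,
the freeze is structural, not merely enforced. How the original
concatenation maps to 1,024 features and how many layers follow is not
uniquely specified anywhere; one expansion layer plus one classifier layer
is the minimal reading and the widths are configurable.

# Baselines

TD-PSD features estimate spectral moments from time-domain root statistics
(Parseval's theorem): `A` is the RMS of the signal and `B`-`E` RMS values
of successive forward differences, each mapped through
`m = root^lambda / lambda` with `lambda = 0.1` (the feature family's
customary value; it is not stated with the feature list itself). The
published root definitions make the third and fourth roots coincide, so the
`m3 - m2` feature is identically zero; the package keeps this `as_printed`
behaviour as the default for fidelity and offers `ordered` mode (difference
orders 0..4) to remove the degeneracy. Classical features are RMS, strict
zero crossings, strict slope-sign changes and waveform length. Both feed
fold-standardised SVM (RBF) or LDA classifiers evaluated on exactly the
same repetition folds as the deep models; zero-variance training columns
are dropped per fold, and a singular within-class covariance triggers a
jittered refit with a warning. The 3D CNN baseline implements the sketched
architecture — two convolution layers of 16 and 32 filters of size
(5, 3, 3), stride 1, valid padding, GELU, dropout 0.2, time-only (2, 1, 1)
max pooling, then 256- and 128-unit FC layers and a linear head. Its
published parameter total is not reproducible from the stated description
alone (pooling and FC input sizes are under-determined), so it is not used
as an arithmetic anchor; the convolution-layer counts (736 and 23,072) are.

# The synthetic generator

`generate_session()` emits a labelled recording laid out like the target
dataset: per gesture, 5 repetitions separated by rest (default 5 s), each
motor unit contributing its temporal template — by default the first
derivative of a Gaussian, 15 samples, biphasic, inside the 20-sample STA
window — scaled per channel by a Gaussian spatial profile (Euclidean
distance on the grid, unit electrode pitch) and placed at the firings of a
Gaussian-ISI renewal process (coefficient of variation 0.15, truncated at
one sample). Rest intervals contain sensor noise only. Firing rates of
15-25 Hz, spatial spreads of 1-2 electrode pitches and a handful of units
per gesture are in the physiological range for moderate contractions.

Two benchmark constructors define the study conditions:

* `make_separable_benchmark()` — each gesture drives its own disjoint unit
  subset at `difficulty = 0`; rows blend linearly toward a common mean as
  difficulty rises to 1. The acceptance benchmark uses 8 gestures, 3 units
  per gesture, 5 repetitions of 8 s (about 40 s of active signal per
  gesture), 64 electrodes, sensor noise 0.05 against unit-amplitude
  templates, window 64 with skip 64, and 1 s rests. Skip 64 and short
  rests keep the benchmark at desk scale: rests are discarded by the
  pipeline before training, and halving the window count halves training
  cost without changing what the benchmark measures.
* `make_mu_pattern_benchmark()` — all gestures share territories and
  firing rates; only the unit waveform shape differs, with the mean
  absolute template amplitude matched across gestures. The per-channel
  envelope is then identical in expectation (macro classification near
  chance) while peak-to-peak MUAP amplitudes differ (micro informative);
  this isolates the fusion model's added value as a direction, not an
  effect size.

What the generator deliberately does not model: volume-conductor
physiology, recruitment order and rate coding with force, electrode-skin
artifacts, motion artifacts, or inter-subject variability. Passing the
synthetic benchmarks therefore demonstrates that the implementation is
correct and that the pipeline can exploit the signal structure it targets;
it does not predict accuracy on real recordings.

# Numerical choices and degenerate inputs

* Layer norm uses eps `1e-6`; attention softmax subtracts the row maximum.
* Cross-entropy clips probabilities at `1e-12` before the log.
* Argmax prediction breaks ties toward the lowest class index.
* An all-rest session windows to an empty dataset with a warning; a window
  longer than every segment likewise.
* Whitening of a rank-deficient covariance ridge-regularises with a
  warning (full mode) or simply drops the null directions (truncated mode).
* `silhouette_score()` returns 0 when either cluster is empty; a zero-norm
  positional-embedding row yields 0 cosine entries and a flag.
* Sessions serialise to a single JSON document (`write_session()` /
  `read_session()`), which round-trips exactly and is intended for
  desk-scale interchange.

# Problem sizes used by the test-suite

The bundled checks run the full pipeline at desk scale: the classification
benchmark trains 5 folds x 20 epochs on about 10,000 windows; the fusion
comparison runs 5 seeds of a 3-gesture waveform-only task (about 345
windows of 512 samples each, decomposed per window); decomposition
recovery uses 2 s mixtures of up to 5 units. These sizes were chosen so a
complete run finishes on a single CPU core in well under half an hour
while leaving every acceptance margin intact.

# Known limitations

* The decomposition is offline and per-window; units are not tracked
  across windows, and the silhouette threshold of 0.92 was validated on
  synthetic mixtures — its transfer to other decomposition frontends is
  not guaranteed, since the silhouette's exact scale differs between
  implementations.
* The `as_printed` TD-PSD mode carries a constant zero feature by design;
  classifiers drop it via the zero-variance filter.
* Training is plain dense linear algebra on the CPU; it is intended for
  desk-scale studies, not for the full 65-gesture, 19-subject workload.
* Shuffled-split numbers must not be compared against repetition-wise
  numbers from other studies; the protocol difference alone is worth
  several accuracy points.
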