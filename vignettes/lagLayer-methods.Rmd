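---
title: "Lag-layer encoding analysis: models, inference and design choices"
author: "lagLayer maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lag-layer encoding analysis: models, inference and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagLayer)
```

## The scientific question

Layered word-embedding models (transformer language models) build a
word's representation through a sequence of nonlinear transformations
across layers. High-temporal-resolution intracranial recordings make it
possible to ask whether that *spatial* layer hierarchy maps onto the
*temporal* unfolding of word processing in language cortex: do deeper
layers' embeddings best predict neural activity at later lags relative
to word onset?

lagLayer implements the full analysis path for this question: lag-wise
cross-validated linear encoding models on smoothed high-gamma band
power, per-layer dimensionality reduction, the lag-layer correlation
statistic, and the inferential machinery (exact parametric p,
layer-index permutation, electrode bootstrap, phase-randomization
electrode selection with FDR control, interpolation and
orthogonalization controls), together with a synthetic-data generator
whose planted ground truth makes every stage testable end to end.

## The encoding model

For each electrode, layer and lag, a separate ordinary-least-squares
model with intercept predicts the windowed neural response per word —
the mean of the signal in a 200 ms window centered at `onset + lag` —
from that layer's embedding, reduced to 50 principal components
*per layer* (pooling layers before PCA would mix information between
layers and is never done). Lags run from −2000 ms to +2000 ms in 25 ms
steps (161 lags) by default; positive lags are after word onset, lag 0
is onset.

Estimation is ten-fold cross-validated: the model is fit on nine folds
and predicts the held-out fold; after all folds, performance is the
*single* Pearson correlation between the pooled out-of-fold
predictions and the observed responses, not an average of per-fold
correlations. Folds are contiguous blocks of words by default, which
limits temporal leakage between neighboring words; a seeded random
assignment is available. Words whose window falls outside the
recording at some lag are dropped from design and response at that lag
only; more than 5% missing raises an error.

Two PCA dialects are provided. `fold_safe` (the default) learns the
projection from the training folds only and applies it to the test
fold, so the projection is a pure function of training rows — the test
suite probes this with a leakage test. `pooled` learns the projection
from train and test jointly; it is retained because the two dialects
give equivalent results in practice and the pooled form is cheaper.

The electrodes × layers × lags correlation tensor is averaged over the
electrodes of a region of interest, each layer's curve optionally
scaled to peak at 1 (`scaleRows()`), and summarized by per-layer peak
lags (ties broken toward the earliest lag — deterministic, and
conservative for positive gradients).

## Inference

The headline statistic is the Pearson (and Spearman) correlation
between layer index and peak lag. Three complementary nulls are
implemented:

* **Exact parametric p** (`pearsonExactP`): the tail probability of
  the sample correlation under bivariate normality, through the
  monotone map to a Student-t statistic with n − 2 degrees of freedom.
* **Layer-index permutation** (`permutationTestLayerIndex`): layer
  indices are shuffled (peak lags fixed), default 100,000 draws, with
  the add-one estimator `p = (1 + #extreme)/(K + 1)` so p is never 0
  and its floor is `1/(K+1)`. For up to 7 layers an exhaustive mode
  enumerates all permutations. Both one- and two-sided versions are
  exposed (`alternative`); two-sided is the default.
* **Interpolation control** (`interpolationControl`): tests the
  rudimentary alternative that intermediate layers merely interpolate
  linearly between the first layer (previous word) and last layer
  (current word). A pool of ~10³ random convex combinations of the
  first and last layers' embeddings is encoded once; each of 10,000
  iterations samples 46 of them (one fewer than the interior layer
  count by default) without replacement, sorts them by interpolation
  weight, frames them with the real first and last layers, and
  recomputes the lag-layer correlation. The observed correlation's
  add-one percentile in that distribution is the p-value (one-sided:
  the question is whether the real, nonlinearly chained layers exceed
  what interpolation achieves).

Supporting machinery: `bootstrapElectrodeMeans` resamples electrodes
with replacement (default 10⁴) and assesses means two-tailed against
zero; the zero-reference reading is a deliberate choice where the
procedure could also be read as comparing two layers — the accessor
returns the full bootstrap distribution so either contrast can be
formed. `levenePeakLagSpread` compares two ROIs' peak-lag spreads
(temporal-receptive-window proxy) via Levene's test, mean-centered by
default with a median-centered option. `pairedTTestLayers` contrasts
peak lags per layer across two conditions (e.g. predicted vs.
not-predicted words) over matched electrodes, BH-corrected across
layers; all-zero differences give t = 0, p = 1, while a zero-variance
nonzero shift is flagged degenerate rather than fabricating an
infinite t. `bhFdr` wraps the Benjamini–Hochberg step-up
(`stats::p.adjust`).

Electrode selection (`selectElectrodes`) follows the familywise-style
construction exactly: each permutation phase-randomizes every
electrode's signal (amplitude spectrum and autocorrelation preserved,
alignment to words destroyed), recomputes the encoding with *static*
single-layer embeddings, keeps each electrode's max over lags, and then
the max across electrodes — one value per permutation (default 5000).
Per-electrode p-values are add-one percentiles in that null, followed
by BH-FDR across electrodes at q < 0.01. The combination of a
max-across-electrodes null with a subsequent FDR pass is unusual but
implemented as specified — fidelity over elegance.

## Preprocessing

`despike` flags samples beyond the median ± 4 inter-quartile ranges
per electrode ("four quartiles above and below the median"), imputes
interior runs by natural cubic spline through unflagged neighbors and
edges by the nearest unflagged value; electrodes with >50% flagged
samples are marked suspect. The operation is idempotent on its own
output. `rereferenceCAR` subtracts the per-sample mean across
electrodes. `highGammaPower` computes 6-cycle complex-Morlet wavelet
power on 10 log-spaced frequencies in 70–200 Hz, drops frequencies
within 5 Hz of the 60/120/180 Hz lines, and averages the rest; the
wavelets are zero-mean, so the result is insensitive to DC offsets.
Note that 6-cycle wavelets are spectrally broad (σ_f = f/6), so line
*exclusion* attenuates rather than nulls a line-frequency tone; full
suppression requires a finer frequency grid and narrower wavelets
(both exposed as `nFreqs`, `nCycles`), which the tests demonstrate.
`smoothHamming` applies a unit-sum 50 ms Hamming window with symmetric
edge padding. The exact wavelet implementation of any particular
toolbox is not reproduced; equivalence is asserted at the level of
band-selectivity properties.

## The synthetic generator

`generateNeuralDataset` builds datasets with the statistical structure
the analysis assumes, plus planted ground truth. Word onsets form a
jittered regular grid (350 ms mean spacing by default, ±20% uniform
jitter, snapped to the sample grid so kernel/window alignment is exact
across words — roughly the density of conversational speech, ~5000
words in 30 minutes). Embeddings come in three regimes:

* `chain_nonlinear`: layer 1 i.i.d. Gaussian per word; each next layer
  is a fixed random affine map (fresh per step, shared across words)
  followed by `tanh` and re-standardization. The gain (1.8/√d per
  entry) keeps successive layers strongly but nonlinearly related —
  adjacent layers are ~85% linearly predictable, mirroring the high
  similarity of neighboring layers in real transformer stacks — while
  interpolation between the endpoints cannot reproduce them, which is
  exactly the contrast the interpolation control draws.
* `linear_interp`: interior layers are convex combinations of the
  i.i.d. first and last layers with monotonically increasing weights —
  the null world of the interpolation control.
* `null`: all layers i.i.d., and the signal's word-evoked response
  amplitudes are random, independent of the embeddings, so peak lags
  are exchangeable across layers and permutation p-values are uniform
  (verified by a Kolmogorov–Smirnov calibration test).

Each electrode's clean signal is a sum over words and designated
layers of a 200 ms raised-cosine kernel centered at
`onset + lagMap(layer)`, scaled by a standardized linear readout of
that word's layer embedding. By default every electrode carries every
layer (so ROI-averaged analyses see the full gradient);
`designatedLayers` can restrict each electrode to a subset, e.g. one
layer per electrode, which makes per-layer peak recovery exact —
with all layers superimposed, cross-layer predictability biases
individual peaks toward the center of the lag map (shrinking the
slope, not the ordering), just as groups of real layers peak at shared
lags.

White Gaussian noise is added with variance set on the
*lagged-window scale*: `snr` is the ratio of the variance across words
of the windowed-mean clean signal at the planted lags to the variance
of the windowed-mean noise (σ²/m for window length m). That is the
scale the encoding model sees, making `snr` directly interpretable for
encoding performance; marginal-sample SNR would be kernel- and
rate-dependent. Correlation metrics are insensitive to marginal scale,
so white noise suffices; autocorrelated noise is left as a config
extension. The generator emulates a signal already on the referenced,
smoothed band-power scale — it does not synthesize raw voltage,
acoustics, or multi-subject structure.

Defaults (chosen once as a desk-scale version of a ~30-minute
naturalistic listening study): 800 words, 24 layers, 64 embedding
dimensions, 8 electrodes, 512 Hz, planted lag map 25·(layer−1) ms
(0–575 ms, matching the ~500 ms first-to-last peak separation seen in
high-order language areas), snr 1.

## Numerical choices and degenerate inputs

Sample indices are 0-based internally; all time parameters are in ms
and converted via the sampling rate. Windowed responses use closed
windows over sample-center times, computed by per-electrode cumulative
sums (the batch path and the direct per-lag operation agree to 1e−12
and are cross-checked in the tests). Rank-deficient designs fall back
to a minimum-norm SVD solution with a warning. Zero-variance peak
lags make the correlation undefined (NA, warning) rather than an
arbitrary value; zero-norm reference rows in the orthogonalization
pass through with a warning; `scaleRows` excludes rows with
non-positive maxima. All resampling operations take explicit seeds and
use the add-one p-value rule.

One stated property of line exclusion — that a pure line-frequency
tone contributes *near-zero* power relative to a neighboring tone —
holds only in the narrowband regime (`nCycles ≈ 60`, `nFreqs ≈ 40`);
with the standard 6-cycle setting the effect is directional but
partial, and the test suite asserts exactly that.

## Problem sizes used by the shipped checks

The package's acceptance checks run on desk-scale problem sizes chosen
to keep a complete verification under a few minutes of CPU: gradient
recovery uses the full default generator (24 layers, 800 words, snr 2,
8 electrodes) over 20 seeded replicates with an 81-lag grid
(−1000..1000 ms) and 10,000-draw permutation tests; null calibration
uses 200 replicates of a lighter configuration (12 layers, 200 words,
1 electrode, 128 Hz, 41 lags, 199-draw permutations); the
interpolation control uses a pool of 250 interpolations and 1000
iterations on the full default dataset. These sizes are the package's
own verification conditions; the machinery itself scales to the full
161-lag, 48-layer setting unchanged.

## What passing tests do and do not show

The generator plants exactly the structure the analysis looks for —
layer information expressed at layer-specific lags under known noise.
Passing recovery and calibration tests therefore demonstrates that the
estimator and its null constructions are correct and calibrated
*under the generative assumptions*: linear readouts, additive white
noise, a stationary response kernel, and regularly spaced single
words. Real recordings violate all of these to some degree
(overlapping naturalistic speech timing, autocorrelated and
non-stationary noise, nonlinear neurovascular/electrode effects), so
green tests certify the machinery, not any empirical claim about
brains. The paired-samples, mixed-model and Bayesian analyses that a
full study would add on top are out of scope here, as are LLM forward
passes (embeddings enter through the array container) and anatomical
electrode localization.

## A worked example

```{r example, eval = FALSE}
cfg <- SyntheticConfig(snr = 2, seed = 1)
ds <- generateNeuralDataset(cfg)
enc <- EncodingConfig(lagMin = -1000, lagMax = 1000, lagStep = 25,
                      pcaK = 50)
tens <- encodeLayerwise(syntheticRecording(ds), syntheticEvents(ds),
                        syntheticEmbeddings(ds), enc)
res <- lagLayerStats(tens, K = 10000, seed = 1)
res
```

The `LagLayerResult` prints the per-layer peak-lag range, the Pearson
and Spearman lag-layer correlations, the exact parametric p and the
permutation p. On planted-gradient data the Pearson correlation is
typically ≥ 0.95 and the permutation p sits at its floor of
1/(K + 1).
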