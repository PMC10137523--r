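---
title: "Certainty, Grad-CAM and sample entropy for 1D signal classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Certainty, Grad-CAM and sample entropy for 1D signal classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

A small 1D convolutional network that classifies one-second
electrophysiology epochs (the motivating case is intracranial EEG sampled at
2000 Hz and band-passed to 60–600 Hz, classified as epileptogenic-like or
not) produces a decision for every epoch, but not every decision deserves
the same trust. This package implements a per-prediction confidence score —
the *certainty index* — and a model-free way to ask whether confident
decisions are the ones for which the network attended to the
information-rich parts of the signal.

Three ingredients are combined:

1. **Certainty index.** For pre-softmax outputs (logits) $y$ and chosen
   node $i$,
   $$C_i = y_i - \frac{1}{N-1}\sum_{j \ne i} y_j,$$
   which for a two-class head is simply the logit margin $y_i - y_j$. It is
   translation-invariant, and non-negative when $i$ is the argmax of a
   two-node output. Scores can be normalized by the per-class sample SD for
   comparison across models (`normalize_certainties()`).

2. **Signed 1D Grad-CAM.** The relevance of feature-map position $i$ for
   class $c$ is $g_i^c = \sum_k \alpha_k^c A_i^k$ with
   $\alpha_k^c = \frac{1}{N}\sum_i \partial y^c / \partial A_i^k$, taken at
   the last convolutional layer. No ReLU is applied to the map: for a 1D
   signal, evidence *against* a class is as informative as evidence for it,
   and discarding negative relevance would bias the correlations computed
   next.

3. **Sliding-window sample entropy.** `SampEn(m, r, N)` is
   $-\log(A/B)$, where $B$ counts ordered pairs of distinct length-$m$
   templates within Chebyshev tolerance $r$, and $A$ the same count at
   length $m+1$ (self-matches excluded, strict inequality). A same-length
   entropy series is built by sliding a centred window of $N$ samples along
   the signal at stride 1.

A heatmap is compared with the raw signal, or with the entropy series, by
zero-extended lagged cross-correlation; the signed maximum over lags
(`max_correlation()`) is the per-sample similarity score, and ordinary
least squares of these maxima on the certainty indices (R², F) summarises
the relationship across a test set. The package's central empirical claim,
reproduced end-to-end by the test suite, is an *ordering*: certainty is
better explained by the heatmap–entropy correlation than by the
heatmap–signal correlation, and the ordering is stable across the entropy
parameter grid.

## Parameters that matter

* `m` (embedding dimension, samples; default 8): template length for the
  match counts. Too large leaves few matches; too small makes the forward
  match uninformative.
* `r_mult` (tolerance, in SDs; default 2): the match tolerance is
  `r_mult` × SD of the *whole epoch* by default (`r_reference =
  "global_sd"`), so one tolerance is shared by all windows of a sample; a
  per-window mode is available but non-default. The global reference makes
  high-amplitude transients register as irregular (their excursions exceed
  the shared tolerance), which is exactly the behaviour that lets the
  series flag localized events.
* `window_len` (`N`, samples; default 100): entropy window; at 2000 Hz the
  default spans 50 ms, a compromise between time resolution and count
  statistics. The one-at-a-time sweep (m ∈ {4, 8, 16, 32},
  r ∈ {1.5, 2, 2.5}, N ∈ {50, 100, 200, 400}) is built into
  `experiment_spec()`.
* Model defaults: three conv–ReLU–maxpool blocks ((8, 11, 4), (16, 9, 2),
  (16, 9, 2)), a 32-unit leaky-ReLU penultimate dense layer, dropout 0.2,
  and a 2-node linear output. A 2000-sample input yields last-conv feature
  maps of length 236 — coarse enough to summarise, long enough to
  correlate. All sizes are configuration, not architecture constants.

## Numerical and design choices

* **Sample-entropy counting.** The standard Richman–Moorman convention is
  used: $N - m$ template start positions at both lengths, self-matches
  excluded, strict `d < r`, Chebyshev distance, natural log. Degenerate
  windows: if $A = 0$ while $B > 0$ the maximum attainable value
  $-\log\!\big(1/((N-m)(N-m-1))\big)$ is assigned; if $B = 0$ the value is
  recorded missing and filled from the nearest finite neighbour so the
  series stays finite for correlation. Constant windows score exactly 0.
* **Series alignment.** Windows are centred with edge clamping, which is
  what makes the output series exactly signal-length; whether the original
  formulation used trailing or centred windows is not stated anywhere we
  could find, and the choice only shifts the series by at most half a
  window.
* **Certainty averaging.** The $1/(N-1)$ mean over the non-chosen outputs
  is the only normalization consistent with the two-class reduction
  $y_i - y_j$; ties at equal logits resolve deterministically to class 0.
  Normalization uses the sample SD ($n-1$).
* **Correlation normalization.** In the default `"normalized"` mode both
  series are standardized (population SD) and the lagged sums are divided
  by the shorter length, so identical aligned shapes score exactly 1. This
  bound holds for equal-length pairs (the only case the pipeline produces,
  since heatmaps are upsampled to series length); for unequal lengths the
  raw Cauchy–Schwarz bound is looser and the `"raw"` mode reproduces the
  literal zero-padded sum. The signed maximum is reported, not the maximum
  of $|z|$; ties break toward the smallest |lag|. Positive lag means the
  first series (the heatmap) leads.
* **Explained class.** Heatmaps explain the model's predicted class by
  default; any class can be requested.
* **Training.** Adam (learning rate 5e-3, batch 32), softmax
  cross-entropy, per-sample standardization of inputs, He-initialised
  convolutions with small positive biases and a zero-initialised output
  layer (training starts from the uniform predictor, which removes an
  instability where early over-confident logits collapsed the network into
  the constant predictor). Training is bit-deterministic given the seed.
  Grad-CAM uses the same analytic backward pass as training, which is why
  the finite-difference agreement test doubles as a check of the trainer.

## What the synthetic generator emulates — and what it does not

`synth_generate()` produces one-second, 2000 Hz, two-class signals: class 0
is 60–600 Hz band-limited Gaussian noise; class 1 adds Poisson-placed
(rate 4/s) Tukey-windowed tone bursts, 50–150 ms long, with frequencies
uniform in 80–500 Hz and amplitude 5× the background RMS. Pseudo-subjects
differ by a background gain, emulating cross-patient amplitude variability
absorbed by the training shuffle. Burst intervals are recorded as ground
truth; class 0 has none by construction, so bursts are the *only*
systematic class difference. With `burst_snr = 0` the generator is an
exact null: both classes are draws from the same distribution.

This emulates the statistical skeleton the method needs — classes separable
by a small CNN through localized, spectrally distinct transients that are
also visible to sample entropy. It does not emulate real iEEG: no 1/f
background, no physiological artefacts, no inter-channel structure, no
graded pathology. Passing tests therefore demonstrate that the pipeline's
machinery behaves as specified and that its headline ordering emerges when
the assumed structure is present; they do not certify effect sizes on
clinical recordings, whose R² values can differ substantially.

## Scales used by the shipped analyses

The end-to-end checks run at 400 signals per class (2000 samples each):
10-fold cross-validation at 6 epochs per fold, one 8-epoch model for the
correlation analysis scored on a 10% held-out split (80 epochs), the r and
N sweeps at the base point m = 8, and a null control with 200 signals per
class evaluated on a 40% split. These sizes keep the full suite within a
desktop-scale run while leaving the cross-validated accuracy (≈97%) and
the R² ordering far from their thresholds.

## Known limitations

* The certainty index is a margin, not a calibrated probability; no
  temperature scaling, ensembling or out-of-distribution detection is
  attempted.
* Only the last convolutional layer is mapped; earlier-layer maps
  degrade and are deliberately out of scope, as are alternative relevance
  methods (LRP, Taylor decomposition, sensitivity analysis).
* Approximate/fuzzy/multiscale entropy variants are not implemented.
* The built-in trainer is a minimal CNN implementation (compiled conv and
  pooling kernels with an R optimisation loop) designed for
  reproducibility and introspection, not a general deep-learning
  framework: no GPU, no early stopping, binary classes only.
* EDF ingestion is not provided; signals enter as in-memory matrices or
  delimited text (`read_signals()`/`write_signals()`).

## A minimal session

```r
library(gradentropy)

ds <- synth_generate(synth_config(n_per_class = 150, seed = 421))
fit <- signal_cnn(ds, epochs = 12, seed = 77)

i <- which(ds$y == 1)[3]
sc <- certainty_scores(fit, ds)
h <- grad_cam(fit, ds$x[i, ], source_id = ds$sample_id[i])
es <- entropy_series(ds$x[i, ], entropy_params(m = 8, r_mult = 2,
                                               window_len = 100))
heatmap_vs_entropy(h, es)   # max corr + lag for one epoch

spec <- experiment_spec(synth = synth_config(n_per_class = 150, seed = 421),
                        m_grid = 8, r_grid = 2, n_grid = 100,
                        epochs = 12, test_fraction = 0.2)
ex <- run_experiment(spec, dataset = ds)
summary(ex)
```
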