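---
title: "Methods: dynamic brain-network features for surgical gesture classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic brain-network features for surgical gesture classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gesturenet)
```

## The model

`gesturenet` treats each annotated surgical gesture epoch as a *multilayer
functional brain network*. EEG channels are nodes; the edge weight between
channels $i$ and $j$ in layer $r$ is their magnitude-squared coherence over
the $r$-th one-second window,

$$C_{ij}(f) = \frac{|S_{ij}(f)|^2}{S_{ii}(f)\,S_{jj}(f)},$$

averaged over an aggregation band. The stack of $T$ layers (one per second
of the epoch, trailing remainder discarded; epochs shorter than 2 s are
rejected because a single layer has no dynamics) is summarized two ways:

* **Static communication structure**, per layer and averaged over layers:
  node strength, weighted transitivity, global efficiency (inverse shortest
  path length with lengths $L_{ij} = 1/w_{ij}$), search information (bits to
  follow the shortest path under random-walk step probabilities
  $w_{uv}/s_u$), and diffusion efficiency (inverse mean first passage time
  of the network random walk).
* **Community dynamics**: multilayer modularity

  $$Q = \frac{1}{2\mu} \sum_{ijlr} \Big[ \big(\Gamma_{ijl} - \gamma\,
  \tfrac{k_{il} k_{jl}}{2 m_l}\big)\,\delta_{lr} + \delta_{ij}\,\omega
  \Big] \, \delta(g_{il}, g_{jr})$$

  is optimized by a greedy Louvain-style algorithm on the supra-modularity
  matrix, repeated over seeded restarts; a consensus partition is extracted
  from the run ensemble, and the module-allegiance matrix $P$ (probability
  that two channels share a community across runs and layers) feeds the
  flexibility, integration and recruitment features.

Features are aggregated over *scopes*: each of the three functional systems
(motor, cognition, perception) restricted to the left hemisphere, the right
hemisphere, or the whole system. Six scoped families x 9 scopes, three
whole-network summaries, and three per-system spectral powers give the
60-dimensional epoch representation.

Classification follows an imbalance-aware protocol: stratified 10-fold
cross-validation in which SMOTE oversampling and ANOVA-F feature scoring are
fitted inside each training fold only, followed by one of KNN, bagged trees,
random forest or extra trees. Classifier pairs are compared with paired
t-tests over matched fold accuracies, Bonferroni-corrected.

### Assumptions

* Coherence (undirected, symmetric) is an adequate connectivity measure;
  no directed or phase-lag measures are computed.
* One second is an appropriate layer timescale: long enough for spectral
  estimation down to ~2.5 Hz resolution, short enough to expose community
  reconfiguration within a gesture.
* Cortical-system membership of each channel is known from the montage; the
  shipped 119-channel montage reproduces the published system sizes
  (motor 70, cognition 37, perception 12) but not exact electrode
  geometry, which is unpublished. Positions matter only for Laplacian
  neighbourhoods and artifact topographies, so the montage generates
  deterministic spherical coordinates.

## Tunable parameters

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| band-pass edges | 0.2–250 | Hz | At fs = 500 the upper edge equals Nyquist, so the filter degenerates to a 0.2 Hz high-pass; a band edge at Nyquist is a no-op. |
| filter steepness | 24 | dB/octave | 4th-order Butterworth, applied forward–backward (so the realized roll-off is twice that; "zero-phase" is the contract). |
| notch | 60, Q = 30 | Hz | Line noise; Q = 30 (2 Hz stop width) is a standard line-noise setting. |
| Laplacian neighbours `k` | 4 | channels | "Small Laplacian": deterministic, robust to montage irregularities. |
| artifact correlation threshold | 0.9 | – | A spatial PC is projected out when its channel-space correlation with the artifact topography (the channel pattern at peak amplitude in the marked intervals) exceeds it. |
| window / layer length | 1 | s | Layer timescale of the multilayer network. |
| coherence sub-segment | 40% of window | samples | Four half-overlapped Hann sub-segments per window (200 samples at 500 Hz): the minimal choice that keeps the estimator non-degenerate (one segment gives coherence ≡ 1) at any sampling rate. |
| aggregation band | 1–50 | Hz | Broadband mean; a neutral choice recorded in the config, switchable for band-specific analyses. |
| resolution $\gamma$ | 1 | – | Canonical default of the modularity literature; stamped into partition provenance. |
| coupling $\omega$ | 1 | – | Canonical default; `topology = "categorical"` couples all layer pairs (ordinal coupling of consecutive layers is available, and is the reading under which flexibility counts *successive* transitions). |
| optimization restarts | 100 | runs | The modularity landscape is near-degenerate; the restart ensemble feeds consensus and allegiance. Smaller values (10–25) are used in tests for speed and already recover planted structure perfectly. |
| Kaiser $\beta$ | 14 | – | High sidelobe suppression for the 1-s spectral-power windows (50% overlap). |
| SMOTE k | 5 | neighbours | Convex synthetic samples between nearest same-class neighbours; k is reduced with a warning for classes of size ≤ k. |
| trees | 350 | – | Ensemble size for BAG/RF/ET, Gini criterion, min split 2, min leaf 1; KNN uses 5 uniform-weight neighbours. |

## The synthetic generator

`generate_dataset()` emulates the structure the pipeline is designed to
detect, not the biophysics of EEG:

* per class, groups of channels share a band-limited latent oscillator
  (band-pass-filtered white noise, *not* a sinusoid — pure tones make
  coherence degenerate) mixed with weight `coupling` against independent
  channel noise, so within-group coherence is high in-band but below 1;
* per class, a multiplicative `power_gain` shifts broadband power;
* epochs have variable duration, classes can be imbalanced, and epochs are
  laid end-to-end with uncoupled idle gaps;
* all randomness derives from one master seed through counter-derived
  substreams, so every fixture is reproducible.

It does **not** model volume conduction, a forward head model, 1/f spectral
shape, non-stationary artifacts, or inter-subject variability. Passing
tests on this generator therefore demonstrate that the pipeline recovers
*planted* connectivity/power structure and that the evaluation protocol is
leak-free and calibrated (chance-level accuracy under a null generator) —
not that real OR recordings reach any particular accuracy.

## Numerical and design choices

* **Zero-phase filtering** pads both ends with odd-symmetric reflections and
  averages the forward–backward and backward–forward passes, which makes
  symmetric inputs exactly symmetric and absorbs edge transients of the
  narrow 0.2 Hz high-pass.
* **Coherence degeneracies**: zero-variance channels produce undefined
  coherence; their rows are zeroed with a warning. Diagonals are forced to
  1 in the adjacency but self-loops are removed before every graph metric.
* **Temporal aggregation** of per-layer graph metrics is the mean over the
  epoch's layers (median available). A time-averaged-Γ mode was considered
  and rejected as the default because averaging adjacencies before the
  nonlinear metrics discards layer-to-layer variability.
* **Search information** follows the single-shortest-path formula; when
  several shortest paths tie exactly, their probability masses are summed
  (the natural degenerate-tie generalization). Disconnected pairs contribute
  $+\infty$ and are excluded from scope means with a logged count;
  diffusion efficiency uses $1/\infty = 0$.
* **Transitivity** uses the geometric-mean weighted triplet convention on
  weights normalized by the layer maximum, keeping the value in $[0, 1]$ and
  scale-invariant.
* **Community labels** are canonicalized by first appearance, making
  partitions comparable across runs. Greedy sweeps randomize node order from
  the seed; ties in the gain favour the current community.
* **Consensus** operates per layer on the across-run co-assignment matrix;
  entries below the maximum co-assignment observed among node-permuted
  surrogate runs are zeroed before re-clustering, iterated until all
  re-clustering restarts agree (cap `consensus_max_iter`, warning and a
  `converged = FALSE` flag on failure). With $\omega = 0$ the multilayer
  optimizer decomposes exactly into independent single-layer runs.
* **Module allegiance** averages over runs *and* layers by default; run-only
  or layer-only averaging is obtained by passing single-layer partitions or
  a single partition.
* **Integration/recruitment scope semantics**: members of a scope are the
  channels of one cortex in one hemisphere scope; integration is their mean
  allegiance to channels *outside the whole cortex* (both hemispheres),
  recruitment their mean allegiance to *other members of the same scope*.
* **Precision and sensitivity** are macro-averaged (weighted versions are
  also reported): with imbalanced classes, micro-averaging collapses onto
  accuracy and would hide per-class behaviour.
* **Folds are stratified**; subject-grouped validation is a known
  alternative when subject leakage is a concern, but with few subjects and
  imbalanced gestures stratification keeps every class present in every
  fold.

## Problem sizes

The test-suite and acceptance runs use 12-channel montages, epochs of 2–4 s,
10–25 optimization restarts, 20 recovery trials, and a 6-class, 60-epochs
per-class end-to-end dataset. These sizes already give perfect planted
recovery and ceiling classification accuracy, and keep a full validation run
in the low minutes on a single core; the defaults (119 channels, 100
restarts) are intended for real recordings.

## Limitations

* The montage's region-to-system mapping matches published system sizes
  only; exact electrode assignments are an approximation.
* The proprietary artifact-correction product used in the original
  acquisition chain is replaced by the documented topographic-PCA
  projection on user-marked intervals; visual artifact inspection is file
  driven, not interactive.
* No per-frequency-band feature variants, no directed connectivity, no
  deep sequence models — deliberate scope bounds, not oversights.
* Real-data accuracies cannot be reproduced or checked here because the
  operating-room EEG recordings are not deposited; all empirical claims in
  this package are about synthetic data with planted structure.
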