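---
title: "Tensor-structured EEG spectral features and (higher-order) PLS regression"
author: "teneeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tensor-structured EEG spectral features and (higher-order) PLS regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A listener's EEG, recorded while they hear a speech stimulus, carries
information about how they experience it. This package predicts per-trial
subjective ratings — overall impression on a 1–5 MOS scale, valence and
arousal on 1–9 scales — from multi-channel EEG epochs, one epoch per
stimulus. The statistical difficulty is the regime: tens of trials per
subject, thousands of correlated features, and noisy ratings. The package
implements two regression strategies over the same spectral features — a
vectorized partial least squares (PLS) and a tensor-structured higher-order
PLS (HOPLS) — so the value of preserving the features' structure can be
measured directly.

# Features

For trial $n$ and channel $m$ the full-trial, unwindowed DFT
$x_{n,m}(f_k)$ gives the periodogram $p_{n,m}(f_k) = |x_{n,m}(f_k)|^2 / T$
and the phase spectrum $h_{n,m}(f_k) = \arg x_{n,m}(f_k)$. Three feature
families are averaged over the canonical bands (delta 1–4, theta 4–8,
alpha 8–12, beta 12–30, gamma 30–45 Hz):

* **PSD**$(m, f)$ — mean periodogram over the band's bins (channel-based);
* **PWD**$(m_1, m_2, f)$ = PSD$(m_1, f)$ − PSD$(m_2, f)$ (pairwise power
  difference);
* **PHD**$(m_1, m_2, f)$ — mean per-bin phase difference
  $h_{m_1} - h_{m_2}$ (pairwise phase difference).

With $M$ channels and $F$ bands this yields $I = F(M(M-1) + M)$ features
per trial. They are arranged either as rows of an $N \times I$ matrix
(`buildFeatureMatrix()`, band-major order recorded in an index map) or as
an $N \times M \times M \times F$ tensor (`buildFeatureTensor()`): PWD
below the diagonal ($m_1 > m_2$), PHD above it, PSD on it.

Numerical choices:

* **Band membership** is half-open $[\mathrm{low}, \mathrm{high})$ on each
  trial's own frequency grid, so touching band edges are counted exactly
  once; only positive-frequency bins enter, never DC. Ragged trials have
  different grids — band averaging is what makes features comparable.
* **Phase wrapping.** Raw angle subtraction is ambiguous modulo $2\pi$;
  each per-bin difference is wrapped to $(-\pi, \pi]$ before averaging,
  which keeps PHD antisymmetric and bounded. `wrap = FALSE` reproduces the
  literal unwrapped subtraction for comparison.
* **No taper, no segment averaging**: the estimator is the raw full-trial
  periodogram, matching the feature definitions exactly.

`preprocessEpochs()` provides the standard front end: a zero-phase
forward–backward Butterworth band-pass (default 0.5–50 Hz) and
integer-factor decimation (512 → 256 Hz). Zero-phase filtering matters
because PHD measures cross-channel phase; a causal filter would distort
it. The band-pass is realized as a high-pass (order 2) plus low-pass
(order 8) cascade: a single 2n-pole band-pass with a 0.5 Hz edge at a
256 Hz Nyquist is numerically unstable in transfer-function form (we
measured catastrophic error growth at order 6), while the cascade is
linear to machine precision and rejects 60 Hz mains by ≈ 28 dB.

# Regression models

Responses are always normalized column-wise to zero mean and unit variance
(sample sd, divisor $N-1$); features are mean-centered but **not**
variance-scaled (a `scaleX` option exists). All reported errors are RMSE
on the normalized response scale, so 1.0 is the score of the
training-mean predictor.

## PLS (vectorized features)

`fitPls()` is classical NIPALS PLS2 with X- and Y-deflation:
$X = \sum_r t_r p_r^\top + E$, $Y = \sum_r t_r c_r^\top + F$, scores
unit-normalized, inner loop converged at $10^{-10}$ relative change (max
500 iterations), weight signs fixed by making the first nonzero element
positive. Predictions use $B = W (P^\top W)^{-1} C^\top$. Y-deflation is
on by default and recorded in serialized models. The test suite
cross-checks predictions against an independent PLS implementation
(mixOmics) at $10^{-6}$.

## HOPLS (tensor features)

`fitHopls()` extracts components sequentially from the centered tensor.
Per component: the cross-covariance tensor
$C[j, m_1, m_2, f] = \sum_n Y[n,j]\, X[n, m_1, m_2, f]$ is formed on the
current residuals; its best rank-$(1, L_1, L_2, L_3)$ orthogonal Tucker
approximation (higher-order orthogonal iteration, truncated-SVD
initialization, ≤ 100 alternations, $10^{-9}$ relative tolerance) yields
the response loading $q_r$ and column-orthonormal mode loadings
$P_r^{(1)} (M \times L_1)$, $P_r^{(2)} (M \times L_2)$,
$P_r^{(3)} (F \times L_3)$; the score $t_r$ is extracted from the residual
tensor projected onto the loadings; the core is
$G_r = X \times_1 t_r^\top \times_2 P_r^{(1)\top} \times_3 P_r^{(2)\top}
\times_4 P_r^{(3)\top}$ and $d_r q_r = Y^\top t_r$; both blocks are
deflated by their rank-one reconstructions.

**The score rule was a genuinely open design point.** Two variants are
implemented:

* `scores = "covariance"` (default): $t_r \propto$ the projected residual
  times the core of the cross-covariance approximation. Scores stay
  response-driven, training scores are reproduced exactly by the
  prediction rule, and at full loading ranks ($L_1 = L_2 = M$, $L_3 = F$)
  the fit and its predictions coincide with NIPALS PLS2 on the vectorized
  tensor to machine precision — HOPLS is then a strict structural
  generalization of PLS, which is the property we verify in the tests.
* `scores = "svd"`: the dominant left singular vector of the mode-1
  unfolding of the projected residual, as in the original HOPLS
  formulation, with prediction through the pseudo-inverse of the core's
  unfolding. At full ranks this rule ignores the responses (the projection
  becomes a rotation and the score is simply the first principal component
  of the unfolded tensor), so it does not reduce to PLS; it is kept for
  comparison.

Sign ambiguity is resolved by forcing the first nonzero element of each
loading column and of $q_r$ non-negative, so refits are bit-identical.
Prediction projects the centered test tensor onto each component's
loadings (one multiply by the Kronecker product
$P^{(3)} \otimes P^{(2)} \otimes P^{(1)}$, since the mode-1 unfolding is
column-major over $(m_1, m_2, f)$), maps the projection to a new score,
accumulates $t\, d\, q^\top$ and deflates in training order. The
coefficient array returned by `coef()` unrolls this recursion exactly, so
attribution uses the same linear map as prediction.

# Evaluation protocol

`loocv()` runs one fold per trial. Response normalization parameters and
the model are fitted on the $N-1$ training trials only; the held-out trial
is scored on the training fold's normalized scale. This avoids leaking the
held-out trial's mean and variance; `globalNormalize = TRUE` reproduces
the literal pre-split normalization for comparison. Because both models'
components nest, the implementation fits each hyperparameter combination
once per fold at the maximal component count and reads off all smaller
models.

`gridSearch()` scans a hyperparameter grid and selects the point with the
smallest mean RMSE across the three scales — one joint winner per subject,
matching a per-subject results table with a single hyperparameter set
covering all scales. Ties go to the smallest model (fewest components,
then smallest $\sum L_k$, then grid order). The full default grids are
$R_1 \in 1..43$ for PLS and $L_1, L_2 \in 1..7$, $L_3, R_2 \in 1..5$
(1225 points) for HOPLS. Selection by best LOOCV performance is not a
nested protocol — with tens of trials per subject there is no room for a
third split — so selected RMSEs are mildly optimistic; this is a property
of the protocol being reproduced, not a bug.

`contributions()` ranks features by coefficient magnitude per scale and
summarizes the top $K$ (default 100): counts by kind (PSD/PWD/PHD), counts
by band, and the top channel pairs by summed pairwise magnitude (both
orientations, both pairwise kinds, all bands). Ties break deterministically
by feature layout order. `pairMap()` joins pairs with a schematic 64-label
10/20 montage for plotting or CSV export.

# The synthetic-data generator

`generateEpochs()` emulates the structure of a per-subject
speech-listening study: 44 trials of 13–22 s at 256 Hz (so per-trial
frequency grids differ), 16 channels by default (configurable up to the
full 64-label montage; 16 keeps the HOPLS grids tractable on one core).
Each trial sums one sinusoid per canonical band at a random in-band
frequency. Channel gains are log-normal around the trial's band amplitude,
with two variance sources:

* **structured**: a few fixed random spatial patterns per band (default 3)
  scaled by per-trial factor scores — multichannel EEG is strongly
  spatially correlated because few cortical sources project to all
  channels through fixed scalp maps, and this is the single property that
  makes structured (tensor) regression worthwhile;
* **unstructured**: independent per-channel log-gain jitter (default 0.1).

Channel phases follow configured pairwise lags plus jitter, which gives
the PHD features their signal. White Gaussian noise is added per sample.

`generateRatings()` computes the actual feature tensor of the generated
epochs, centers it across trials, takes the inner product with a
ground-truth coefficient array per scale (`makeTruth()`: sparse cells or a
low-rank outer-product pattern, antisymmetrized off the diagonal), adds
Gaussian noise scaled relative to the signal sd, and rescales affinely
into the printed rating ranges. The full ground-truth record (truth
tensor, raw values, noise draws, scaling) is returned for test
assertions.

What the generator does **not** emulate: 1/f background spectra,
artifacts (blinks, muscle), non-stationarity within a trial,
volume-conduction forward physics, or rating distributions of real
observers. Passing tests therefore demonstrate correctness of the
algorithms and the direction of the structural advantage under a known
model — not performance on real recordings.

`hoplsModelData()` draws data exactly from the sequential HOPLS
decomposition for recovery tests. Its scores are zero-mean orthonormal
and its channel-mode loading subspaces are orthogonal across components:
in that identifiable regime greedy sequential extraction recovers the
model exactly in the noiseless case (observed at machine precision),
whereas with overlapping component subspaces greedy deflation is not
exact — a known property of sequential tensor decompositions, which is
why the recovery tests pin down this regime explicitly.

# Calibration of the comparison experiment

The headline experiment (`compareTensorVector()`) asks whether tensor
HOPLS beats vectorized PLS under leave-one-out evaluation on synthetic
studies with low-rank spatial-spectral truth. Its conditions are fixed at:
44 trials, 16 channels, rank-1 pairwise-only truth per scale, rating
noise 1.5 relative to the signal sd, grids $R_1 \in 1..8$ and
$L_1, L_2 \in 2..3$, $L_3 \in 1..2$, $R_2 \in 1..5$ (the full protocol
scaled to desk size), HOOI capped at 5 sweeps (fit residuals match the
default setting to three digits at a fraction of the cost). Three
calibration choices deserve explanation:

* **Pairwise-only truth.** The tensor's PSD diagonal is `diag(a)` across
  trials — full rank in the channel modes — so weight placed on it cannot
  be expressed by low-rank channel loadings, and pairwise features are
  also where the predictive signal was reported to live on real data.
* **Spatial structure dominant.** With spatially i.i.d. channel jitter
  the loading constraint has nothing to exploit and the flexible
  vectorized model wins; the experiment uses a high spatial-factor share
  (factor sd 0.8 against unstructured jitter sd 0.05), as volume
  conduction produces on real scalps.
* **Weak signal.** Predicting subjective ratings from single-trial EEG
  is an overfitting-limited problem: with tens of trials and thousands
  of features, a flexible vectorized model can easily score worse than
  predicting the mean (RMSE above 1 on the normalized scale), and the
  interesting question is which model degrades more gracefully. Rating
  noise 1.5 puts the experiment in that regime: the
  vectorized model hovers near 1 while the constrained tensor model
  retains a margin of skill, winning in 16 of 20 synthetic subjects
  (mean RMSE 0.974 vs 0.994). With very clean ratings the ordering
  reverses slightly — worth remembering when interpreting the method on
  high-SNR data.

The mean-RMSE advantage of the tensor model is stable across independent
seed sets (0.006–0.02 on the normalized scale), but the per-subject win
fraction fluctuates around 0.75–0.85 because the per-subject gap is of
the same order as the grid-selection noise; single-subject comparisons
of the two models should therefore not be over-interpreted.

The null-skill study uses the same selection protocol with zero truth;
its RMSE sits near 1 since there is nothing to predict. Fixed (unselected)
hyperparameters on pure noise give LOOCV RMSE up to ~1.2 — honest
overfitting, and the reason the null check is run under the selection
protocol actually used for comparisons.

# Known limitations

* Grid search over the full 1225-point HOPLS grid with 44-fold LOOCV is
  minutes per subject on one core; the experiment wrappers use scaled
  grids.
* HOPLS assumes the predictive structure aligns with low-rank mode
  subspaces shared across components; when feature variation is spatially
  isotropic the constraint only costs accuracy (we observe exactly this
  with the generator's spatial structure disabled).
* PHD is meaningful only where band power is non-negligible; on silent
  channels phases are numerical noise. The generator always places a
  sinusoid in every band, so its PHD is well-defined; real data may need
  band-power screening.
* The feature matrix and tensor carry each pairwise feature once per
  ordered pair; with exact linear dependencies among features (PWD is a
  difference of PSDs by construction) coefficient attribution spreads
  weight across dependent features, and rankings should be read with that
  in mind.
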