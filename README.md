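# teneeg

Predicting subjective speech-quality ratings from a listener's EEG, with
tensor-structured spectral features.

## The problem

In a per-subject listening study, each trial is a multi-channel EEG epoch
recorded while the subject hears one stimulus, followed by ratings:
overall impression (MOS, 1–5), valence and arousal (1–9). With ~44 trials,
up to 64 channels and thousands of correlated spectral features, fitting a
predictive model is a small-N, large-I problem. `teneeg` implements the
full pipeline and lets the key modelling question be tested directly:
does *preserving the structure* of the features — organizing them as a
trials × channel × channel × band tensor instead of a flat vector — give
better predictions?

## Features and models

Per trial and channel the full-trial periodogram `p(f) = |x(f)|²/T` and
phase spectrum are averaged over the canonical bands (delta, theta, alpha,
beta, gamma), giving three families:

* `PSD(m, f)` — band power of a channel,
* `PWD(m1, m2, f) = PSD(m1, f) − PSD(m2, f)` — pairwise power difference,
* `PHD(m1, m2, f)` — mean pairwise phase difference (wrapped per bin).

With M channels and F bands that is `I = F(M(M−1)+M)` features per trial,
arranged as an `N × I` matrix or an `N × M × M × F` tensor (PWD below the
diagonal, PHD above, PSD on it). Two regressions share the evaluation
protocol:

* **PLS** — NIPALS PLS2 on the vectorized features,
  `X = Σ t_r p_r' + E`, `Y = Σ t_r c_r' + F`;
* **HOPLS** — higher-order PLS on the tensor: per component a score
  vector, column-orthonormal loading matrices `P⁽¹⁾ (M×L1)`,
  `P⁽²⁾ (M×L2)`, `P⁽³⁾ (F×L3)` from a rank-(1, L1, L2, L3) Tucker
  approximation of the cross-covariance tensor, and a core `G_r`.

Evaluation is per-subject leave-one-out cross-validation with grid search
(`R1 ∈ 1..43`; `L1, L2 ∈ 1..7`, `L3, R2 ∈ 1..5`), RMSE on
variance-normalized ratings (1.0 = the training-mean predictor).
Feature attribution ranks coefficient magnitudes: top-100 counts by kind
and band, top-10 channel pairs.

## Worked example

Everything below runs on synthetic data with known ground truth; no
recordings are required.

```r
library(teneeg)

cfg <- simulationConfig(nTrials = 44, nChannels = 16, ratingNoiseSd = 1.5,
                        seed = 2)
study <- simulateStudy(cfg, truthKind = "lowRank", rank = 1,
                       includeDiagonal = FALSE)

study$tensor
#> FeatureTensor: 44 x 16 x 16 x 5 (trials x ch x ch x bands)
ncol(featureValues(study$matrix))    # 5 * (16*15 + 16)
#> [1] 1280

evP <- gridSearch(study$matrix, study$ratings, "pls",
                  grid = data.frame(R1 = 1:8))
evH <- gridSearch(study$tensor, study$ratings, "hopls",
                  grid = expand.grid(L1 = 2:4, L2 = 2:4, L3 = 1:2,
                                     R2 = 1:4))
evaluationTable(evP, evH, subject = subjectId(study$epochs))
```

The table has one row per subject in the schema
`MOS/VAL/ARL RMSE (vector), MOS/VAL/ARL RMSE (tensor), R1, L1, L2, L3, R2`;
RMSE is on the normalized scale, so values below 1 indicate genuine
predictive skill and the vector-vs-tensor columns can be compared
directly.

Attribution of a fitted model:

```r
Y <- normalizeResponses(study$ratings[c("MOS", "VAL", "ARL")])$values
m <- fitHopls(study$tensor, Y, ncomp = 2, L = c(3, 3, 2))
rep <- contributions(m, K = 100)
rep@bandCounts          # band counts among the top 100 features
pairMap(rep, scale = "MOS")   # top channel pairs on scalp coordinates
                              # from standardMontage()
```

A thin command-line interface wraps the same functions:

```sh
Rscript inst/scripts/teneeg simulate --out study_dir --seed 1
Rscript inst/scripts/teneeg extract --epochs study_dir/epochs --out feats.bin
Rscript inst/scripts/teneeg evaluate --features feats.bin \
    --ratings study_dir/ratings.csv --model hopls --grid default --out ev.json
Rscript inst/scripts/teneeg contrib --model model.json --out report_dir
```

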