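# shared fixtures and independent oracles

# independent brute-force DFT (double loop over time and frequency,
# vectorized over time only) — the oracle for computeSpectrum
bruteDft <- function(x) {
  Tn <- length(x)
  tt <- 0:(Tn - 1)
  vapply(0:(Tn - 1),
         function(k) sum(x * exp(-2i * pi * k * tt / Tn)),
         complex(1))
}

# small EpochSet with random white-noise trials
randomEpochs <- function(nTrials = 3, M = 3, Tn = 256, rate = 256,
                         seed = 1, subject = "s1") {
  set.seed(seed)
  trials <- lapply(seq_len(nTrials), function(i) {
    len <- if (length(Tn) > 1) Tn[(i - 1) %% length(Tn) + 1] else Tn
    matrix(rnorm(M * len), M, len)
  })
  EpochSet(subject, trials, standardMontage()$label[seq_len(M)], rate)
}

# one-trial EpochSet holding a pure sinusoid on every channel
sineEpochs <- function(freq = 10, Tn = 256, rate = 256, M = 1, amp = 1,
                       phase = rep(0, M)) {
  tt <- (0:(Tn - 1)) / rate
  tr <- matrix(0, M, Tn)
  for (m in seq_len(M)) tr[m, ] <- amp * cos(2 * pi * freq * tt + phase[m])
  EpochSet("s1", list(tr), standardMontage()$label[seq_len(M)], rate)
}

# FeatureSet from random epochs (full pipeline, small)
randomFeatureSet <- function(nTrials = 4, M = 3, seed = 1, Tn = 256,
                             bands = spectralBands()) {
  computeFeatures(randomEpochs(nTrials, M, Tn, seed = seed), bands)
}

# responses in the span of the leading latent directions of centered X:
# Y = X B with rank-k B, fit exactly by k PLS components
latentResponses <- function(X, k = 3, J = 3, seed = 1) {
  set.seed(seed)
  s <- svd(scale(X, scale = FALSE))
  rot <- qr.Q(qr(matrix(rnorm(J * J), J)))
  Y <- s$u[, seq_len(k)] %*% diag(seq(k + 2, 3, length.out = k)) %*%
    rot[seq_len(k), , drop = FALSE]
  colnames(Y) <- c("MOS", "VAL", "ARL")[seq_len(J)]
  Y
}

normalizedRatings <- function(ratings) {
  normalizeResponses(ratings[c("MOS", "VAL", "ARL")])$values
}
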