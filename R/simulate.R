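#' Simulation configuration for synthetic EEG studies
#'
#' Describes a synthetic per-subject study: trials of band-limited
#' oscillatory activity with inter-channel phase lags plus white noise, and
#' ratings coupled linearly to the extracted tensor features. Defaults
#' emulate a desk-scale version of a single-subject speech-listening
#' session: 44 trials of 13-22 s at 256 Hz; 16 channels keep the
#' tensor-regression grids tractable while the generator accepts up to the
#' full 64-channel montage.
#'
#' @param nTrials number of trials (default 44).
#' @param nChannels number of channels M (default 16, up to 64).
#' @param samplingRate sampling rate in Hz (default 256).
#' @param durationRange trial duration range in seconds (default 13-22).
#' @param bandAmplitude per-band amplitude range(s): a length-2 vector
#'   applied to every band, or a 2 x F matrix (columns = bands). Per trial
#'   and band an amplitude is drawn uniformly from the range.
#' @param channelGainSd log-normal sd of the per-trial, per-channel
#'   unstructured gain jitter (makes power-difference features
#'   informative).
#' @param nSpatialFactors number of latent spatial amplitude patterns per
#'   band (default 3). Multichannel EEG is strongly spatially correlated —
#'   few sources project to all channels through fixed scalp maps — so
#'   per-trial channel gains are modulated through a small set of fixed
#'   random patterns with per-trial, per-band factor scores; 0 disables
#'   the structure (purely independent gain jitter).
#' @param spatialFactorSd log-scale sd of the spatial factor scores.
#' @param phaseLags named numeric vector of inter-channel phase lags in
#'   radians; names are "A-B" channel-label pairs and the value is the phase
#'   of A minus the phase of B. Unknown labels raise a config error.
#' @param phaseJitterSd sd of per-trial, per-channel phase jitter in
#'   radians (makes phase-difference features informative).
#' @param noiseSd white-noise standard deviation added to every sample.
#' @param ratingNoiseSd rating noise, expressed relative to the sd of the
#'   noiseless rating signal (0.1 means signal-to-noise ratio 10).
#' @param subject subject identifier.
#' @param seed random seed (mandatory for reproducibility).
#' @return a validated \code{SimulationConfig} list.
#' @export
simulationConfig <- function(nTrials = 44, nChannels = 16,
                             samplingRate = 256, durationRange = c(13, 22),
                             bandAmplitude = c(0.5, 1.5),
                             channelGainSd = 0.1, nSpatialFactors = 3,
                             spatialFactorSd = 0.5, phaseLags = NULL,
                             phaseJitterSd = 0.3, noiseSd = 1,
                             ratingNoiseSd = 0.1, subject = "sim01",
                             seed = 1) {
  stopifnot(nTrials >= 1, nChannels >= 2, samplingRate > 0,
            length(durationRange) == 2, durationRange[1] > 0,
            durationRange[1] <= durationRange[2],
            channelGainSd >= 0, nSpatialFactors >= 0, spatialFactorSd >= 0,
            phaseJitterSd >= 0, noiseSd >= 0,
            ratingNoiseSd >= 0, is.numeric(seed), length(seed) == 1)
  cfg <- list(nTrials = as.integer(nTrials),
              nChannels = as.integer(nChannels),
              samplingRate = samplingRate, durationRange = durationRange,
              bandAmplitude = bandAmplitude, channelGainSd = channelGainSd,
              nSpatialFactors = as.integer(nSpatialFactors),
              spatialFactorSd = spatialFactorSd,
              phaseLags = phaseLags, phaseJitterSd = phaseJitterSd,
              noiseSd = noiseSd, ratingNoiseSd = ratingNoiseSd,
              subject = subject, seed = as.integer(seed))
  class(cfg) <- c("SimulationConfig", "list")
  cfg
}

# resolve pairwise lags into per-channel phase offsets
lagOffsets <- function(phaseLags, channels) {
  off <- stats::setNames(rep(0, length(channels)), channels)
  if (is.null(phaseLags)) return(off)
  for (k in seq_along(phaseLags)) {
    pair <- strsplit(names(phaseLags)[k], "-", fixed = TRUE)[[1]]
    if (length(pair) != 2 || !all(pair %in% channels))
      stop("config error: phase-lag pair '", names(phaseLags)[k],
           "' references unknown channels")
    off[pair[1]] <- off[pair[2]] + phaseLags[k]
  }
  off
}

#' Generate a synthetic EpochSet
#'
#' Each trial is a sum over the frequency bands of sinusoids at random
#' in-band frequencies: per trial and band, one frequency, a base amplitude
#' and a base phase are drawn; each channel modulates the amplitude by a
#' log-normal gain — structured through a few fixed spatial patterns with
#' per-trial factor scores, emulating the strong inter-channel correlation
#' of source-projected EEG, plus independent jitter — and shifts the phase
#' by its configured offset plus jitter. White Gaussian noise is added on
#' top. Trial lengths are uniform over the configured duration range, so
#' per-trial frequency grids differ, as for variable-length stimuli.
#'
#' @param config a [simulationConfig()].
#' @param bands band table (default [spectralBands()]).
#' @return an [EpochSet-class] with \code{config$nChannels} 10/20-style
#'   channel labels.
#' @export
generateEpochs <- function(config, bands = spectralBands()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  M <- config$nChannels
  channels <- standardMontage()$label[seq_len(M)]
  off <- lagOffsets(config$phaseLags, channels)
  Fb <- nrow(bands)
  amp <- config$bandAmplitude
  if (is.null(dim(amp))) amp <- matrix(amp, nrow = 2, ncol = Fb)
  rate <- config$samplingRate
  K <- config$nSpatialFactors
  # fixed unit spatial patterns per band; per-trial factor scores modulate
  # the channel gains through them (log scale keeps gains positive)
  U <- if (K > 0)
    lapply(seq_len(Fb), function(f) {
      u <- matrix(stats::rnorm(M * K), M, K)
      sweep(u, 2, sqrt(colSums(u^2)), "/")
    })
  else NULL
  trials <- vector("list", config$nTrials)
  for (n in seq_len(config$nTrials)) {
    Tn <- round(stats::runif(1, config$durationRange[1],
                             config$durationRange[2]) * rate)
    tt <- (seq_len(Tn) - 1) / rate
    x <- matrix(stats::rnorm(M * Tn, sd = config$noiseSd), M, Tn)
    for (f in seq_len(Fb)) {
      freq <- stats::runif(1, bands$low[f], min(bands$high[f], rate / 2))
      a0 <- stats::runif(1, amp[1, f], amp[2, f])
      ph0 <- stats::runif(1, -pi, pi)
      lg <- stats::rnorm(M, sd = config$channelGainSd)
      if (K > 0)
        lg <- lg + drop(U[[f]] %*% stats::rnorm(K,
                                                sd = config$spatialFactorSd))
      gain <- a0 * exp(lg)
      ph <- ph0 + off + stats::rnorm(M, sd = config$phaseJitterSd)
      x <- x + gain * cos(outer(ph, 2 * pi * freq * tt, `+`))
    }
    trials[[n]] <- x
  }
  EpochSet(config$subject, trials, channels, rate)
}

#' Construct a ground-truth coefficient tensor
#'
#' Builds one M x M x F coefficient array per rating scale, either
#' \code{"sparse"} (a few nonzero cells, optionally at given positions) or
#' \code{"lowRank"} (a sum of outer products of random unit channel and
#' band factors, with the off-diagonal part antisymmetrized across the two
#' channel modes).
#'
#' @param kind "sparse" or "lowRank".
#' @param M,Fb channel and band counts.
#' @param J number of rating scales (default 3).
#' @param k number of nonzero cells per scale (sparse).
#' @param rank number of outer-product terms per scale (lowRank).
#' @param cells optional data.frame (m1, m2, f) fixing the sparse support
#'   (recycled over scales); values default to 1.
#' @param bandWeights optional length-F multiplier, e.g. to confine the
#'   truth to one band.
#' @param includeDiagonal allow weight on the PSD diagonal (default TRUE).
#' @param seed random seed.
#' @return M x M x F x J numeric array.
#' @export
makeTruth <- function(kind = c("sparse", "lowRank"), M, Fb, J = 3, k = 3,
                      rank = 1, cells = NULL, bandWeights = NULL,
                      includeDiagonal = TRUE, seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  W <- array(0, dim = c(M, M, Fb, J))
  for (j in seq_len(J)) {
    if (kind == "sparse") {
      if (is.null(cells)) {
        pool <- expand.grid(m1 = seq_len(M), m2 = seq_len(M),
                            f = seq_len(Fb))
        if (!includeDiagonal) pool <- pool[pool$m1 != pool$m2, ]
        cj <- pool[sample(nrow(pool), k), ]
        vals <- stats::rnorm(k)
      } else {
        cj <- cells
        vals <- if (is.null(cells$value)) rep(1, nrow(cells)) else
          cells$value
      }
      for (i in seq_len(nrow(cj)))
        W[cj$m1[i], cj$m2[i], cj$f[i], j] <- vals[i]
    } else {
      Wj <- array(0, dim = c(M, M, Fb))
      for (r in seq_len(rank)) {
        u <- stats::rnorm(M); u <- u / sqrt(sum(u^2))
        v <- stats::rnorm(M); v <- v / sqrt(sum(v^2))
        b <- abs(stats::rnorm(Fb)); b <- b / sqrt(sum(b^2))
        Wj <- Wj + outer(outer(u, v), b)
      }
      # antisymmetrize the pairwise (off-diagonal) regions
      dg <- array(0, dim = dim(Wj))
      for (f in seq_len(Fb)) dg[, , f] <- diag(diag(Wj[, , f]))
      anti <- (Wj - aperm(Wj, c(2, 1, 3))) / 2
      Wj <- anti + if (includeDiagonal) dg else 0
      W[, , , j] <- Wj
    }
    if (!is.null(bandWeights))
      W[, , , j] <- W[, , , j] *
        aperm(array(bandWeights, dim = c(Fb, M, M)), c(2, 3, 1))
  }
  W
}

#' Generate ratings linearly coupled to the feature tensor
#'
#' Extracts the feature tensor from the epochs, centers it across trials,
#' and sets the raw response of scale j to the inner product of trial n's
#' centered slice with the scale's ground-truth coefficient array, plus
#' Gaussian noise whose sd is \code{noiseSd} times the sd of the noiseless
#' signal. Raw responses are then affinely rescaled into the printed rating
#' ranges (MOS into [1, 5]; VAL and ARL into [1, 9]).
#'
#' @param epochs an [EpochSet-class].
#' @param truth M x M x F x J array from [makeTruth()] (J = 3, scales
#'   MOS, VAL, ARL).
#' @param noiseSd relative rating noise (see above).
#' @param seed random seed for the noise draws.
#' @param bands band table used for feature extraction.
#' @param wrap phase-wrapping flag (see [computePhd()]).
#' @param tensor optional precomputed [FeatureTensor-class] of
#'   \code{epochs} (avoids re-extracting features).
#' @return list with \code{ratings} (data.frame subject, trial, MOS, VAL,
#'   ARL), \code{truth} (the coefficient array), \code{raw} (noiseless
#'   inner products), \code{noise} (the added noise) and \code{scaling}
#'   (per-scale affine parameters) — the full ground-truth record.
#' @export
generateRatings <- function(epochs, truth, noiseSd = 0.1, seed = 1,
                            bands = spectralBands(), wrap = TRUE,
                            tensor = NULL) {
  stopifnot(is(epochs, "EpochSet"))
  ft <- if (is.null(tensor))
    buildFeatureTensor(computeFeatures(epochs, bands, wrap = wrap))
  else tensor
  X <- centerTensor(ft@values)$values
  d <- dim(X)
  if (!all(dim(truth)[1:3] == d[2:4]))
    stop("shape error: truth dimensions do not match the feature tensor")
  N <- d[1]; J <- dim(truth)[4]
  Xm <- matrix(X, nrow = N)
  raw <- Xm %*% matrix(truth, ncol = J)
  set.seed(seed)
  sig <- apply(raw, 2, stats::sd)
  noise <- matrix(stats::rnorm(N * J), N, J) *
    rep(noiseSd * ifelse(sig > 0, sig, 1), each = N)
  y <- raw + noise
  lo <- c(1, 1, 1); hi <- c(5, 9, 9)
  scaling <- data.frame(scale = c("MOS", "VAL", "ARL"), a = NA_real_,
                        b = NA_real_)
  out <- matrix(0, N, 3, dimnames = list(NULL, c("MOS", "VAL", "ARL")))
  for (j in seq_len(3)) {
    rng <- range(y[, j])
    a <- if (diff(rng) > 0) (hi[j] - lo[j]) / diff(rng) else 0
    b <- lo[j] - a * rng[1]
    out[, j] <- a * y[, j] + b
    scaling$a[j] <- a; scaling$b[j] <- b
  }
  ratings <- data.frame(subject = subjectId(epochs), trial = seq_len(N),
                        MOS = out[, "MOS"], VAL = out[, "VAL"],
                        ARL = out[, "ARL"])
  list(ratings = ratings, truth = truth, raw = raw, noise = noise,
       scaling = scaling)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: epochs, features and coupled ratings with a known
#' ground truth, fully determined by the configuration seed.
#'
#' @param config a [simulationConfig()].
#' @param truthKind "lowRank" (default) or "sparse" (see [makeTruth()]).
#' @param bands band table.
#' @param ... further arguments to [makeTruth()].
#' @return list with \code{epochs}, \code{features} (a
#'   [FeatureSet-class]), \code{tensor}, \code{matrix}, \code{ratings} and
#'   \code{truth} (ground-truth record from [generateRatings()]).
#' @export
simulateStudy <- function(config, truthKind = "lowRank",
                          bands = spectralBands(), ...) {
  epochs <- generateEpochs(config, bands)
  truth <- makeTruth(truthKind, M = config$nChannels, Fb = nrow(bands),
                     seed = config$seed + 1L, ...)
  fs <- computeFeatures(epochs, bands)
  ft <- buildFeatureTensor(fs)
  gt <- generateRatings(epochs, truth, noiseSd = config$ratingNoiseSd,
                        seed = config$seed + 2L, bands = bands,
                        tensor = ft)
  list(epochs = epochs, features = fs,
       tensor = ft, matrix = buildFeatureMatrix(fs),
       ratings = gt$ratings, truth = gt)
}

#' Synthetic data drawn exactly from the HOPLS model
#'
#' Draws a four-mode predictor tensor and responses from the sequential
#' rank-(1, L1, L2, L3) decomposition itself: zero-mean orthonormal score
#' vectors, random column-orthonormal loading matrices whose channel-mode
#' subspaces are orthogonal across components (an identifiable regime in
#' which sequential extraction recovers the model exactly in the noiseless
#' case), random cores with decreasing strengths, plus optional Gaussian
#' noise on both blocks. Used for recovery and calibration experiments.
#'
#' @param N,M,Fb,J mode dimensions (trials, channels, bands, responses).
#' @param R2 number of components; requires \code{R2 * L[1] <= M} and
#'   \code{R2 * L[2] <= M} for across-component orthogonality.
#' @param L loading ranks (L1, L2, L3).
#' @param noiseSd sd of additive Gaussian noise on X and Y entries.
#' @param seed random seed.
#' @return list with X (array), Y (matrix), and the generating scores,
#'   loadings and cores.
#' @export
hoplsModelData <- function(N, M, Fb, J = 3, R2 = 3, L = c(2, 2, 2),
                           noiseSd = 0, seed = 1) {
  stopifnot(R2 * L[1] <= M, R2 * L[2] <= M, L[3] <= Fb)
  set.seed(seed)
  rorth <- function(n, k) qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))
  Tm <- qr.Q(qr(scale(matrix(stats::rnorm(N * R2), N, R2), scale = FALSE)))
  P1a <- rorth(M, R2 * L[1]); P2a <- rorth(M, R2 * L[2])
  Q <- rorth(J, min(J, R2))
  X <- array(0, dim = c(N, M, M, Fb)); Y <- matrix(0, N, J)
  comps <- list()
  for (r in seq_len(R2)) {
    P1 <- P1a[, ((r - 1) * L[1] + 1):(r * L[1]), drop = FALSE]
    P2 <- P2a[, ((r - 1) * L[2] + 1):(r * L[2]), drop = FALSE]
    P3 <- rorth(Fb, L[3])
    G <- array(stats::rnorm(prod(L)), dim = L) * (R2 - r + 1)
    D <- G
    for (k in 1:3) D <- modeProduct(D, list(P1, P2, P3)[[k]], k)
    X <- X + outer(Tm[, r], D)
    Y <- Y + tcrossprod(Tm[, r], Q[, min(r, ncol(Q))]) * 3 * (R2 - r + 1)
    comps[[r]] <- list(P = list(P1, P2, P3), G = G)
  }
  if (noiseSd > 0) {
    X <- X + array(stats::rnorm(length(X), sd = noiseSd), dim = dim(X))
    Y <- Y + matrix(stats::rnorm(length(Y), sd = noiseSd), N, J)
  }
  nm <- c("MOS", "VAL", "ARL")
  colnames(Y) <- if (J <= 3) nm[seq_len(J)] else c(nm, paste0("Y", 4:J))
  list(X = X, Y = Y, scores = Tm, components = comps)
}
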