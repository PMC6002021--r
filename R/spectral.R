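#' Canonical EEG frequency bands
#'
#' The five canonical bands: delta 1-4, theta 4-8, alpha 8-12, beta 12-30
#' and gamma 30-45 Hz. Band membership of a frequency bin is decided on
#' half-open intervals [low, high), so touching edges (4, 8, 12, 30 Hz)
#' belong to the upper band exactly once.
#'
#' @return data.frame with columns name, low, high (Hz).
#' @export
spectralBands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low = c(1, 4, 8, 12, 30),
             high = c(4, 8, 12, 30, 45),
             stringsAsFactors = FALSE)
}

#' Validate a band definition table
#'
#' @param bands data.frame with columns name, low, high.
#' @return the validated table, invisibly.
#' @export
validateBands <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("name", "low", "high") %in%
                                        names(bands)))
  if (any(bands$low <= 0) || any(bands$low >= bands$high))
    stop("band definition error: need 0 < low < high for every band")
  if (nrow(bands) > 1) {
    o <- order(bands$low)
    if (any(bands$high[o][-nrow(bands)] > bands$low[o][-1] + 1e-12))
      stop("band definition error: bands must be non-overlapping")
  }
  invisible(bands)
}

#' Full-trial Fourier spectra of an EpochSet
#'
#' Computes, for each trial and channel, the unwindowed, untapered DFT of
#' the entire trial. The periodogram power estimate is p(f_k) =
#' |x(f_k)|^2 / T and the phase spectrum is the complex argument; both are
#' derived on demand by [periodogram()] and [phaseSpectrum()]. Each trial
#' uses its own grid f_k = k * rate / T, so ragged trials yield different
#' grids; band averaging makes the features comparable across trials.
#'
#' @param epochs an [EpochSet-class].
#' @return a [SpectrumSet-class].
#' @export
computeSpectrum <- function(epochs) {
  stopifnot(is(epochs, "EpochSet"))
  coefs <- vector("list", nTrials(epochs))
  freqs <- vector("list", nTrials(epochs))
  for (n in seq_len(nTrials(epochs))) {
    tr <- epochs@trials[[n]]
    Tn <- ncol(tr)
    if (Tn < 2L) stop(sprintf("input error: trial %d shorter than 2 samples",
                              n))
    coefs[[n]] <- t(stats::mvfft(t(tr)))
    freqs[[n]] <- (seq_len(Tn) - 1) * epochs@rate / Tn
  }
  new("SpectrumSet", coefficients = coefs, freqs = freqs,
      channels = epochs@channels, rate = epochs@rate)
}

#' Periodogram and phase spectrum of one trial
#'
#' @param spectra a [SpectrumSet-class].
#' @param trial trial index.
#' @return \code{periodogram}: channels x bins matrix of power values
#'   |x(f_k)|^2 / T (all DFT bins, so the Parseval identity
#'   \code{sum(p)} = time-domain sum of squares holds per channel);
#'   \code{phaseSpectrum}: channels x bins matrix of phases in (-pi, pi].
#' @export
periodogram <- function(spectra, trial) {
  stopifnot(is(spectra, "SpectrumSet"))
  x <- spectra@coefficients[[trial]]
  Mod(x)^2 / ncol(x)
}

#' @rdname periodogram
#' @export
phaseSpectrum <- function(spectra, trial) {
  stopifnot(is(spectra, "SpectrumSet"))
  Arg(spectra@coefficients[[trial]])
}

#' @rdname periodogram
#' @export
trialFrequencies <- function(spectra, trial) spectra@freqs[[trial]]

# indices of positive-frequency bins (k = 1 .. floor(T/2)) of a band,
# half-open membership [low, high)
bandBinIndices <- function(freqs, low, high) {
  Tn <- length(freqs)
  pos <- 2:(floor(Tn / 2) + 1L)
  pos[freqs[pos] >= low & freqs[pos] < high]
}

#' Band-averaged power spectral density
#'
#' Averages the periodogram over the frequency bins of each band:
#' PSD(m, f) = mean of p(f_k) over bins f_k in band f. Only
#' positive-frequency bins (k = 1 .. floor(T/2)) enter a band; the DC bin
#' is never included.
#'
#' @param spectra a [SpectrumSet-class].
#' @param bands band table as from [spectralBands()].
#' @return N x M x F array of band powers.
#' @export
bandAveragePsd <- function(spectra, bands = spectralBands()) {
  stopifnot(is(spectra, "SpectrumSet"))
  validateBands(bands)
  N <- nTrials(spectra); M <- length(spectra@channels); Fb <- nrow(bands)
  psd <- array(0, dim = c(N, M, Fb),
               dimnames = list(NULL, spectra@channels, bands$name))
  for (n in seq_len(N)) {
    p <- periodogram(spectra, n)
    fr <- spectra@freqs[[n]]
    for (f in seq_len(Fb)) {
      idx <- bandBinIndices(fr, bands$low[f], bands$high[f])
      if (!length(idx))
        stop(sprintf("band '%s' contains no frequency bins for trial %d",
                     bands$name[f], n))
      psd[n, , f] <- rowMeans(p[, idx, drop = FALSE])
    }
  }
  psd
}

#' Pairwise band-power differences
#'
#' PWD(m1, m2, f) = PSD(m1, f) - PSD(m2, f) for every ordered channel pair;
#' antisymmetric in the channel modes and zero on the diagonal.
#'
#' @param psd N x M x F array from [bandAveragePsd()].
#' @return N x M x M x F array.
#' @export
computePwd <- function(psd) {
  d <- dim(psd)
  N <- d[1]; M <- d[2]; Fb <- d[3]
  a <- array(psd, dim = c(N, M, 1, Fb))[, , rep(1, M), , drop = FALSE]
  b <- aperm(a, c(1, 3, 2, 4))
  out <- a - b
  dimnames(out) <- list(NULL, dimnames(psd)[[2]], dimnames(psd)[[2]],
                        dimnames(psd)[[3]])
  out
}

#' Wrap angles to (-pi, pi]
#'
#' @param x angles in radians.
#' @return wrapped angles.
#' @export
wrapPhase <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

#' Pairwise mean phase differences
#'
#' PHD(m1, m2, f) = mean over the band's bins of the phase difference
#' h_{m1}(f_k) - h_{m2}(f_k). Raw angle subtraction is ambiguous modulo
#' 2 pi, so by default every per-bin difference is wrapped to (-pi, pi]
#' before averaging, which preserves antisymmetry and boundedness;
#' \code{wrap = FALSE} reproduces the literal unwrapped subtraction.
#'
#' @param spectra a [SpectrumSet-class].
#' @param bands band table.
#' @param wrap wrap per-bin differences to (-pi, pi] (default TRUE).
#' @return N x M x M x F array.
#' @export
computePhd <- function(spectra, bands = spectralBands(), wrap = TRUE) {
  stopifnot(is(spectra, "SpectrumSet"))
  validateBands(bands)
  N <- nTrials(spectra); M <- length(spectra@channels); Fb <- nrow(bands)
  phd <- array(0, dim = c(N, M, M, Fb),
               dimnames = list(NULL, spectra@channels, spectra@channels,
                               bands$name))
  for (n in seq_len(N)) {
    h <- phaseSpectrum(spectra, n)
    fr <- spectra@freqs[[n]]
    for (f in seq_len(Fb)) {
      idx <- bandBinIndices(fr, bands$low[f], bands$high[f])
      if (!length(idx))
        stop(sprintf("band '%s' contains no frequency bins for trial %d",
                     bands$name[f], n))
      hb <- h[, idx, drop = FALSE]                    # M x B
      B <- length(idx)
      a1 <- aperm(array(hb, dim = c(M, B, M)), c(1, 3, 2))  # h[m1, k]
      a2 <- aperm(array(hb, dim = c(M, B, M)), c(3, 1, 2))  # h[m2, k]
      d <- a1 - a2
      if (wrap) d <- wrapPhase(d)
      phd[n, , , f] <- matrix(d, nrow = M * M) %*% rep(1 / B, B)
    }
  }
  phd
}

#' Compute all spectral features of an EpochSet
#'
#' Convenience wrapper running [computeSpectrum()], [bandAveragePsd()],
#' [computePwd()] and [computePhd()].
#'
#' @param epochs an [EpochSet-class].
#' @param bands band table as from [spectralBands()].
#' @param wrap wrap per-bin phase differences (see [computePhd()]).
#' @return a [FeatureSet-class].
#' @export
computeFeatures <- function(epochs, bands = spectralBands(), wrap = TRUE) {
  sp <- computeSpectrum(epochs)
  psd <- bandAveragePsd(sp, bands)
  new("FeatureSet", psd = psd, pwd = computePwd(psd),
      phd = computePhd(sp, bands, wrap = wrap),
      channels = epochs@channels, bands = bands$name)
}
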