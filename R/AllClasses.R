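#' @import methods
NULL

#' EpochSet: a subject's epoched multi-channel recording
#'
#' Container for one subject's EEG trials. Trials may be ragged (different
#' numbers of time samples) but share the channel montage and sampling rate.
#' Each trial is stored as a channels x samples numeric matrix in
#' \code{channelLabels} order.
#'
#' @slot subject single subject identifier.
#' @slot trials list of numeric matrices, one per trial, each with
#'   \code{length(channels)} rows and at least 2 columns of finite samples.
#' @slot channels character vector of 10/20-system channel labels.
#' @slot rate sampling rate in Hz (positive scalar).
#'
#' @seealso [readEpochs()], [writeEpochs()], [generateEpochs()]
#' @export
setClass("EpochSet",
  representation(subject = "character", trials = "list",
                 channels = "character", rate = "numeric"))

setValidity("EpochSet", function(object) {
  M <- length(object@channels)
  if (length(object@subject) != 1L || !nzchar(object@subject))
    return("subject must be a single non-empty string")
  if (M < 1L || anyDuplicated(object@channels))
    return("channels must be a non-empty set of unique labels")
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    return("rate must be a positive number")
  if (length(object@trials) < 1L)
    return("at least one trial is required")
  for (n in seq_along(object@trials)) {
    tr <- object@trials[[n]]
    if (!is.matrix(tr) || !is.numeric(tr))
      return(sprintf("trial %d is not a numeric matrix", n))
    if (nrow(tr) != M)
      return(sprintf("trial %d has %d rows but %d channels are declared",
                     n, nrow(tr), M))
    if (ncol(tr) < 2L)
      return(sprintf("trial %d has fewer than 2 samples", n))
    if (!all(is.finite(tr)))
      return(sprintf("trial %d contains non-finite samples", n))
  }
  TRUE
})

#' Construct an EpochSet
#'
#' @param subject subject identifier.
#' @param trials list of channels x samples numeric matrices.
#' @param channels channel labels (one per row of each trial).
#' @param rate sampling rate in Hz.
#' @return an [EpochSet-class] object.
#' @examples
#' e <- EpochSet("s1", list(matrix(rnorm(20), 2)), c("Fz", "Cz"), 256)
#' nTrials(e)
#' @export
EpochSet <- function(subject, trials, channels, rate) {
  new("EpochSet", subject = as.character(subject), trials = trials,
      channels = as.character(channels), rate = as.numeric(rate))
}

#' SpectrumSet: per-trial Fourier spectra
#'
#' Full-trial discrete Fourier transforms of an [EpochSet-class]. Each trial
#' keeps its own frequency grid (ragged trials have different grids). The
#' periodogram and phase spectrum are derived through [periodogram()] and
#' [phaseSpectrum()].
#'
#' @slot coefficients list of complex matrices (channels x DFT bins).
#' @slot freqs list of per-trial frequency grids, Hz, bins k = 0 .. T-1
#'   at k * rate / T.
#' @slot channels channel labels.
#' @slot rate sampling rate in Hz.
#' @export
setClass("SpectrumSet",
  representation(coefficients = "list", freqs = "list",
                 channels = "character", rate = "numeric"))

#' FeatureSet: band-averaged spectral features per trial
#'
#' Holds the three feature families for N trials: channel band power
#' (\code{psd}, N x M x F), pairwise band-power differences (\code{pwd},
#' N x M x M x F) and pairwise mean phase differences (\code{phd},
#' N x M x M x F). PWD and PHD are antisymmetric in the two channel modes
#' and zero on the diagonal.
#'
#' @slot psd N x M x F array.
#' @slot pwd N x M x M x F array.
#' @slot phd N x M x M x F array.
#' @slot channels channel labels (length M).
#' @slot bands band names (length F).
#' @export
setClass("FeatureSet",
  representation(psd = "array", pwd = "array", phd = "array",
                 channels = "character", bands = "character"))

#' FeatureMatrix: vectorized trial features
#'
#' N x I matrix of features with I = F * (M * (M - 1) + M): per band, the M
#' PSD values, the M(M-1)/2 PWD values (channel1 > channel2) and the
#' M(M-1)/2 PHD values (channel1 < channel2). \code{indexMap} records, for
#' every column, the feature kind, the channel label(s) and the band.
#'
#' @slot values N x I numeric matrix.
#' @slot indexMap data.frame with columns kind, channel1, channel2, band.
#' @slot channels channel labels.
#' @slot bands band names.
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", indexMap = "data.frame",
                 channels = "character", bands = "character"))

#' FeatureTensor: four-mode trial features
#'
#' N x M x M x F array whose entry (n, m1, m2, f) is the PWD of the channel
#' pair when m1 > m2, the PHD when m1 < m2, and the channel PSD on the
#' diagonal m1 = m2. Modes are trials, channel-1, channel-2, frequency band.
#'
#' @slot values N x M x M x F numeric array.
#' @slot channels channel labels.
#' @slot bands band names.
#' @export
setClass("FeatureTensor",
  representation(values = "array", channels = "character",
                 bands = "character"))

setValidity("FeatureTensor", function(object) {
  d <- dim(object@values)
  if (length(d) != 4L) return("values must be a 4-mode array")
  if (d[2] != d[3]) return("channel modes must have equal length")
  if (d[2] != length(object@channels)) return("channel labels do not match")
  if (d[4] != length(object@bands)) return("band names do not match")
  TRUE
})

#' PLSModel: fitted NIPALS PLS2 regression
#'
#' Two-block partial least squares fit of a feature matrix against a
#' response matrix: X = sum_r t_r p_r' + E, Y = sum_r t_r c_r' + F with
#' unit-norm, mutually orthogonal score vectors t_r.
#'
#' @slot ncomp number of extracted components (R1).
#' @slot weights I x R weight vectors w_r (unit norm).
#' @slot loadings I x R X-loadings p_r.
#' @slot yloadings J x R Y-loadings c_r.
#' @slot scores N x R training score vectors.
#' @slot xcenter,ycenter training column means.
#' @slot xscale column scales (all 1 unless \code{scaleX = TRUE}).
#' @slot residX,residY residual Frobenius norms after each component.
#' @slot indexMap feature descriptors (may have zero rows).
#' @export
setClass("PLSModel",
  representation(ncomp = "integer", weights = "matrix", loadings = "matrix",
                 yloadings = "matrix", scores = "matrix",
                 xcenter = "numeric", ycenter = "numeric", xscale = "numeric",
                 residX = "numeric", residY = "numeric",
                 indexMap = "data.frame"))

#' HOPLSModel: fitted higher-order PLS tensor regression
#'
#' Sequential rank-(1, L1, L2, L3) decomposition of a centered four-mode
#' feature tensor against responses: each component r has a unit-norm score
#' vector t_r, column-orthonormal loading matrices P_r^(1) (M x L1),
#' P_r^(2) (M x L2), P_r^(3) (F x L3), a core tensor G_r (1 x L1 x L2 x L3)
#' and a unit-norm response loading q_r with strength d_r.
#'
#' @slot ncomp achieved number of components (may be below the request if
#'   residuals vanish early).
#' @slot L loading ranks (L1, L2, L3).
#' @slot scoreMethod "covariance" (scores from the cross-covariance core,
#'   the default) or "svd" (dominant left singular vector of the projected
#'   residual tensor).
#' @slot loadings list (per component) of lists with P1, P2, P3.
#' @slot cores list of core tensors G_r (arrays L1 x L2 x L3).
#' @slot weights list of projected weight vectors (covariance method).
#' @slot weightNorms training score normalizers (covariance method).
#' @slot d component strengths d_r.
#' @slot yloadings J x R matrix of unit response loadings q_r.
#' @slot scores N x R training scores.
#' @slot xcenter M x M x F mean tensor; \code{ycenter} response means.
#' @slot residX,residY residual norms after each component.
#' @slot channels,bands mode labels.
#' @export
setClass("HOPLSModel",
  representation(ncomp = "integer", L = "integer", scoreMethod = "character",
                 loadings = "list", cores = "list", weights = "list",
                 weightNorms = "numeric", d = "numeric", yloadings = "matrix",
                 scores = "matrix", xcenter = "array", ycenter = "numeric",
                 residX = "numeric", residY = "numeric",
                 channels = "character", bands = "character"))

#' EvaluationResult: leave-one-out cross-validation summary
#'
#' @slot model "pls", "hopls" or "mean".
#' @slot rmse named per-scale RMSE on the normalized response scale.
#' @slot hyperparams list of hyperparameters (R1, or L1, L2, L3, R2).
#' @slot predictions,actuals N x J fold-wise values on the normalized scale.
#' @slot folds number of folds (equals N).
#' @slot grid full grid-search table (zero rows when not applicable).
#' @export
setClass("EvaluationResult",
  representation(model = "character", rmse = "numeric", hyperparams = "list",
                 predictions = "matrix", actuals = "matrix", folds = "integer",
                 grid = "data.frame"))

#' ContributionReport: coefficient-magnitude feature attribution
#'
#' @slot ranking per-scale data.frames of features ordered by decreasing
#'   coefficient magnitude.
#' @slot kindCounts per-scale counts of PSD/PWD/PHD among the top K.
#' @slot bandCounts per-scale counts of each band among the top K.
#' @slot topPairs per-scale top channel pairs by summed pairwise magnitude.
#' @slot K number of top features summarized.
#' @export
setClass("ContributionReport",
  representation(ranking = "list", kindCounts = "data.frame",
                 bandCounts = "data.frame", topPairs = "list", K = "integer"))

#' TopoSummary: channel-pair contributions with scalp coordinates
#'
#' @slot coordinates data.frame with columns label, x, y.
#' @slot edges data.frame with columns channel1, channel2, magnitude,
#'   x1, y1, x2, y2, ordered by decreasing magnitude.
#' @slot scale the rating scale summarized.
#' @export
setClass("TopoSummary",
  representation(coordinates = "data.frame", edges = "data.frame",
                 scale = "character"))
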