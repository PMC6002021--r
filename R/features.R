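# layout of one band's block in the vectorized feature order:
# PSD by channel, then PWD pairs (m1 > m2, lexicographic), then PHD pairs
# (m1 < m2, lexicographic); blocks are band-major.
bandBlockMap <- function(channels) {
  M <- length(channels)
  pwd <- which(lower.tri(matrix(0, M, M)), arr.ind = TRUE)  # row > col
  pwd <- pwd[order(pwd[, 1], pwd[, 2]), , drop = FALSE]
  phd <- which(upper.tri(matrix(0, M, M)), arr.ind = TRUE)  # row < col
  phd <- phd[order(phd[, 1], phd[, 2]), , drop = FALSE]
  data.frame(
    kind = c(rep("PSD", M), rep("PWD", nrow(pwd)), rep("PHD", nrow(phd))),
    m1 = c(seq_len(M), pwd[, 1], phd[, 1]),
    m2 = c(seq_len(M), pwd[, 2], phd[, 2]),
    stringsAsFactors = FALSE)
}

featureIndexMap <- function(channels, bands) {
  blk <- bandBlockMap(channels)
  im <- do.call(rbind, lapply(bands, function(b) cbind(blk, band = b)))
  data.frame(kind = im$kind,
             channel1 = channels[im$m1],
             channel2 = ifelse(im$kind == "PSD", NA_character_,
                               channels[im$m2]),
             band = im$band,
             m1 = im$m1, m2 = im$m2,
             stringsAsFactors = FALSE)
}

#' Build the vectorized feature matrix
#'
#' Arranges every trial's features as one row of an N x I matrix with
#' I = F * (M * (M - 1) + M): per band, all M PSD values, the M(M-1)/2
#' power differences (channel1 > channel2) and the M(M-1)/2 phase
#' differences (channel1 < channel2), each ordered-pair feature counted
#' once. The column order is band-major and recorded in the index map so
#' that any coefficient can be traced back to its feature.
#'
#' @param features a [FeatureSet-class].
#' @return a [FeatureMatrix-class].
#' @seealso [buildFeatureTensor()], [describeIndex()]
#' @export
buildFeatureMatrix <- function(features) {
  stopifnot(is(features, "FeatureSet"))
  M <- length(features@channels); Fb <- length(features@bands)
  N <- dim(features@psd)[1]
  im <- featureIndexMap(features@channels, features@bands)
  I <- nrow(im)
  stopifnot(I == Fb * (M * (M - 1) + M))
  vals <- matrix(0, N, I)
  for (i in seq_len(I)) {
    vals[, i] <- switch(im$kind[i],
      PSD = features@psd[, im$m1[i], match(im$band[i], features@bands)],
      PWD = features@pwd[, im$m1[i], im$m2[i],
                         match(im$band[i], features@bands)],
      PHD = features@phd[, im$m1[i], im$m2[i],
                         match(im$band[i], features@bands)])
  }
  new("FeatureMatrix", values = vals,
      indexMap = im[, c("kind", "channel1", "channel2", "band")],
      channels = features@channels, bands = features@bands)
}

#' Build the four-mode feature tensor
#'
#' Organizes the features as an N x M x M x F array: the entry at
#' (n, m1, m2, f) is PWD(m1, m2, f) when m1 > m2, PHD(m1, m2, f) when
#' m1 < m2, and PSD(m1, f) on the diagonal. The off-diagonal slices keep
#' the antisymmetry of their source features.
#'
#' @param features a [FeatureSet-class].
#' @return a [FeatureTensor-class].
#' @export
buildFeatureTensor <- function(features) {
  stopifnot(is(features, "FeatureSet"))
  M <- length(features@channels); Fb <- length(features@bands)
  N <- dim(features@psd)[1]
  vals <- features@pwd
  lower <- lower.tri(matrix(0, M, M))   # m1 > m2: PWD (already in place)
  upper <- upper.tri(matrix(0, M, M))   # m1 < m2: PHD
  for (f in seq_len(Fb)) {
    for (n in seq_len(N)) {
      sl <- vals[n, , , f]
      sl[upper] <- features@phd[n, , , f][upper]
      diag(sl) <- features@psd[n, , f]
      vals[n, , , f] <- sl
    }
  }
  dimnames(vals) <- list(NULL, features@channels, features@channels,
                         features@bands)
  new("FeatureTensor", values = vals, channels = features@channels,
      bands = features@bands)
}

#' Describe a feature index
#'
#' Maps a position in the vectorized layout (a column index of a
#' [FeatureMatrix-class]) or in the tensor layout (a 1-based
#' \code{c(m1, m2, f)} triple of a [FeatureTensor-class]) to its feature
#' descriptor: kind, channel label(s), band name. The inverse of
#' [featureIndex()].
#'
#' @param x a FeatureMatrix or FeatureTensor.
#' @param i column index (matrix) or integer triple \code{c(m1, m2, f)}
#'   (tensor).
#' @return data.frame row with kind, channel1, channel2, band.
#' @export
describeIndex <- function(x, i) {
  if (is(x, "FeatureMatrix")) {
    if (length(i) != 1L || i < 1L || i > ncol(x@values))
      stop("index error: column index out of range")
    return(x@indexMap[i, , drop = FALSE])
  }
  if (!is(x, "FeatureTensor")) stop("x must be a FeatureMatrix or ",
                                    "FeatureTensor")
  M <- length(x@channels); Fb <- length(x@bands)
  if (length(i) != 3L || any(i < 1L) || i[1] > M || i[2] > M || i[3] > Fb)
    stop("index error: tensor index out of range")
  kind <- if (i[1] > i[2]) "PWD" else if (i[1] < i[2]) "PHD" else "PSD"
  data.frame(kind = kind, channel1 = x@channels[i[1]],
             channel2 = if (kind == "PSD") NA_character_ else
               x@channels[i[2]],
             band = x@bands[i[3]], stringsAsFactors = FALSE)
}

#' Locate a feature descriptor in the vectorized layout
#'
#' @param x a [FeatureMatrix-class].
#' @param kind "PSD", "PWD" or "PHD".
#' @param channel1,channel2 channel labels (\code{channel2} ignored for
#'   PSD).
#' @param band band name.
#' @return the 1-based column index.
#' @export
featureIndex <- function(x, kind, channel1, channel2 = NA, band) {
  stopifnot(is(x, "FeatureMatrix"))
  im <- x@indexMap
  hit <- which(im$kind == kind & im$channel1 == channel1 & im$band == band &
                 (kind == "PSD" | im$channel2 == channel2))
  if (length(hit) != 1L)
    stop("index error: descriptor not found in the feature layout")
  hit
}
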