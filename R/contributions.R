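#' Coefficient-magnitude feature attribution
#'
#' Ranks features by the magnitude of their regression coefficients, per
#' rating scale, and summarizes the top K: counts by feature kind
#' (PSD/PWD/PHD), counts by frequency band, and the channel pairs with the
#' largest summed pairwise magnitude (over both orientations, both pairwise
#' kinds and all bands). Ties are broken deterministically by feature
#' layout order.
#'
#' @param object a fitted [PLSModel-class] (fitted on a
#'   [FeatureMatrix-class], so the index map is available) or
#'   [HOPLSModel-class] (fitted on a [FeatureTensor-class]).
#' @param K number of top features to summarize (default 100); clipped with
#'   a warning when larger than the feature count.
#' @param nPairs number of top channel pairs to report (default 10).
#' @param ... unused.
#' @return a [ContributionReport-class].
#' @export
setGeneric("contributions",
           function(object, K = 100, nPairs = 10, ...)
             standardGeneric("contributions"))

contributionsCore <- function(desc, B, K, nPairs) {
  scales <- colnames(B)
  if (is.null(scales)) scales <- paste0("Y", seq_len(ncol(B)))
  nfeat <- nrow(B)
  if (K > nfeat) {
    warning("K = ", K, " exceeds the feature count ", nfeat, "; clipped")
    K <- nfeat
  }
  K <- as.integer(K)
  ranking <- list(); topPairs <- list()
  kindLevels <- c("PSD", "PWD", "PHD")
  bandLevels <- unique(desc$band)
  kc <- matrix(0L, length(scales), 3,
               dimnames = list(scales, kindLevels))
  bc <- matrix(0L, length(scales), length(bandLevels),
               dimnames = list(scales, bandLevels))
  pairkey <- ifelse(desc$kind == "PSD", NA,
                    paste(pmin(desc$channel1, desc$channel2),
                          pmax(desc$channel1, desc$channel2), sep = "|"))
  for (s in seq_along(scales)) {
    mag <- abs(B[, s])
    o <- order(-mag, seq_len(nfeat))
    top <- o[seq_len(K)]
    ranking[[scales[s]]] <- data.frame(
      rank = seq_len(K), desc[top, , drop = FALSE],
      coefficient = B[top, s], magnitude = mag[top],
      row.names = NULL)
    kc[s, ] <- as.integer(table(factor(desc$kind[top],
                                       levels = kindLevels)))
    bc[s, ] <- as.integer(table(factor(desc$band[top],
                                       levels = bandLevels)))
    pw <- !is.na(pairkey)
    agg <- tapply(mag[pw], pairkey[pw], sum)
    agg <- sort(agg, decreasing = TRUE)
    np <- min(nPairs, length(agg))
    keys <- strsplit(names(agg)[seq_len(np)], "|", fixed = TRUE)
    topPairs[[scales[s]]] <- data.frame(
      channel1 = vapply(keys, `[`, "", 1),
      channel2 = vapply(keys, `[`, "", 2),
      magnitude = as.numeric(agg[seq_len(np)]), row.names = NULL)
  }
  new("ContributionReport", ranking = ranking,
      kindCounts = data.frame(scale = scales, kc, row.names = NULL),
      bandCounts = data.frame(scale = scales, bc, row.names = NULL),
      topPairs = topPairs, K = K)
}

#' @rdname contributions
#' @export
setMethod("contributions", "PLSModel", function(object, K = 100,
                                                nPairs = 10, ...) {
  if (!nrow(object@indexMap))
    stop("model was not fitted on a FeatureMatrix; no index map available")
  B <- coef(object)
  colnames(B) <- names(object@ycenter)
  contributionsCore(object@indexMap, B, K, nPairs)
})

#' @rdname contributions
#' @export
setMethod("contributions", "HOPLSModel", function(object, K = 100,
                                                  nPairs = 10, ...) {
  if (!length(object@channels))
    stop("model was not fitted on a FeatureTensor; no mode labels available")
  W <- coef(object)
  dm <- dim(W)
  M <- dm[1]; Fb <- dm[3]; J <- dm[4]
  idx <- expand.grid(m1 = seq_len(M), m2 = seq_len(M), f = seq_len(Fb))
  kind <- ifelse(idx$m1 > idx$m2, "PWD",
                 ifelse(idx$m1 < idx$m2, "PHD", "PSD"))
  desc <- data.frame(
    kind = kind,
    channel1 = object@channels[idx$m1],
    channel2 = ifelse(kind == "PSD", NA_character_,
                      object@channels[idx$m2]),
    band = object@bands[idx$f], stringsAsFactors = FALSE)
  B <- matrix(W, nrow = M * M * Fb, ncol = J)
  colnames(B) <- names(object@ycenter)
  contributionsCore(desc, B, K, nPairs)
})

#' Summaries of a contribution report
#'
#' Recomputes, from the ranked feature lists alone, the per-scale counts of
#' each feature kind and of each frequency band among the top K. A pure
#' function of the report.
#'
#' @param report a [ContributionReport-class].
#' @return list with data.frames \code{kindCounts} and \code{bandCounts}.
#' @export
summarizeTopK <- function(report) {
  stopifnot(is(report, "ContributionReport"))
  scales <- names(report@ranking)
  kindLevels <- c("PSD", "PWD", "PHD")
  bandLevels <- setdiff(names(report@bandCounts), "scale")
  kc <- t(vapply(scales, function(s)
    as.integer(table(factor(report@ranking[[s]]$kind,
                            levels = kindLevels))),
    integer(3)))
  bc <- t(vapply(scales, function(s)
    as.integer(table(factor(report@ranking[[s]]$band,
                            levels = bandLevels))),
    integer(length(bandLevels))))
  colnames(kc) <- kindLevels; colnames(bc) <- bandLevels
  list(kindCounts = data.frame(scale = scales, kc, row.names = NULL),
       bandCounts = data.frame(scale = scales, bc, row.names = NULL))
}

#' Write a contribution report as CSV files
#'
#' Emits \code{ranking_<scale>.csv}, \code{top_pairs_<scale>.csv},
#' \code{kind_counts.csv} and \code{band_counts.csv} under \code{dir}.
#'
#' @param report a [ContributionReport-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeContributionReport <- function(report, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("I/O error: cannot create directory ", dir)
  for (s in names(report@ranking)) {
    utils::write.csv(report@ranking[[s]],
                     file.path(dir, sprintf("ranking_%s.csv", s)),
                     row.names = FALSE)
    utils::write.csv(report@topPairs[[s]],
                     file.path(dir, sprintf("top_pairs_%s.csv", s)),
                     row.names = FALSE)
  }
  utils::write.csv(report@kindCounts, file.path(dir, "kind_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(report@bandCounts, file.path(dir, "band_counts.csv"),
                   row.names = FALSE)
  invisible(dir)
}
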