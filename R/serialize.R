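# matrices/arrays are stored flat with explicit dimensions so the JSON
# reader never has to guess shapes; 17 significant digits round-trip
# doubles exactly
packArr <- function(a) list(d = dim(a), v = as.vector(a))
unpackArr <- function(p) array(as.numeric(unlist(p$v)),
                               dim = as.integer(unlist(p$d)))
unpackMat <- function(p) {
  m <- unpackArr(p); dim(m) <- dim(m)[1:2]; m
}
writeJsonExact <- function(obj, path)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
readJsonRaw <- function(path)
  jsonlite::fromJSON(path, simplifyVector = TRUE,
                     simplifyDataFrame = FALSE, simplifyMatrix = FALSE)

packIndexMap <- function(im) {
  lapply(as.list(im), function(col) {
    col <- as.character(col); col[is.na(col)] <- ""; col
  })
}
unpackIndexMap <- function(p) {
  if (is.null(p) || !length(p$kind))
    return(data.frame(kind = character(), channel1 = character(),
                      channel2 = character(), band = character()))
  df <- data.frame(kind = unlist(p$kind), channel1 = unlist(p$channel1),
                   channel2 = unlist(p$channel2), band = unlist(p$band),
                   stringsAsFactors = FALSE)
  df$channel2[df$channel2 == ""] <- NA_character_
  df
}

#' Save and load fitted models
#'
#' Serializes a [PLSModel-class] or [HOPLSModel-class] to a single JSON
#' file at full double precision (17 significant digits, which restores
#' every value bit-exactly), recording the model kind, the score rule and
#' the deflation convention. Identical fits produce bit-identical files.
#'
#' @param model a fitted model.
#' @param path output file.
#' @return \code{saveModel}: the path, invisibly; \code{loadModel}: the
#'   model.
#' @export
saveModel <- function(model, path) {
  if (is(model, "PLSModel")) {
    obj <- list(kind = "pls", deflation = "X and Y", ncomp = model@ncomp,
                weights = packArr(model@weights),
                loadings = packArr(model@loadings),
                yloadings = packArr(model@yloadings),
                scores = packArr(model@scores),
                xcenter = model@xcenter,
                ycenter = as.list(model@ycenter),
                xscale = model@xscale, residX = model@residX,
                residY = model@residY,
                indexMap = packIndexMap(model@indexMap))
  } else if (is(model, "HOPLSModel")) {
    obj <- list(kind = "hopls", ncomp = model@ncomp, L = model@L,
                scoreMethod = model@scoreMethod,
                components = lapply(seq_len(model@ncomp), function(r) list(
                  P1 = packArr(model@loadings[[r]][[1]]),
                  P2 = packArr(model@loadings[[r]][[2]]),
                  P3 = packArr(model@loadings[[r]][[3]]),
                  core = as.vector(model@cores[[r]]),
                  weight = model@weights[[r]])),
                weightNorms = model@weightNorms, d = model@d,
                yloadings = packArr(model@yloadings),
                scores = packArr(model@scores),
                xcenter = packArr(model@xcenter),
                ycenter = as.list(model@ycenter),
                residX = model@residX, residY = model@residY,
                channels = model@channels, bands = model@bands)
  } else stop("unsupported model class: ", class(model))
  writeJsonExact(obj, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  o <- readJsonRaw(path)
  ycen <- stats::setNames(as.numeric(unlist(o$ycenter)), names(o$ycenter))
  if (o$kind == "pls") {
    new("PLSModel", ncomp = as.integer(o$ncomp),
        weights = unpackMat(o$weights), loadings = unpackMat(o$loadings),
        yloadings = unpackMat(o$yloadings), scores = unpackMat(o$scores),
        xcenter = as.numeric(unlist(o$xcenter)), ycenter = ycen,
        xscale = as.numeric(unlist(o$xscale)),
        residX = as.numeric(unlist(o$residX)),
        residY = as.numeric(unlist(o$residY)),
        indexMap = unpackIndexMap(o$indexMap))
  } else if (o$kind == "hopls") {
    R <- as.integer(o$ncomp)
    L <- as.integer(unlist(o$L))
    new("HOPLSModel", ncomp = R, L = L, scoreMethod = o$scoreMethod,
        loadings = lapply(o$components, function(cp)
          list(unpackMat(cp$P1), unpackMat(cp$P2), unpackMat(cp$P3))),
        cores = lapply(o$components, function(cp)
          array(as.numeric(unlist(cp$core)), dim = L)),
        weights = lapply(o$components, function(cp)
          as.numeric(unlist(cp$weight))),
        weightNorms = as.numeric(unlist(o$weightNorms)),
        d = as.numeric(unlist(o$d)), yloadings = unpackMat(o$yloadings),
        scores = unpackMat(o$scores), xcenter = unpackArr(o$xcenter),
        ycenter = ycen, residX = as.numeric(unlist(o$residX)),
        residY = as.numeric(unlist(o$residY)),
        channels = as.character(unlist(o$channels)),
        bands = as.character(unlist(o$bands)))
  } else stop("unknown model kind in ", path)
}

#' Save and load a feature tensor or matrix
#'
#' Single-file binary container (little-endian float64 with an integer
#' shape header) plus a JSON sidecar (\code{<path>.json}) holding the
#' channel labels, band names and — for matrices — the feature index map.
#'
#' @param x a [FeatureTensor-class] or [FeatureMatrix-class].
#' @param path output file (binary); the sidecar is written next to it.
#' @return \code{writeFeatureArray}: the path, invisibly;
#'   \code{readFeatureArray}: the restored object.
#' @export
writeFeatureArray <- function(x, path) {
  vals <- featureValues(x)
  d <- dim(vals)
  con <- file(path, "wb")
  writeBin(as.integer(c(length(d), d)), con, size = 4, endian = "little")
  writeBin(as.vector(vals), con, size = 8, endian = "little")
  close(con)
  side <- list(class = class(x)[1], channels = x@channels,
               bands = x@bands)
  if (is(x, "FeatureMatrix")) side$indexMap <- packIndexMap(x@indexMap)
  writeJsonExact(side, paste0(path, ".json"))
  invisible(path)
}

#' @rdname writeFeatureArray
#' @export
readFeatureArray <- function(path) {
  con <- file(path, "rb")
  nd <- readBin(con, "integer", 1, size = 4, endian = "little")
  d <- readBin(con, "integer", nd, size = 4, endian = "little")
  vals <- readBin(con, "double", prod(d), size = 8, endian = "little")
  close(con)
  side <- readJsonRaw(paste0(path, ".json"))
  channels <- as.character(unlist(side$channels))
  bands <- as.character(unlist(side$bands))
  if (side$class == "FeatureMatrix")
    new("FeatureMatrix", values = matrix(vals, d[1], d[2]),
        indexMap = unpackIndexMap(side$indexMap),
        channels = channels, bands = bands)
  else
    new("FeatureTensor", values = array(vals, dim = d),
        channels = channels, bands = bands)
}
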