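#' @rdname EpochSet-class
#' @param x,object an object.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname EpochSet-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname EpochSet-class
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname EpochSet-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname EpochSet-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname EpochSet-class
#' @param i trial index.
#' @export
setGeneric("trialData", function(x, i) standardGeneric("trialData"))

#' @rdname EpochSet-class
#' @export
setMethod("nTrials", "EpochSet", function(x) length(x@trials))
#' @rdname EpochSet-class
#' @export
setMethod("nChannels", "EpochSet", function(x) length(x@channels))
#' @rdname EpochSet-class
#' @export
setMethod("channelLabels", "EpochSet", function(x) x@channels)
#' @rdname EpochSet-class
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@rate)
#' @rdname EpochSet-class
#' @export
setMethod("subjectId", "EpochSet", function(x) x@subject)
#' @rdname EpochSet-class
#' @export
setMethod("trialData", "EpochSet", function(x, i) x@trials[[i]])

#' @rdname SpectrumSet-class
#' @export
setMethod("nTrials", "SpectrumSet", function(x) length(x@coefficients))
#' @rdname SpectrumSet-class
#' @export
setMethod("channelLabels", "SpectrumSet", function(x) x@channels)

#' @rdname FeatureTensor-class
#' @export
setMethod("nTrials", "FeatureTensor", function(x) dim(x@values)[1])
#' @rdname FeatureTensor-class
#' @export
setMethod("channelLabels", "FeatureTensor", function(x) x@channels)
#' @rdname FeatureMatrix-class
#' @export
setMethod("nTrials", "FeatureMatrix", function(x) nrow(x@values))
#' @rdname FeatureMatrix-class
#' @export
setMethod("channelLabels", "FeatureMatrix", function(x) x@channels)

#' Extract feature values and index map
#'
#' \code{featureValues} returns the numeric matrix or array inside a
#' [FeatureMatrix-class] or [FeatureTensor-class]; \code{indexMap} returns
#' the per-column feature descriptors of a [FeatureMatrix-class].
#'
#' @param x a FeatureMatrix or FeatureTensor.
#' @return numeric matrix/array, or a data.frame for \code{indexMap}.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
#' @rdname featureValues
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)
#' @rdname featureValues
#' @export
setMethod("featureValues", "FeatureTensor", function(x) x@values)
#' @rdname featureValues
#' @export
setGeneric("indexMap", function(x) standardGeneric("indexMap"))
#' @rdname featureValues
#' @export
setMethod("indexMap", "FeatureMatrix", function(x) x@indexMap)
#' @rdname featureValues
#' @export
setMethod("indexMap", "PLSModel", function(x) x@indexMap)

setMethod("show", "EpochSet", function(object) {
  Ts <- vapply(object@trials, ncol, 1L)
  cat(sprintf("EpochSet: subject %s, %d trials, %d channels @ %g Hz\n",
              object@subject, length(object@trials),
              length(object@channels), object@rate))
  cat(sprintf("  samples per trial: %d-%d\n", min(Ts), max(Ts)))
})

setMethod("show", "SpectrumSet", function(object) {
  cat(sprintf("SpectrumSet: %d trials, %d channels @ %g Hz\n",
              length(object@coefficients), length(object@channels),
              object@rate))
})

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet: %d trials, %d channels, bands %s\n",
              dim(object@psd)[1], length(object@channels),
              paste(object@bands, collapse = ", ")))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d trials x %d features (%d channels, %d bands)\n",
              nrow(object@values), ncol(object@values),
              length(object@channels), length(object@bands)))
})

setMethod("show", "FeatureTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("FeatureTensor: %d x %d x %d x %d (trials x ch x ch x bands)\n",
              d[1], d[2], d[3], d[4]))
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d component(s), %d features, %d responses\n",
              object@ncomp, length(object@xcenter), length(object@ycenter)))
})

setMethod("show", "HOPLSModel", function(object) {
  cat(sprintf(
    "HOPLSModel: %d component(s), L = (%s), scores = %s, %d responses\n",
    object@ncomp, paste(object@L, collapse = ", "), object@scoreMethod,
    length(object@ycenter)))
})

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf("EvaluationResult (%s): %d folds\n", object@model, object@folds))
  cat("  RMSE:", paste(sprintf("%s = %.4f", names(object@rmse), object@rmse),
                       collapse = ", "), "\n")
  hp <- object@hyperparams
  if (length(hp))
    cat("  hyperparameters:",
        paste(sprintf("%s = %s", names(hp), unlist(hp)), collapse = ", "), "\n")
})

setMethod("show", "ContributionReport", function(object) {
  cat(sprintf("ContributionReport: top %d features for %s\n", object@K,
              paste(names(object@ranking), collapse = ", ")))
})
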