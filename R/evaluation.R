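#' Normalize response columns to zero mean and unit variance
#'
#' Column-wise (y - mean) / sd with the sample standard deviation (divisor
#' N - 1). The parameters are returned for the inverse transform.
#'
#' @param y numeric matrix or data.frame (N x J) of responses.
#' @return list with \code{values} (normalized matrix), \code{center} and
#'   \code{scale} (per-column parameters).
#' @export
normalizeResponses <- function(y) {
  Y <- as.matrix(y)
  ctr <- colMeans(Y)
  scl <- apply(Y, 2, stats::sd)
  if (any(scl == 0 | !is.finite(scl)))
    stop("degenerate-response error: constant response column '",
         colnames(Y)[which(scl == 0 | !is.finite(scl))[1]], "'")
  list(values = scale(Y, center = ctr, scale = scl)[, , drop = FALSE],
       center = ctr, scale = scl)
}

#' Root mean squared error
#'
#' @param predicted,actual numeric vectors of equal length.
#' @return sqrt of the mean squared difference.
#' @export
rmse <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("shape error: predicted and actual differ in length")
  if (!length(predicted)) stop("shape error: empty input")
  sqrt(mean((predicted - actual)^2))
}

ratingsMatrix <- function(y) {
  if (is.data.frame(y)) {
    cols <- intersect(c("MOS", "VAL", "ARL"), names(y))
    y <- as.matrix(y[, cols, drop = FALSE])
  }
  y <- as.matrix(y)
  if (is.null(colnames(y))) colnames(y) <- paste0("Y", seq_len(ncol(y)))
  y
}

fitAny <- function(x, Ytr, model, maxComp, L, scores, maxit, tol) {
  if (model == "pls") fitPls(x, Ytr, ncomp = maxComp)
  else fitHopls(x, Ytr, ncomp = maxComp, L = L, scores = scores,
                maxit = maxit, tol = tol)
}

subsetRows <- function(x, idx) {
  if (is(x, "FeatureMatrix"))
    new("FeatureMatrix", values = x@values[idx, , drop = FALSE],
        indexMap = x@indexMap, channels = x@channels, bands = x@bands)
  else if (is(x, "FeatureTensor"))
    new("FeatureTensor", values = x@values[idx, , , , drop = FALSE],
        channels = x@channels, bands = x@bands)
  else if (length(dim(x)) == 4L) x[idx, , , , drop = FALSE]
  else x[idx, , drop = FALSE]
}

# leave-one-out predictions for component counts 1..maxComp (and the
# 0-component mean model in slice 1 when includeZero)
loocvPath <- function(x, y, model, maxComp, L = NULL,
                      scores = "covariance", globalNormalize = FALSE,
                      maxit = 100, tol = 1e-9) {
  Y <- ratingsMatrix(y)
  N <- nrow(Y); J <- ncol(Y)
  if (N < 3L) stop("parameter error: leave-one-out needs at least 3 trials")
  if (model == "pls" && maxComp > N - 2L)
    stop("parameter error: R1 = ", maxComp,
         " infeasible for fold size ", N - 1L, " (max ", N - 2L, ")")
  nrm_all <- if (globalNormalize) normalizeResponses(Y) else NULL
  preds <- array(NA_real_, dim = c(N, J, maxComp + 1L),
                 dimnames = list(NULL, colnames(Y), NULL))
  acts <- matrix(NA_real_, N, J, dimnames = list(NULL, colnames(Y)))
  for (i in seq_len(N)) {
    tr <- setdiff(seq_len(N), i)
    nrm <- if (globalNormalize) nrm_all else
      normalizeResponses(Y[tr, , drop = FALSE])
    Ytr <- scale(Y[tr, , drop = FALSE], nrm$center, nrm$scale)
    acts[i, ] <- (Y[i, ] - nrm$center) / nrm$scale
    preds[i, , 1L] <- colMeans(Ytr)     # 0-component mean predictor
    if (maxComp > 0L) {
      fit <- fitAny(subsetRows(x, tr), Ytr, model, maxComp, L, scores,
                    maxit, tol)
      xte <- subsetRows(x, i)
      for (k in seq_len(maxComp))
        preds[i, , k + 1L] <- predict(fit, xte, ncomp = k)
    }
  }
  list(preds = preds, actuals = acts)
}

pathRmse <- function(path, k) {
  p <- path$preds[, , k + 1L, drop = FALSE]
  vapply(seq_len(ncol(path$actuals)),
         function(j) rmse(p[, j, 1], path$actuals[, j]), numeric(1)) |>
    stats::setNames(colnames(path$actuals))
}

#' Per-subject leave-one-out cross-validation
#'
#' Runs N folds, one per trial. Within each fold the response normalization
#' parameters are estimated on the N - 1 training trials only, the model is
#' fitted on those trials, and the held-out trial is predicted; RMSE per
#' rating scale is computed over all folds on the normalized scale.
#' \code{globalNormalize = TRUE} instead normalizes once on all trials
#' before splitting (the literal pre-split protocol, which leaks the
#' held-out trial's mean and variance).
#'
#' @param x a [FeatureMatrix-class] (for \code{model = "pls"}) or
#'   [FeatureTensor-class] (for \code{model = "hopls"}).
#' @param y ratings: data.frame with MOS/VAL/ARL columns or numeric matrix.
#' @param model "pls", "hopls", or "mean" (0-component baseline predicting
#'   the training mean).
#' @param R1 PLS component count; must satisfy \code{R1 <= N - 2}.
#' @param R2,L HOPLS component count and loading ranks (L1, L2, L3).
#' @param scores HOPLS score rule (see [fitHopls()]).
#' @param globalNormalize normalize responses before splitting.
#' @param maxit,tol HOPLS alternation control, forwarded to [fitHopls()].
#' @return an [EvaluationResult-class] with \code{folds == N}.
#' @export
loocv <- function(x, y, model = c("pls", "hopls", "mean"), R1 = NULL,
                  R2 = NULL, L = NULL, scores = "covariance",
                  globalNormalize = FALSE, maxit = 100, tol = 1e-9) {
  model <- match.arg(model)
  k <- switch(model, pls = R1, hopls = R2, mean = 0L)
  if (is.null(k)) stop("parameter error: supply R1 (pls) or R2 (hopls)")
  fitmodel <- if (model == "mean") "pls" else model
  path <- loocvPath(x, y, fitmodel, maxComp = as.integer(k), L = L,
                    scores = scores, globalNormalize = globalNormalize,
                    maxit = maxit, tol = tol)
  hp <- switch(model, pls = list(R1 = R1), mean = list(),
               hopls = list(L1 = L[1], L2 = L[2], L3 = L[3], R2 = R2))
  new("EvaluationResult", model = model, rmse = pathRmse(path, k),
      hyperparams = hp,
      predictions = path$preds[, , as.integer(k) + 1L],
      actuals = path$actuals, folds = nrow(path$actuals),
      grid = data.frame())
}

#' Default hyperparameter grids
#'
#' The full search ranges: R1 from 1 to 43 for PLS; L1 and L2 from 1 to 7,
#' L3 and R2 from 1 to 5 for HOPLS (1225 combinations).
#'
#' @param model "pls" or "hopls".
#' @return data.frame of grid points.
#' @export
defaultGrid <- function(model = c("pls", "hopls")) {
  model <- match.arg(model)
  if (model == "pls") data.frame(R1 = 1:43)
  else expand.grid(L1 = 1:7, L2 = 1:7, L3 = 1:5, R2 = 1:5)
}

#' Hyperparameter grid search under leave-one-out cross-validation
#'
#' Runs [loocv()] at every grid point and returns the point minimizing the
#' mean RMSE across the rating scales, together with the full grid table.
#' Ties are broken toward the smallest model: fewest components, then the
#' smallest sum of loading ranks, then grid order. Component counts nest, so
#' each distinct loading-rank combination is fitted once per fold at the
#' maximal component count.
#'
#' @param x feature matrix or tensor (see [loocv()]).
#' @param y ratings.
#' @param model "pls" or "hopls".
#' @param grid data.frame of hyperparameters (default [defaultGrid()]):
#'   column R1 for PLS; columns L1, L2, L3, R2 for HOPLS.
#' @param scores,globalNormalize passed to [loocv()].
#' @param maxit,tol HOPLS alternation control, forwarded to [fitHopls()].
#' @return an [EvaluationResult-class] for the best point; its \code{grid}
#'   slot holds per-point RMSEs per scale and their mean.
#' @export
gridSearch <- function(x, y, model = c("pls", "hopls"),
                       grid = defaultGrid(model), scores = "covariance",
                       globalNormalize = FALSE, maxit = 100, tol = 1e-9) {
  model <- match.arg(model)
  if (!nrow(grid)) stop("parameter error: empty hyperparameter grid")
  Y <- ratingsMatrix(y)
  scales <- colnames(Y)
  res <- grid
  for (s in scales) res[[s]] <- NA_real_
  best <- NULL
  if (model == "pls") {
    path <- loocvPath(x, y, "pls", maxComp = max(grid$R1),
                      globalNormalize = globalNormalize)
    for (g in seq_len(nrow(grid)))
      res[g, scales] <- as.list(pathRmse(path, grid$R1[g]))
    paths <- list(path)
    res$.path <- 1L
  } else {
    combos <- unique(grid[, c("L1", "L2", "L3")])
    paths <- vector("list", nrow(combos))
    res$.path <- NA_integer_
    for (ci in seq_len(nrow(combos))) {
      sel <- grid$L1 == combos$L1[ci] & grid$L2 == combos$L2[ci] &
        grid$L3 == combos$L3[ci]
      paths[[ci]] <- loocvPath(x, y, "hopls", maxComp = max(grid$R2[sel]),
                               L = as.integer(combos[ci, ]), scores = scores,
                               globalNormalize = globalNormalize,
                               maxit = maxit, tol = tol)
      for (g in which(sel))
        res[g, scales] <- as.list(pathRmse(paths[[ci]], grid$R2[g]))
      res$.path[sel] <- ci
    }
  }
  res$mean_rmse <- rowMeans(res[, scales, drop = FALSE])
  ncompcol <- if (model == "pls") res$R1 else res$R2
  sumL <- if (model == "pls") rep(0L, nrow(res)) else
    res$L1 + res$L2 + res$L3
  o <- order(res$mean_rmse, ncompcol, sumL, seq_len(nrow(res)))[1]
  k <- ncompcol[o]
  path <- paths[[res$.path[o]]]
  hp <- if (model == "pls") list(R1 = k) else
    list(L1 = res$L1[o], L2 = res$L2[o], L3 = res$L3[o], R2 = k)
  res$.path <- NULL
  new("EvaluationResult", model = model, rmse = pathRmse(path, k),
      hyperparams = hp, predictions = path$preds[, , k + 1L],
      actuals = path$actuals, folds = nrow(path$actuals), grid = res)
}

#' Combine vector- and tensor-model results into one summary row
#'
#' Reproduces the per-subject result schema: RMSE of the vectorized model
#' and of the tensor model per rating scale, plus the selected
#' hyperparameters R1 and L1, L2, L3, R2.
#'
#' @param vectorResult [EvaluationResult-class] from a PLS evaluation.
#' @param tensorResult [EvaluationResult-class] from a HOPLS evaluation.
#' @param subject subject identifier for the row.
#' @return one-row data.frame with columns subject, MOS_vector, VAL_vector,
#'   ARL_vector, MOS_tensor, VAL_tensor, ARL_tensor, R1, L1, L2, L3, R2.
#' @export
evaluationTable <- function(vectorResult, tensorResult, subject = "s1") {
  v <- vectorResult@rmse; h <- tensorResult@rmse
  data.frame(subject = subject,
             MOS_vector = v[["MOS"]], VAL_vector = v[["VAL"]],
             ARL_vector = v[["ARL"]],
             MOS_tensor = h[["MOS"]], VAL_tensor = h[["VAL"]],
             ARL_tensor = h[["ARL"]],
             R1 = vectorResult@hyperparams$R1,
             L1 = tensorResult@hyperparams$L1,
             L2 = tensorResult@hyperparams$L2,
             L3 = tensorResult@hyperparams$L3,
             R2 = tensorResult@hyperparams$R2)
}
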