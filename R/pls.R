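#' Fit a NIPALS PLS2 regression
#'
#' Two-block partial least squares: extracts \code{ncomp} latent components
#' maximizing successive covariance between X-scores and the responses, with
#' X- and Y-deflation per component (classical PLS2). Columns of X are
#' mean-centered but, by default, not variance-scaled — only the responses
#' are normalized upstream (see [normalizeResponses()]). Scores are
#' unit-normalized; the sign of each weight vector is fixed by making its
#' first nonzero element positive.
#'
#' @param x a [FeatureMatrix-class] or numeric matrix (N x I).
#' @param y response matrix (N x J), typically normalized.
#' @param ncomp number of components R1; \code{0 <= ncomp <= min(N-1, I)}.
#'   \code{ncomp = 0} yields the training-mean predictor.
#' @param scaleX also scale X columns to unit variance (default FALSE).
#' @param tol,maxit NIPALS inner-loop convergence control: iterate until the
#'   score vector changes by less than \code{tol} (relative), at most
#'   \code{maxit} times.
#' @return a [PLSModel-class].
#' @seealso [predict,PLSModel-method], [coef,PLSModel-method]
#' @export
fitPls <- function(x, y, ncomp, scaleX = FALSE, tol = 1e-10, maxit = 500) {
  im <- if (is(x, "FeatureMatrix")) x@indexMap else
    data.frame(kind = character(), channel1 = character(),
               channel2 = character(), band = character())
  X <- if (is(x, "FeatureMatrix")) x@values else as.matrix(x)
  Y <- as.matrix(y)
  N <- nrow(X); I <- ncol(X); J <- ncol(Y)
  stopifnot(nrow(Y) == N)
  ncomp <- as.integer(ncomp)
  if (ncomp < 0L || ncomp > min(N - 1L, I))
    stop("parameter error: ncomp must lie in 0 .. min(N-1, I) = ",
         min(N - 1L, I))
  xm <- colMeans(X); ym <- colMeans(Y)
  E <- sweep(X, 2, xm)
  xs <- rep(1, I)
  if (scaleX) {
    xs <- apply(E, 2, stats::sd)
    xs[xs == 0] <- 1
    E <- sweep(E, 2, xs, "/")
  }
  if (ncomp > 0L && all(abs(E) < 1e-300))
    stop("degenerate-input error: X has zero variance after centering")
  Fm <- sweep(Y, 2, ym)
  W <- matrix(0, I, ncomp); P <- matrix(0, I, ncomp)
  C <- matrix(0, J, ncomp); Tm <- matrix(0, N, ncomp)
  rX <- numeric(ncomp); rY <- numeric(ncomp)
  r <- 0L
  while (r < ncomp) {
    u <- Fm[, which.max(colSums(Fm^2))]
    if (sum(u^2) < 1e-24 || sum(E^2) < 1e-24) {
      warning("residual vanished after ", r, " component(s); stopping early")
      break
    }
    t_old <- rep(0, N)
    for (it in seq_len(maxit)) {
      w <- drop(crossprod(E, u))
      wn <- sqrt(sum(w^2))
      if (wn < 1e-150) break
      w <- w / wn
      tt <- drop(E %*% w)
      q <- drop(crossprod(Fm, tt))
      q <- q / sqrt(sum(q^2))
      u <- drop(Fm %*% q)
      if (sqrt(sum((tt - t_old)^2)) <= tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    i0 <- which(abs(w) > 0)[1]
    if (!is.na(i0) && w[i0] < 0) { w <- -w; tt <- -tt }
    tn <- tt / sqrt(sum(tt^2))
    p <- drop(crossprod(E, tn))
    cc <- drop(crossprod(Fm, tn))
    E <- E - tcrossprod(tn, p)
    Fm <- Fm - tcrossprod(tn, cc)
    r <- r + 1L
    W[, r] <- w; P[, r] <- p; C[, r] <- cc; Tm[, r] <- tn
    rX[r] <- sqrt(sum(E^2)); rY[r] <- sqrt(sum(Fm^2))
  }
  new("PLSModel", ncomp = r,
      weights = W[, seq_len(r), drop = FALSE],
      loadings = P[, seq_len(r), drop = FALSE],
      yloadings = C[, seq_len(r), drop = FALSE],
      scores = Tm[, seq_len(r), drop = FALSE],
      xcenter = xm, ycenter = ym, xscale = xs,
      residX = rX[seq_len(r)], residY = rY[seq_len(r)], indexMap = im)
}

plsCoefInternal <- function(object, ncomp = object@ncomp) {
  if (ncomp == 0L)
    return(matrix(0, length(object@xcenter), length(object@ycenter)))
  k <- seq_len(ncomp)
  W <- object@weights[, k, drop = FALSE]
  P <- object@loadings[, k, drop = FALSE]
  C <- object@yloadings[, k, drop = FALSE]
  B <- W %*% solve(crossprod(P, W), t(C))
  B / object@xscale
}

#' Predict responses from a fitted PLS model
#'
#' Applies the stored centering (and scaling, if any) and maps through the
#' model's weight/loading structure. Predictions are on the (normalized)
#' response scale used at training.
#'
#' @param object a [PLSModel-class].
#' @param newdata [FeatureMatrix-class] or matrix with the training number
#'   of columns, in the same column order (same index map).
#' @param ncomp use only the first \code{ncomp} components (default: all).
#' @return rows x J matrix of predictions.
#' @export
setMethod("predict", "PLSModel", function(object, newdata,
                                          ncomp = object@ncomp) {
  X <- if (is(newdata, "FeatureMatrix")) newdata@values else
    as.matrix(newdata)
  if (ncol(X) != length(object@xcenter))
    stop("shape error: newdata has ", ncol(X), " columns; model expects ",
         length(object@xcenter))
  B <- plsCoefInternal(object, ncomp)
  sweep(sweep(X, 2, object@xcenter) %*% B, 2, object@ycenter, "+")
})

#' Regression coefficients of a PLS model
#'
#' Returns the I x J array B such that prediction = (Xnew - center) B +
#' y-center on the training response scale. Feature contributions are read
#' from the magnitude of these coefficients.
#'
#' @param object a [PLSModel-class].
#' @param ... ignored.
#' @return I x J numeric matrix.
#' @export
setMethod("coef", "PLSModel", function(object, ...) plsCoefInternal(object))
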