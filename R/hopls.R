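# center a trials x M x M x F tensor by the trial-wise mean tensor
centerTensor <- function(x, xm = NULL) {
  d <- dim(x)
  if (is.null(xm)) xm <- apply(x, seq_along(d)[-1], mean)
  list(values = x - aperm(array(xm, dim = c(d[-1], d[1])),
                          c(length(d), seq_along(d)[-length(d)])),
       center = xm)
}

# the mode-1 unfolding of a trials x M x M x F tensor is column-major over
# (m1, m2, f), so projecting modes 2-4 onto P1, P2, P3 is one multiply by
# the Kronecker product P3 x P2 x P1 (and reconstruction is its transpose)
kronLoadings <- function(P) kronecker(P[[3]], kronecker(P[[2]], P[[1]]))

#' Fit a higher-order PLS tensor regression
#'
#' Sequentially extracts \code{ncomp} components from a centered four-mode
#' feature tensor (trials x channel x channel x band) against responses.
#' Per component: (a) the cross-covariance tensor C with entries
#' \code{C[j, m1, m2, f] = sum_n Y[n, j] X[n, m1, m2, f]} is formed on the
#' current residuals; (b) its best rank-(1, L1, L2, L3) orthogonal Tucker
#' approximation (higher-order orthogonal iteration, truncated-SVD
#' initialization) yields the response loading q_r and the column-orthonormal
#' mode loadings P_r^(k); (c) the score vector t_r is extracted from the
#' residual tensor projected onto the loadings; (d) the core G_r and
#' strength d_r q_r = Y' t_r are computed; (e) both blocks are deflated by
#' their rank-one reconstructions.
#'
#' Two score rules are available. \code{"covariance"} (default) projects the
#' residual tensor onto the core of the cross-covariance approximation, so
#' scores stay response-driven; with full loading ranks (L1 = L2 = M,
#' L3 = F) the fit and its predictions coincide exactly with NIPALS PLS2 on
#' the vectorized tensor. \code{"svd"} takes the dominant left singular
#' vector of the mode-1 unfolding of the projected residual, the rule used
#' in the original HOPLS formulation.
#'
#' @param x a [FeatureTensor-class] or numeric 4-mode array (N x M x M x F).
#' @param y response matrix (N x J), typically normalized.
#' @param ncomp number of components R2 (>= 1). Extraction stops early with
#'   a warning if a residual vanishes; the achieved count is stored.
#' @param L integer triple (L1, L2, L3) of loading ranks; 1 <= L1, L2 <= M
#'   and 1 <= L3 <= F.
#' @param scores "covariance" or "svd" (see Details).
#' @param maxit,tol higher-order orthogonal iteration control: at most
#'   \code{maxit} alternations, converged when the approximation norm
#'   changes by less than \code{tol} relative.
#' @return a [HOPLSModel-class].
#' @seealso [predict,HOPLSModel-method], [coef,HOPLSModel-method]
#' @export
fitHopls <- function(x, y, ncomp, L, scores = c("covariance", "svd"),
                     maxit = 100, tol = 1e-9) {
  scores <- match.arg(scores)
  channels <- if (is(x, "FeatureTensor")) x@channels else character()
  bands <- if (is(x, "FeatureTensor")) x@bands else character()
  X <- if (is(x, "FeatureTensor")) x@values else x
  Y <- as.matrix(y)
  d <- dim(X)
  stopifnot(length(d) == 4L, nrow(Y) == d[1])
  N <- d[1]; M <- d[2]; Fb <- d[4]
  L <- as.integer(L)
  if (length(L) != 3L)
    stop("parameter error: L must be the triple (L1, L2, L3)")
  if (L[1] < 1L || L[2] < 1L || L[1] > M || L[2] > d[3])
    stop("parameter error: channel loading ranks must lie in 1 .. M = ", M)
  if (L[3] < 1L || L[3] > Fb)
    stop("parameter error: band loading rank must lie in 1 .. F = ", Fb)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L) stop("parameter error: ncomp must be >= 1")

  Xm <- matrix(X, nrow = N)                    # mode-1 unfolding
  xmv <- colMeans(Xm)
  Xm <- sweep(Xm, 2, xmv)
  ym <- colMeans(Y)
  Yr <- sweep(Y, 2, ym)
  J <- ncol(Y)
  loadings <- list(); cores <- list(); weights <- list()
  wnorms <- numeric(0); dvec <- numeric(0)
  Q <- matrix(0, J, 0); Tm <- matrix(0, N, 0)
  rX <- numeric(0); rY <- numeric(0)
  for (r in seq_len(ncomp)) {
    if (sqrt(sum(Xm^2)) < 1e-12 || sqrt(sum(Yr^2)) < 1e-12) {
      warning("residual vanished after ", r - 1L,
              " component(s); stopping early")
      break
    }
    C <- array(crossprod(Yr, Xm), dim = c(J, d[-1]))   # J x M x M x F
    h <- hooiTucker(C, c(1L, L), maxit = maxit, tol = tol)
    P <- h$factors[2:4]
    K <- kronLoadings(P)                       # (M*M*F) x (L1*L2*L3)
    Zm <- Xm %*% K
    if (scores == "svd") {
      tt <- topLeftSV(Zm, 1)[, 1]
      wproj <- numeric(0); wn <- NA_real_
    } else {
      wproj <- as.vector(h$core)               # C-core with q applied
      wproj <- wproj / sqrt(sum(wproj^2))
      tt <- drop(Zm %*% wproj)
      wn <- sqrt(sum(tt^2))
      if (wn < 1e-150) {
        warning("degenerate component ", r, "; stopping early")
        break
      }
      tt <- tt / wn
    }
    g <- drop(crossprod(Zm, tt))               # vec of core G_r
    cc <- drop(crossprod(Yr, tt))              # d_r * q_r
    dr <- sqrt(sum(cc^2))
    qr <- if (dr > 0) cc / dr else cc
    # sign convention: first nonzero element of q_r non-negative; flip q
    # together with t (and the core) so t d q' and the deflations are
    # unchanged
    i0 <- which(abs(qr) > 1e-12)[1]
    if (!is.na(i0) && qr[i0] < 0) {
      qr <- -qr; tt <- -tt; g <- -g
      if (length(wproj)) wproj <- -wproj
    }
    Xm <- Xm - tcrossprod(tt, drop(K %*% g))   # deflate by t (G x P...)
    Yr <- Yr - tcrossprod(tt, qr) * dr
    loadings[[r]] <- P; cores[[r]] <- array(g, dim = L)
    weights[[r]] <- wproj; wnorms <- c(wnorms, wn)
    dvec <- c(dvec, dr); Q <- cbind(Q, qr); Tm <- cbind(Tm, tt)
    rX <- c(rX, sqrt(sum(Xm^2))); rY <- c(rY, sqrt(sum(Yr^2)))
  }
  new("HOPLSModel", ncomp = length(cores), L = L, scoreMethod = scores,
      loadings = loadings, cores = cores, weights = weights,
      weightNorms = wnorms, d = dvec, yloadings = Q, scores = Tm,
      xcenter = array(xmv, dim = d[-1]), ycenter = ym, residX = rX,
      residY = rY, channels = channels, bands = bands)
}

#' Predict responses from a fitted HOPLS model
#'
#' Centers the test tensor with the training mean, projects each residual
#' onto the component's loading matrices across modes 2-4, maps the
#' projection to a new score (through the stored covariance weight, or
#' through the pseudo-inverse of the core's mode-1 unfolding for
#' \code{scores = "svd"}), accumulates t d q' and deflates in training
#' order.
#'
#' @param object a [HOPLSModel-class].
#' @param newdata [FeatureTensor-class] or array (rows x M x M x F) with the
#'   training mode dimensions.
#' @param ncomp use only the first \code{ncomp} components (default: all).
#' @return rows x J matrix of predictions on the training response scale.
#' @export
setMethod("predict", "HOPLSModel", function(object, newdata,
                                            ncomp = object@ncomp) {
  X <- if (is(newdata, "FeatureTensor")) newdata@values else newdata
  d <- dim(X)
  if (length(d) != 4L || !all(d[-1] == dim(object@xcenter)))
    stop("shape error: newdata modes do not match the training tensor")
  Xm <- sweep(matrix(X, nrow = d[1]), 2, as.vector(object@xcenter))
  pred <- matrix(0, d[1], length(object@ycenter))
  for (r in seq_len(min(ncomp, object@ncomp))) {
    g <- as.vector(object@cores[[r]])
    K <- kronLoadings(object@loadings[[r]])
    Zm <- Xm %*% K
    tn <- if (object@scoreMethod == "svd")
      drop(Zm %*% g) / sum(g^2)
    else
      drop(Zm %*% object@weights[[r]]) / object@weightNorms[r]
    pred <- pred + tcrossprod(tn, object@yloadings[, r]) * object@d[r]
    Xm <- Xm - tcrossprod(tn, drop(K %*% g))
  }
  sweep(pred, 2, object@ycenter, "+")
})

#' Coefficient tensor of a HOPLS model
#'
#' Returns the M x M x F x J array W such that the prediction for a
#' centered test tensor equals its inner product with \code{W[, , , j]} per
#' response (plus the response center), matching
#' [predict,HOPLSModel-method] exactly. Used for coefficient-magnitude
#' feature attribution.
#'
#' @param object a [HOPLSModel-class].
#' @param ... ignored.
#' @return M x M x F x J numeric array.
#' @export
setMethod("coef", "HOPLSModel", function(object, ...) {
  dm <- dim(object@xcenter)
  J <- length(object@ycenter)
  R <- object@ncomp
  B <- array(0, dim = c(dm, J))
  if (R == 0L) return(B)
  # per component: t_r = <residual, a_r>; residual_(r+1) = residual - t_r D_r.
  # Unrolling the recursion gives t_r = <x, atilde_r> with
  # atilde_r = a_r - sum_{s<r} <D_s, a_r> atilde_s.
  avec <- matrix(0, prod(dm), R)
  dvecs <- matrix(0, prod(dm), R)
  for (r in seq_len(R)) {
    K <- kronLoadings(object@loadings[[r]])
    g <- as.vector(object@cores[[r]])
    dvecs[, r] <- drop(K %*% g)
    avec[, r] <- if (object@scoreMethod == "svd")
      dvecs[, r] / sum(g^2)
    else
      drop(K %*% object@weights[[r]]) / object@weightNorms[r]
  }
  atil <- matrix(0, prod(dm), R)
  for (r in seq_len(R)) {
    a <- avec[, r]
    if (r > 1L) {
      s <- seq_len(r - 1L)
      a <- a - atil[, s, drop = FALSE] %*%
        drop(crossprod(dvecs[, s, drop = FALSE], avec[, r]))
    }
    atil[, r] <- a
  }
  Bm <- atil %*% (t(object@yloadings[, seq_len(R), drop = FALSE]) *
                    object@d[seq_len(R)])
  array(Bm, dim = c(dm, J))
})
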