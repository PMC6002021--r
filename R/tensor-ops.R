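#' Tensor mode-k unfolding
#'
#' Matricizes an array along one mode: mode-k fibers become the columns of
#' a matrix with \code{dim(a)[k]} rows; the remaining modes are cycled in
#' their original order.
#'
#' @param a a numeric array.
#' @param mode the mode to bring to the rows.
#' @return a matrix.
#' @export
unfold <- function(a, mode) {
  d <- dim(a)
  perm <- c(mode, seq_along(d)[-mode])
  matrix(aperm(a, perm), nrow = d[mode])
}

#' Refold an unfolded tensor
#'
#' Inverse of [unfold()] given the target dimensions.
#'
#' @param m a matrix produced by (or conformable with) [unfold()].
#' @param mode the mode that was unfolded.
#' @param dims the dimensions of the refolded array.
#' @return an array with \code{dim = dims}.
#' @export
refold <- function(m, mode, dims) {
  perm <- c(mode, seq_along(dims)[-mode])
  aperm(array(m, dim = dims[perm]), order(perm))
}

#' Tensor mode-k product
#'
#' Multiplies a tensor by a matrix along mode k:
#' \code{modeProduct(a, m, k)} has mode-k dimension \code{nrow(m)}.
#'
#' @param a a numeric array.
#' @param m a matrix with \code{ncol(m) == dim(a)[mode]}.
#' @param mode the mode to contract.
#' @return an array.
#' @export
modeProduct <- function(a, m, mode) {
  d <- dim(a)
  d2 <- d; d2[mode] <- nrow(m)
  refold(m %*% unfold(a, mode), mode, d2)
}

tensorNorm <- function(a) sqrt(sum(a^2))

# leading k left singular vectors with the sign of the first non-negligible
# element forced positive (reproducibility)
topLeftSV <- function(m, k) {
  s <- svd(m, nu = k, nv = 0)
  u <- s$u
  for (j in seq_len(ncol(u))) {
    i <- which(abs(u[, j]) > 1e-12)[1]
    if (!is.na(i) && u[i, j] < 0) u[, j] <- -u[, j]
  }
  u
}

# best rank-(r1, ..., rK) orthogonal Tucker approximation by higher-order
# orthogonal iteration, initialized from the truncated SVD of each unfolding
hooiTucker <- function(a, ranks, maxit = 100, tol = 1e-9) {
  K <- length(dim(a))
  stopifnot(length(ranks) == K)
  fac <- lapply(seq_len(K), function(k) topLeftSV(unfold(a, k), ranks[k]))
  gn_old <- 0
  for (it in seq_len(maxit)) {
    for (k in seq_len(K)) {
      w <- a
      for (j in setdiff(seq_len(K), k))
        w <- modeProduct(w, t(fac[[j]]), j)
      fac[[k]] <- topLeftSV(unfold(w, k), ranks[k])
    }
    g <- a
    for (j in seq_len(K)) g <- modeProduct(g, t(fac[[j]]), j)
    gn <- tensorNorm(g)
    if (abs(gn - gn_old) < tol * max(gn, 1)) break
    gn_old <- gn
  }
  list(factors = fac, core = g)
}
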