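test_that("tensor unfolding and mode product match brute-force loops", {
  set.seed(1)
  a <- array(rnorm(3 * 4 * 2 * 5), dim = c(3, 4, 2, 5))
  u2 <- unfold(a, 2)
  # fibers: u2[i2, col] enumerates (i1, i3, i4) with i1 fastest
  col <- 1
  for (i4 in 1:5) for (i3 in 1:2) for (i1 in 1:3) {
    expect_equal(u2[, col], a[i1, , i3, i4])
    col <- col + 1
  }
  expect_equal(refold(u2, 2, dim(a)), a)

  m <- matrix(rnorm(3 * 4), 3, 4)
  pr <- modeProduct(a, m, 2)
  ref <- array(0, dim = c(3, 3, 2, 5))
  for (i1 in 1:3) for (i3 in 1:2) for (i4 in 1:5)
    ref[i1, , i3, i4] <- m %*% a[i1, , i3, i4]
  expect_equal(pr, ref, tolerance = 1e-12)
})

test_that("noiseless model data are recovered exactly at the true ranks", {
  for (seed in 1:3) {
    d <- hoplsModelData(N = 40, M = 6, Fb = 3, J = 3, R2 = 3,
                        L = c(2, 2, 2), noiseSd = 0, seed = seed)
    m <- fitHopls(d$X, d$Y, ncomp = 3, L = c(2, 2, 2))
    relV <- m@residY[3] / sqrt(sum(scale(d$Y, scale = FALSE)^2))
    expect_lt(relV, 1e-6)
    expect_lt(max(abs(predict(m, d$X) - d$Y)), 1e-6)
    # orthonormal loadings, unit scores, monotone residuals
    for (r in 1:3) {
      for (k in 1:3) {
        P <- m@loadings[[r]][[k]]
        expect_lt(max(abs(crossprod(P) - diag(ncol(P)))), 1e-8)
      }
      expect_equal(sum(m@scores[, r]^2), 1, tolerance = 1e-10)
    }
    expect_true(all(diff(m@residX) <= 1e-10))
    expect_true(all(diff(m@residY) <= 1e-10))
  }
})

test_that("residual norms decrease monotonically on noisy data too", {
  d <- hoplsModelData(N = 30, M = 6, Fb = 3, R2 = 2, L = c(2, 2, 2),
                      noiseSd = 0.5, seed = 4)
  m <- fitHopls(d$X, d$Y, ncomp = 5, L = c(2, 2, 2))
  expect_true(all(diff(m@residX) <= 1e-10))
  expect_true(all(diff(m@residY) <= 1e-10))
})

test_that("full loading ranks reduce HOPLS to PLS on the vectorized tensor", {
  set.seed(5)
  N <- 20; M <- 4; Fb <- 2; J <- 3
  X <- array(rnorm(N * M * M * Fb), dim = c(N, M, M, Fb))
  Y <- matrix(rnorm(N * J), N)
  Xt <- array(rnorm(8 * M * M * Fb), dim = c(8, M, M, Fb))
  for (R in 1:3) {
    h <- fitHopls(X, Y, ncomp = R, L = c(M, M, Fb))
    p <- fitPls(unfold(X, 1), Y, ncomp = R)
    expect_lt(max(abs(predict(h, Xt) - predict(p, unfold(Xt, 1)))), 1e-6)
  }
})

test_that("loading ranks beyond the mode dimensions are rejected", {
  d <- hoplsModelData(N = 15, M = 7, Fb = 5, R2 = 1, L = c(1, 1, 1),
                      seed = 6)
  # the full search ranges are accepted at M = 7, F = 5
  expect_silent(fitHopls(d$X, d$Y, ncomp = 1, L = c(7, 7, 5)) -> m)
  expect_error(fitHopls(d$X, d$Y, ncomp = 1, L = c(8, 7, 5)),
               "parameter error")
  expect_error(fitHopls(d$X, d$Y, ncomp = 1, L = c(7, 7, 6)),
               "parameter error")
  expect_error(fitHopls(d$X, d$Y, ncomp = 0, L = c(1, 1, 1)),
               "parameter error")
})

test_that("prediction centering and shape checks", {
  d <- hoplsModelData(N = 20, M = 5, Fb = 3, R2 = 2, L = c(2, 2, 2),
                      noiseSd = 0.2, seed = 7)
  m <- fitHopls(d$X, d$Y, ncomp = 2, L = c(2, 2, 2))
  # the training-mean tensor predicts the response mean
  mu <- array(apply(d$X, 2:4, mean), dim = c(1, 5, 5, 3))
  expect_equal(drop(predict(m, mu)), unname(m@ycenter), tolerance = 1e-8)
  expect_error(predict(m, d$X[, 1:4, , , drop = FALSE]), "shape error")
})

test_that("coefficient tensor reproduces predictions on random inputs", {
  d <- hoplsModelData(N = 25, M = 5, Fb = 3, R2 = 2, L = c(2, 2, 2),
                      noiseSd = 0.3, seed = 8)
  for (sc in c("covariance", "svd")) {
    m <- fitHopls(d$X, d$Y, ncomp = 3, L = c(2, 2, 2), scores = sc)
    W <- coef(m)
    set.seed(9)
    Xt <- array(rnorm(100 * 5 * 5 * 3), dim = c(100, 5, 5, 3))
    Xc <- Xt - aperm(array(m@xcenter, dim = c(5, 5, 3, 100)), c(4, 1, 2, 3))
    pr <- sweep(matrix(Xc, 100) %*% matrix(W, ncol = 3), 2, m@ycenter, "+")
    expect_lt(max(abs(pr - predict(m, Xt))), 1e-8)
  }

  # zero responses give a zero coefficient tensor
  m0 <- suppressWarnings(fitHopls(d$X, matrix(0, 25, 3), ncomp = 1,
                                  L = c(1, 1, 1)))
  expect_true(all(coef(m0) == 0))
})

test_that("rank-(1,1,1) single component coefficients factor as outer product", {
  d <- hoplsModelData(N = 20, M = 5, Fb = 3, R2 = 1, L = c(1, 1, 1),
                      noiseSd = 0, seed = 10)
  m <- fitHopls(d$X, d$Y, ncomp = 1, L = c(1, 1, 1))
  W <- coef(m)[, , , 1]
  # a triple outer product unfolds to a rank-one matrix along every mode
  for (k in 1:3) {
    sv <- svd(unfold(W, k))$d
    expect_lt(sv[2] / sv[1], 1e-10)
  }
})

test_that("channel relabeling equivariance: permuted train/test predict alike", {
  d <- hoplsModelData(N = 20, M = 5, Fb = 3, R2 = 2, L = c(2, 2, 2),
                      noiseSd = 0.2, seed = 11)
  set.seed(12)
  Xt <- array(rnorm(6 * 5 * 5 * 3), dim = c(6, 5, 5, 3))
  perm <- sample(5)
  m1 <- fitHopls(d$X, d$Y, ncomp = 2, L = c(2, 2, 2))
  m2 <- fitHopls(d$X[, perm, perm, , drop = FALSE], d$Y, ncomp = 2,
                 L = c(2, 2, 2))
  expect_equal(predict(m1, Xt), predict(m2, Xt[, perm, perm, , drop = FALSE]),
               tolerance = 1e-8)
})

test_that("held-out error approaches the noise floor as N grows", {
  sigma <- 0.1
  err <- vapply(c(20, 40, 80), function(N) {
    e <- numeric(3)
    for (s in 1:3) {
      d <- hoplsModelData(N = N + 30, M = 6, Fb = 3, R2 = 2, L = c(2, 2, 2),
                          noiseSd = sigma, seed = 100 * s + N)
      tr <- seq_len(N); te <- (N + 1):(N + 30)
      m <- fitHopls(d$X[tr, , , , drop = FALSE], d$Y[tr, ], ncomp = 2,
                    L = c(2, 2, 2))
      e[s] <- sqrt(mean((predict(m, d$X[te, , , , drop = FALSE]) -
                           d$Y[te, ])^2))
    }
    mean(e)
  }, numeric(1))
  expect_lt(err[3], err[1])
  expect_lt(err[3], 2 * sigma)
})

test_that("identical inputs produce bit-identical model files", {
  d <- hoplsModelData(N = 15, M = 5, Fb = 3, R2 = 2, L = c(2, 2, 2),
                      noiseSd = 0.2, seed = 13)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  saveModel(fitHopls(d$X, d$Y, ncomp = 2, L = c(2, 2, 2)), f1)
  saveModel(fitHopls(d$X, d$Y, ncomp = 2, L = c(2, 2, 2)), f2)
  expect_identical(readLines(f1), readLines(f2))
  m2 <- loadModel(f1)
  expect_equal(predict(m2, d$X), predict(loadModel(f2), d$X))
})
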