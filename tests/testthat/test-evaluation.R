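test_that("response normalization uses the sample sd and is idempotent", {
  y <- cbind(MOS = c(1, 2, 3), VAL = c(2, 4, 6), ARL = c(1, 1.5, 2))
  n <- normalizeResponses(y)
  expect_equal(unname(n$values[, "MOS"]), c(-1, 0, 1))
  expect_equal(unname(n$scale), c(1, 2, 0.5))
  n2 <- normalizeResponses(n$values)
  expect_lt(max(abs(n2$values - n$values)), 1e-12)
  expect_lt(max(abs(colMeans(n$values))), 1e-10)
  expect_equal(unname(apply(n$values, 2, sd)), rep(1, 3), tolerance = 1e-10)
  expect_error(normalizeResponses(cbind(MOS = c(5, 5, 5), VAL = 1:3,
                                        ARL = 1:3)),
               "degenerate-response")
})

test_that("rmse matches hand arithmetic", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(1, 1), c(0, 0)), 1)
  expect_equal(rmse(c(2, 0, 1), c(0, 0, 1)), sqrt(4 / 3))
  expect_error(rmse(1:3, 1:4), "shape error")
})

test_that("loocv runs one fold per trial and the mean model scores ~1", {
  set.seed(1)
  fs <- randomFeatureSet(nTrials = 44, M = 3, seed = 1, Tn = 128)
  fm <- buildFeatureMatrix(fs)
  ratings <- data.frame(subject = "s1", trial = 1:44,
                        MOS = runif(44, 1, 5), VAL = runif(44, 1, 9),
                        ARL = runif(44, 1, 9))
  ev <- loocv(fm, ratings, "mean")
  expect_equal(ev@folds, 44L)
  expect_equal(nrow(ev@predictions), 44L)
  # fold-wise renormalization inflates the mean-model RMSE slightly above 1
  expect_equal(unname(mean(ev@rmse)), 1, tolerance = 0.1)
  expect_true(all(ev@rmse >= 0))
})

test_that("strong linear signal yields clearly sub-unit LOOCV error", {
  set.seed(2)
  fs <- randomFeatureSet(nTrials = 44, M = 8, seed = 2, Tn = 256)
  fm <- buildFeatureMatrix(fs)
  Y <- latentResponses(featureValues(fm), k = 2, seed = 3)
  # add noise at signal-to-noise ratio 10
  Yn <- Y + matrix(rnorm(length(Y)), nrow(Y)) %*%
    diag(apply(Y, 2, sd) / 10)
  colnames(Yn) <- colnames(Y)
  ev <- loocv(fm, Yn, "pls", R1 = 4)
  expect_lt(mean(ev@rmse), 0.7)
})

test_that("infeasible fold-size hyperparameters raise a parameter error", {
  fs <- randomFeatureSet(nTrials = 10, M = 3, seed = 4, Tn = 128)
  fm <- buildFeatureMatrix(fs)
  Y <- data.frame(subject = "s", trial = 1:10, MOS = runif(10, 1, 5),
                  VAL = runif(10, 1, 9), ARL = runif(10, 1, 9))
  expect_error(loocv(fm, Y, "pls", R1 = 9), "parameter error")
  expect_silent(loocv(fm, Y, "pls", R1 = 8) -> ev)
})

test_that("default grids match the full search protocol", {
  gp <- defaultGrid("pls")
  expect_equal(nrow(gp), 43L)
  expect_equal(gp$R1, 1:43)
  gh <- defaultGrid("hopls")
  expect_equal(nrow(gh), 7 * 7 * 5 * 5)
  expect_equal(sort(unique(gh$L1)), 1:7)
  expect_equal(sort(unique(gh$L2)), 1:7)
  expect_equal(sort(unique(gh$L3)), 1:5)
  expect_equal(sort(unique(gh$R2)), 1:5)
})

test_that("a one-point grid equals loocv at that point", {
  fs <- randomFeatureSet(nTrials = 12, M = 3, seed = 5, Tn = 128)
  fm <- buildFeatureMatrix(fs)
  set.seed(6)
  Y <- data.frame(subject = "s", trial = 1:12, MOS = runif(12, 1, 5),
                  VAL = runif(12, 1, 9), ARL = runif(12, 1, 9))
  g1 <- gridSearch(fm, Y, "pls", grid = data.frame(R1 = 3))
  ev <- loocv(fm, Y, "pls", R1 = 3)
  expect_equal(g1@rmse, ev@rmse, tolerance = 1e-12)
  expect_equal(g1@hyperparams$R1, 3)
  expect_equal(nrow(g1@grid), 1L)
  expect_error(gridSearch(fm, Y, "pls", grid = data.frame(R1 = integer())),
               "parameter error")
})

test_that("grid search is deterministic and breaks ties toward small models", {
  fs <- randomFeatureSet(nTrials = 12, M = 3, seed = 7, Tn = 128)
  ft <- buildFeatureTensor(fs)
  set.seed(8)
  Y <- data.frame(subject = "s", trial = 1:12, MOS = runif(12, 1, 5),
                  VAL = runif(12, 1, 9), ARL = runif(12, 1, 9))
  grid <- expand.grid(L1 = 1:2, L2 = 1:2, L3 = 1, R2 = 1:2)
  g1 <- gridSearch(ft, Y, "hopls", grid = grid)
  g2 <- gridSearch(ft, Y, "hopls", grid = grid)
  expect_identical(g1@rmse, g2@rmse)
  expect_identical(g1@hyperparams, g2@hyperparams)
  expect_equal(nrow(g1@grid), 8L)
  expect_true(all(c("MOS", "VAL", "ARL", "mean_rmse") %in% names(g1@grid)))

  # duplicated grid rows tie exactly; the earliest smallest model wins
  gdup <- gridSearch(ft, Y, "hopls",
                     grid = data.frame(L1 = c(2, 2), L2 = 2, L3 = 1,
                                       R2 = c(2, 2)))
  expect_equal(gdup@hyperparams$R2, 2)
})

test_that("evaluation summary reproduces the per-subject table schema", {
  fs <- randomFeatureSet(nTrials = 12, M = 3, seed = 9, Tn = 128)
  set.seed(10)
  Y <- data.frame(subject = "s", trial = 1:12, MOS = runif(12, 1, 5),
                  VAL = runif(12, 1, 9), ARL = runif(12, 1, 9))
  ev_v <- gridSearch(buildFeatureMatrix(fs), Y, "pls",
                     grid = data.frame(R1 = 1:3))
  ev_t <- gridSearch(buildFeatureTensor(fs), Y, "hopls",
                     grid = expand.grid(L1 = 1:2, L2 = 1:2, L3 = 1,
                                        R2 = 1:2))
  tab <- evaluationTable(ev_v, ev_t, subject = "s7")
  expect_identical(names(tab),
                   c("subject", "MOS_vector", "VAL_vector", "ARL_vector",
                     "MOS_tensor", "VAL_tensor", "ARL_tensor",
                     "R1", "L1", "L2", "L3", "R2"))
  expect_equal(tab$subject, "s7")
  expect_true(all(is.finite(unlist(tab[, -1]))))
})

test_that("global normalization reproduces the pre-split protocol", {
  fs <- randomFeatureSet(nTrials = 10, M = 3, seed = 11, Tn = 128)
  fm <- buildFeatureMatrix(fs)
  set.seed(12)
  Y <- data.frame(subject = "s", trial = 1:10, MOS = runif(10, 1, 5),
                  VAL = runif(10, 1, 9), ARL = runif(10, 1, 9))
  ev <- loocv(fm, Y, "pls", R1 = 2, globalNormalize = TRUE)
  n <- normalizeResponses(as.matrix(Y[c("MOS", "VAL", "ARL")]))
  expect_equal(unname(ev@actuals), unname(n$values), tolerance = 1e-12)
})

test_that("grid search recovers the generating loading ranks approximately", {
  # moderate noise makes rank selection informative: with little noise all
  # ranks >= truth fit near-perfectly and the selection is arbitrary
  hits <- 0L
  for (s in 1:4) {
    d <- hoplsModelData(N = 24, M = 8, Fb = 4, R2 = 2, L = c(2, 2, 2),
                        noiseSd = 0.2, seed = 20 + s)
    grid <- expand.grid(L1 = 1:4, L2 = 1:4, L3 = 2, R2 = 1:2)
    g <- gridSearch(d$X, d$Y, "hopls", grid = grid)
    hp <- g@hyperparams
    if (all(abs(c(hp$L1, hp$L2, hp$L3) - 2) <= 1)) hits <- hits + 1L
  }
  expect_gte(hits, 3L)
})
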