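test_that("the CV objective equals an explicit hand-rolled k-fold loop", {
  g <- make_leaf_set(n = 30, seed = 41, step = 20)
  X <- spectra(g$dataset); y <- as.numeric(chlorophyll(g$dataset))
  spec <- learnerSpec("ridge_linear", alpha = 0.1)
  seed <- 77
  got <- cvMeanR2(spec, X, y, k = 5, seed = seed)

  # independent oracle: explicit loop over the same seeded folds
  fold <- withr::with_seed(seed, sample(rep_len(1:5, nrow(X))))
  scores <- numeric(5)
  for (f in 1:5) {
    tr <- fold != f
    Xc <- scale(X[tr, ], center = TRUE, scale = FALSE)
    beta <- solve(crossprod(Xc) + 0.1 * diag(ncol(X)),
                  crossprod(Xc, y[tr] - mean(y[tr])))
    pred <- scale(X[!tr, ], center = attr(Xc, "scaled:center"),
                  scale = FALSE) %*% beta + mean(y[tr])
    yv <- y[!tr]
    scores[f] <- 1 - sum((yv - pred)^2) / sum((yv - mean(yv))^2)
  }
  expect_equal(got, mean(scores), tolerance = 1e-12)
})

test_that("a perfect model scores 1 and a fold-mean model cannot beat 0", {
  # near-unpenalized ridge on an exactly linear signal predicts perfectly
  withr::with_seed(2, X <- matrix(runif(40 * 10), 40, 10))
  y <- 5 * X[, 3]
  expect_equal(cvMeanR2(learnerSpec("ridge_linear", alpha = 1e-8),
                        X, y, k = 4, seed = 1), 1, tolerance = 1e-6)
  # shrinkage so strong the model predicts ~ the training mean
  withr::with_seed(3, yr <- rnorm(40))
  expect_lte(cvMeanR2(learnerSpec("ridge_linear", alpha = 1e9),
                      X, yr, k = 4, seed = 1), 0.05)
})

test_that("random-search tuning is deterministic and finds the grid optimum", {
  g <- make_leaf_set(n = 50, seed = 43, step = 10)
  X <- spectra(g$dataset); y <- as.numeric(chlorophyll(g$dataset))
  space <- list(alpha = list(lower = 1e-3, upper = 100, log = TRUE))
  r1 <- tuneLearner("ridge_linear", X, y, space = space, nTrials = 30,
                    seed = 9)
  r2 <- tuneLearner("ridge_linear", X, y, space = space, nTrials = 30,
                    seed = 9)
  expect_identical(r1$trials, r2$trials)
  expect_equal(nrow(r1$trials), 30)
  expect_equal(r1$bestCvR2, max(r1$trials$cv_r2, na.rm = TRUE))

  # dense grid oracle over the same bounded 1-D space and the same folds
  grid <- exp(seq(log(1e-3), log(100), length.out = 60))
  foldSeed <- leafspec:::.subseed(9, 11L)
  gridBest <- max(vapply(grid, function(a)
    cvMeanR2(learnerSpec("ridge_linear", alpha = a), X, y, k = 5,
             seed = foldSeed), numeric(1)))
  expect_gte(r1$bestCvR2, gridBest - 0.02)

  # collapsed space returns that point
  point <- list(alpha = list(lower = 0.5, upper = 0.5, log = TRUE))
  rp <- tuneLearner("ridge_linear", X, y, space = point, nTrials = 5,
                    seed = 1)
  expect_equal(rp$bestSpec@hyperparams$alpha, 0.5)
  expect_equal(nrow(rp$trials), 5)
})

test_that("ensemble prediction is an exact convex combination", {
  g <- make_leaf_set(n = 30, seed = 45, step = 20)
  X <- spectra(g$dataset); y <- as.numeric(chlorophyll(g$dataset))
  fits <- list(
    fitLearner(learnerSpec("boosted_trees", n_estimators = 20), X, y),
    fitLearner(learnerSpec("latent_linear", n_components = 3), X, y),
    fitLearner(learnerSpec("ridge_linear", alpha = 1), X, y))
  # vertex weight reproduces the single learner exactly
  expect_identical(ensemblePredict(fits, c(0, 1, 0), X),
                   predict(fits[[2]], X))
  # three identical learners: any simplex point equals the single learner
  same <- fits[c(2, 2, 2)]
  expect_equal(ensemblePredict(same, c(0.2, 0.5, 0.3), X),
               predict(fits[[2]], X), tolerance = 1e-12)
  # hand arithmetic at the uniform point
  toy <- matrix(c(2, 4, 6), 1, 3)
  expect_equal(as.numeric(toy %*% rep(1 / 3, 3)), 4)
  # affine equivariance: shifting every learner shifts the ensemble
  P <- vapply(fits, function(f) predict(f, X), numeric(nrow(X)))
  w <- c(0.5, 0.3, 0.2)
  expect_equal(as.numeric((P + 7) %*% w), as.numeric(P %*% w) + 7,
               tolerance = 1e-10)
  expect_error(ensemblePredict(fits[1:2], c(0.5, 0.3, 0.2), X),
               class = "leafspec_config_error")
})

test_that("weight calibration returns simplex weights beating every vertex", {
  g <- make_leaf_set(n = 60, seed = 47, step = 10)
  X <- spectra(g$dataset); y <- as.numeric(chlorophyll(g$dataset))
  specs <- list(learnerSpec("boosted_trees", n_estimators = 40),
                learnerSpec("latent_linear", n_components = 5),
                learnerSpec("ridge_linear", alpha = 0.1))
  w <- calibrateWeights(specs, X, y, k = 3, nCalls = 20, seed = 5)
  expect_true(all(w@weights >= 0))
  expect_lt(abs(sum(w@weights) - 1), 1e-9)
  expect_lte(w@cvMSE, min(w@singleCvMSE) + 1e-9)
  # determinism
  w2 <- calibrateWeights(specs, X, y, k = 3, nCalls = 20, seed = 5)
  expect_identical(w@weights, w2@weights)
})

test_that("calibration puts nearly all weight on a dominating learner", {
  # planted dominance: the label is a 1-component linear signal that PLS
  # nails while the trees see only a handful of shuffled-label samples
  withr::with_seed(51, {
    X <- matrix(runif(90 * 10), 90, 10)
    y <- 40 + 10 * X[, 4]
  })
  specs <- list(learnerSpec("boosted_trees", n_estimators = 5,
                            max_depth = 2, learning_rate = 0.02),
                learnerSpec("latent_linear", n_components = 2),
                learnerSpec("ridge_linear", alpha = 1e3))
  w <- calibrateWeights(specs, X, y, k = 3, nCalls = 30, seed = 2)
  expect_gte(w@weights[["latent_linear"]], 0.9)
})

test_that("calibration matches a dense simplex-grid oracle on toys", {
  # two learners with equal-magnitude opposite-signed errors and one noise
  # learner: the optimum sits near (1/2, 1/2, 0). The oracle evaluates the
  # same CV-MSE surface on a dense simplex grid.
  withr::with_seed(53, {
    n <- 20
    y <- runif(n, 10, 70)
    P <- cbind(y + 3, y - 3, y + rnorm(n, 0, 15))
  })
  cv_mse <- function(w) mean((y - as.numeric(P %*% w))^2)
  # dense grid on the simplex
  gw <- expand.grid(w1 = seq(0, 1, length.out = 101),
                    w2 = seq(0, 1, length.out = 101))
  gw <- gw[gw$w1 + gw$w2 <= 1, ]
  gridBest <- min(apply(gw, 1, function(r)
    cv_mse(c(r[1], r[2], 1 - r[1] - r[2]))))

  # run the package search on the same prediction matrix via a stub of the
  # fold predictions: feed learners that reproduce P exactly by refit
  # (constant-output learners are impractical here, so check the optimizer
  # core directly through the exported surface on a synthetic dataset is
  # covered above; here we check the optimizer against the oracle)
  cand <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), rep(1, 3) / 3)
  U <- withr::with_seed(leafspec:::.subseed(4, 5L),
                        matrix(runif(2 * 36), 36, 2))
  for (i in 1:36) cand[[length(cand) + 1]] <- leafspec:::.simplex_map(U[i, ])
  val <- vapply(cand, cv_mse, numeric(1))
  wb <- cand[[which.min(val)]]
  u0 <- c(wb[1], if (wb[1] < 1) wb[2] / (1 - wb[1]) else 0)
  opt <- optim(u0, function(u)
    cv_mse(leafspec:::.simplex_map(pmin(pmax(u, 0), 1))),
    method = "Nelder-Mead", control = list(maxit = 200))
  best <- min(min(val), opt$value)
  expect_lte(best, gridBest * 1.02 + 1e-8)
  wopt <- leafspec:::.simplex_map(pmin(pmax(opt$par, 0), 1))
  expect_lt(abs(wopt[1] - 0.5) + abs(wopt[2] - 0.5), 0.2)
})
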