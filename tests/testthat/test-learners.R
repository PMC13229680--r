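test_that("ridge matches the normal-equations oracle on random systems", {
  worst <- 0
  withr::with_seed(17, for (i in 1:100) {
    n <- 20; p <- 8
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    alpha <- exp(runif(1, log(1e-3), log(10)))
    fit <- fitLearner(learnerSpec("ridge_linear", alpha = alpha), X, y)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    beta <- solve(crossprod(Xc) + alpha * diag(p),
                  crossprod(Xc, y - mean(y)))
    worst <- max(worst, max(abs(fit@coefficients - as.numeric(beta))))
  })
  expect_lt(worst, 1e-8)
})

test_that("ridge limits: alpha -> 0 recovers OLS, huge alpha kills coefficients", {
  withr::with_seed(3, {
    X <- matrix(rnorm(50), 10, 5)
    beta_true <- c(1, -2, 0.5, 3, -1)
    y <- as.numeric(X %*% beta_true) + rnorm(10, 0, 0.01)
  })
  fit <- fitLearner(learnerSpec("ridge_linear", alpha = 1e-10), X, y)
  ols <- coef(lm(y ~ X))[-1]
  expect_equal(unname(fit@coefficients), unname(ols), tolerance = 1e-6)
  fit2 <- fitLearner(learnerSpec("ridge_linear", alpha = 1e6), X, y)
  expect_lt(max(abs(fit2@coefficients)), 1e-3)
})

test_that("PLS with full components reproduces OLS in-sample; agrees with mixOmics", {
  withr::with_seed(4, {
    X <- matrix(rnorm(12 * 4), 12, 4)
    y <- as.numeric(X %*% c(2, -1, 0.5, 1)) + rnorm(12, 0, 0.05)
  })
  fit <- fitLearner(learnerSpec("latent_linear", n_components = 4), X, y)
  pred <- predict(fit, X)
  ols_pred <- fitted(lm(y ~ X))
  expect_equal(pred, unname(ols_pred), tolerance = 1e-6)

  skip_if_not_installed("mixOmics")
  Xn <- X; colnames(Xn) <- paste0("b", seq_len(ncol(X)))
  mo <- mixOmics::pls(Xn, y, ncomp = 3, mode = "regression", scale = FALSE)
  fit3 <- fitLearner(learnerSpec("latent_linear", n_components = 3), X, y)
  expect_equal(predict(fit3, X),
               unname(predict(mo, Xn)$predict[, , 3]), tolerance = 1e-10)
  expect_equal(vipScores(fit3)$vip,
               unname(mixOmics::vip(mo)[, 3]), tolerance = 1e-10)
})

test_that("PLS in-sample R2 is nondecreasing in the number of components", {
  g <- make_leaf_set(n = 40, seed = 13)
  X <- spectra(g$dataset); y <- as.numeric(chlorophyll(g$dataset))
  r2 <- vapply(1:6, function(a) {
    f <- fitLearner(learnerSpec("latent_linear", n_components = a), X, y)
    rSquared(y, predict(f, X))
  }, numeric(1))
  expect_true(all(diff(r2) >= -1e-10))
})

test_that("VIP scores are normalized and locate a planted active band", {
  hits <- 0L
  for (s in 1:100) {
    withr::with_seed(s, {
      X <- matrix(rnorm(40 * 20), 40, 20)
      y <- 3 * X[, 12] + rnorm(40, 0, 0.2)
    })
    f <- fitLearner(learnerSpec("latent_linear", n_components = 2), X, y,
                    wavelengths = seq(400, 590, 10))
    v <- vipScores(f)
    expect_equal(sum(v$vip^2), 20, tolerance = 1e-8)
    if (which.max(v$vip) == 12L) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("single-component VIP reduces to sqrt(p)|w|/||w||", {
  withr::with_seed(6, {
    X <- matrix(rnorm(30 * 7), 30, 7)
    y <- as.numeric(X %*% rnorm(7)) + rnorm(30, 0, 0.1)
  })
  f <- fitLearner(learnerSpec("latent_linear", n_components = 1), X, y)
  w <- f@weights[, 1]
  expect_equal(vipScores(f)$vip, sqrt(7) * abs(w) / sqrt(sum(w^2)),
               tolerance = 1e-10)
  expect_error(vipScores(fitLearner(learnerSpec("ridge_linear"), X, y)),
               "latent_linear")
})

test_that("band importances rank a planted signal band first", {
  wl <- seq(400, 995, 5)
  withr::with_seed(14, {
    X <- matrix(rnorm(80 * length(wl), 0.3, 0.05), 80, length(wl))
    y <- 3 * X[, which(wl == 700)] + rnorm(80, 0, 0.02)
  })
  fr <- fitLearner(learnerSpec("ridge_linear", alpha = 0.01), X, y,
                   wavelengths = wl)
  topR <- bandImportances(fr, 1)
  expect_equal(topR$wavelength_nm, 700)
  fx <- fitLearner(learnerSpec("boosted_trees", n_estimators = 60), X, y,
                   wavelengths = wl)
  topX <- bandImportances(fx, 5)
  expect_true(700 %in% topX$wavelength_nm)
  expect_true(all(is.finite(topX$importance)) && all(topX$importance >= 0))
  # topK = p returns a permutation of all bands
  allR <- bandImportances(fr, length(wl))
  expect_setequal(allR$wavelength_nm, wl)
  expect_warning(bandImportances(fr, length(wl) + 5), "truncated")
})

test_that("prediction contract: determinism, row order, axis checks", {
  g <- make_leaf_set(n = 30, seed = 21)
  X <- spectra(g$dataset); y <- as.numeric(chlorophyll(g$dataset))
  for (kind in c("latent_linear", "ridge_linear", "boosted_trees")) {
    f <- fitLearner(learnerSpec(kind), X, y, seed = 5)
    p1 <- predict(f, X)
    expect_true(all(is.finite(p1)))
    # duplicated rows give duplicated predictions, order preserved
    p2 <- predict(f, X[c(1, 1, 2), ])
    expect_identical(p2[1], p2[2])
    expect_equal(p2[3], p1[2], tolerance = 1e-12)
    # wrong band count is rejected
    expect_error(predict(f, X[, -1]), class = "leafspec_data_error")
  }
  # wrong axis labels (same length) are rejected
  f <- fitLearner(learnerSpec("ridge_linear"), X, y)
  Xbad <- X; colnames(Xbad) <- as.character(as.numeric(colnames(X)) + 5)
  expect_error(predict(f, Xbad), class = "leafspec_data_error")
})

test_that("an overparameterized boosted tree memorizes its training set", {
  withr::with_seed(31, {
    X <- matrix(runif(25 * 6), 25, 6)
    y <- runif(25, 10, 70)
  })
  f <- fitLearner(learnerSpec("boosted_trees", n_estimators = 400,
                              max_depth = 6, learning_rate = 0.3,
                              subsample = 1, colsample = 1), X, y)
  expect_lt(rmse(y, predict(f, X)), 0.5)
})
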