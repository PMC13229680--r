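test_that("moving average matches hand-computed truncated-window means", {
  expect_equal(movingAverage(c(1, 2, 3, 4, 5), 3), c(1.5, 2, 3, 4, 4.5))
  expect_equal(movingAverage(rep(2.5, 9), 5), rep(2.5, 9))
  x <- runif(20)
  expect_equal(movingAverage(x, 1), x)
  expect_error(movingAverage(x, 4), class = "leafspec_config_error")
  expect_error(movingAverage(x, -3), class = "leafspec_config_error")
  expect_error(movingAverage(x, 21), class = "leafspec_config_error")
})

test_that("moving average is linear and range-bounded", {
  withr::with_seed(5, {
    for (i in 1:20) {
      x <- rnorm(31); y <- rnorm(31)
      a <- rnorm(1); b <- rnorm(1)
      expect_equal(movingAverage(a * x + b * y, 7),
                   a * movingAverage(x, 7) + b * movingAverage(y, 7),
                   tolerance = 1e-10)
      mx <- movingAverage(x, 9)
      expect_true(all(mx >= min(x) - 1e-12 & mx <= max(x) + 1e-12))
    }
  })
})

test_that("moving average on a SpectralSet smooths every sample", {
  ds <- make_random_set(n = 4, p = 11)
  sm <- movingAverage(ds, 3)
  expect_s4_class(sm, "SpectralSet")
  expect_equal(spectra(sm)[2, ], movingAverage(spectra(ds)[2, ], 3),
               ignore_attr = TRUE)
  expect_equal(chlorophyll(sm), chlorophyll(ds))
})

test_that("correlation profile matches the Pearson formula and flags flat bands", {
  y <- c(1, 2, 3, 4, 5)
  X <- cbind(2 * y + 1, -y, c(2, 1, 4, 3, 5), rep(0.4, 5))
  ds <- SpectralSet(X, c(400, 500, 600, 700), y,
                    ids = paste0("s", 1:5))
  pr <- correlationProfile(ds)
  expect_equal(pr$r[1], 1)
  expect_equal(pr$r[2], -1)
  expect_equal(pr$r[3], 0.8)  # hand-evaluated Pearson of (2,1,4,3,5) vs 1:5
  expect_true(is.na(pr$r[4]) && pr$zero_variance[4])

  # invariance to affine relabelling of y
  ds2 <- SpectralSet(X, c(400, 500, 600, 700), 3.7 * y + 11,
                     ids = paste0("s", 1:5))
  expect_equal(correlationProfile(ds2)$r, pr$r, tolerance = 1e-12)

  flat <- SpectralSet(X, c(400, 500, 600, 700), rep(1, 5),
                      ids = paste0("s", 1:5))
  expect_error(correlationProfile(flat), class = "leafspec_data_error")
})

test_that("stratification cuts ranked labels into near-equal levels", {
  ds <- SpectralSet(matrix(runif(18), 9, 2), c(500, 600), 1:9,
                    ids = paste0("s", 1:9))
  st <- stratifyLevels(ds)
  lv <- setNames(st$assignment$level, st$assignment$id)
  expect_setequal(names(lv[lv == "low"]), paste0("s", 1:3))
  expect_setequal(names(lv[lv == "medium"]), paste0("s", 4:6))
  expect_setequal(names(lv[lv == "high"]), paste0("s", 7:9))
  expect_equal(st$cut_points, c(3, 6))

  # n = 3: one sample per level
  ds3 <- SpectralSet(matrix(runif(6), 3, 2), c(500, 600), c(5, 1, 9),
                     ids = c("a", "b", "c"))
  st3 <- stratifyLevels(ds3)
  expect_setequal(st3$assignment$level, c("low", "medium", "high"))

  # degenerate: identical labels
  dsc <- SpectralSet(matrix(runif(8), 4, 2), c(500, 600), rep(2, 4),
                     ids = paste0("s", 1:4))
  expect_warning(stc <- stratifyLevels(dsc), "identical")
  expect_true(all(stc$assignment$level == "low"))

  # group sizes differ by at most one
  ds10 <- make_random_set(n = 10, p = 2)
  st10 <- stratifyLevels(ds10)
  expect_lte(diff(range(table(st10$assignment$level))), 1)
})

test_that("PCA scores match a brute-force eigendecomposition of the train covariance", {
  withr::with_seed(8, {
    Xtr <- matrix(rnorm(20 * 10), 20, 10)
    Xva <- matrix(rnorm(8 * 10), 8, 10)
  })
  wl <- seq(400, 490, 10)
  train <- SpectralSet(Xtr, wl, runif(20), ids = sprintf("t%02d", 1:20))
  val <- SpectralSet(Xva, wl, runif(8), ids = sprintf("v%02d", 1:8))
  sc <- pcaScores(train, val, nComponents = 3)

  # oracle: eigenvectors of the train covariance matrix
  C <- cov(Xtr)
  ev <- eigen(C, symmetric = TRUE)
  ctr <- scale(Xtr, center = TRUE, scale = FALSE)
  oracle <- ctr %*% ev$vectors[, 1:3]
  got <- as.matrix(sc[sc$set == "train", c("PC1", "PC2", "PC3")])
  for (j in 1:3)  # sign of each component is arbitrary
    expect_lt(min(max(abs(got[, j] - oracle[, j])),
                  max(abs(got[, j] + oracle[, j]))), 1e-8)
  expect_equal(attr(sc, "explained_variance"),
               (ev$values / sum(ev$values))[1:3], tolerance = 1e-8)

  # identical train and val give identical score clouds
  val2 <- SpectralSet(Xtr, wl, runif(20), ids = sprintf("w%02d", 1:20))
  sc2 <- pcaScores(train, val2, nComponents = 2)
  expect_equal(as.matrix(sc2[sc2$set == "train", c("PC1", "PC2")]),
               as.matrix(sc2[sc2$set == "val", c("PC1", "PC2")]),
               ignore_attr = TRUE)
})

test_that("rank-1 data concentrates all PCA variance on component 1", {
  base <- sin(seq(0, 3, length.out = 6))
  X <- outer(2 + runif(8), base)
  wl <- seq(400, 450, 10)
  tr <- SpectralSet(X, wl, runif(8), ids = paste0("r", 1:8))
  sc <- pcaScores(tr, tr, nComponents = 2)
  expect_equal(attr(sc, "explained_variance")[1], 1, tolerance = 1e-10)
})

test_that("mean spectrum obeys the weighted-mean identity over tertiles", {
  ds <- make_random_set(n = 11, p = 6, seed = 4)
  single <- meanSpectrum(ds, sampleIDs(ds)[3])
  expect_equal(single$reflectance, unname(spectra(ds)[3, ]))
  st <- stratifyLevels(ds)
  parts <- lapply(st$levels, function(l)
    st$assignment$id[st$assignment$level == l])
  weighted <- Reduce(`+`, lapply(parts, function(ids)
    length(ids) * meanSpectrum(ds, ids)$reflectance)) / ncol(ds)
  expect_equal(weighted, meanSpectrum(ds)$reflectance, tolerance = 1e-12)
  expect_error(meanSpectrum(ds, "nope"), class = "leafspec_data_error")
})
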