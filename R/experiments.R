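#' Coefficient of determination
#'
#' `R2 = 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)`, with the mean taken
#' over the vector being evaluated.
#'
#' @param y observed values (length >= 2, non-constant).
#' @param yHat predicted values.
#' @return R-squared (<= 1; negative when worse than the mean predictor).
#' @export
rSquared <- function(y, yHat) {
    y <- as.numeric(y); yHat <- as.numeric(yHat)
    if (length(y) < 2L) .config_error("need at least 2 values")
    if (length(y) != length(yHat)) .config_error("length mismatch")
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot == 0) .data_error("R-squared is undefined for constant y")
    1 - sum((y - yHat)^2) / ss_tot
}

#' Root mean square error
#'
#' @param y observed values.
#' @param yHat predicted values.
#' @return `sqrt(mean((y - yHat)^2))`, in label units.
#' @export
rmse <- function(y, yHat) {
    y <- as.numeric(y); yHat <- as.numeric(yHat)
    if (length(y) < 1L) .config_error("need at least 1 value")
    if (length(y) != length(yHat)) .config_error("length mismatch")
    sqrt(mean((y - yHat)^2))
}

.MODEL_ORDER <- c("boosted_trees", "latent_linear", "ridge_linear")

# tune the three base learners on (X, y) with one shared seed so the CV
# folds are identical across learners (paired objective comparisons)
.tune_all <- function(X, y, nTrials, k, seed, spaces = NULL) {
    specs <- lapply(.MODEL_ORDER, function(kind) {
        sp <- if (!is.null(spaces) && !is.null(spaces[[kind]]))
            spaces[[kind]] else searchSpace(kind)
        tuneLearner(kind, X, y, space = sp, nTrials = nTrials, k = k,
                    seed = seed)$bestSpec
    })
    names(specs) <- .MODEL_ORDER
    specs
}

# fit + calibrate + evaluate one training set against one validation set
.run_setting <- function(trainSet, val, specs, seed, calibK = 3L,
                         nCalls = 40L) {
    Xtr <- spectra(trainSet); ytr <- as.numeric(chlorophyll(trainSet))
    Xva <- spectra(val); yva <- as.numeric(chlorophyll(val))
    fits <- lapply(specs, function(s) fitLearner(s, Xtr, ytr, seed = seed))
    wts <- calibrateWeights(specs, Xtr, ytr, k = calibK, nCalls = nCalls,
                            seed = seed)
    pred_tr <- lapply(fits, predict, newdata = Xtr)
    pred_va <- lapply(fits, predict, newdata = Xva)
    pred_tr$ensemble <- ensemblePredict(fits, wts, Xtr)
    pred_va$ensemble <- ensemblePredict(fits, wts, Xva)
    rows <- do.call(rbind, lapply(names(pred_tr), function(m) data.frame(
        model = m,
        train_r2 = rSquared(ytr, pred_tr[[m]]),
        train_rmse = rmse(ytr, pred_tr[[m]]),
        val_r2 = rSquared(yva, pred_va[[m]]),
        val_rmse = rmse(yva, pred_va[[m]]),
        seed = seed, row.names = NULL)))
    list(rows = rows, fits = fits, weights = wts)
}

#' Baseline run: tune, fit and evaluate without augmentation
#'
#' Tunes the three base learners on the (un-augmented) training set,
#' refits them on the full training set, calibrates convex ensemble
#' weights, and reports train/validation R-squared and RMSE for each
#' learner and for the ensemble.
#'
#' @param train,val disjoint [SpectralSet-class]s from [splitDataset()].
#' @param seed integer seed for tuning, folds and learner randomness.
#' @param nTrials tuning trials per learner (default 30).
#' @param k folds of the tuning objective (default 5).
#' @param specs optional pre-tuned named list of 3 [LearnerSpec-class]s
#'   (skips tuning).
#' @param spaces optional named list of search spaces per learner kind.
#' @return data.frame with one row per model
#'   `(mode, noise_sigma, warp_magnitude, model, train_r2, train_rmse,
#'   val_r2, val_rmse, seed)`; the tuned specs, fitted learners and
#'   calibrated weights are attached as attributes `"specs"`, `"fits"`,
#'   `"weights"`.
#' @export
runBaseline <- function(train, val, seed = 42L, nTrials = 30L, k = 5L,
                        specs = NULL, spaces = NULL) {
    if (length(intersect(sampleIDs(train), sampleIDs(val))) > 0L)
        .data_error("train and validation sets overlap")
    if (is.null(specs))
        specs <- .tune_all(spectra(train), as.numeric(chlorophyll(train)),
                           nTrials, k, seed, spaces)
    res <- .run_setting(train, val, specs, seed)
    rows <- cbind(data.frame(mode = "baseline", noise_sigma = 0,
                             warp_magnitude = 0), res$rows)
    attr(rows, "specs") <- specs
    attr(rows, "fits") <- res$fits
    attr(rows, "weights") <- res$weights
    rows
}

#' Default augmentation grids
#'
#' Single-factor noise levels 0.001-0.008 (step 0.001), single-factor warp
#' magnitudes 0.01-0.07 (step 0.01), and the 16 composite noise x warp
#' combinations (noise 0.001-0.004 crossed with warp 0.01, 0.015, 0.02,
#' 0.025).
#'
#' @param mode `"noise"`, `"warp"` or `"composite"`.
#' @return data.frame with columns `noise_sigma` and `warp_magnitude`.
#' @export
defaultGrid <- function(mode = c("composite", "noise", "warp")) {
    mode <- match.arg(mode)
    switch(mode,
        noise = data.frame(noise_sigma = seq(0.001, 0.008, by = 0.001),
                           warp_magnitude = 0),
        warp = data.frame(noise_sigma = 0,
                          warp_magnitude = seq(0.01, 0.07, by = 0.01)),
        composite = expand.grid(
            warp_magnitude = c(0.01, 0.015, 0.02, 0.025),
            noise_sigma = c(0.001, 0.002, 0.003, 0.004))[, 2:1])
}

#' Augmentation grid experiment
#'
#' For every `(noise_sigma, warp_magnitude)` setting, rebuilds the
#' augmented training set from the same originals, runs the full
#' tune-fit-calibrate-evaluate chain, and appends one row per model. The
#' validation set is never augmented. A setting with both perturbations at
#' zero is run as the un-augmented baseline, so it reproduces
#' [runBaseline()] exactly under a shared seed.
#'
#' @param train,val disjoint [SpectralSet-class]s; `train` must contain
#'   only originals.
#' @param mode augmentation mode applied to non-zero settings.
#' @param settings data.frame of settings (default [defaultGrid()] for
#'   `mode`).
#' @param seed integer seed; per-setting augmentation seeds are derived
#'   from it.
#' @param nTrials,k tuning budget per setting.
#' @param reuseTuning if `TRUE`, tune once on the un-augmented training set
#'   and reuse those specifications for every setting (much cheaper).
#' @param nControl interior anchors of the warp fields.
#' @param spaces optional search-space overrides.
#' @param specs optional pre-tuned named list of 3 [LearnerSpec-class]s
#'   shared by every setting (implies `reuseTuning`), e.g. the `"specs"`
#'   attribute of a [runBaseline()] result.
#' @return data.frame with `|settings| x 4` rows (3 learners + ensemble).
#' @export
runAugmentationGrid <- function(train, val,
                                mode = c("composite", "noise", "warp"),
                                settings = NULL, seed = 42L, nTrials = 30L,
                                k = 5L, reuseTuning = FALSE, nControl = 4L,
                                spaces = NULL, specs = NULL) {
    mode <- match.arg(mode)
    if (is.null(settings)) settings <- defaultGrid(mode)
    if (nrow(settings) == 0L) .config_error("settings must be nonempty")
    if (!all(provenance(train) == "original"))
        .data_error("training set must contain only original samples")
    if (!is.null(specs)) reuseTuning <- TRUE
    sharedSpecs <- if (!is.null(specs)) specs
        else if (reuseTuning)
        .tune_all(spectra(train), as.numeric(chlorophyll(train)),
                  nTrials, k, seed, spaces) else NULL
    out <- vector("list", nrow(settings))
    for (i in seq_len(nrow(settings))) {
        sg <- settings$noise_sigma[i]; wm <- settings$warp_magnitude[i]
        trainSet <- if (sg == 0 && wm == 0) train
            else augmentTrainingSet(train, augmentConfig(
                mode = mode, noiseSigma = sg, warpMagnitude = wm,
                nControl = nControl, seed = .subseed(seed, 1000L + i)))
        specs <- if (reuseTuning) sharedSpecs
            else .tune_all(spectra(trainSet),
                           as.numeric(chlorophyll(trainSet)),
                           nTrials, k, seed, spaces)
        res <- .run_setting(trainSet, val, specs, seed)
        out[[i]] <- cbind(data.frame(mode = if (sg == 0 && wm == 0)
                                         "baseline" else mode,
                                     noise_sigma = sg, warp_magnitude = wm),
                          res$rows)
    }
    do.call(rbind, out)
}

#' Residual analysis
#'
#' Residuals `r = y - y_hat`, a Gaussian-kernel density summary (Silverman
#' bandwidth) over a fixed evaluation grid, and per-tertile mean residuals
#' of the observed values — the latter exposes range-dependent bias such as
#' underestimation of high-chlorophyll samples.
#'
#' @param y observed values.
#' @param yHat predicted values.
#' @return list with `residuals` (data.frame y, y_hat, residual),
#'   `density` (data.frame x, density) and `tertile_summary` (data.frame
#'   level, n, mean_residual).
#' @export
residualAnalysis <- function(y, yHat) {
    y <- as.numeric(y); yHat <- as.numeric(yHat)
    if (length(y) != length(yHat)) .config_error("length mismatch")
    r <- y - yHat
    dens <- if (stats::sd(r) == 0)
        data.frame(x = r[1L], density = Inf)
    else {
        d <- stats::density(r, bw = "nrd0", n = 512L)
        data.frame(x = d$x, density = d$y)
    }
    ord <- order(y, seq_along(y))
    n <- length(y)
    sizes <- rep(n %/% 3L, 3L); rem <- n %% 3L
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    lev <- character(n)
    lev[ord] <- rep(c("low", "medium", "high"), times = sizes)
    ts <- do.call(rbind, lapply(c("low", "medium", "high"), function(l)
        data.frame(level = l, n = sum(lev == l),
                   mean_residual = mean(r[lev == l]))))
    list(residuals = data.frame(y = y, y_hat = yHat, residual = r),
         density = dens, tertile_summary = ts)
}

#' Sample-size response curve
#'
#' Repeats the baseline pipeline on nested training subsets of increasing
#' size and reports, per subset fraction and model, the mean and standard
#' deviation of the validation RMSE across repeats. Within a repeat the
#' subsets are nested (a larger fraction contains every smaller one). The
#' `fraction = 1` entry of the first repeat is exactly a standard
#' [runBaseline()] run under the same seed.
#'
#' @param train,val disjoint [SpectralSet-class]s.
#' @param fractions training-set fractions to evaluate (each must leave at
#'   least `2 * k` samples).
#' @param nRepeats repeats per fraction (default 5).
#' @param seed integer seed.
#' @param nTrials,k tuning budget.
#' @param spaces optional search-space overrides.
#' @return data.frame `(fraction, n_train, model, mean_val_rmse,
#'   sd_val_rmse)`.
#' @export
sampleSizeCurve <- function(train, val, fractions = c(0.2, 0.4, 0.6, 0.8, 1),
                            nRepeats = 5L, seed = 42L, nTrials = 30L,
                            k = 5L, spaces = NULL) {
    ids <- sort(sampleIDs(train))
    nTr <- length(ids)
    acc <- list()
    for (r in seq_len(nRepeats)) {
        seed_r <- if (r == 1L) seed else .subseed(seed, 900L + r)
        perm <- withr::with_seed(.subseed(seed, 500L + r), sample(ids))
        for (fr in fractions) {
            nSub <- max(2L, floor(fr * nTr + 0.5))
            if (nSub < 2L * k)
                .config_error("fraction %.2f leaves fewer than 2k samples", fr)
            sub <- if (fr >= 1) train
                   else .subsetSamples(train, sort(perm[seq_len(nSub)]))
            rows <- runBaseline(sub, val, seed = seed_r, nTrials = nTrials,
                                k = k, spaces = spaces)
            rows$fraction <- fr; rows$repeat_id <- r; rows$n_train <- nSub
            acc[[length(acc) + 1L]] <- as.data.frame(rows)
        }
    }
    all <- do.call(rbind, acc)
    agg <- stats::aggregate(val_rmse ~ fraction + n_train + model, data = all,
        FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
    out <- data.frame(fraction = agg$fraction, n_train = agg$n_train,
                      model = agg$model,
                      mean_val_rmse = agg$val_rmse[, "mean"],
                      sd_val_rmse = agg$val_rmse[, "sd"])
    out[order(out$fraction, out$model), , drop = FALSE]
}
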