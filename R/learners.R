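#' Create a learner specification
#'
#' @param kind `"latent_linear"` (NIPALS PLS), `"ridge_linear"` or
#'   `"boosted_trees"`.
#' @param ... kind-specific hyperparameters overriding the defaults:
#'   `n_components` (latent_linear), `alpha` (ridge_linear),
#'   `n_estimators`, `max_depth`, `learning_rate`, `subsample`, `colsample`
#'   (boosted_trees).
#' @return a [LearnerSpec-class].
#' @examples
#' learnerSpec("ridge_linear", alpha = 0.5)
#' @export
learnerSpec <- function(kind, ...) {
    defaults <- switch(kind,
        latent_linear = list(n_components = 10L),
        ridge_linear = list(alpha = 1.0),
        boosted_trees = list(n_estimators = 200L, max_depth = 4L,
                             learning_rate = 0.1, subsample = 0.8,
                             colsample = 0.8),
        .config_error("unknown learner kind '%s'", kind))
    hp <- utils::modifyList(defaults, list(...))
    if (kind == "latent_linear" && hp$n_components < 1L)
        .config_error("n_components must be >= 1")
    if (kind == "ridge_linear" && hp$alpha <= 0)
        .config_error("alpha must be positive")
    new("LearnerSpec", kind = kind, hyperparams = hp)
}

setMethod("show", "LearnerSpec", function(object) {
    hp <- object@hyperparams
    cat(sprintf("LearnerSpec<%s>: %s\n", object@kind,
        paste(sprintf("%s=%s", names(hp),
                      vapply(hp, function(v) format(v, digits = 4), "")),
              collapse = ", ")))
})

# --- NIPALS PLS1 ------------------------------------------------------------
# Extracts components maximizing covariance between X and y. Returns weight
# and loading matrices plus per-component explained-y sums of squares, from
# which both the regression vector and VIP scores are derived.
.fit_nipals <- function(X, y, ncomp) {
    n <- nrow(X); p <- ncol(X)
    xm <- colMeans(X); ym <- mean(y)
    E <- sweep(X, 2L, xm); f <- y - ym
    W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
    q <- numeric(ncomp); ssy <- numeric(ncomp)
    Tm <- matrix(0, n, ncomp)
    a_used <- 0L
    for (a in seq_len(ncomp)) {
        w <- crossprod(E, f)
        nw <- sqrt(sum(w^2))
        if (nw < 1e-12) break
        w <- w / nw
        t <- E %*% w
        tt <- sum(t^2)
        if (tt < 1e-12) break
        pvec <- crossprod(E, t) / tt
        qa <- sum(f * t) / tt
        E <- E - tcrossprod(t, pvec)
        f <- f - qa * t
        W[, a] <- w; P[, a] <- pvec; q[a] <- qa
        Tm[, a] <- t; ssy[a] <- qa^2 * tt
        a_used <- a
    }
    if (a_used == 0L)
        .data_error("degenerate inputs: no covariance between X and y; check for constant spectra or labels")
    idx <- seq_len(a_used)
    W <- W[, idx, drop = FALSE]; P <- P[, idx, drop = FALSE]
    q <- q[idx]; ssy <- ssy[idx]
    B <- W %*% solve(crossprod(P, W), q)
    list(W = W, P = P, q = q, ssy = ssy, coef = as.numeric(B),
         xMean = xm, yMean = ym)
}

#' @describeIn fitLearner fit any of the three learner kinds.
#' @export
setMethod("fitLearner", "LearnerSpec",
function(spec, X, y, wavelengths = NULL, seed = 1L) {
    X <- .as_matrix_X(X)
    y <- as.numeric(y)
    if (nrow(X) < 2L) .data_error("need at least 2 samples to fit")
    if (length(y) != nrow(X)) .config_error("length(y) must equal nrow(X)")
    if (any(!is.finite(X)) || any(!is.finite(y)))
        .data_error("missing or non-finite values in the training data")
    axis <- if (!is.null(wavelengths)) as.numeric(wavelengths)
            else .axis_of(X)
    if (is.null(axis)) axis <- as.numeric(seq_len(ncol(X)))
    if (length(axis) != ncol(X))
        .config_error("wavelength axis length must equal ncol(X)")
    hp <- spec@hyperparams
    switch(spec@kind,
        latent_linear = {
            ncomp <- as.integer(hp$n_components)
            if (ncomp > min(nrow(X) - 1L, ncol(X)))
                .config_error("n_components exceeds min(n - 1, n_bands)")
            fit <- .fit_nipals(X, y, ncomp)
            new("PLSFit", spec = spec, axis = axis, weights = fit$W,
                loadings = fit$P, yloadings = fit$q,
                coefficients = fit$coef, xMean = fit$xMean,
                yMean = fit$yMean, ssy = fit$ssy)
        },
        ridge_linear = {
            alpha <- hp$alpha
            xm <- colMeans(X); ym <- mean(y)
            Xc <- sweep(X, 2L, xm); yc <- y - ym
            A <- crossprod(Xc)
            diag(A) <- diag(A) + alpha
            beta <- tryCatch(as.numeric(solve(A, crossprod(Xc, yc))),
                error = function(e) .data_error(
                    "ridge system is singular; increase alpha or remove constant bands"))
            new("RidgeFit", spec = spec, axis = axis, coefficients = beta,
                xMean = xm, yMean = ym)
        },
        boosted_trees = {
            Xu <- X; colnames(Xu) <- paste0("wl_", axis)
            dtrain <- xgboost::xgb.DMatrix(Xu, label = y, nthread = 1L)
            params <- list(
                max_depth = as.integer(hp$max_depth),
                eta = hp$learning_rate,
                subsample = hp$subsample,
                colsample_bytree = hp$colsample,
                objective = "reg:squarederror",
                tree_method = "hist", max_bin = 64L,
                nthread = 1L, seed = as.integer(seed) %% 2147483647L)
            bst <- xgboost::xgb.train(params = params, data = dtrain,
                                      nrounds = as.integer(hp$n_estimators),
                                      verbose = 0L)
            new("XGBFit", spec = spec, axis = axis, booster = bst)
        })
})

#' Predict chlorophyll from new spectra
#'
#' @param object a fitted learner.
#' @param newdata samples x bands matrix on the training wavelength axis
#'   (checked against numeric colnames when present).
#' @param ... unused.
#' @return numeric predictions, one per row of `newdata`, in row order.
#' @export
setMethod("predict", "PLSFit", function(object, newdata, ...) {
    newdata <- .as_matrix_X(newdata)
    .check_axis(object@axis, newdata)
    as.numeric(sweep(newdata, 2L, object@xMean) %*% object@coefficients +
               object@yMean)
})

#' @rdname predict-PLSFit-method
#' @export
setMethod("predict", "RidgeFit", function(object, newdata, ...) {
    newdata <- .as_matrix_X(newdata)
    .check_axis(object@axis, newdata)
    as.numeric(sweep(newdata, 2L, object@xMean) %*% object@coefficients +
               object@yMean)
})

#' @rdname predict-PLSFit-method
#' @export
setMethod("predict", "XGBFit", function(object, newdata, ...) {
    newdata <- .as_matrix_X(newdata)
    .check_axis(object@axis, newdata)
    colnames(newdata) <- paste0("wl_", object@axis)
    as.numeric(predict(object@booster,
                       xgboost::xgb.DMatrix(newdata, nthread = 1L)))
})

#' @describeIn vipScores VIP scores of a fitted PLS model:
#'   `VIP_j = sqrt(p * sum_a ssy_a (w_aj / ||w_a||)^2 / sum_a ssy_a)`, so
#'   that `sum_j VIP_j^2 = p`.
#' @export
setMethod("vipScores", "PLSFit", function(object) {
    W <- object@weights
    ssy <- object@ssy
    p <- nrow(W)
    Wn2 <- sweep(W^2, 2L, colSums(W^2), "/")
    vip <- sqrt(p * as.numeric(Wn2 %*% ssy) / sum(ssy))
    data.frame(wavelength_nm = object@axis, vip = vip, row.names = NULL)
})

#' @describeIn vipScores only latent-variable models carry VIP scores.
#' @export
setMethod("vipScores", "FittedLearner", function(object) {
    stop("VIP scores are defined only for latent_linear (PLS) models")
})

.importance_frame <- function(axis, score, model, topK) {
    p <- length(axis)
    if (topK > p) {
        warning(sprintf("topK (%d) exceeds number of bands (%d); truncated",
                        topK, p))
        topK <- p
    }
    ord <- order(-score, axis)
    out <- data.frame(wavelength_nm = axis[ord], importance = score[ord],
                      rank = seq_len(p), model = model, row.names = NULL)
    out[seq_len(topK), , drop = FALSE]
}

#' @describeIn bandImportances absolute ridge coefficients per band.
#' @export
setMethod("bandImportances", "RidgeFit", function(object, topK = 20L)
    .importance_frame(object@axis, abs(object@coefficients),
                      "ridge_linear", topK))

#' @describeIn bandImportances VIP scores per band.
#' @export
setMethod("bandImportances", "PLSFit", function(object, topK = 20L)
    .importance_frame(object@axis, vipScores(object)$vip,
                      "latent_linear", topK))

#' @describeIn bandImportances gain-based tree importances mapped back to
#'   physical wavelengths (bands never used by a tree score 0).
#' @export
setMethod("bandImportances", "XGBFit", function(object, topK = 20L) {
    imp <- xgboost::xgb.importance(model = object@booster)
    score <- setNames(rep(0, length(object@axis)),
                      paste0("wl_", object@axis))
    if (nrow(imp) > 0) score[imp$Feature] <- imp$Gain
    .importance_frame(object@axis, as.numeric(score), "boosted_trees", topK)
})
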