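#' Convex-weighted ensemble prediction
#'
#' `y_hat = w_1 y_boost + w_2 y_pls + w_3 y_ridge`, elementwise, with
#' nonnegative weights summing to one. Learner order follows the weight
#' order: (boosted_trees, latent_linear, ridge_linear).
#'
#' @param fits list of 3 fitted learners on the same wavelength axis.
#' @param weights an [EnsembleWeights-class] or numeric(3) on the simplex.
#' @param X samples x bands matrix to predict.
#' @return numeric ensemble predictions.
#' @export
ensemblePredict <- function(fits, weights, X) {
    w <- if (is(weights, "EnsembleWeights")) weights@weights
         else as.numeric(weights)
    if (length(fits) != length(w))
        .config_error("number of learners (%d) and weights (%d) differ",
                      length(fits), length(w))
    P <- vapply(fits, function(f) predict(f, X), numeric(nrow(X)))
    as.numeric(P %*% w)
}

# map 2 free coordinates in [0,1]^2 onto the probability simplex
.simplex_map <- function(u) {
    w1 <- u[1]; w2 <- u[2] * (1 - u[1])
    w <- c(w1, w2, 1 - w1 - w2)
    w / sum(w)
}

#' Calibrate convex ensemble weights against cross-validated MSE
#'
#' The training samples are partitioned into `k` seeded folds; each of the
#' three (already tuned) base learners is refitted on every fold's training
#' part and predicts the held-out part, yielding one out-of-fold prediction
#' per learner per sample. The weight vector minimizing the mean squared
#' error of the weighted out-of-fold predictions is then searched on the
#' probability simplex: the three vertices and the uniform point are always
#' evaluated (so the calibrated ensemble can never do worse than the best
#' single learner under this objective), followed by seeded random simplex
#' draws and a Nelder-Mead polish on the 2 free simplex coordinates.
#'
#' @param specs named list of 3 tuned [LearnerSpec-class]s in the order
#'   (boosted_trees, latent_linear, ridge_linear).
#' @param X,y training spectra and labels.
#' @param k folds (default 3).
#' @param nCalls total candidate evaluations before the polish (default 40).
#' @param seed integer seed fixing folds, learner randomness and draws.
#' @return an [EnsembleWeights-class].
#' @export
calibrateWeights <- function(specs, X, y, k = 3L, nCalls = 40L, seed = 1L) {
    if (length(specs) != 3L) .config_error("exactly 3 learner specs required")
    X <- .as_matrix_X(X); y <- as.numeric(y)
    fold <- .cv_folds(nrow(X), k, .subseed(seed, 3L))
    P <- matrix(NA_real_, nrow(X), 3L)
    for (f in seq_len(k)) {
        tr <- fold != f
        for (m in seq_len(3L)) {
            fit <- fitLearner(specs[[m]], X[tr, , drop = FALSE], y[tr],
                              seed = seed)
            P[!tr, m] <- predict(fit, X[!tr, , drop = FALSE])
        }
    }
    cv_mse <- function(w) mean((y - as.numeric(P %*% w))^2)
    single <- apply(P, 2L, function(p) mean((y - p)^2))
    cand <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), rep(1, 3) / 3)
    nRand <- max(0L, nCalls - length(cand))
    Ur <- withr::with_seed(.subseed(seed, 5L),
                           matrix(runif(2L * nRand), nRand, 2L))
    for (i in seq_len(nRand)) cand[[length(cand) + 1L]] <- .simplex_map(Ur[i, ])
    val <- vapply(cand, cv_mse, numeric(1))
    w_best <- cand[[which.min(val)]]
    # polish on the 2 free coordinates (clamped to [0,1]^2)
    u0 <- c(w_best[1], if (w_best[1] < 1) w_best[2] / (1 - w_best[1]) else 0)
    opt <- optim(u0, function(u)
        cv_mse(.simplex_map(pmin(pmax(u, 0), 1))),
        method = "Nelder-Mead", control = list(maxit = 200L))
    w_opt <- .simplex_map(pmin(pmax(opt$par, 0), 1))
    if (cv_mse(w_opt) < min(val)) w_best <- w_opt
    w_best <- pmax(w_best, 0); w_best <- w_best / sum(w_best)
    names(w_best) <- c("boosted_trees", "latent_linear", "ridge_linear")
    new("EnsembleWeights", weights = w_best, cvMSE = cv_mse(w_best),
        singleCvMSE = setNames(single, names(w_best)))
}

setMethod("show", "EnsembleWeights", function(object) {
    w <- object@weights
    cat("EnsembleWeights:",
        paste(sprintf("%s=%.3f", names(w), w), collapse = " "),
        sprintf("(CV MSE %.4f)\n", object@cvMSE))
})
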