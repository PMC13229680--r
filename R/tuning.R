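#' Default bounded hyperparameter search spaces
#'
#' One entry per tunable hyperparameter: `lower`, `upper`, plus optional
#' `log = TRUE` (sampled on the log scale) and `integer = TRUE` (continuous
#' proposals rounded). The boosted-tree bounds are desk-scale defaults for
#' single-threaded fitting on ~600-band spectra; widen them for larger
#' budgets. All bounds are overridable by passing a modified space to
#' [tuneLearner()].
#'
#' @param kind learner kind.
#' @return named list of parameter definitions.
#' @export
searchSpace <- function(kind) {
    switch(kind,
        latent_linear = list(
            n_components = list(lower = 1, upper = 30, integer = TRUE)),
        ridge_linear = list(
            alpha = list(lower = 1e-4, upper = 1e3, log = TRUE)),
        boosted_trees = list(
            n_estimators = list(lower = 50, upper = 400, integer = TRUE),
            max_depth = list(lower = 2, upper = 6, integer = TRUE),
            learning_rate = list(lower = 0.02, upper = 0.3, log = TRUE),
            subsample = list(lower = 0.5, upper = 1.0),
            colsample = list(lower = 0.5, upper = 1.0)),
        .config_error("unknown learner kind '%s'", kind))
}

# seeded fold assignment shared by every spec evaluated in one search
.cv_folds <- function(n, k, seed) {
    if (k < 2L) .config_error("k must be >= 2")
    if (n < 2L * k) .config_error("need at least 2k samples for %d folds", k)
    withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
}

#' Cross-validated mean R-squared of a learner specification
#'
#' The tuning objective: the training samples are partitioned into `k`
#' seed-determined folds (identical folds for every specification sharing
#' the same seed, so comparisons are paired); for each fold the learner is
#' fitted on the remaining folds and scored on the held-out fold with the
#' coefficient of determination computed against the held-out fold's own
#' mean; the k fold scores are averaged.
#'
#' @param spec a [LearnerSpec-class].
#' @param X,y training spectra and labels.
#' @param k number of folds (default 5).
#' @param seed integer seed fixing the fold assignment and learner
#'   randomness.
#' @return mean held-out R-squared across folds.
#' @export
cvMeanR2 <- function(spec, X, y, k = 5L, seed = 1L) {
    X <- .as_matrix_X(X); y <- as.numeric(y)
    fold <- .cv_folds(nrow(X), k, seed)
    mean(vapply(seq_len(k), function(f) {
        tr <- fold != f
        fit <- fitLearner(spec, X[tr, , drop = FALSE], y[tr], seed = seed)
        rSquared(y[!tr], predict(fit, X[!tr, , drop = FALSE]))
    }, numeric(1)))
}

.sample_params <- function(space, u) {
    hp <- list()
    for (j in seq_along(space)) {
        def <- space[[j]]
        val <- if (isTRUE(def$log))
            exp(log(def$lower) + u[j] * (log(def$upper) - log(def$lower)))
        else def$lower + u[j] * (def$upper - def$lower)
        if (isTRUE(def$integer)) val <- as.integer(round(val))
        hp[[names(space)[j]]] <- val
    }
    hp
}

#' Tune a learner by seeded random search over a bounded space
#'
#' Evaluates `nTrials` candidate specifications drawn uniformly (log scale
#' where declared) from the bounded search space, scoring each with
#' [cvMeanR2()] under one shared fold assignment, and returns the argmax.
#' Random search is used as the bounded black-box optimizer behind the
#' tuning contract; any sampler respecting the bounds could be substituted.
#' Integer dimensions round the continuous proposal.
#'
#' @param kind learner kind.
#' @param X,y training spectra and labels.
#' @param space bounded search space (default [searchSpace()] for `kind`).
#' @param nTrials number of candidate evaluations (default 30).
#' @param k folds of the inner objective (default 5).
#' @param seed integer seed: fixes both the candidate draws and the fold
#'   assignment.
#' @return list with `bestSpec` ([LearnerSpec-class]), `bestCvR2`, and
#'   `trials` (data.frame log of every candidate and its objective).
#' @export
tuneLearner <- function(kind, X, y, space = searchSpace(kind),
                        nTrials = 30L, k = 5L, seed = 1L) {
    d <- length(space)
    U <- withr::with_seed(.subseed(seed, 7L),
                          matrix(runif(nTrials * d), nTrials, d))
    foldSeed <- .subseed(seed, 11L)
    logs <- vector("list", nTrials)
    best <- NULL; bestR2 <- -Inf
    firstErr <- NULL; nFail <- 0L
    for (t in seq_len(nTrials)) {
        hp <- .sample_params(space, U[t, ])
        spec <- do.call(learnerSpec, c(list(kind = kind), hp))
        obj <- tryCatch(cvMeanR2(spec, X, y, k = k, seed = foldSeed),
                        error = function(e) { e })
        if (inherits(obj, "error")) {
            if (is.null(firstErr)) firstErr <- obj
            nFail <- nFail + 1L
            obj <- NA_real_
        } else if (obj > bestR2) {
            bestR2 <- obj; best <- spec
        }
        logs[[t]] <- data.frame(trial = t, as.data.frame(hp),
                                cv_r2 = obj)
    }
    if (nFail == nTrials)
        stop(sprintf("all %d trials failed; first failure: %s",
                     nTrials, conditionMessage(firstErr)))
    list(bestSpec = best, bestCvR2 = bestR2,
         trials = do.call(rbind, logs))
}
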