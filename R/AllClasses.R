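#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @importFrom stats approx coef cor density optim predict quantile rnorm
#'   runif sd setNames spline var
#' @importFrom utils head
NULL

.PROVENANCE_LEVELS <- c("original", "noise", "warp", "composite")
.LEARNER_KINDS <- c("boosted_trees", "latent_linear", "ridge_linear")

#' SpectralSet: labelled reflectance spectra on a shared wavelength axis
#'
#' `SpectralSet` extends [SummarizedExperiment::SummarizedExperiment] to hold
#' an n-sample collection of reflectance spectra on one strictly increasing
#' wavelength axis, together with a continuous chlorophyll reference value per
#' sample and a provenance record distinguishing original measurements from
#' augmented variants (which carry the identifier of their parent sample).
#'
#' The single assay `"reflectance"` is stored bands x samples (rows are
#' wavelengths, as features), following the SummarizedExperiment convention;
#' [spectra()] returns the samples x bands orientation used by the
#' regression code.
#'
#' @slot .  inherits all slots from `SummarizedExperiment`; `rowData` holds
#'   `wavelength_nm`, `colData` holds `chlorophyll`, `provenance` and
#'   `parent_id`.
#' @seealso [SpectralSet()] for the constructor, [spectra()],
#'   [chlorophyll()], [wavelengths()], [provenance()].
#' @export
setClass("SpectralSet", contains = "SummarizedExperiment")

.validSpectralSet <- function(object) {
    msg <- character()
    if (!("reflectance" %in% SummarizedExperiment::assayNames(object)))
        return("assay 'reflectance' is required")
    R <- SummarizedExperiment::assay(object, "reflectance")
    wl <- SummarizedExperiment::rowData(object)$wavelength_nm
    cd <- SummarizedExperiment::colData(object)
    if (is.null(wl)) msg <- c(msg, "rowData must contain 'wavelength_nm'")
    else {
        if (any(!is.finite(wl)) || any(wl <= 0))
            msg <- c(msg, "wavelengths must be finite and positive")
        if (length(wl) >= 2 && any(diff(wl) <= 0))
            msg <- c(msg, "wavelengths must be strictly increasing")
    }
    if (any(!is.finite(R)))
        msg <- c(msg, "reflectance contains missing or non-finite values")
    ids <- colnames(object)
    if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
        msg <- c(msg, "sample identifiers must be unique, non-empty colnames")
    for (col in c("chlorophyll", "provenance", "parent_id"))
        if (!(col %in% colnames(cd)))
            msg <- c(msg, sprintf("colData must contain '%s'", col))
    if ("chlorophyll" %in% colnames(cd) && any(!is.finite(cd$chlorophyll)))
        msg <- c(msg, "chlorophyll labels must be finite")
    if ("provenance" %in% colnames(cd)) {
        prov <- cd$provenance
        if (!all(prov %in% .PROVENANCE_LEVELS))
            msg <- c(msg, sprintf("provenance must be one of: %s",
                                  paste(.PROVENANCE_LEVELS, collapse = ", ")))
        if ("parent_id" %in% colnames(cd)) {
            pid <- cd$parent_id
            orig <- prov == "original"
            if (any(!is.na(pid[orig])))
                msg <- c(msg, "original samples must have parent_id = NA")
            aug <- !orig
            if (any(is.na(pid[aug])))
                msg <- c(msg, "augmented samples must record a parent_id")
            bad <- aug & !is.na(pid) & !(pid %in% ids[orig])
            if (any(bad))
                msg <- c(msg, sprintf(
                    "parent_id of augmented sample(s) %s not found among originals",
                    paste(head(ids[bad], 3), collapse = ", ")))
        }
    }
    if (length(msg)) msg else TRUE
}

setValidity("SpectralSet", .validSpectralSet)

#' Warp field: a smooth displacement of the wavelength axis
#'
#' Describes a smooth signed displacement d(lambda) of the wavelength axis,
#' pinned to zero at both endpoints, bounded by `magnitude * span`, and
#' guaranteed to keep the remapped axis lambda + d(lambda) strictly
#' increasing (no fold-over). Created by [makeWarpField()] and consumed by
#' [applyWarp()].
#'
#' @slot axis numeric, the wavelength axis the field was built for (nm).
#' @slot displacement numeric, d(lambda) evaluated on `axis` (nm).
#' @slot controlWavelengths numeric, anchor positions (nm).
#' @slot controlDisplacements numeric, anchor displacements (nm).
#' @slot magnitude numeric(1), maximum fractional displacement of the span.
#' @export
setClass("WarpField",
    representation(axis = "numeric", displacement = "numeric",
                   controlWavelengths = "numeric",
                   controlDisplacements = "numeric",
                   magnitude = "numeric"))

setValidity("WarpField", function(object) {
    msg <- character()
    ax <- object@axis; d <- object@displacement
    if (length(ax) != length(d))
        return("axis and displacement lengths differ")
    span <- diff(range(ax))
    if (max(abs(d)) > object@magnitude * span + 1e-9)
        msg <- c(msg, "displacement exceeds magnitude * span bound")
    if (abs(d[1]) > 1e-12 || abs(d[length(d)]) > 1e-12)
        msg <- c(msg, "endpoint displacements must be zero")
    if (any(diff(ax + d) <= 0))
        msg <- c(msg, "remapped axis must be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' Learner specification
#'
#' Identifies one of the three heterogeneous base regressors and its
#' hyperparameters: `"latent_linear"` (NIPALS partial least squares, tunable
#' `n_components`), `"ridge_linear"` (closed-form ridge on centered data,
#' tunable `alpha`), or `"boosted_trees"` (gradient-boosted regression trees,
#' tunable `n_estimators`, `max_depth`, `learning_rate`, `subsample`,
#' `colsample`). Build with [learnerSpec()].
#'
#' @slot kind character(1), one of the three learner kinds.
#' @slot hyperparams named list of kind-specific hyperparameters.
#' @export
setClass("LearnerSpec",
    representation(kind = "character", hyperparams = "list"))

setValidity("LearnerSpec", function(object) {
    if (!(object@kind %in% .LEARNER_KINDS))
        return(sprintf("kind must be one of: %s",
                       paste(.LEARNER_KINDS, collapse = ", ")))
    TRUE
})

#' Fitted learner objects
#'
#' Virtual parent of the three fitted-model classes. All carry the training
#' wavelength axis so that [predict()] can reject inputs measured on a
#' different axis.
#'
#' @slot spec the [LearnerSpec-class] the model was fitted from.
#' @slot axis numeric, training wavelength axis (nm).
#' @export
setClass("FittedLearner",
    representation("VIRTUAL", spec = "LearnerSpec", axis = "numeric"))

#' @rdname FittedLearner-class
#' @slot weights,loadings,yloadings NIPALS weight/loading matrices.
#' @slot coefficients regression vector on centered data.
#' @slot xMean,yMean training centering statistics.
#' @slot ssy per-component explained y sum of squares (for VIP).
#' @export
setClass("PLSFit", contains = "FittedLearner",
    representation(weights = "matrix", loadings = "matrix",
                   yloadings = "numeric", coefficients = "numeric",
                   xMean = "numeric", yMean = "numeric", ssy = "numeric"))

#' @rdname FittedLearner-class
#' @export
setClass("RidgeFit", contains = "FittedLearner",
    representation(coefficients = "numeric", xMean = "numeric",
                   yMean = "numeric"))

#' @rdname FittedLearner-class
#' @slot booster the underlying gradient-boosting handle.
#' @export
setClass("XGBFit", contains = "FittedLearner",
    representation(booster = "ANY"))

#' Convex ensemble weights
#'
#' A length-3 nonnegative weight vector over the base learners
#' (boosted_trees, latent_linear, ridge_linear) summing to one, calibrated by
#' [calibrateWeights()] against k-fold cross-validated MSE.
#'
#' @slot weights named numeric(3) on the probability simplex.
#' @slot cvMSE numeric(1), the cross-validated MSE attained.
#' @slot singleCvMSE named numeric(3), per-learner CV MSE under the same folds.
#' @export
setClass("EnsembleWeights",
    representation(weights = "numeric", cvMSE = "numeric",
                   singleCvMSE = "numeric"))

setValidity("EnsembleWeights", function(object) {
    w <- object@weights
    msg <- character()
    if (length(w) != 3L) msg <- c(msg, "exactly 3 weights are required")
    if (any(w < -1e-12)) msg <- c(msg, "weights must be nonnegative")
    if (abs(sum(w) - 1) > 1e-9) msg <- c(msg, "weights must sum to 1")
    if (length(msg)) msg else TRUE
})
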