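#' @describeIn SpectralSet-class wavelength axis in nm.
#' @param x,object a `SpectralSet` (or fitted learner where noted).
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @describeIn SpectralSet-class samples x bands reflectance matrix, with
#'   sample identifiers as rownames and wavelengths as colnames.
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @describeIn SpectralSet-class chlorophyll reference values, named by
#'   sample identifier.
#' @export
setGeneric("chlorophyll", function(x) standardGeneric("chlorophyll"))

#' @describeIn SpectralSet-class sample identifiers.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @describeIn SpectralSet-class provenance tag per sample (`original`,
#'   `noise`, `warp` or `composite`).
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @describeIn SpectralSet-class parent identifier per sample (`NA` for
#'   originals).
#' @export
setGeneric("parentIDs", function(x) standardGeneric("parentIDs"))

#' Fit a base learner
#'
#' @param spec a [LearnerSpec-class].
#' @param X samples x bands reflectance matrix.
#' @param y chlorophyll labels, length `nrow(X)`.
#' @param wavelengths numeric axis for the columns of `X` (defaults to
#'   numeric colnames of `X`).
#' @param seed integer seed forwarded to any stochastic learner internals.
#' @return a [FittedLearner-class] subclass.
#' @export
setGeneric("fitLearner",
    function(spec, X, y, wavelengths = NULL, seed = 1L)
        standardGeneric("fitLearner"))

#' Variable importance in projection (VIP) scores
#'
#' @param object a fitted latent-variable (PLS) model.
#' @return data.frame with `wavelength_nm` and `vip`; the squared scores
#'   average to 1 across bands.
#' @export
setGeneric("vipScores", function(object) standardGeneric("vipScores"))

#' Per-band importances of a fitted learner
#'
#' @param object a fitted learner.
#' @param topK how many top bands to return.
#' @return data.frame `(wavelength_nm, importance, rank, model)` sorted by
#'   descending importance, ties broken toward shorter wavelength first.
#' @export
setGeneric("bandImportances",
    function(object, topK = 20L) standardGeneric("bandImportances"))
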