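#' Construct a SpectralSet
#'
#' @param reflectance samples x bands numeric matrix of reflectance values.
#' @param wavelengths strictly increasing numeric wavelength axis (nm), one
#'   entry per column of `reflectance`.
#' @param chlorophyll numeric chlorophyll reference value per sample
#'   (unit-agnostic continuous reals).
#' @param ids unique character sample identifiers; defaults to the rownames
#'   of `reflectance`.
#' @param provenance character provenance tag per sample; defaults to
#'   `"original"`.
#' @param parentID character parent identifier per sample (`NA` for
#'   originals).
#' @return a [SpectralSet-class].
#' @examples
#' wl <- seq(400, 1000, by = 50)
#' X <- matrix(runif(3 * length(wl)), 3, length(wl))
#' ss <- SpectralSet(X, wl, chlorophyll = c(20, 40, 60),
#'                   ids = c("a", "b", "c"))
#' dim(spectra(ss))
#' @export
SpectralSet <- function(reflectance, wavelengths, chlorophyll,
                        ids = rownames(reflectance),
                        provenance = "original",
                        parentID = NA_character_) {
    reflectance <- as.matrix(reflectance)
    n <- nrow(reflectance)
    if (is.null(ids))
        stop("sample identifiers are required (ids or rownames)")
    ids <- trimws(as.character(ids))
    provenance <- rep_len(as.character(provenance), n)
    parentID <- rep_len(as.character(parentID), n)
    if (length(wavelengths) != ncol(reflectance))
        stop("length(wavelengths) must equal ncol(reflectance)")
    if (length(chlorophyll) != n)
        stop("length(chlorophyll) must equal the number of samples")
    A <- t(reflectance)
    dimnames(A) <- list(NULL, ids)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(reflectance = A),
        rowData = S4Vectors::DataFrame(wavelength_nm = as.numeric(wavelengths)),
        colData = S4Vectors::DataFrame(
            chlorophyll = as.numeric(chlorophyll),
            provenance = provenance,
            parent_id = parentID,
            row.names = ids))
    new("SpectralSet", se)
}

#' @rdname SpectralSet
#' @aliases wavelengths,SpectralSet-method
#' @param x a `SpectralSet`.
#' @export
setMethod("wavelengths", "SpectralSet", function(x)
    as.numeric(SummarizedExperiment::rowData(x)$wavelength_nm))

#' @rdname SpectralSet
#' @aliases spectra,SpectralSet-method
#' @export
setMethod("spectra", "SpectralSet", function(x) {
    M <- t(SummarizedExperiment::assay(x, "reflectance"))
    colnames(M) <- as.character(wavelengths(x))
    M
})

#' @rdname SpectralSet
#' @aliases chlorophyll,SpectralSet-method
#' @export
setMethod("chlorophyll", "SpectralSet", function(x)
    setNames(as.numeric(SummarizedExperiment::colData(x)$chlorophyll),
             colnames(x)))

#' @rdname SpectralSet
#' @aliases sampleIDs,SpectralSet-method
#' @export
setMethod("sampleIDs", "SpectralSet", function(x) colnames(x))

#' @rdname SpectralSet
#' @aliases provenance,SpectralSet-method
#' @export
setMethod("provenance", "SpectralSet", function(x)
    setNames(as.character(SummarizedExperiment::colData(x)$provenance),
             colnames(x)))

#' @rdname SpectralSet
#' @aliases parentIDs,SpectralSet-method
#' @export
setMethod("parentIDs", "SpectralSet", function(x)
    setNames(as.character(SummarizedExperiment::colData(x)$parent_id),
             colnames(x)))

setMethod("show", "SpectralSet", function(object) {
    wl <- wavelengths(object)
    prov <- table(factor(provenance(object), levels = .PROVENANCE_LEVELS))
    cat(sprintf("SpectralSet: %d samples x %d bands [%.0f-%.0f nm]\n",
                ncol(object), nrow(object), min(wl), max(wl)))
    chl <- chlorophyll(object)
    cat(sprintf("  chlorophyll: %.2f-%.2f (mean %.2f)\n",
                min(chl), max(chl), mean(chl)))
    cat("  provenance:",
        paste(sprintf("%s=%d", names(prov), prov), collapse = " "), "\n")
})

# internal: rebuild a SpectralSet row-subset by sample ids (keeps parent
# references valid only when parents are retained; used by split on originals)
.subsetSamples <- function(x, ids) {
    stopifnot(all(ids %in% colnames(x)))
    x[, ids]
}
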