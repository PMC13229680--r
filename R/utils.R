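# classed conditions: configuration errors are caller mistakes (bad
# parameters), data errors are problems with the data itself
.config_error <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
                        class = c("leafspec_config_error", "leafspec_error")))
}

.data_error <- function(fmt, ...) {
    stop(errorCondition(sprintf(fmt, ...),
                        class = c("leafspec_data_error", "leafspec_error")))
}

# deterministic sub-stream seeds below 2^31, so one user-facing seed can
# drive several independent random stages
.subseed <- function(seed, k) {
    as.integer((as.double(seed) %% 1e6) * 2039 + 100003 * k) %% 2147483629L
}

.as_matrix_X <- function(X) {
    X <- as.matrix(X)
    if (!is.numeric(X)) .data_error("reflectance matrix must be numeric")
    X
}

# wavelength axis attached to a plain matrix via numeric colnames, if any
.axis_of <- function(X) {
    cn <- colnames(X)
    if (is.null(cn)) return(NULL)
    suppressWarnings(ax <- as.numeric(cn))
    if (any(is.na(ax))) NULL else ax
}

.check_axis <- function(fitted_axis, X) {
    if (ncol(X) != length(fitted_axis))
        .data_error("input has %d bands but the model was trained on %d",
                    ncol(X), length(fitted_axis))
    ax <- .axis_of(X)
    if (!is.null(ax) && !isTRUE(all.equal(ax, fitted_axis, tolerance = 1e-8)))
        .data_error("input wavelength axis differs from the training axis")
    invisible(TRUE)
}
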