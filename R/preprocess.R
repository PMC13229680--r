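#' Moving-average smoothing
#'
#' Centered moving-average filter along the wavelength axis with a
#' shrinking-window edge policy: near the spectrum ends the window is
#' truncated to the available bands, so the output has the same length as
#' the input and no reflectance is fabricated outside the measured range.
#' The window is counted in bands, not nm; the default of 63 bands is the
#' empirical compromise used for the reference dataset (small enough to
#' keep the 670-750 nm absorption/red-edge structure, large enough to
#' suppress high-frequency noise).
#'
#' @param x numeric vector (one spectrum), samples x bands matrix, or
#'   [SpectralSet-class].
#' @param window odd positive integer window width in bands.
#' @return same shape/class as the input, smoothed bandwise.
#' @export
movingAverage <- function(x, window = 63L) {
    window <- as.integer(window)
    if (is.na(window) || window < 1L || window %% 2L == 0L)
        .config_error("window must be an odd positive integer (got %s)",
                      as.character(window))
    if (is(x, "SpectralSet")) {
        X <- movingAverage(spectra(x), window)
        A <- t(X)
        dimnames(A) <- list(NULL, sampleIDs(x))
        out <- x
        SummarizedExperiment::assay(out, "reflectance",
                                    withDimnames = FALSE) <- A
        return(out)
    }
    smooth_vec <- function(v) {
        p <- length(v)
        if (window > p)
            .config_error("window (%d) exceeds number of bands (%d)",
                          window, p)
        h <- (window - 1L) %/% 2L
        cs <- c(0, cumsum(v))
        j <- seq_len(p)
        lo <- pmax(j - h, 1L); hi <- pmin(j + h, p)
        (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }
    if (is.matrix(x)) t(apply(x, 1L, smooth_vec)) else smooth_vec(x)
}

#' Per-wavelength Pearson correlation with the chlorophyll label
#'
#' For each band, the Pearson correlation between reflectance at that band
#' and the chlorophyll reference value across samples. Bands with zero
#' variance are flagged (`zero_variance = TRUE`, `r = NA`) rather than
#' silently zeroed.
#'
#' @param dataset a [SpectralSet-class] with at least 3 samples.
#' @return data.frame `(wavelength_nm, r, zero_variance)`.
#' @export
correlationProfile <- function(dataset) {
    X <- spectra(dataset)
    y <- as.numeric(chlorophyll(dataset))
    if (nrow(X) < 3L) .config_error("need at least 3 samples")
    if (stats::var(y) == 0) .data_error("chlorophyll label is constant")
    sds <- apply(X, 2L, stats::sd)
    flat <- sds == 0
    r <- rep(NA_real_, ncol(X))
    if (any(!flat))
        r[!flat] <- as.numeric(stats::cor(X[, !flat, drop = FALSE], y))
    data.frame(wavelength_nm = wavelengths(dataset), r = r,
               zero_variance = flat, row.names = NULL)
}

#' Stratify samples into chlorophyll levels
#'
#' Ranks samples by label and cuts the ranking into `nLevels` groups of
#' near-equal size (tertiles by default, labelled low/medium/high), ties
#' broken by identifier order. The reported cut points are the label values
#' at the group boundaries.
#'
#' @param dataset a [SpectralSet-class].
#' @param nLevels number of levels (default 3).
#' @return list with `assignment` (data.frame id, level), `cut_points`
#'   (numeric, length `nLevels - 1`) and `levels` (ordered level names).
#' @export
stratifyLevels <- function(dataset, nLevels = 3L) {
    n <- ncol(dataset)
    if (n < nLevels) .config_error("need at least nLevels samples")
    y <- as.numeric(chlorophyll(dataset))
    ids <- sampleIDs(dataset)
    if (length(unique(y)) == 1L)
        warning("all labels identical; every sample assigned the lowest level")
    lev_names <- if (nLevels == 3L) c("low", "medium", "high")
                 else paste0("L", seq_len(nLevels))
    ord <- order(y, ids)
    sizes <- rep(n %/% nLevels, nLevels)
    rem <- n %% nLevels
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    if (length(unique(y)) == 1L) {
        level <- rep(lev_names[1L], n)
        cut_points <- rep(y[1L], nLevels - 1L)
    } else {
        level <- character(n)
        level[ord] <- rep(lev_names, times = sizes)
        bounds <- cumsum(sizes)[-nLevels]
        cut_points <- y[ord][bounds]
    }
    list(assignment = data.frame(id = ids, level = level,
                                 stringsAsFactors = FALSE),
         cut_points = cut_points, levels = lev_names)
}

#' Train-anchored PCA score diagnostic
#'
#' Fits a principal-component basis on the training spectra only (centering
#' on train means, no scaling) and projects both training and validation
#' samples into it. This is a descriptive check that the random split
#' preserved the main spectral coverage, not a test of partition bias.
#'
#' @param train,val [SpectralSet-class] objects on the same axis.
#' @param nComponents number of components to return.
#' @return data.frame `(id, set, PC1, PC2, ...)` with attribute
#'   `explained_variance` (fraction per component).
#' @export
pcaScores <- function(train, val, nComponents = 2L) {
    Xtr <- spectra(train); Xva <- spectra(val)
    if (nrow(Xtr) < 2L) .data_error("need at least 2 training samples")
    nComponents <- as.integer(nComponents)
    if (nComponents > min(nrow(Xtr) - 1L, ncol(Xtr)))
        .config_error("nComponents exceeds min(n_train - 1, n_bands)")
    ctr <- colMeans(Xtr)
    pc <- stats::prcomp(Xtr, center = ctr, scale. = FALSE, rank. = nComponents)
    Str <- pc$x[, seq_len(nComponents), drop = FALSE]
    Sva <- scale(Xva, center = ctr, scale = FALSE) %*%
        pc$rotation[, seq_len(nComponents), drop = FALSE]
    out <- rbind(
        data.frame(id = sampleIDs(train), set = "train", Str,
                   check.names = FALSE, row.names = NULL),
        data.frame(id = sampleIDs(val), set = "val", Sva,
                   check.names = FALSE, row.names = NULL))
    ev <- pc$sdev^2 / sum(pc$sdev^2)
    attr(out, "explained_variance") <- ev[seq_len(nComponents)]
    out
}

#' Bandwise mean spectrum over a subset of samples
#'
#' @param dataset a [SpectralSet-class].
#' @param subsetIDs identifiers of the samples to average (default: all).
#' @return data.frame `(wavelength_nm, reflectance)`.
#' @export
meanSpectrum <- function(dataset, subsetIDs = sampleIDs(dataset)) {
    if (length(subsetIDs) == 0L) .config_error("subset must be nonempty")
    unknown <- setdiff(subsetIDs, sampleIDs(dataset))
    if (length(unknown))
        .data_error("unknown sample id(s): %s",
                    paste(head(unknown, 3), collapse = ", "))
    X <- spectra(dataset)[subsetIDs, , drop = FALSE]
    data.frame(wavelength_nm = wavelengths(dataset),
               reflectance = colMeans(X), row.names = NULL)
}
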