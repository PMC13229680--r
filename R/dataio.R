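#' Read and match a label table with a spectra table
#'
#' Reads two delimited tables — one with sample identifiers and a continuous
#' chlorophyll reference column, one with the same identifiers plus one
#' column per wavelength (header = wavelength in nm) — and establishes a
#' supervised sample set by one-to-one identifier matching. Identifiers are
#' compared by exact string match after whitespace stripping; rows present in
#' only one table are dropped and counted. The matched rows are sorted by
#' identifier so downstream splits depend on the identifier set, not on file
#' order.
#'
#' @param labelPath path to the label CSV (id column + target column).
#' @param spectraPath path to the spectra CSV (id column + numeric-nm
#'   headers).
#' @param idColumn name of the identifier column, present in both files.
#' @param targetColumn name of the chlorophyll reference column in the label
#'   file.
#' @return a list with `dataset` (a [SpectralSet-class]) and `report`, a
#'   one-row data.frame with counts `n_labels_read`, `n_spectra_read`,
#'   `n_matched`, `n_dropped_labels`, `n_dropped_spectra`.
#' @export
readMatchedDataset <- function(labelPath, spectraPath,
                               idColumn = "id", targetColumn = "chl") {
    if (!file.exists(labelPath))
        .config_error("label file not found: %s", labelPath)
    if (!file.exists(spectraPath))
        .config_error("spectra file not found: %s", spectraPath)
    labels <- utils::read.csv(labelPath, check.names = FALSE,
                              stringsAsFactors = FALSE)
    spec <- utils::read.csv(spectraPath, check.names = FALSE,
                            stringsAsFactors = FALSE)
    for (nm in c(idColumn, targetColumn))
        if (!(nm %in% colnames(labels)))
            .config_error("column '%s' missing from label table", nm)
    if (!(idColumn %in% colnames(spec)))
        .config_error("column '%s' missing from spectra table", idColumn)
    wl_cols <- setdiff(colnames(spec), idColumn)
    suppressWarnings(wl <- as.numeric(wl_cols))
    if (any(is.na(wl)))
        .config_error("non-numeric wavelength header(s): %s",
                      paste(head(wl_cols[is.na(wl)], 3), collapse = ", "))
    lab_ids <- trimws(as.character(labels[[idColumn]]))
    spc_ids <- trimws(as.character(spec[[idColumn]]))
    if (anyDuplicated(lab_ids))
        .data_error("duplicated identifier(s) in label table: %s",
                    paste(unique(lab_ids[duplicated(lab_ids)]), collapse = ", "))
    if (anyDuplicated(spc_ids))
        .data_error("duplicated identifier(s) in spectra table: %s",
                    paste(unique(spc_ids[duplicated(spc_ids)]), collapse = ", "))
    matched <- sort(intersect(lab_ids, spc_ids))
    if (length(matched) == 0L)
        .data_error("no identifiers are shared between the two tables")
    ord <- order(wl)
    X <- as.matrix(spec[match(matched, spc_ids), wl_cols[ord], drop = FALSE])
    storage.mode(X) <- "double"
    y <- as.numeric(labels[[targetColumn]][match(matched, lab_ids)])
    if (any(!is.finite(X)) || any(!is.finite(y)))
        .data_error("missing or non-finite values among matched rows")
    ds <- SpectralSet(X, wl[ord], y, ids = matched)
    report <- data.frame(
        n_labels_read = length(lab_ids),
        n_spectra_read = length(spc_ids),
        n_matched = length(matched),
        n_dropped_labels = length(lab_ids) - length(matched),
        n_dropped_spectra = length(spc_ids) - length(matched))
    list(dataset = ds, report = report)
}

#' Trim a dataset to a closed wavelength interval
#'
#' Keeps exactly the bands whose wavelength lies in `[loNm, hiNm]`
#' (endpoints included). Labels, identifiers and provenance are unchanged.
#' The default interval is the visible/red-edge/NIR window used for
#' chlorophyll modelling.
#'
#' @param dataset a [SpectralSet-class].
#' @param loNm,hiNm interval bounds in nm, `loNm < hiNm`.
#' @return the trimmed [SpectralSet-class].
#' @export
trimBands <- function(dataset, loNm = 400, hiNm = 1000) {
    if (!(loNm < hiNm))
        .config_error("trim interval requires loNm < hiNm (got %g, %g)",
                      loNm, hiNm)
    wl <- wavelengths(dataset)
    keep <- wl >= loNm & wl <= hiNm
    if (sum(keep) < 2L)
        .data_error("fewer than 2 bands inside [%g, %g] nm", loNm, hiNm)
    dataset[keep, ]
}

#' Split a dataset into train and validation sets
#'
#' Samples are sorted by identifier, then a seeded random subset of size
#' `floor(n * trainFraction + 0.5)` forms the training set; the rest form the
#' validation set. The same `(seed, n)` always yields the same identifier
#' sets, and sorting first makes membership independent of file row order.
#' With the reference 1,113-sample dataset and the default fraction this
#' gives a 779/334 partition.
#'
#' @param dataset a [SpectralSet-class] with at least 2 samples.
#' @param trainFraction fraction of samples assigned to training, in (0, 1).
#' @param seed integer seed controlling the permutation.
#' @return list with `train` and `val` [SpectralSet-class] objects.
#' @export
splitDataset <- function(dataset, trainFraction = 0.7, seed = 42L) {
    if (!(trainFraction > 0 && trainFraction < 1))
        .config_error("trainFraction must lie in (0, 1)")
    n <- ncol(dataset)
    if (n < 2L) .config_error("need at least 2 samples to split")
    nTrain <- floor(n * trainFraction + 0.5)
    if (nTrain < 1L || nTrain >= n)
        .config_error("degenerate partition: train size %d of %d", nTrain, n)
    ids <- sort(sampleIDs(dataset))
    idx <- withr::with_seed(seed, sample.int(n, nTrain))
    trainIDs <- ids[sort(idx)]
    valIDs <- setdiff(ids, trainIDs)
    list(train = .subsetSamples(dataset, trainIDs),
         val = .subsetSamples(dataset, valIDs))
}

#' Write / read a SpectralSet as a plain-text directory
#'
#' The on-disk schema is a directory containing `spectra.csv` (id +
#' wavelength columns), `labels.csv` (id, chlorophyll), `provenance.csv`
#' (id, provenance, parent_id) and `meta.yaml`. [readSpectralSet()] is the
#' inverse.
#'
#' @param dataset a [SpectralSet-class].
#' @param path directory to create/populate.
#' @return `path`, invisibly (write) or a [SpectralSet-class] (read).
#' @export
writeSpectralSet <- function(dataset, path) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    X <- spectra(dataset)
    spec_df <- data.frame(id = sampleIDs(dataset), X, check.names = FALSE)
    utils::write.csv(spec_df, file.path(path, "spectra.csv"),
                     row.names = FALSE)
    utils::write.csv(
        data.frame(id = sampleIDs(dataset),
                   chlorophyll = as.numeric(chlorophyll(dataset))),
        file.path(path, "labels.csv"), row.names = FALSE)
    utils::write.csv(
        data.frame(id = sampleIDs(dataset),
                   provenance = as.character(provenance(dataset)),
                   parent_id = as.character(parentIDs(dataset))),
        file.path(path, "provenance.csv"), row.names = FALSE)
    yaml::write_yaml(list(
        n_samples = ncol(dataset), n_bands = nrow(dataset),
        wavelength_range_nm = as.numeric(range(wavelengths(dataset))),
        written_by = "leafspec"), file.path(path, "meta.yaml"))
    invisible(path)
}

#' @rdname writeSpectralSet
#' @export
readSpectralSet <- function(path) {
    spec <- utils::read.csv(file.path(path, "spectra.csv"),
                            check.names = FALSE, stringsAsFactors = FALSE)
    lab <- utils::read.csv(file.path(path, "labels.csv"),
                           stringsAsFactors = FALSE)
    prov_path <- file.path(path, "provenance.csv")
    ids <- trimws(as.character(spec$id))
    wl_cols <- setdiff(colnames(spec), "id")
    X <- as.matrix(spec[, wl_cols, drop = FALSE])
    storage.mode(X) <- "double"
    y <- lab$chlorophyll[match(ids, trimws(as.character(lab$id)))]
    if (file.exists(prov_path)) {
        pv <- utils::read.csv(prov_path, stringsAsFactors = FALSE)
        m <- match(ids, trimws(as.character(pv$id)))
        provenance <- pv$provenance[m]
        parent <- as.character(pv$parent_id[m])
        parent[parent == "NA" | parent == ""] <- NA_character_
    } else {
        provenance <- "original"; parent <- NA_character_
    }
    SpectralSet(X, as.numeric(wl_cols), y, ids = ids,
                provenance = provenance, parentID = parent)
}
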