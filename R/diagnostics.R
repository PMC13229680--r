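#' First derivative of a spectrum
#'
#' Central differences on the (possibly non-uniform) wavelength axis,
#' `d_j = (R_{j+1} - R_{j-1}) / (lambda_{j+1} - lambda_{j-1})`, with
#' one-sided differences at the endpoints. Exact for affine spectra and for
#' quadratics at interior points.
#'
#' @param reflectance numeric vector, one spectrum.
#' @param axis strictly increasing wavelength axis (nm), same length.
#' @return numeric derivative, same length as the input.
#' @export
firstDerivative <- function(reflectance, axis) {
    p <- length(reflectance)
    if (p < 3L) .config_error("need at least 3 bands")
    if (length(axis) != p) .config_error("axis length mismatch")
    d <- numeric(p)
    d[1L] <- (reflectance[2L] - reflectance[1L]) / (axis[2L] - axis[1L])
    d[p] <- (reflectance[p] - reflectance[p - 1L]) / (axis[p] - axis[p - 1L])
    i <- 2:(p - 1L)
    d[i] <- (reflectance[i + 1L] - reflectance[i - 1L]) /
            (axis[i + 1L] - axis[i - 1L])
    d
}

#' Red-edge position of a spectrum
#'
#' Estimates the red-edge position as the wavelength of maximum first
#' derivative within the red-edge window (default 680-760 nm). By default
#' the discrete argmax is refined by a 3-point parabolic fit to the
#' derivative peak, giving a continuous (tie-free) position on a sampled
#' grid; set `refine = FALSE` for the raw grid argmax (ties broken toward
#' the longer wavelength). The estimate is invariant to multiplicative
#' brightness scaling. When the maximum sits on the window boundary the
#' result is flagged (`at_edge = TRUE`), which typically indicates a
#' spectrum without a red-edge rise in the window.
#'
#' @param reflectance numeric vector, one spectrum.
#' @param axis wavelength axis (nm).
#' @param window numeric(2) red-edge window in nm.
#' @param refine logical, apply sub-grid parabolic refinement.
#' @return list with `red_edge_nm`, `window` and `at_edge`.
#' @export
redEdgePosition <- function(reflectance, axis, window = c(680, 760),
                            refine = TRUE) {
    if (length(window) != 2L || window[1L] >= window[2L])
        .config_error("window must be (lo, hi) with lo < hi")
    d <- firstDerivative(reflectance, axis)
    inw <- which(axis >= window[1L] & axis <= window[2L])
    if (length(inw) < 3L)
        .config_error("red-edge window [%g, %g] covers fewer than 3 bands",
                      window[1L], window[2L])
    dw <- d[inw]
    # ties broken toward the longer wavelength
    j <- inw[max(which(dw == max(dw)))]
    at_edge <- j == inw[1L] || j == inw[length(inw)]
    pos <- axis[j]
    if (refine && !at_edge) {
        y1 <- d[j - 1L]; y2 <- d[j]; y3 <- d[j + 1L]
        denom <- y1 - 2 * y2 + y3
        if (denom < 0) {  # genuine local maximum
            # parabola through three points on a possibly non-uniform grid
            x1 <- axis[j - 1L]; x2 <- axis[j]; x3 <- axis[j + 1L]
            num <- (y1 - y2) * (x3^2 - x2^2) - (y3 - y2) * (x1^2 - x2^2)
            den <- 2 * ((y1 - y2) * (x3 - x2) - (y3 - y2) * (x1 - x2))
            if (den != 0) {
                cand <- num / den
                if (cand >= x1 && cand <= x3) pos <- cand
            }
        }
    }
    if (at_edge)
        warning("derivative maximum at the window edge; no red-edge rise detected in window")
    list(red_edge_nm = pos, window = window, at_edge = at_edge)
}

#' Red-edge positions stratified by chlorophyll level
#'
#' Computes the red-edge position of every sample and summarizes the
#' positions per chlorophyll level (from [stratifyLevels()]).
#'
#' @param dataset a [SpectralSet-class].
#' @param levels a [stratifyLevels()] result for `dataset` (computed if
#'   omitted).
#' @param window red-edge window in nm.
#' @param refine sub-grid refinement flag, see [redEdgePosition()].
#' @return list with `per_sample` (data.frame id, level, red_edge_nm,
#'   at_edge) and `summary` (data.frame level, n, mean_nm, sd_nm).
#' @export
stratifiedRedEdge <- function(dataset, levels = stratifyLevels(dataset),
                              window = c(680, 760), refine = TRUE) {
    X <- spectra(dataset)
    axis <- wavelengths(dataset)
    res <- lapply(seq_len(nrow(X)), function(i)
        redEdgePosition(X[i, ], axis, window, refine))
    per_sample <- data.frame(
        id = sampleIDs(dataset),
        level = levels$assignment$level[
            match(sampleIDs(dataset), levels$assignment$id)],
        red_edge_nm = vapply(res, `[[`, numeric(1), "red_edge_nm"),
        at_edge = vapply(res, `[[`, logical(1), "at_edge"),
        row.names = NULL)
    present <- intersect(levels$levels, unique(per_sample$level))
    summary <- do.call(rbind, lapply(present, function(l) {
        v <- per_sample$red_edge_nm[per_sample$level == l]
        data.frame(level = l, n = length(v), mean_nm = mean(v),
                   sd_nm = if (length(v) > 1L) stats::sd(v) else NA_real_)
    }))
    list(per_sample = per_sample, summary = summary)
}
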