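#' Augmentation configuration
#'
#' Bundles the perturbation settings for [augmentTrainingSet()]: additive
#' Gaussian noise in reflectance units, smooth wavelength warping expressed
#' as a fraction of the modelled span, or their sequential composite
#' (warp first, then noise). The default search bounds mirror the
#' physically plausible ranges used in the grid experiments: noise sigma in
#' [0.001, 0.008] and warp magnitude in [0.01, 0.07].
#'
#' @param mode one of `"noise"`, `"warp"`, `"composite"`.
#' @param noiseSigma standard deviation of the additive Gaussian noise
#'   (reflectance units), `>= 0`.
#' @param warpMagnitude maximum displacement of the wavelength axis as a
#'   fraction of the axis span, `>= 0` (0.07 on a 600 nm span allows up to
#'   42 nm of drift).
#' @param nControl number of interior anchor points of the warp field.
#' @param seed integer seed; one seed drives all per-sample draws.
#' @return a list of class `"AugmentConfig"`.
#' @export
augmentConfig <- function(mode = c("composite", "noise", "warp"),
                          noiseSigma = 0.002, warpMagnitude = 0.02,
                          nControl = 4L, seed = 42L) {
    mode <- match.arg(mode)
    if (noiseSigma < 0) .config_error("noiseSigma must be nonnegative")
    if (warpMagnitude < 0) .config_error("warpMagnitude must be nonnegative")
    if (nControl < 2L) .config_error("nControl must be >= 2")
    structure(list(mode = mode, noiseSigma = noiseSigma,
                   warpMagnitude = warpMagnitude,
                   nControl = as.integer(nControl),
                   seed = as.integer(seed)),
              class = "AugmentConfig")
}

#' Additive Gaussian measurement noise
#'
#' Adds i.i.d. Normal(0, sigma^2) noise to every entry, emulating random
#' sensor noise. No clipping is applied: at the plausible sigmas (<= 0.008)
#' negative reflectance is vanishingly rare on leaf spectra; values below
#' -0.05 trigger a warning as a gross-error flag.
#'
#' @param X numeric vector or samples x bands matrix.
#' @param sigma noise standard deviation, `>= 0`.
#' @param seed integer seed for reproducibility.
#' @return perturbed copy of `X`, same shape.
#' @export
addGaussianNoise <- function(X, sigma, seed = 1L) {
    if (sigma < 0) .config_error("sigma must be nonnegative")
    if (sigma == 0) return(X)
    eps <- withr::with_seed(seed, rnorm(length(X), 0, sigma))
    out <- X + eps
    if (any(out < -0.05))
        warning("noise produced reflectance below -0.05; check sigma scale")
    out
}

#' Draw a smooth random warp field for a wavelength axis
#'
#' Interior anchor displacements are drawn Uniform(-m*span, +m*span) at
#' `nControl` equally spaced interior positions, the endpoints are pinned at
#' zero, and the field is interpolated with a natural cubic spline over the
#' full axis. The field is then rescaled (if needed) so that
#' `max |d| <= magnitude * span` and the remap `lambda + d(lambda)` stays
#' strictly increasing (no fold-over).
#'
#' @param axis strictly increasing numeric wavelength axis (nm).
#' @param magnitude maximum fractional displacement of the span, `>= 0`.
#' @param nControl number of interior anchors (default 4).
#' @param seed integer seed.
#' @return a [WarpField-class].
#' @export
makeWarpField <- function(axis, magnitude, nControl = 4L, seed = 1L) {
    if (magnitude < 0) .config_error("magnitude must be nonnegative")
    if (nControl < 2L) .config_error("nControl must be >= 2")
    if (any(diff(axis) <= 0)) .data_error("axis must be strictly increasing")
    span <- diff(range(axis))
    interior <- seq(min(axis), max(axis),
                    length.out = nControl + 2L)[-c(1L, nControl + 2L)]
    ctrl_wl <- c(min(axis), interior, max(axis))
    disp <- withr::with_seed(seed,
        runif(nControl, -magnitude * span, magnitude * span))
    ctrl_d <- c(0, disp, 0)
    d <- if (magnitude == 0) rep(0, length(axis))
         else spline(ctrl_wl, ctrl_d, xout = axis, method = "natural")$y
    # cubic interpolation can overshoot the anchor range: enforce the bound
    mx <- max(abs(d))
    if (mx > magnitude * span && mx > 0)
        d <- d * (magnitude * span) / mx
    # enforce strict monotonicity of the remap by the largest admissible
    # uniform rescale of the displacements
    dl <- diff(axis); dd <- diff(d)
    neg <- dd < 0
    if (any(dl + dd <= 0)) {
        s_max <- min(dl[neg] / (-dd[neg]))
        d <- d * 0.95 * s_max
    }
    new("WarpField", axis = as.numeric(axis), displacement = as.numeric(d),
        controlWavelengths = ctrl_wl, controlDisplacements = ctrl_d,
        magnitude = magnitude)
}

#' Apply a warp field to spectra
#'
#' Each output value is the linear interpolation of the input spectrum
#' evaluated at the remapped position `lambda + d(lambda)`, clamped to the
#' axis range at the boundaries. Because the remap is strictly increasing,
#' monotone segments of the spectrum stay monotone.
#'
#' @param X numeric vector or samples x bands matrix on `axis`.
#' @param axis the wavelength axis of `X`.
#' @param field a [WarpField-class] built for `axis`.
#' @return warped copy of `X`, same shape.
#' @export
applyWarp <- function(X, axis, field) {
    if (!isTRUE(all.equal(as.numeric(axis), field@axis, tolerance = 1e-9)))
        .data_error("warp field was built for a different axis")
    q <- pmin(pmax(axis + field@displacement, min(axis)), max(axis))
    warp_vec <- function(v) approx(axis, v, xout = q, rule = 2)$y
    if (is.matrix(X)) t(apply(X, 1L, warp_vec)) else warp_vec(X)
}

#' Composite perturbation: warp, then noise
#'
#' Applies one fresh random warp field per sample (sample-state shape drift)
#' followed by one fresh additive-noise draw (sensor noise), in that fixed
#' order so the noise stays white on top of the drifted shape.
#'
#' @param X samples x bands matrix.
#' @param axis wavelength axis of `X`.
#' @param sigma noise standard deviation.
#' @param magnitude warp magnitude (fraction of span).
#' @param nControl interior anchors of each warp field.
#' @param seed integer seed driving all draws.
#' @return perturbed copy of `X`.
#' @export
compositePerturb <- function(X, axis, sigma, magnitude, nControl = 4L,
                             seed = 1L) {
    X <- .as_matrix_X(X)
    W <- X
    for (i in seq_len(nrow(X))) {
        f <- makeWarpField(axis, magnitude, nControl,
                           seed = .subseed(seed, i))
        W[i, ] <- applyWarp(X[i, ], axis, f)
    }
    addGaussianNoise(W, sigma, seed = .subseed(seed, nrow(X) + 1L))
}

#' Build a leakage-safe augmented training set
#'
#' Returns the original training samples together with exactly one
#' perturbed variant per original (the set doubles), the variant inheriting
#' its parent's chlorophyll label and recording the augmentation mode and
#' parent identifier in its provenance. The input must contain only
#' original-provenance samples, which prevents compounding augmentation and
#' — together with augmenting after the train/validation split — guarantees
#' that no variant of a validation sample can reach training.
#'
#' @param train a [SpectralSet-class] of original samples only.
#' @param config an [augmentConfig()].
#' @return a [SpectralSet-class] with `2 n` samples.
#' @export
augmentTrainingSet <- function(train, config) {
    stopifnot(inherits(config, "AugmentConfig"))
    if (!all(provenance(train) == "original"))
        .data_error("training set already contains augmented samples")
    X <- spectra(train)
    axis <- wavelengths(train)
    seed <- config$seed
    V <- switch(config$mode,
        noise = addGaussianNoise(X, config$noiseSigma,
                                 seed = .subseed(seed, 1L)),
        warp = {
            W <- X
            for (i in seq_len(nrow(X))) {
                f <- makeWarpField(axis, config$warpMagnitude,
                                   config$nControl, seed = .subseed(seed, i))
                W[i, ] <- applyWarp(X[i, ], axis, f)
            }
            W
        },
        composite = compositePerturb(X, axis, config$noiseSigma,
                                     config$warpMagnitude, config$nControl,
                                     seed = seed))
    ids <- sampleIDs(train)
    aug_ids <- paste0(ids, "_", config$mode)
    SpectralSet(rbind(X, V), axis,
                chlorophyll = c(chlorophyll(train), chlorophyll(train)),
                ids = c(ids, aug_ids),
                provenance = c(rep("original", length(ids)),
                               rep(config$mode, length(ids))),
                parentID = c(rep(NA_character_, length(ids)), ids))
}
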