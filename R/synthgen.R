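#' Synthetic leaf-spectrum generator configuration
#'
#' The generator emulates the structural features of leaf reflectance in
#' the 400-1000 nm window that the pipeline exploits: chlorophyll-dependent
#' visible absorption (a green peak near 550 nm whose amplitude decreases
#' with chlorophyll), a red edge whose inflection tracks chlorophyll
#' (`lambda_re = 690 + 0.5 * chl` nm), a near-infrared plateau, and a water
#' absorption dip near 970 nm. It is phenomenological (logistic + Gaussian
#' features), not a radiative-transfer model.
#'
#' @param nSamples number of samples to generate.
#' @param axis wavelength axis (nm), default 400-1000 at 1 nm (601 bands).
#' @param chlRange uniform sampling range of the chlorophyll label,
#'   default (10, 70).
#' @param noiseSD additive measurement noise SD in reflectance units
#'   (default 0.003).
#' @param brightnessSD SD of the multiplicative log-normal brightness
#'   factor (default 0.05).
#' @param labelNoiseSD SD of additive reference-measurement error on the
#'   label (default 0).
#' @param seed integer seed.
#' @return list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(nSamples = 1000L, axis = seq(400, 1000, by = 1),
                            chlRange = c(10, 70), noiseSD = 0.003,
                            brightnessSD = 0.05, labelNoiseSD = 0,
                            seed = 7L) {
    if (chlRange[1L] <= 0 || diff(chlRange) <= 0)
        .config_error("chlRange must be positive and increasing")
    if (min(axis) < 400 - 1e-9 || max(axis) > 1000 + 1e-9)
        .config_error("axis must lie within [400, 1000] nm")
    structure(list(nSamples = as.integer(nSamples), axis = as.numeric(axis),
                   chlRange = chlRange, noiseSD = noiseSD,
                   brightnessSD = brightnessSD, labelNoiseSD = labelNoiseSD,
                   seed = as.integer(seed)),
              class = "SyntheticConfig")
}

# noiseless reflectance model: brightness * (baseline + red-edge sigmoid +
# green peak - water dip)
.synth_noiseless <- function(chl, axis, brightness = 1) {
    lambda_re <- 690 + 0.5 * chl
    g <- 0.15 * exp(-chl / 40)
    r0 <- 0.05 +
        0.45 * stats::plogis((axis - lambda_re) / 15) +
        g * exp(-(axis - 550)^2 / (2 * 30^2)) -
        0.06 * exp(-(axis - 975)^2 / (2 * 25^2))
    brightness * r0
}

#' Generate one synthetic leaf spectrum
#'
#' @param chl chlorophyll value, within the configured range.
#' @param config a [syntheticConfig()].
#' @param seed integer seed for the brightness and noise draws.
#' @return list with `wavelength_nm`, `reflectance` (clipped to [0, 1]) and
#'   `truth` (chl, brightness, noiseless spectrum, red-edge inflection
#'   `lambda_re = 690 + 0.5 * chl`).
#' @export
generateSpectrum <- function(chl, config = syntheticConfig(), seed = 1L) {
    if (chl < config$chlRange[1L] || chl > config$chlRange[2L])
        .config_error("chl = %g outside configured range [%g, %g]", chl,
                      config$chlRange[1L], config$chlRange[2L])
    axis <- config$axis
    draws <- withr::with_seed(seed, list(
        b = exp(rnorm(1L, 0, config$brightnessSD)),
        eps = rnorm(length(axis), 0, config$noiseSD)))
    r0 <- .synth_noiseless(chl, axis, draws$b)
    r <- pmin(pmax(r0 + draws$eps, 0), 1)
    list(wavelength_nm = axis, reflectance = r,
         truth = list(chl = chl, brightness = draws$b, noiseless = r0,
                      lambda_re = 690 + 0.5 * chl))
}

#' Generate a synthetic chlorophyll-labelled spectral dataset
#'
#' Chlorophyll values are drawn uniformly over the configured range;
#' identifiers are `SYN-000001` upward; the label equals the generator
#' chlorophyll (plus optional reference-measurement error). Output is
#' deterministic for a given config (including seed).
#'
#' @param config a [syntheticConfig()].
#' @return list with `dataset` (a [SpectralSet-class]) and `truth`
#'   (data.frame id, chl, brightness, lambda_re).
#' @export
generateDataset <- function(config = syntheticConfig()) {
    n <- config$nSamples
    if (n < 1L) .config_error("nSamples must be >= 1")
    axis <- config$axis
    chl <- withr::with_seed(config$seed,
        runif(n, config$chlRange[1L], config$chlRange[2L]))
    X <- matrix(0, n, length(axis))
    bright <- numeric(n)
    for (i in seq_len(n)) {
        sp <- generateSpectrum(chl[i], config,
                               seed = .subseed(config$seed, i))
        X[i, ] <- sp$reflectance
        bright[i] <- sp$truth$brightness
    }
    y <- chl
    if (config$labelNoiseSD > 0)
        y <- y + withr::with_seed(.subseed(config$seed, n + 1L),
                                  rnorm(n, 0, config$labelNoiseSD))
    ids <- sprintf("SYN-%06d", seq_len(n))
    list(dataset = SpectralSet(X, axis, y, ids = ids),
         truth = data.frame(id = ids, chl = chl, brightness = bright,
                            lambda_re = 690 + 0.5 * chl, row.names = NULL))
}
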