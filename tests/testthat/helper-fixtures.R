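# Shared fixtures: everything is generated in code at test time.

# small random labelled spectral set (no leaf structure; for plumbing tests)
make_random_set <- function(n = 10, p = 8, seed = 1,
                            wl = seq(400, length.out = p, by = 10)) {
  withr::with_seed(seed, {
    X <- matrix(runif(n * p, 0.1, 0.6), n, p)
    y <- runif(n, 10, 70)
  })
  SpectralSet(X, wl, y, ids = sprintf("S%03d", seq_len(n)))
}

# small synthetic leaf set with real structure (for modelling tests)
make_leaf_set <- function(n = 60, seed = 11, noiseSD = 0.003,
                          step = 5) {
  cfg <- syntheticConfig(nSamples = n, axis = seq(400, 1000, by = step),
                         noiseSD = noiseSD, seed = seed)
  generateDataset(cfg)
}

# cheap search spaces so tuning-dependent tests stay fast
fast_spaces <- function() {
  list(
    latent_linear = list(
      n_components = list(lower = 1, upper = 8, integer = TRUE)),
    ridge_linear = list(
      alpha = list(lower = 1e-3, upper = 100, log = TRUE)),
    boosted_trees = list(
      n_estimators = list(lower = 20, upper = 60, integer = TRUE),
      max_depth = list(lower = 2, upper = 3, integer = TRUE),
      learning_rate = list(lower = 0.05, upper = 0.3, log = TRUE),
      subsample = list(lower = 0.7, upper = 1.0),
      colsample = list(lower = 0.7, upper = 1.0)))
}

# write a labelled pair of CSV files for dataio tests; returns the paths
write_pair <- function(dir, ids_lab, ids_spec, p = 4, seed = 3,
                       dup_label = NULL) {
  wl <- seq(500, length.out = p, by = 10)
  lab <- data.frame(id = c(ids_lab, dup_label),
                    chl = seq_along(c(ids_lab, dup_label)) + 10)
  spc <- withr::with_seed(seed, {
    m <- matrix(runif(length(ids_spec) * p), length(ids_spec), p)
    df <- data.frame(id = ids_spec, m)
    colnames(df) <- c("id", wl)
    df
  })
  lp <- file.path(dir, "labels.csv"); sp <- file.path(dir, "spectra.csv")
  write.csv(lab, lp, row.names = FALSE)
  write.csv(spc, sp, row.names = FALSE)
  list(labels = lp, spectra = sp, wl = wl)
}
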