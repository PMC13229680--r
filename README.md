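# leafspec

Hyperspectral estimation of leaf chlorophyll under small-sample conditions,
built as an R package around two ideas:

1. **Physically constrained spectral augmentation** — expand a small
   training set with label-preserving perturbations of the reflectance
   spectra: additive Gaussian noise (sensor noise, sigma in 0.001–0.008
   reflectance units) and smooth wavelength warping (calibration/sample
   drift, magnitude 0.01–0.07 of the axis span), applied **only** to
   training originals so no variant of a validation sample can leak into
   training.
2. **A convex-weighted heterogeneous ensemble** — gradient-boosted trees,
   partial least squares (NIPALS) and ridge regression behind one
   fit/predict contract, each tuned by maximizing the 5-fold
   cross-validated mean R²,

   maxθ (1/5) Σₖ R²(y⁽ᵏ⁾, ŷ⁽ᵏ⁾(θ)),

   then combined as

   ŷ_ens = w₁·ŷ_XGB + w₂·ŷ_PLS + w₃·ŷ_Ridge,  wₘ ≥ 0, Σ wₘ = 1,

   with the weights calibrated against 3-fold cross-validated MSE on the
   training set. Evaluation uses R² and RMSE.

The package is aimed at plant-phenotyping and chemometrics work where
spectra are 400–1000 nm leaf reflectance, labels are continuous chlorophyll
reference values, and sample sizes are in the hundreds. A synthetic
leaf-spectrum generator (chlorophyll-dependent visible absorption, a
chlorophyll-tracking red edge at 690 + 0.5·chl nm, an NIR plateau, a
~970 nm water dip) makes every stage testable without downloading data.

## Worked example

```r
library(leafspec)

# 300 synthetic leaf spectra, 400-1000 nm at 1 nm, chlorophyll in (10, 70)
g  <- generateDataset(syntheticConfig(nSamples = 300, seed = 7))
ds <- movingAverage(g$dataset, 63)          # window-63 smoothing
sp <- splitDataset(ds, 0.7, seed = 42)      # seeded 70/30 split

# leakage-safe composite augmentation of the training set (warp then noise)
aug <- augmentTrainingSet(sp$train,
  augmentConfig("composite", noiseSigma = 0.002, warpMagnitude = 0.02,
                seed = 42))
aug
#> SpectralSet: 420 samples x 601 bands [400-1000 nm]
#>   chlorophyll: 10.50-69.33 (mean 40.74)
#>   provenance: original=210 noise=0 warp=0 composite=210

# tune the three learners, calibrate convex ensemble weights, evaluate
res <- runBaseline(sp$train, sp$val, seed = 42, nTrials = 10)
res[, c("model", "train_r2", "train_rmse", "val_r2", "val_rmse")]
#>           model train_r2 train_rmse val_r2 val_rmse
#> 1 boosted_trees   0.9999     0.1887 0.9936   1.3624
#> 2 latent_linear   0.9974     0.8194 0.9977   0.8236
#> 3  ridge_linear   0.9973     0.8322 0.9977   0.8133
#> 4      ensemble   0.9981     0.6906 0.9981   0.7382
attr(res, "weights")
#> EnsembleWeights: boosted_trees=0.165 latent_linear=0.323 ridge_linear=0.512 (CV MSE 0.6013)
```

The ensemble's validation RMSE (0.74 chlorophyll units) undercuts the best
single model (ridge, 0.81): the three learners' errors are not aligned, and
the convex weights exploit that. The red-edge diagnostic recovers the
physiological ordering of the generator — its position shifts longward with
chlorophyll level:

```r
stratifiedRedEdge(sp$val)$summary
#>    level  n mean_nm  sd_nm
#> 1    low 30  701.67 4.7773
#> 2 medium 30  712.47 4.4208
#> 3   high 30  719.70 2.9042
```

The grid harness (`runAugmentationGrid`) repeats the tune–fit–calibrate–
evaluate chain over the 8 noise levels, 7 warp magnitudes, or the 16
composite noise × warp combinations, always rebuilding the augmented
training set from the same originals and never touching validation.
Interpretability outputs are `vipScores()` (PLS variable importance in
projection, Σ VIP² = p), ridge coefficient magnitudes and gain-based tree
importances, all mapped to physical wavelengths via `bandImportances()`.

A thin command-line dispatcher over these functions ships at
`inst/exec/leafspec.R` (subcommands `simulate`, `match`, `preprocess`,
`augment`, `train`, `grid`, `diagnose`).

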