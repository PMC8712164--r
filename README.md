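# osteotex

Texture-based classification of bone radiographs in R.

Malignant bone lesions change the texture of an X-ray: the affected
region shows widely scattered intensities concentrated on few gray levels
(high variance, low Shannon entropy), a shifted histogram skewness, and a
ragged "moth-eaten" margin, where benign findings have smooth,
well-defined borders. `osteotex` implements a classical pipeline that
turns a 2-D grayscale radiograph into a nine-feature texture descriptor
and classifies it as *cancerous* or *healthy*:

1. 3×3 median denoising and unsharp-mask sharpening;
2. Canny edge detection (Sobel/Prewitt available) and region-of-interest
   extraction as the bounding box of the largest 8-connected edge
   component;
3. features: four gray-level co-occurrence matrix statistics — contrast
   `Σ(i−j)²A_ij`, correlation `Σ(i−μ_i)(j−μ_j)A_ij/(σ_iσ_j)`, energy
   `ΣA_ij²`, homogeneity `ΣA_ij/(1+|i−j|)` — histogram skewness
   `Σ(GL_s−μ)³k_s/((N−1)σ³)`, Shannon entropy `E(X) = −Σp log₂ p` and its
   σ-weighted product `E(X)·D(X)` with `D(X) = E(X)·σ`, the Gini
   inequality index `GI = 2Σ i·X₍ᵢ₎/(nΣX) − (n+1)/n` of the line-Hough
   accumulator votes, and a 384-long HOG block (25×25 resize, 3×3 cells,
   6 orientation bins);
4. a soft-margin linear SVM (C = 1) or a 100-tree random forest, with
   per-feature z-scoring learned on training folds only, and stratified
   k-fold cross-validation reporting accuracy / precision / recall / F1
   with *cancerous* as the positive class.

Because clinical images cannot be redistributed, the package ships a
synthetic bone-phantom generator (`generate_phantom`, `generate_dataset`)
that reproduces the class contrasts above with controllable effect sizes
and realistic acquisition nuisance (exposure gain, tone-curve gamma,
illumination ramp, sensor noise). Every pipeline stage is validated
against closed-form and brute-force oracles plus end-to-end phantom
experiments; see `vignettes/osteotex-methods.Rmd` for the full design
rationale.

## Worked example

```r
library(osteotex)

ds  <- generate_dataset(n_cancerous = 20, n_healthy = 14, seed = 42)
ft  <- extract_feature_table(ds$images, with_hog = TRUE)
res <- kfold_cv(ft, k = 5, model_kind = "linear_svm", seed = 42)
res$confusion
#> <confusion_matrix> (positive = cancerous)
#>                pred cancerous pred healthy
#> true cancerous             18            2
#> true healthy                3           11
str(res$metrics)
#> List of 4
#>  $ accuracy : num 85.3
#>  $ precision: num 85.7
#>  $ recall   : num 90
#>  $ f1       : num 87.8
```

Out of 20 cancerous phantoms the cross-validated SVM recovers 18 (recall
90%), misclassifying 3 of 14 healthy ones (precision 85.7%); pooled
accuracy is 85.3%. Feature distributions can be summarised for box-plot
inspection:

```r
boxplot_table(ft[, c("id", "label", FEATURE_NAMES)])[1:4, ]
#>    feature      min      q1 median     q3    max
#> 1  entropy  5.43674 5.94714 6.2358 6.4685 6.8320
#> 2   energy  0.00612 0.00982 0.0136 0.0181 0.0319
#> 3     gini  0.67189 0.68796 0.6950 0.7022 0.7579
#> 4 skewness -0.45658 0.15767 0.4510 0.7049 1.1088
```

Single images go through `load_image()` (PNG/TIFF/JPEG; RGB converted by
ITU-R 601 luminance, 16-bit rescaled to [0, 255]), `preprocess()`,
`detect_edges()`, `extract_roi()`, `crop()` and `extract_features()`.

A thin command-line wrapper covers the same workflow from a shell:

```sh
exec/osteotex synth --n-cancerous 65 --n-healthy 40 --out data/ --seed 42
exec/osteotex features --data data/ --out features.csv
exec/osteotex train --data features.csv --model svm --cv 5 --seed 42 --out metrics.json
```

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "osteotex", load_package = "installed")'
```

The suite covers per-module unit tests against independent oracles
(naive double-loop GLCM features, pairwise-difference Gini, per-pixel
median, brute-force connected components), property-style invariants on
seeded random inputs, and the end-to-end phantom study (feature-direction
checks, HOG-advantage direction over ten seeded repetitions,
byte-identical determinism of a seeded pipeline run).

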