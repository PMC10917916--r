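# mammofuse

Two-class (benign vs. malignant) mammogram mass classification as a
reusable, fully tested R pipeline — built for researchers who want to
study, extend or stress-test this family of methods without GPU training
runs or access-restricted clinical images.

The pipeline chains five components:

1. **Deep features.** Two bespoke bottleneck-residual convolutional
   networks — a parallel-branch *three-block* model (15.9M learnable
   parameters) and a single-path *four-block* model (25.1M) — consume
   227×227×3 images and expose a 2,048-wide global-average-pool (GAP)
   feature vector per image. Grad-CAM heatmaps localize the image regions
   driving a prediction.
2. **Kernel-CCA + entropy fusion.** With Gaussian kernels
   K<sub>ij</sub> = exp(−‖f<sub>i</sub>−f<sub>j</sub>‖²/2σ²) per view, the
   regularized kernel-CCA eigenproblem
   max<sub>ξ,η</sub> ξ′K<sub>u</sub>K<sub>v</sub>η subject to
   ξ′K<sub>u</sub>K<sub>u</sub>ξ = η′K<sub>v</sub>K<sub>v</sub>η = 1
   yields the first canonical correlation ρ as a fusion diagnostic; the
   fused matrix is the entropy-weighted concatenation
   [F₁ | F₂] · diag(H<sub>c</sub>/max H<sub>c</sub>), giving N×4,096 from
   two N×2,048 views.
3. **Q-GNDO selection.** A quantum-behaved generalized normal
   distribution optimizer searches binary column masks with wrapper cost
   0.99·(1−cvAccuracy) + 0.01·(selected/D).
4. **Classification.** Five shallow neural-network presets (narrow /
   medium / wide / bilayered / trilayered), 10-fold stratified
   cross-validation, and a full metric panel: accuracy, macro sensitivity
   and precision, F1, FNR, G-measure, MCC, Cohen's kappa, AUC.
5. **Paired t analysis.** t = √N·μ/σ on absolute accuracy differences of
   two classifiers across experiments, with the critical interval from the
   t distribution.

A synthetic-data module generates seedable stand-ins for every stage:
lesion-bearing two-class images with controllable separability and known
lesion masks, feature pairs with a planted canonical correlation, and
selection benchmarks with known informative columns. Everything is
deterministic given a seed.

The CNN layer machinery (im2col convolutions, batch normalization,
pooling, backpropagation, SGD-momentum) is implemented in
R + RcppArmadillo inside the package — no deep-learning framework is
required.

## Worked example

```r
library(mammofuse)

## the two architectures and their parameter budgets
net <- buildNetwork("three_block", seed = 1)
net
#> Network 'three_block' (input 227x227x3): 15,904,834 parameters, untrained

## fusion of two views with a planted canonical correlation of 0.8
pair <- generateCorrelatedPair(n = 120, p1 = 6, p2 = 6, r = 0.8, seed = 2)
fused <- fuseFeatures(pair$F1, pair$F2)
fused
#> FusedFeatures: 120 x 12 (rho = 0.8591)

## wrapper selection on a benchmark with 5 planted informative columns
bench <- generateSelectionBenchmark(n = 200, pInf = 5, pNoise = 20, seed = 3)
sel <- selectFeatures(bench$X, bench$y, cfg = list(n = 10, iters = 10, seed = 3))
sel
#> SelectionResult: 20/25 columns, cost = 0.1070, CV accuracy = 0.900
mean(bench$informativeIdx %in% which(selectionMask(sel)))
#> [1] 1

## cross-validated evaluation on the selected columns
crossvalEvaluate(bench$X[, selectionMask(sel)], bench$y,
                 preset = "bilayered", folds = 10, seed = 4)
#> MetricsReport (rows = truth)
#>            pred
#> truth       benign malignant
#>   benign        89        11
#>   malignant     12        88
#>    accuracy sensitivity   precision          f1         fnr   g_measure
#>       88.50       88.50       88.50       88.50       11.50       88.50
#>         mcc       kappa         auc
#>       77.00       77.00        0.96

## paired t analysis of two classifiers across four experiments
pairedTTest(a = c(94.3, 94.6, 94.3, 96.2), b = c(94.9, 93.4, 93.1, 96.1))
#> Paired t: mean |diff| = 0.775, sd = 0.531, t = 2.919 (dof = 3)
#>   interval at p = 0.05: (-3.182, 3.182) -> t inside
```

The numbers read: the fusion diagnostic ρ = 0.859 recovers the planted
correlation 0.8 to within kernel-CCA's expected upward bias; the selector
keeps all 5 informative columns (recall 1.0) at a cost dominated by the
10% cross-validation error; the bilayered classifier reaches 88.5%
pooled 10-fold accuracy on the selected columns with κ = MCC = 77; and
the four-experiment accuracy table gives t = 2.919, inside the ±3.182
critical interval at p = 0.05 — no significant accuracy difference
between the two classifiers.

`runPipeline(defaultPipelineConfig(...))` chains all stages (simulate →
split → augment → train → extract → fuse → select → classify → t-test)
with per-stage artifacts, file-hash manifest and resume;
`inst/cli/mammofuse.R` wraps the same functions as shell subcommands.
The methods vignette (`vignettes/methods.Rmd`) documents the model,
parameter defaults, numerical choices and limitations.

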