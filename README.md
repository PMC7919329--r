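# livseg

Binary semantic segmentation of the **liver** and of **liver lesions
(tumors)** in axial CT slices, built around a reduced-filter U-Net with a
class-balancing training pipeline. The package targets researchers who
want a fully inspectable, dependency-light implementation of this model
family in R: the network, its gradients and the Adam optimizer are
implemented natively (R + C++ BLAS kernels), with no deep-learning
framework required.

## The method

Three models share one architecture and differ only in inputs and
targets:

| experiment          | input                          | target      | default loss   |
|---------------------|--------------------------------|-------------|----------------|
| `liver`             | abdominal slice                | liver mask  | weighted dice  |
| `tumor_from_liver`  | slice × liver mask             | tumor mask  | weighted dice  |
| `tumor_from_abdomen`| abdominal slice                | tumor mask  | BCE            |

The network is a U-shaped encoder–decoder: four contracting blocks of
two (3×3 conv → ReLU → batch norm) units with 2×2 max pooling and 0.5
dropout, filter counts 16→32→64→128; a two-convolution bottleneck; four
expanding blocks of stride-2 transposed convolution, skip concatenation
and two convolution units; and a 1×1 convolution + sigmoid head. The
reduced filter widths cut trainable parameters to ~1/18 of the base-64
equivalent.

Training minimizes the weighted dice loss

    Loss = −W · (2·TP + ε) / (2·TP + FP + FN + ε),

with soft (probabilistic) counts for differentiability, or binary
cross-entropy

    BCE = −(1/N) Σ [ yᵢ·log p(yᵢ) + (1 − yᵢ)·log(1 − p(yᵢ)) ].

Class imbalance — white:black pixel ratios near 1:9 (liver) and 1:85
(tumor) — is mitigated by the weight factor `W` and, centrally, by
**removing slices with no target foreground** before training
(`filterSlices()`). Evaluation reports DSC = 2TP/(2TP+FP+FN),
JSC = TP/(TP+FP+FN), pixel accuracy, and the symmetric volume
difference SVD = 1 − DSC, per slice and aggregated.

Since clinical CT corpora cannot ship with a package, a phantom
generator synthesizes axial-slice look-alikes (elliptical liver, disk
lesions placed inside it, hypo-/hyperdense contrast, noise) whose
pooled class imbalance matches the ratios above, with exact ground
truth. All experiments in the tests run on these phantoms.

## Worked example

```r
library(livseg)
# a 60-slice phantom "scan" with empty end slices, 64 x 64
vol <- generateVolume(phantomConfig(imageSize = 64), 60,
                      emptyMargin = 0.2, seed = 7)
vol
#> VolumePair: 60 slices of 64 x 64 (spacing 1.00 mm)
#>   liver foreground: 14395 px | tumor foreground: 1095 px

fl <- filterSlices(vol, "tumor")
fl$report
#> Class balance report (target: tumor)
#>   slices: 60 total, 21 kept, 39 removed
#>   white:black ratio 0.0045 -> 0.0129

# train the liver model briefly and evaluate on held-out slices
res <- runExperiment(vol, "liver", architectureConfig(inputSize = 64L),
                     trainConfig(epochs = 10, learningRate = 1e-3, seed = 1))
res$metrics
#> MetricsReport (per-slice-mean over 11 slices)
#>   DSC 0.9196 | JSC 0.8515 | accuracy 0.9835 | SVD 0.0804
#>   DSC sd 0.0152, se 0.0046
```

Reading the output: 39 of 60 slices carried no tumor and are dropped,
which almost triples the pooled foreground ratio (0.0045 → 0.0129) — the
class-balancing step. Ten epochs of liver training already reach a mean
held-out Dice overlap of 0.92 (SVD 0.08); the acceptance runs train
longer and reach ≥ 0.99. `predictMask()` produces masks for new slices,
and `overlapImage()` renders disagreements (missed foreground cyan,
false foreground magenta) for visual review.

A thin command-line front end over the same functions is installed at
`inst/cli/livseg.R` with `simulate`, `prepare`, `train` and `evaluate`
subcommands.

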