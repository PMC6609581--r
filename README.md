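# dbnexpr

Deep belief network and hybrid SVM classifiers for high-dimensional
gene-expression data.

## What this is for

Classifying patients from transcriptome-wide expression profiles — for
example calling the estrogen-receptor status of a breast tumor, or telling
Crohn's disease from ulcerative colitis — is a standard computational
diagnostics task. The data are hard: tens of thousands of genes, a few
hundred samples, substantial noise, and often badly imbalanced classes.
`dbnexpr` implements a deep-learning approach to this problem alongside the
evaluation protocol needed to judge it fairly: deep belief networks (DBNs),
autoencoders, combined deep-network/SVM classifiers, and a cross-validation
harness with class-balancing undersampling.

The package is aimed at methodologists who want a transparent, fully
inspectable implementation of these classifiers in base R — every gradient,
update rule, and resampling step is open code, tested against independent
oracles (exact enumeration for RBM likelihoods, finite differences for
gradients).

## The models

**DBN.** A feedforward network with logistic units,
`a^(l) = φ(W^(l) a^(l−1) + b^(l))`, trained in two stages:

1. *Unsupervised pretraining.* Each pair of adjacent layers is initialized
   as a binary-unit restricted Boltzmann machine trained by contrastive
   divergence (CD-k, default k = 1); the stack is greedy — each RBM is
   trained on the hidden-unit probabilities of the one below.
2. *Supervised fine-tuning.* The unrolled network minimizes the mean squared
   error `E = (1/n) Σᵢ ‖oᵢ − tᵢ‖²` by backpropagation, either as mini-batch
   SGD with the regularized update
   `θ(t+1) = θ(t) − η ∇E − λθ(t) + νΔθ(t−1)` (`bprop`), or full-batch
   resilient backpropagation with weight backtracking (iRprop+, `rprop`).
   Regularization options follow common practice for these models: a
   momentum schedule (0.5 → 0.9 after epoch 50), L2 weight-cost, early
   stopping at a fixed epoch, and per-column weight normalization
   `‖W·j‖₂ = 1`.

**Autoencoder.** The pretrained stack unfolded into a mirror-symmetric
encoder/decoder, fine-tuned to reconstruct its input; the bottleneck (code
layer) is a learned low-dimensional representation.

**Hybrid classifiers.** A trained DBN, RBM stack, or autoencoder used as a
representation learner: samples are mapped to a chosen hidden layer (or the
code layer) and an SVM (LIBSVM via `e1071`) is trained on those features.
With a passthrough extractor the hybrid reduces exactly to a plain SVM.

**Evaluation.** Stratified k-fold cross-validation (default k = 10) with
undersampling of the training folds only (every class is drawn down to the
smallest class size; held-out folds keep their natural balance), reporting
accuracy, sensitivity (TPR), specificity (TNR), and error rate per fold with
means and standard errors (sd/√k).

A synthetic-data generator (`simulate_expression()`) produces log2-scale
expression matrices with known class structure — per-gene baselines from
Normal(8, 2), disjoint blocks of differential genes shifted by a chosen
effect size — so the whole pipeline is testable without any downloads.

## Worked example

```r
library(dbnexpr)

# an imbalanced two-class cohort: 100 vs 60 samples, 1000 genes,
# 40 genes shifted by 1.2 log2 units in class 2
sim <- simulate_expression(n_per_class = c(100, 60), n_genes = 1000,
                           n_differential = 40, effect_size = 1.2,
                           noise_sd = 1, seed = 42)
ds <- sim$dataset
ds
#> expression_dataset: 160 samples x 1000 genes
#> labels: class1=100, class2=60

# fit a DBN: two stacked RBMs, then iRprop+ fine-tuning
fit <- dbn(ds, architecture = "A-50-10-1",
           control = train_control("rprop", epochs = 60),
           cd = cd_control(epochs = 10), seed = 42)
fit
#> Deep belief network classifier
#>   architecture: 1000-50-10-1 (A-50-10-1)
#>   fine-tuning: rprop (60 epochs run)
#>   pretraining: 2 stacked RBMs
#>   classes: class1, class2
#>   final train error 0.0018, train accuracy 1.000

# the hybrid DBN+SVM under the full evaluation protocol
report <- cross_validate(ds,
    learner_hybrid(source = "finetuned-dbn", architecture = "A-50-10-1",
                   control = train_control("rprop", epochs = 60),
                   cd = cd_control(epochs = 10)),
    k = 10, balance = TRUE, seed = 42)
report
#> 10-fold cross-validation: finetuned-dbn+svm-linear (undersampled training folds)
#>   accuracy     95.00% +/- 2.24%
#>   tpr          95.00% +/- 2.69%
#>   tnr          95.00% +/- 2.55%
#>   error_rate    5.00% +/- 2.24%
```

The report says the combined classifier recovers the planted 40-gene signal
at 95% cross-validated accuracy despite the 100/60 imbalance, with matching
sensitivity and specificity because the training folds were rebalanced by
undersampling before each fit.

Real expression matrices arrive through `read_expression_matrix()`
(delimited text, samples-as-rows or GEO series-matrix-style genes-as-rows)
plus `attach_labels()`; `log_transform()` handles intensity-scale input.
`select_top_variance()` provides the usual unsupervised gene filter.

There is also a command-line wrapper (installed under `exec/dbnexpr`) with
`simulate`, `train`, `evaluate`, and `extract` subcommands driven by a YAML
config; every run writes its fully-resolved configuration next to its
outputs, and re-running from that file reproduces them bit-exact.

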