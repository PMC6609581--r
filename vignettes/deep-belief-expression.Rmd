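---
title: "Deep belief networks and hybrid SVMs for expression classification: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep belief networks and hybrid SVMs for expression classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbnexpr)
```

This vignette is the package's account of the science it implements: the
two-stage deep belief network (DBN) learning procedure, the resilient
fine-tuning algorithm, the hybrid deep-representation/SVM classifiers, the
evaluation protocol, and — importantly — the numerical and design choices
made where the procedure leaves room, so that a reader can judge exactly
what was computed.

## The classification problem and its assumptions

The input is a samples × genes matrix of log2-scale expression values with
2 or 3 class labels (disease subtype, receptor status, control). Sample
sizes in this field are a few hundred at most, the feature dimension is in
the tens of thousands, and classes are often imbalanced. The package's
models assume:

* expression values are finite and on a roughly bounded (log) scale, so a
  per-gene min–max rescaling to $[0,1]$ is meaningful;
* class structure, where present, is expressed as location shifts of some
  subset of genes — which is also exactly what the synthetic generator
  plants;
* samples are exchangeable within a class (no batch or pedigree structure).

## Stage 1: pretraining with stacked RBMs

A binary-unit restricted Boltzmann machine over visible units $v$ and
hidden units $h$ has joint energy
$-E(v,h) = b^\top v + c^\top h + v^\top W h$, giving logistic conditionals
in both directions. Training follows contrastive divergence: positive
statistics from $(v^0, P(h\,|\,v^0))$, negative statistics after $k$
alternating Gibbs steps.

Numerical choices (the procedure itself does not fix them):

* **CD-k with k = 1** by default. One Gibbs step is the standard choice and
  is what the acceptance checks enumerate against.
* **Gibbs chain detail.** Hidden states are *sampled* binary at every step
  (otherwise the chain mixes nowhere), visible reconstructions are kept as
  *probabilities*, and the final negative-phase statistics use
  probabilities on both sides. This is the common variance-reduction
  convention.
* **Input scaling.** Binary-unit RBMs expect inputs in $[0,1]$, so each
  gene is min–max scaled using *training-data* parameters; test data are
  transformed with the stored parameters and clamped into $[0,1]$. A gene
  that is constant in training carries no information and is pinned at 0.
* **Initialization.** Weights $\sim N(0, 0.01)$, biases 0, under a fixed
  seed. Training is a deterministic function of the seed.
* **Default hyperparameters** (all exposed in `cd_control()`): learning
  rate 0.1, mini-batches of 10, momentum 0.5 switching to 0.9 after 5
  epochs, weight-cost $2\times10^{-4}$. These are conventional RBM settings;
  nothing in the pipeline is sensitive to them at the problem sizes below.

Stacking is greedy and bottom-up: RBM $r$ is trained on the hidden-unit
probabilities of RBM $r-1$. Layer orderings other than bottom-up are
possible in principle but are not implemented.

## Stage 2: supervised fine-tuning

The unrolled network uses the logistic activation on *all* layers,
including the output — the output encodings below assume values in
$[0,1]$. The error is the mean squared error
$E = \tfrac1n \sum_i \lVert o_i - t_i \rVert^2$.

**A factor-of-two bookkeeping choice.** The per-sample output derivative
used by backpropagation is $(a_j - t_j)$, which is the exact gradient of
$\tfrac12\sum_i \lVert o_i - t_i\rVert^2$, not of the $1/n$-scaled form
used for reporting. The package keeps both conventions deliberately:
gradients follow $(a - t)$ summed over the mini-batch, error *reporting*
uses the $1/n$ form. For SGD the difference is a constant factor absorbed
by the learning rate; for sign-based Rprop it is irrelevant. The
finite-difference tests check the gradients against the
$\tfrac12\sum$ objective, which is the one they actually differentiate.

**Bprop** is mini-batch SGD with the regularized update
$\theta(t{+}1) = \theta(t) - \eta\, g - \lambda\,\theta(t) + \nu\,
\Delta\theta(t{-}1)$, with the weight-cost term applied to weights only,
never biases. Defaults: $\eta = 0.1$, batches of 10, momentum schedule
0.5 → 0.9 after epoch 50.

**Rprop** is iRprop+ — per-parameter adaptive step sizes with weight
backtracking — run *full-batch*, one update per epoch, because sign-based
methods degrade badly on mini-batch gradient estimates. Constants are the
standard literature values $\eta^+ = 1.2$, $\eta^- = 0.5$,
$\Delta_0 = 0.1$, $\Delta_{\min} = 10^{-6}$, $\Delta_{\max} = 50$. On a
sign change the step size shrinks and, if the epoch error increased, the
previous update is reverted exactly and the stored gradient zeroed (the
"+" in iRprop+). Only iRprop+ is provided; the Rprop−/Rprop+/iRprop−
variants are rejected with a clear message rather than silently aliased.

**Weight-cost under Rprop.** The SGD update's $-\lambda\theta$ term has no
meaning in a method without a learning rate, so for Rprop the weight-cost
enters the objective instead: the gradient becomes $g + \lambda w$ before
the sign rule. This is also how the established implementations of
resilient training handle decay, and it is the only reading under which
large $\lambda$ (up to ~1) behaves as a usable regularizer rather than
destroying the weights. The package's regularization check exercises
$\lambda = 0.5$ on a one-hidden-layer network and verifies that test
accuracy is maintained while mean $|w|$ shrinks by an order of magnitude.

**Other regularizers.** Early stopping is a fixed-epoch cutoff
(`early_stop_epoch`; a patience-based monitor stop exists but is off by
default). Weight normalization rescales every weight-matrix *column* to
unit L2 norm — zero columns untouched — at the end of each epoch, weights
only. It is exact to $10^{-12}$ and idempotent.

**Output encodings.** Binary tasks use either a single output node with
hard targets $\{0,1\}$ (prediction = rounded output; an exact 0.5 falls to
the lower class via round-half-to-even) or one node per class with softened
one-hot targets $\{p, 1-p\}$, default $p = 0.9$ (prediction = arg max, ties
to the lowest index). The two encodings perform near-identically; both are
kept. Three-class tasks extend the multi-node form with
$\{p, 1-p, 1-p\}$-style target vectors — a documented extension beyond the
two-class scheme.

## Autoencoders and hybrid classifiers

The pretrained stack unfolds into a mirror-symmetric network; decoder
weights start as the transposed encoder weights with the RBM visible
biases, and are *untied* during reconstruction fine-tuning (classic
unfolding). Reconstruction targets are the scaled inputs, matching the
logistic output range.

A hybrid classifier is `extract ∘ svm`: features are the activations of a
chosen hidden layer of a fine-tuned DBN (default: the last hidden layer),
the chained hidden-unit probabilities of a pretrained stack, or the code
layer of an autoencoder; an SVM (LIBSVM through `e1071`, kernels linear or
RBF, defaults $C = 1$, $\gamma = 1/d$) is trained on them. Two exact laws
are enforced by tests: a passthrough extractor reduces the hybrid to a
plain SVM (identical predictions on every sample), and prediction always
decomposes as the SVM applied to the extracted features. Test-set
extraction reuses the training-set scaler — there is no leakage path from
test data into the representation. If an extractor collapses to constant
features the classifier degrades, with a warning and a flag, to the
majority class rather than failing mid-protocol.

Re-implementing the SVM itself is explicitly out of scope; the SVM is a
pluggable downstream component, and `e1071` is the same LIBSVM surface used
in this literature.

## The evaluation protocol

`cross_validate()` implements the full protocol as one deterministic
function of a seed:

1. one stratified split into $k$ disjoint folds (default $k = 10$), fold
   sizes within 1 of each other and per-class counts within 1 across folds;
   plain random folds on request;
2. per fold: the training portion is balanced by undersampling — every
   class is drawn down, uniformly without replacement, to the smallest
   class size; with three classes, to the global minimum. Test folds are
   never rebalanced, so reported metrics reflect deployment conditions;
3. all preprocessing (optional top-variance gene selection, scaling) and
   all training (pretraining, fine-tuning, SVM) happen inside the training
   fold;
4. metrics per fold: accuracy, TPR, TNR, error rate
   ($\mathrm{Acc} + E = 1$ exactly); a metric with a zero denominator is
   reported `NA`, never 0. Means carry standard errors $sd/\sqrt{k}$ —
   the SE is over folds, not over repeated CV runs, and is documented as
   such since the two conventions differ.

Two protocol questions are genuinely open in this setting and both options
are provided: feature selection is computed inside training folds by
default (leakage-safe) with `selection_scope = "global"` to mimic a
whole-dataset selection; and the deep model is refit in every fold by
default, which is the leakage-safe reading of the combined-classifier
recipe. Neither option is asserted to be "the" original procedure.

Top-variance selection breaks variance ties by ascending gene index, making
the selection reproducible and permutation-equivariant.

## The synthetic generator: what it does and does not emulate

`simulate_expression()` draws per-gene baselines $\mu_g \sim N(8, 2)$ (a
typical log2 microarray intensity range), plants a disjoint block of
`n_differential` genes per non-reference class shifted by `effect_size`
$\delta$ (log2 units), and adds $N(0, \sigma^2)$ noise. Defaults follow the
study conditions used across the tests: $\delta = 1$, $\sigma = 1$,
50 differential genes among 2000, 100 samples per class — a regime where
the pooled signal ($\sqrt{50}\,\delta \approx 7\sigma$ between class
centroids) is clearly recoverable but individual genes are weak, as in real
cohorts. Imbalanced designs (209/77, 59/42/26) mirror the class sizes of
well-known breast-cancer and IBD cohorts.

The generator deliberately does **not** model probe effects, batch effects,
intensity-dependent variance, or gene–gene correlation (an option for a
correlated block exists but is off by default). Passing tests on this
generator therefore show that the implementations are correct and that the
protocol recovers planted mean-shift signal; they do not certify
performance on real microarray noise.

## Problem sizes and numerical tolerances used by the checks

The package's heavier checks run the full study at 200 samples × 2000
genes with `A-50-10-1` networks, 15 pretraining epochs and 60–80 iRprop+
epochs — sizes chosen so every training run is seconds on one CPU while the
network is still genuinely deep and overparameterized relative to $n$.
Gradient agreement with central finite differences (step $10^{-5}$) is
required to relative $10^{-6}$ (with a $10^{-3}$ floor on the denominator
to keep the ratio meaningful for near-zero gradients); weight normalization
to $10^{-12}$; exact identities (metric arithmetic, backtracking, the
passthrough reduction) are asserted identically, not approximately.

## Data handling conventions

* Loading accepts samples-as-rows or genes-as-rows (series-matrix style)
  delimited text; a missing or non-numeric cell is an error naming the row
  and column, and duplicate gene identifiers are rejected outright.
* The log transform is $\log_2(v + 1)$; the procedure's sources say only
  "logarithmic scale", and the +1 keeps zeros finite. Negative input is an
  error rather than a silent `NaN`.
* Datasets serialize as a TSV pair written at `%.17g` precision; model
  containers are versioned JSON with 17 significant digits — both
  round-trip bit-exact. A hybrid container stores the extractor, SVM
  hyperparameters, and the extracted training features/labels, and refits
  the SVM deterministically on load (LIBSVM training is deterministic given
  the data), which keeps the container plain text.
* All randomness in a composite run fans out from one top-level seed
  through fixed offsets; every run command writes its fully-resolved
  configuration next to its outputs, and re-running from that file
  reproduces them byte-for-byte.

## Known limitations

* Only logistic activations with MSE; no softmax/cross-entropy, ReLU, or
  conjugate-gradient fine-tuning.
* No persistent CD, parallel tempering, or Gaussian-visible RBMs — inputs
  must be scaled to $[0,1]$, and min–max scaling is the only provided path.
* The iRprop+ error comparison uses the regularized full-batch objective;
  with `weight_cost = 0` this is exactly the training error, otherwise the
  backtracking criterion includes the penalty term.
* Standard errors over 10 folds are themselves noisy; differences within
  ~2 SE should not be over-interpreted, which is why the package's own
  checks use inequality margins rather than point comparisons.
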