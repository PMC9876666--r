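---
title: "Methods: the multiview deep forest in mvdf"
author: "mvdf authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the multiview deep forest in mvdf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and assumptions

`mvdf` targets multiclass prediction on small-to-moderate clinical
cohorts (hundreds to low thousands of patients) whose indicators carry a
*view* structure: groups of columns that describe the same patient from
different angles (demographics, pathology, treatment, tumor markers).
The modelling assumptions are those of deep-forest methods generally:

* indicators are numeric after upstream coding (categories are
  integer-coded by the user; trees are order-based, so any monotone
  coding works);
* the signal is axis-aligned enough for tree splits to find, but the
  class boundary may be a deep composition of such splits;
* views are informative both alone and jointly — hence class vectors are
  extracted from *every* non-empty view subset, not only the single
  views;
* redundancy across views is substantial, which motivates compressing
  the non-selected ("secondary") indicators before the boosted stage
  rather than feeding them to trees raw.

No survival-time modelling is attempted: the outcome is a categorical
survival class, and censoring, date arithmetic and time-to-event
likelihoods are out of scope.

# Pipeline stages

## Preprocessing

Imputation distinguishes indicators that are biologically sex-dependent
(height, weight) from the rest: the former are filled with the
within-sex mean of the *observed training* values, everything else with
a single unified constant (default 0 on the normalized scale — after
min-max scaling this is an out-of-range-low sentinel that trees can
isolate with one split). A sex stratum with no observed values falls
back to the overall mean with a warning. All statistics are learned on
the training partition and re-applied verbatim to held-out data.

Normalization defaults to min-max onto [0, 1]. Tree splits are
scale-invariant, so this choice is for the encoder's benefit: bounded
inputs keep the bottleneck network's first-layer activations in a stable
range. Constant columns map to 0; held-out values outside the training
range are *not* clipped, so the scaler is an affine map, invertible and
honest about extrapolation. Z-score and identity normalization are
available as config options.

The stratified split draws exactly `round(f · n_c)` samples per class
(default `f = 0.3`), seeded; classes with fewer than two samples are
rejected.

## Multiview class vectors (z1)

Each of the `2^m − 1` view subsets trains two forests: a completely
random tree forest (kind A: uniformly random non-constant feature,
uniformly random threshold, grown until every leaf is pure) and a
Gini-split random forest (kind B: best weighted-impurity decrease among
`√d` random candidate features, bootstrap per tree). Subsets are ordered
by size then lexicographically, so the `2K(2^m − 1)` z1 columns have a
stable identity across runs.

Class vectors for the *training* table come from k-fold cross-fitting
(default 3 folds): each sample's vector is produced by the fold model
that never saw it. Without this the training-set z1 of pure-leaf forests
would be nearly one-hot and the cascade would overfit immediately; the
published deep-forest lineage uses the same device, and we adopt it even
though the extraction stage could formally be defined without it. New
data is pushed through the full-data models.

"Permutation and combination" of views is read as the set of non-empty
subsets: forests are insensitive to column order, so permutations of the
same subset would duplicate extractors without adding diversity, and the
subset count `2^m − 1` is the one the dimensionality arithmetic
(186 = 2·3·31 at m = 5, K = 3) requires.

## Importance and the information bottleneck

Gini importance sums, over every node split on indicator *i* in the
kind-B forests, the node impurity minus the *sample-fraction-weighted*
impurities of its children. The weighting is deliberate: the unweighted
difference can be negative for perfectly reasonable splits and does not
correspond to any impurity-decrease reading; the weighted form is the
standard mean-decrease-in-impurity importance that the Gini-score
formulation is invoking. Kind-A forests are excluded — their split
choices are random and carry no importance information. The top 5
indicators by score, united with an optional expert list (union
semantics when they overlap), form the important set `X^v`; everything
else is secondary (`X^s`).

The secondary indicators are compressed by a variational information
bottleneck: a stochastic Gaussian encoder `q(T | X^s)` (one 64-unit
ReLU hidden layer, then mean and log-variance heads), a categorical
softmax decoder for the class label, and the objective

    minimize  CE(Y, decoder(T)) + β · KL(q(T|X^s) || N(0, I)).

The cross-entropy term is (up to the constant `H(Y)`) a lower-bound
surrogate for `−I(T;Y)`; the KL term is the standard variational upper
bound on `I(X^s;T)`. Both are recorded per epoch in the training
history. The sign convention follows the hyperparameter table (β = 0.1,
β ≥ 0): larger β compresses harder, and at β = 0 the objective reduces
to purely label-predictive training. Training is full-batch Adam
(lr 0.01, 200 epochs) with one reparameterized sample per example per
epoch, log-variances clamped to [−10, 10], and every random draw seeded.
The encoder is implemented directly in R matrix algebra as a small
variational network — the architecture is deliberately minimal because
the secondary block is low-dimensional (tens of columns) and the
encoder's job is compression, not representation learning at scale.
Inference uses the posterior mean, so encoding is deterministic.

## Boosted correction features (z2)

One multiclass tree (Gini splits over all important indicators,
depth ≤ 5, min node 5) is fit on `X^v`. A decision tree has no native
real-valued score vector for the softmax to consume; we emit the log of
the leaf's class-frequency vector, clipped at 1e-6, so that the softmax
reproduces the leaf frequencies exactly and the negative gradients
`r = y − p` have their textbook meaning. Keeping this tree shallow
matters: grown to purity its probabilities are one-hot, all residuals
vanish and the correction stage would have nothing to learn.

Each of the `h = 200` repetitions draws an independent Bernoulli(η=0.5)
mask over the secondary features, zeroes the masked-out columns at the
*encoder input* and fits a multi-output SSE regression tree (depth ≤ 5)
on the latent codes against the residual matrix. One encoder serves all
repetitions — retraining 200 encoders would dominate the runtime for no
statistical gain, and the coverage guarantee `1 − (1−η)^h` depends only
on the mask draws, which are preserved. Leaf outputs use the multiclass
Newton step `c_k = ((K−1)/K)·Σ r_k / Σ |r_k|(1−|r_k|)` with `|r|` in the
denominator because residuals are signed; denominators below 1e-12
yield 0 (converged leaf). Each repetition contributes its leaf vector
`c ∈ R^K` per sample; z2 is their concatenation (`h·K` columns). The
alternative reading — emitting the corrected probabilities
`softmax(ŷ + c)` instead of `c` — is noted as open; we emit `c`, which
is what the second tree itself generates, and which one boosting step
demonstrably uses to reduce the training loss.

## Pruned cascade

The cascade input is `Z = [z1 | z2 | X]`. Each level holds four forests
(two of each kind); level ℓ > 1 additionally receives the previous
level's 4K class vectors, so its input width is |Z| + 4K. Per level and
per forest, fold models are trained on the cross-fitting partition; each
tree is scored on its held-out fold as

    s_t = mean over validation samples of P_t(true class) + α · Gini_t,

where `Gini_t` is the training-sample-weighted mean impurity of the
tree's leaves. The score uses the probability of the sample's *true*
class: scoring the predicted class instead would reward confidently
wrong trees. α is not given in the published hyperparameter table; the
default is −0.5 so that leaf impurity is penalized, and the sign and
magnitude are exposed in the config. Trees are kept by an independent
Bernoulli draw with `p_t = exp(s_t − max s)`, taken literally from the
max-normalized form: the arg-max tree has `p = 1` and is additionally
retained unconditionally, so a forest can never be emptied. Pruning
draws are seeded and recorded.

Level growth stops when the cross-validated accuracy of the aggregated
four class vectors fails to improve for `patience = 1` consecutive
level(s), or at `maxLevels = 10`; the model is truncated at the best
level. Prediction averages the four class vectors of the last level
(each forest slot averaging its fold models); the class is the row
argmax with ties broken by the lowest class id.

# The synthetic cohort generator

`generateCohort()` emulates the *shape* of the target cohort: 939
samples, 61 indicators in 5 views, 3 classes with priors 223:219:497,
mixed continuous/binary indicators, cross-view redundancy, missing
values. Its generative model is deliberately simple and analytically
transparent:

* class labels follow the priors exactly (largest-remainder quota, then
  a seeded shuffle), so cohort-level class counts are reproducible;
* informative indicators are class-conditional Gaussians with unit SD
  whose class means are a random permutation of an equispaced grid with
  step `effectSize` (default 1.5 SD); designated "important" indicators
  double the step, standing in for the clinically decisive indicators
  an expert would name;
* redundant indicators are ρ-correlated copies (default ρ = 0.6) of an
  informative indicator from the *next* view, giving the cross-view
  redundancy the bottleneck stage exists to squeeze out;
* the remaining columns are N(0, 1) noise;
* a seeded subset of non-redundant columns (default 30%) is
  dichotomized at its median — redundant pairs are exempt so the
  planted correlation remains measurable;
* missingness is MCAR at the configured rate (default 5%).

What it does *not* emulate: survival-time mechanics and censoring,
informative (follow-up-related) missingness, realistic marker
distributions (skewed CA125/AFP), measurement error correlated across
views, or label noise. Tests passing on this generator therefore
demonstrate mechanical and statistical correctness of the pipeline —
recovery of planted signal, honest cross-fitting, calibrated structural
dimensions — not clinical validity on real data.

# Numerical and design choices

* **Tolerances.** Probability slices of z1 must sum to 1 within 1e-9;
  softmax is max-shift stabilized; loss probabilities clip at 1e-12;
  leaf-value denominators guard at 1e-12; tree1 leaf frequencies clip
  at 1e-6 before the log.
* **Tie-breaks.** Split search accepts a candidate only on a strict
  improvement (> 1e-12), making the first best split deterministic;
  class prediction uses the lowest class id among tied maxima; top-k
  importance ties break by indicator name.
* **Degenerate inputs.** Constant columns: min-max maps them to 0,
  extractors trained on all-constant subsets emit the class prior via
  a root-leaf tree. Completely random trees cap at depth 50 to bound
  recursion on duplicated samples; a node whose candidate features are
  all constant becomes a leaf. A secondary split with zero remaining
  indicators is rejected before encoder training.
* **Seeding.** All randomness flows from one master seed through a
  multiplicative-congruential derivation (kept within 32-bit range);
  C++ forest growth uses its own seeded mt19937, so R-level user RNG
  state is never consumed (and is restored around every library call).
* **Forest engine.** The trees are grown by a compact Rcpp engine
  rather than an off-the-shelf forest package because the method needs
  internals those packages do not expose together: per-node Gini and
  class-count records (importance, decision-path dumps), pure-leaf
  completely-random growth, per-tree scoring and pruning of a fitted
  forest, and multi-output regression trees with externally assigned
  leaf values. An independent random-forest implementation is used in
  the tests as a baseline and cross-check, never as the engine.

# Problem sizes used by the test suite

The suite exercises every stage at sizes chosen to make the checked
properties sharp but cheap: structural-width checks with 10-tree debug
forests (the widths are tree-count-invariant); oracle comparisons on
n ≤ 1000 random instances; the compression trend on an n = 600 cohort
with 5 seeds; pruning safety on a 300-tree forest across 100 seeded
draws; and the end-to-end recovery on the cohort-shaped task (n = 900,
61 indicators, priors 223:219:497, effect 1.5, 5% missingness) with 50
trees per forest and 5 seeds, where the full model must clear the
majority rate by ≥ 10 points and stay within 2 points of a 300-tree
random forest. At effect size 1.5 both models typically reach perfect
test accuracy — the margin criteria, not the ceiling, are the content
of that check.

# Known limitations

* The cascade's fold models double as its predictors; a refit-on-full
  variant would predict marginally better at the cost of invalidating
  the pruning scores. We keep the fold ensemble for coherence.
* The variational bounds reported for `I(T;Y)` and `I(X^s;T)` are
  surrogates; they order β settings correctly (the property the tests
  pin) but are not calibrated mutual-information estimates.
* Pruning draws are independent Bernoulli per tree, so the retained
  tree count is random; only the best tree is guaranteed.
* With strongly separable inputs the cascade stops at one level and the
  deep part of "deep forest" never engages; depth pays off only near
  the decision boundary's noise floor.
* Runtime is dominated by the `2(2^m − 1)` extractor forests; m beyond
  ~8 views is impractical without subset capping.
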