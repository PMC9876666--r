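# mvdf — multiview deep forest for clinical survival-class prediction

`mvdf` implements a multiview deep forest (MVDF) classifier for
multiclass prediction on clinical tabular data, aimed at tasks such as
predicting a patient's overall-survival class (e.g. OS < 3 years,
3–5 years, ≥ 5 years) from a table of clinical indicators that fall into
semantically coherent **views** (demographics, pathology, treatment,
pre-/post-operative tumor markers, ...). It is written for
biostatisticians and ML practitioners who want a deep-forest model with
interpretable tree internals on desk-scale cohorts where deep neural
networks are data-starved.

## The model

Given a cohort `X = [X^1, ..., X^m]` of `n` indicators split into `m`
views with `K` classes, the pipeline has three learned feature stages and
a cascade classifier:

1. **Multiview class vectors (z1).** For every non-empty subset of the
   `m` views (there are `2^m − 1`), two forests are trained on the
   subset's columns: a completely random tree forest (uniformly random
   split feature and threshold, grown to pure leaves) and a Gini-split
   random forest. Each forest emits a `K`-dimensional class-probability
   vector per sample, so `z1` has `2·K·(2^m − 1)` columns — 186 for
   `K = 3, m = 5`. Training-set vectors are produced by k-fold
   cross-fitting so the cascade never sees resubstitution probabilities.
2. **Importance split + information bottleneck.** Indicators are ranked
   by Gini importance `VIM_i = Σ_j (GINI_j − w_l·GINI_jl − w_r·GINI_jr)`
   over all splits on indicator `i` in the Gini-split forests; the top 5
   plus an optional expert list form the important set `X^v`, the rest
   `X^s`. A variational information-bottleneck encoder compresses `X^s`
   into a latent `T` (default 10 dims) by maximizing
   `I(T;Y) − β·I(X^s;T)` (β = 0.1).
3. **Boosted correction features (z2).** One multiclass tree is fit on
   `X^v`; its softmax probabilities `p_k = exp(ŷ_k)/Σ exp(ŷ_k)` give
   negative gradients `r_ik = y_ik − p_k(x_i)` of the log-likelihood
   loss. For each of `h = 200` repetitions, a Bernoulli(η = 0.5) feature
   mask is drawn, the masked `X^s` is encoded, and a regression tree is
   fit on `(T, r)` with multiclass leaf values
   `c_jk = ((K−1)/K)·Σr_ik / Σ|r_ik|(1−|r_ik|)`. Each repetition
   contributes `K` columns: `z2` has `h·K` = 600 columns. Every feature
   is touched by some mask with probability `1 − (1−η)^h`.
4. **Pruned cascade forest.** Levels of four forests (two completely
   random, two Gini-split) are grown on `Z = [z1 | z2 | X]`, each level
   consuming the previous level's 4K class vectors. Every tree `t` is
   scored `s_t = meanTrueProb_t + α·Gini_t` on held-out folds and kept
   with probability `p_t = exp(s_t − max s)` — the best tree always
   survives. Depth grows until cross-validated accuracy stops improving;
   prediction averages the last level's four class vectors.

A synthetic cohort generator (`generateCohort()`) emulates the shape of
the gastric-cancer cohort the model targets (939 patients, 61 indicators
in 5 views, class priors 223:219:497, cross-view redundancy, MCAR
missingness) so the whole system is testable without patient data.

## Worked example

```r
library(mvdf)

spec   <- syntheticSpec(nSamples = 600, seed = 7)   # 61 indicators, 5 views
cohort <- generateCohort(spec)
cohort
#> MultiviewTable: 600 samples x 61 indicators in 5 view(s)
#> classes: 1=142, 2=140, 3=318
#> missing cells: 1829 (5.0%)

parts <- stratifiedSplit(cohort, preprocessConfig(testFraction = 0.3,
                                                  splitSeed = 7))
prep  <- preprocessFit(parts$train, preprocessConfig())  # impute + min-max
test  <- preprocessApply(prep$state, parts$test)

cfg   <- mvdfConfig(treesPerForest = 50, cascadeTrees = 50, seed = 7)
model <- mvdfFit(prep$table, cfg)
model
#> MVDFModel
#>   indicators: 61 | classes: 1/2/3
#>   modules: z1=TRUE z2=TRUE prune=TRUE
#>   important indicators: v4_inf1, v1_inf1, v5_inf1, v3_inf1, v2_inf1
#>   cascade: 1 level(s), CV accuracy 1.0000, 1.0000

pred <- mvdfPredict(model, test)
mvdfEvaluate(labelLevels(test)[classLabels(test)], pred)$accuracy
#> [1] 1
```

The model recovers the five planted high-effect indicators
(`v1_inf1 ... v5_inf1`) as its top-5 Gini-importance set and classifies
the held-out samples perfectly at this effect size (1.5 SD between
adjacent class means); on real cohorts the interesting regime is much
noisier. Individual trees remain inspectable as clinical decision paths:

```r
cat(head(exportDecisionPaths(model, level = 1, forest = 3), 4), sep = "\n")
#> if v3_inf1 <= 0.388739 | gini=0.6083 n=279 [1=64, 2=67, 3=148]
#>   if z1_B_s23_c3 <= 0.52 | gini=0.0675 n=143 [1=0, 2=5, 3=138]
#>     leaf: predict 2 | gini=0.0000 n=5 [1=0, 2=5, 3=0]
#>     leaf: predict 3 | gini=0.0000 n=138 [1=0, 2=0, 3=138]
```

## Command line

A thin wrapper over the same functions ships in `inst/scripts/mvdf`:

```sh
Rscript inst/scripts/mvdf simulate   --config cfg.yaml --seed 3 --out run/
Rscript inst/scripts/mvdf preprocess --config cfg.yaml --data run/cohort.csv --views run/views.yaml --out run/
Rscript inst/scripts/mvdf fit        --config cfg.yaml --data run/train.csv  --views run/views.yaml --out run/
Rscript inst/scripts/mvdf evaluate   --config cfg.yaml --data run/test.csv   --views run/views.yaml --model run/model.rds --out run/
```

Subcommands: `simulate`, `preprocess`, `fit`, `predict`, `evaluate`,
`ablate` (toggles the z1 / z2 / pruning modules independently),
`explain` (decision-path dump). Flags override the YAML config, which
overrides the defaults; every run writes its resolved `config.yaml`
beside its outputs.

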