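# Shared fixtures and independent oracles, built in code at test time.

# A tiny labeled two-view table with hand-written values.
tinyTable <- function(n = 12, seed = 42) {
  set.seed(seed)
  x <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n), d = rnorm(n))
  y <- rep(c("lo", "hi"), length.out = n)
  multiviewTable(x, list(v1 = c("a", "b"), v2 = c("c", "d")), labels = y)
}

smallCohort <- function(n = 300, seed = 1, effectSize = 1.5,
                        missingRate = 0, viewSizes = c(5, 5, 4),
                        informativePerView = 3, ...) {
  generateCohort(syntheticSpec(
    nSamples = n, viewSizes = viewSizes,
    informativePerView = informativePerView, effectSize = effectSize,
    missingRate = missingRate, seed = seed,
    importantIndicators = sprintf("v%d_inf1", seq_along(viewSizes)), ...))
}

preppedCohort <- function(...) {
  t <- smallCohort(...)
  preprocessFit(t, preprocessConfig())$table
}

# Independent oracle: route a set of samples through a stored tree purely
# in R and return, per node, the raw sample indices that reach it.
oracleNodeMembers <- function(tree, x, rows = seq_len(nrow(x))) {
  members <- vector("list", length(tree$feature))
  rec <- function(node, idx) {
    members[[node]] <<- idx
    f <- tree$feature[node]
    if (f < 0L || !length(idx)) return()
    goLeft <- x[idx, f + 1L] <= tree$threshold[node]
    rec(tree$left[node] + 1L, idx[goLeft])
    rec(tree$right[node] + 1L, idx[!goLeft])
  }
  rec(1L, rows)
  members
}

oracleGini <- function(y, K) {
  if (!length(y)) return(0)
  p <- tabulate(y, K) / length(y)
  1 - sum(p^2)
}

# Brute-force Gini importance: recompute every node's impurity from the
# raw in-bag sample routing and accumulate the weighted decreases.
oracleImportance <- function(forest, x, y, K) {
  vim <- setNames(numeric(length(forest$featureNames)),
                  forest$featureNames)
  for (tree in forest$trees) {
    mem <- oracleNodeMembers(tree, x, rows = tree$inbag)
    for (node in which(tree$feature >= 0L)) {
      idx <- mem[[node]]
      l <- tree$left[node] + 1L
      r <- tree$right[node] + 1L
      nL <- length(mem[[l]])
      nR <- length(mem[[r]])
      dec <- oracleGini(y[idx], K) -
        (nL / length(idx)) * oracleGini(y[mem[[l]]], K) -
        (nR / length(idx)) * oracleGini(y[mem[[r]]], K)
      f <- forest$featureNames[tree$feature[node] + 1L]
      vim[f] <- vim[f] + dec
    }
  }
  vim
}

# Independent per-sample class vector of one tree: walk in R, then use
# the in-bag class frequencies recomputed from raw labels.
oracleTreeProba <- function(tree, xTrain, yTrain, xNew, K) {
  mem <- oracleNodeMembers(tree, xTrain, rows = tree$inbag)
  out <- matrix(NA_real_, nrow(xNew), K)
  for (i in seq_len(nrow(xNew))) {
    node <- 1L
    while (tree$feature[node] >= 0L) {
      node <- if (xNew[i, tree$feature[node] + 1L] <= tree$threshold[node])
        tree$left[node] + 1L else tree$right[node] + 1L
    }
    out[i, ] <- tabulate(yTrain[mem[[node]]], K) / length(mem[[node]])
  }
  out
}

oracleForestProba <- function(forest, xTrain, yTrain, xNew, K) {
  acc <- matrix(0, nrow(xNew), K)
  for (tree in forest$trees) {
    acc <- acc + oracleTreeProba(tree, xTrain, yTrain, xNew, K)
  }
  acc / length(forest$trees)
}
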