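#' Score a decision tree on validation data
#'
#' The score is the tree's mean estimated probability of the true class
#' over the validation samples, plus \code{alpha} times the tree's final
#' Gini value — the training-sample-weighted mean impurity of its leaves.
#' Negative \code{alpha} penalizes impure trees.
#'
#' @param tree a tree as stored inside an \code{mvdfForest}.
#' @param zVal validation matrix in the tree's feature space.
#' @param labels true class ids of the validation samples.
#' @param alpha leaf-impurity weight (default -0.5).
#' @return list with \code{s}, \code{meanTrueProb}, \code{giniT}.
#' @export
treeScore <- function(tree, zVal, labels, alpha = -0.5) {
  if (!nrow(zVal)) stop("validation set is empty")
  pr <- treeProba(tree, zVal)
  meanTrueProb <- mean(pr[cbind(seq_along(labels), labels)])
  leaves <- which(tree$feature < 0L)
  giniT <- sum((tree$n[leaves] / tree$n[1L]) * tree$gini[leaves])
  list(s = meanTrueProb + alpha * giniT, meanTrueProb = meanTrueProb,
       giniT = giniT)
}

forestTreeScores <- function(forest, zVal, labels, alpha = -0.5) {
  rows <- lapply(forest$trees, treeScore, zVal = zVal, labels = labels,
                 alpha = alpha)
  data.frame(s = vapply(rows, `[[`, 0, "s"),
             meanTrueProb = vapply(rows, `[[`, 0, "meanTrueProb"),
             giniT = vapply(rows, `[[`, 0, "giniT"))
}

#' Keep probabilities from tree scores
#'
#' \eqn{p_t = \exp(s_t - \max_u s_u)}: the best tree always has keep
#' probability 1 and is retained unconditionally, so a pruned forest can
#' never be emptied.
#'
#' @param scores numeric vector of tree scores over one forest.
#' @return keep probabilities in (0,1].
#' @export
keepProbability <- function(scores) {
  if (!length(scores)) stop("forest has no trees")
  exp(scores - max(scores))
}

#' Prune a forest by seeded Bernoulli keep draws
#'
#' Each tree is retained with its keep probability; the maximum-score tree
#' is retained unconditionally. Order of the surviving trees is preserved.
#'
#' @param forest an \code{mvdfForest}.
#' @param scores numeric tree scores (same length as the forest).
#' @param seed RNG seed of the Bernoulli draws.
#' @return the pruned \code{mvdfForest} (with a \code{keep} attribute).
#' @export
pruneForest <- function(forest, scores, seed = 1L) {
  nT <- length(forest$trees)
  if (length(scores) != nT) stop("one score per tree is required")
  keepP <- keepProbability(scores)
  keep <- withSeed(seed, stats::runif(nT) < keepP)
  keep[which.max(scores)] <- TRUE
  out <- subsetForest(forest, keep)
  attr(out, "keep") <- keep
  out
}

# One cascade level: 4 forest slots (A, A, B, B), each as cvFolds
# cross-fitting fold models, scored and pruned on their held-out folds.
fitCascadeLevel <- function(zIn, y, K, foldAssign, kinds, treesPerForest,
                            alpha, prune, minNode, seed) {
  cvFolds <- max(foldAssign)
  n <- nrow(zIn)
  slots <- vector("list", length(kinds))
  cvVectors <- matrix(NA_real_, n, length(kinds) * K)
  colnames(cvVectors) <- prevVectorNames(length(kinds), K)
  for (s in seq_along(kinds)) {
    foldModels <- vector("list", cvFolds)
    for (f in seq_len(cvFolds)) {
      tr <- foldAssign != f
      forest <- fitForest(zIn[tr, , drop = FALSE], y[tr], K,
                          kind = kinds[s], nTrees = treesPerForest,
                          minNode = minNode,
                          seed = deriveSeed(seed, s, f))
      held <- zIn[!tr, , drop = FALSE]
      if (prune) {
        sc <- forestTreeScores(forest, held, y[!tr], alpha)
        forest <- pruneForest(forest, sc$s,
                              seed = deriveSeed(seed, s, f, 77L))
      }
      cvVectors[!tr, (s - 1) * K + seq_len(K)] <-
        predictForestProba(forest, held)
      foldModels[[f]] <- forest
    }
    slots[[s]] <- list(kind = kinds[s], foldModels = foldModels)
  }
  list(slots = slots, cvVectors = cvVectors, inputWidth = ncol(zIn))
}

prevVectorNames <- function(nSlots, K) {
  sprintf("prev_f%d_c%d", rep(seq_len(nSlots), each = K),
          rep(seq_len(K), nSlots))
}

levelPredictVectors <- function(level, zIn, K) {
  out <- matrix(0, nrow(zIn), length(level$slots) * K)
  colnames(out) <- prevVectorNames(length(level$slots), K)
  for (s in seq_along(level$slots)) {
    fm <- level$slots[[s]]$foldModels
    p <- Reduce(`+`, lapply(fm, predictForestProba, x = zIn)) / length(fm)
    out[, (s - 1) * K + seq_len(K)] <- p
  }
  out
}

#' Grow the pruned cascade forest
#'
#' Level 1 trains four forests (two completely-random, two Gini-split) on
#' the assembled feature matrix Z; every further level trains on Z
#' concatenated with the previous level's 4K class-vector columns. Class
#' vectors for training data are produced by k-fold cross-fitting, each
#' forest's trees are scored on the held-out fold and pruned by the
#' score-based keep probability, and growth stops when cross-validated
#' accuracy fails to improve for \code{patience} consecutive levels (or at
#' \code{maxLevels}); the model is truncated at the best level.
#'
#' @param z numeric feature matrix (column names form the schema).
#' @param labels integer class ids in \code{1..K}.
#' @param K number of classes (default \code{max(labels)}).
#' @param nForests forests per level (default 4: A, A, B, B).
#' @param treesPerForest trees per forest before pruning (default 300).
#' @param cvFolds cross-fitting folds (default 3).
#' @param alpha leaf-impurity weight of the tree score (default -0.5).
#' @param prune apply score-based pruning (default TRUE).
#' @param patience levels without improvement tolerated (default 1).
#' @param maxLevels hard level cap (default 10).
#' @param minNode minimum samples per child node.
#' @param seed master seed.
#' @return A [CascadeModel-class].
#' @export
growCascade <- function(z, labels, K = max(labels), nForests = 4L,
                        treesPerForest = 300L, cvFolds = 3L, alpha = -0.5,
                        prune = TRUE, patience = 1L, maxLevels = 10L,
                        minNode = 1L, seed = 1L) {
  z <- as.matrix(z)
  storage.mode(z) <- "double"
  if (is.null(colnames(z))) colnames(z) <- sprintf("Z%d", seq_len(ncol(z)))
  y <- as.integer(labels)
  minClass <- min(table(y))
  if (minClass < 2 * cvFolds) {
    stop("every class needs at least ", 2 * cvFolds, " samples")
  }
  kinds <- rep(c("A", "B"), length.out = nForests)
  kinds <- kinds[order(kinds)]          # A..A then B..B
  foldAssign <- stratifiedFolds(y, cvFolds, deriveSeed(seed, 3L))

  levels <- list()
  cvAcc <- numeric(0)
  zIn <- z
  best <- -Inf
  bad <- 0L
  for (lv in seq_len(maxLevels)) {
    level <- fitCascadeLevel(zIn, y, K, foldAssign, kinds, treesPerForest,
                             alpha, prune, minNode,
                             deriveSeed(seed, 1000L, lv))
    agg <- matrix(0, nrow(z), K)
    for (s in seq_len(nForests)) {
      agg <- agg + level$cvVectors[, (s - 1) * K + seq_len(K)]
    }
    acc <- mean(rowArgmax(agg) == y)
    levels[[lv]] <- level
    cvAcc[lv] <- acc
    if (acc > best + 1e-12) {
      best <- acc
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) break
    }
    if (lv == maxLevels) break
    zIn <- cbind(z, level$cvVectors)
  }
  bestLevel <- which.max(cvAcc)
  new("CascadeModel", levels = levels[seq_len(bestLevel)], K = as.integer(K),
      alpha = as.numeric(alpha), schema = colnames(z),
      cvAccuracy = cvAcc, bestLevel = as.integer(bestLevel),
      growth = list(patience = as.integer(patience),
                    maxLevels = as.integer(maxLevels),
                    cvFolds = as.integer(cvFolds), prune = prune,
                    treesPerForest = as.integer(treesPerForest),
                    nForests = as.integer(nForests)),
      seed = as.integer(seed))
}

#' Cascade class-probability prediction
#'
#' Pushes new samples through the levels (each level's input is Z plus the
#' previous level's class vectors; a slot's prediction averages its fold
#' models) and returns the mean of the last level's four class vectors.
#'
#' @param model a [CascadeModel-class].
#' @param zNew matrix matching the fit-time schema (matched by column name
#'   when present).
#' @return numeric n x K matrix; rows sum to 1.
#' @export
cascadePredictProba <- function(model, zNew) {
  zNew <- as.matrix(zNew)
  storage.mode(zNew) <- "double"
  if (!is.null(colnames(zNew))) {
    miss <- setdiff(model@schema, colnames(zNew))
    if (length(miss)) {
      stop("input lacks column(s): ", paste(miss, collapse = ", "))
    }
    zNew <- zNew[, model@schema, drop = FALSE]
  } else if (ncol(zNew) != length(model@schema)) {
    stop("expected ", length(model@schema), " columns, got ", ncol(zNew))
  }
  K <- model@K
  zIn <- zNew
  for (lv in seq_along(model@levels)) {
    vec <- levelPredictVectors(model@levels[[lv]], zIn, K)
    if (lv < length(model@levels)) zIn <- cbind(zNew, vec)
  }
  nS <- length(model@levels[[length(model@levels)]]$slots)
  agg <- matrix(0, nrow(zNew), K)
  for (s in seq_len(nS)) agg <- agg + vec[, (s - 1) * K + seq_len(K)]
  agg / nS
}

#' Cascade class prediction
#'
#' Argmax of [cascadePredictProba()], ties broken by the lowest class id.
#'
#' @inheritParams cascadePredictProba
#' @return integer class ids.
#' @export
cascadePredict <- function(model, zNew) {
  rowArgmax(cascadePredictProba(model, zNew))
}

#' Export a decision path from a cascade
#'
#' Plain-text dump of one tree: split indicator names, thresholds, node
#' Gini values and training class counts, indented by depth.
#'
#' @param model a [CascadeModel-class] (or an [MVDFModel-class]).
#' @param level level index.
#' @param forest forest slot index (1..4).
#' @param fold fold-model index.
#' @param tree tree index within the (pruned) forest.
#' @param classNames optional class names.
#' @return character vector of lines (one per node).
#' @export
exportDecisionPaths <- function(model, level = 1L, forest = 1L, fold = 1L,
                                tree = 1L, classNames = NULL) {
  if (is(model, "MVDFModel")) {
    if (is.null(classNames)) classNames <- model@labelLevels
    model <- model@cascade
  }
  if (level < 1 || level > length(model@levels)) {
    stop("unknown level: ", level)
  }
  slots <- model@levels[[level]]$slots
  if (forest < 1 || forest > length(slots)) stop("unknown forest: ", forest)
  fm <- slots[[forest]]$foldModels
  if (fold < 1 || fold > length(fm)) stop("unknown fold: ", fold)
  f <- fm[[fold]]
  if (tree < 1 || tree > length(f$trees)) stop("unknown tree: ", tree)
  tr <- f$trees[[tree]]
  formatTree(tr, featureNames = f$featureNames, classNames = classNames)
}

setMethod("show", "CascadeModel", function(object) {
  cat(sprintf(
    "CascadeModel: %d level(s) (best %d), K = %d, alpha = %g, %s\n",
    length(object@levels), object@bestLevel, object@K, object@alpha,
    if (object@growth$prune) "pruned" else "unpruned"))
  cat("CV accuracy by level:",
      paste(sprintf("%.4f", object@cvAccuracy), collapse = ", "), "\n")
})
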