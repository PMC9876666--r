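#' Fit a forest of decision trees
#'
#' Two kinds mirror the model's two forest flavours:
#' \describe{
#'   \item{\code{"A"}}{completely random trees — a uniformly random
#'     non-constant feature and a uniform threshold at every node, grown
#'     until every leaf is pure (depth-capped at 50), no bootstrap.}
#'   \item{\code{"B"}}{Gini-split random forest — the best Gini decrease
#'     among \code{mtry} (default \eqn{\sqrt{d}}) random candidate
#'     features, bootstrap resampling per tree.}
#' }
#' Trees record per-node class counts, sample counts and Gini impurity, so
#' importance, per-tree scoring and decision-path dumps need no re-walk of
#' the training data.
#'
#' @param x numeric matrix of predictors (column names kept as schema).
#' @param y integer class ids in \code{1..K}.
#' @param K number of classes.
#' @param kind \code{"A"} or \code{"B"}.
#' @param nTrees trees in the forest (default 300).
#' @param mtry candidate features per split (kind B; default
#'   \code{floor(sqrt(d))}).
#' @param maxDepth depth cap (default 50 for A, 30 for B).
#' @param minNode minimum samples per child.
#' @param bootstrap bootstrap per tree (default: B yes, A no).
#' @param seed RNG seed (C++ RNG; independent of R's stream).
#' @return An object of class \code{mvdfForest}: list of trees plus schema.
#' @export
fitForest <- function(x, y, K, kind = c("B", "A"), nTrees = 300L,
                      mtry = NULL, maxDepth = NULL, minNode = 1L,
                      bootstrap = NULL, seed = 1L) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  stopifnot(all(y >= 1L), all(y <= K), nrow(x) == length(y))
  mode <- if (kind == "A") 1L else 0L
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  if (is.null(maxDepth)) maxDepth <- if (kind == "A") 50L else 30L
  if (is.null(bootstrap)) bootstrap <- kind == "B"
  trees <- .cppFitForest(x, y - 1L, as.integer(K), as.integer(nTrees),
                         mode, as.integer(mtry), as.integer(maxDepth),
                         as.integer(minNode), bootstrap, as.integer(seed))
  structure(list(trees = trees, K = as.integer(K), kind = kind,
                 featureNames = colnames(x), nTrain = nrow(x)),
            class = "mvdfForest")
}

#' Class-probability prediction of a forest
#'
#' The forest's class vector for a sample is the mean over trees of the
#' class-frequency vector of the leaf the sample falls into.
#'
#' @param forest an \code{mvdfForest}.
#' @param x matrix with the forest's feature schema.
#' @return numeric matrix n x K; rows sum to 1.
#' @export
predictForestProba <- function(forest, x) {
  x <- alignColumns(x, forest$featureNames)
  .cppForestProba(forest$trees, x, forest$K)
}

# Per-tree leaf index (1-based node index) for each row of x.
treeLeafIndex <- function(tree, x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  .cppPredictLeaf(tree, x)
}

# Per-tree class-frequency vectors at the leaves x falls into.
treeProba <- function(tree, x) {
  leaf <- treeLeafIndex(tree, x)
  tree$counts[leaf, , drop = FALSE] / tree$n[leaf]
}

# Fit a single classification tree (Gini splits over all features).
fitClassTree <- function(x, y, K, maxDepth = 5L, minNode = 5L, seed = 1L) {
  f <- fitForest(x, y, K, kind = "B", nTrees = 1L, mtry = ncol(x),
                 maxDepth = maxDepth, minNode = minNode,
                 bootstrap = FALSE, seed = seed)
  tree <- f$trees[[1]]
  tree$featureNames <- colnames(x)
  tree
}

# Fit a multi-output SSE regression tree.
fitRegTree <- function(x, r, maxDepth = 5L, minNode = 5L, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  r <- as.matrix(r)
  storage.mode(r) <- "double"
  tree <- .cppFitRegTree(x, r, ncol(x), as.integer(maxDepth),
                         as.integer(minNode), as.integer(seed))
  tree$featureNames <- colnames(x)
  tree
}

alignColumns <- function(x, featureNames) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.null(featureNames) && !is.null(colnames(x))) {
    miss <- setdiff(featureNames, colnames(x))
    if (length(miss)) {
      stop("input lacks column(s): ", paste(miss, collapse = ", "))
    }
    x <- x[, featureNames, drop = FALSE]
  }
  x
}

# Subset the trees of a forest, preserving order.
subsetForest <- function(forest, keep) {
  forest$trees <- forest$trees[keep]
  forest
}

#' Dump a fitted tree as an indented decision path
#'
#' Each internal node prints its split indicator and threshold; every node
#' prints its Gini impurity, training sample count and per-class counts —
#' the textual analogue of inspecting a clinical decision path.
#'
#' @param tree a tree as stored inside an \code{mvdfForest}.
#' @param featureNames indicator names of the tree's input schema.
#' @param classNames optional class names for the count header.
#' @return character vector of lines.
#' @export
formatTree <- function(tree, featureNames = tree$featureNames,
                       classNames = NULL) {
  cnt <- tree$counts
  if (is.null(classNames)) classNames <- paste0("c", seq_len(ncol(cnt)))
  lines <- character(0)
  rec <- function(node, depth) {
    pad <- strrep("  ", depth)
    counts <- paste(sprintf("%s=%g", classNames, cnt[node, ]),
                    collapse = ", ")
    if (tree$feature[node] < 0) {
      pred <- classNames[which.max(cnt[node, ])]
      lines <<- c(lines, sprintf(
        "%sleaf: predict %s | gini=%.4f n=%d [%s]",
        pad, pred, tree$gini[node], tree$n[node], counts))
    } else {
      nm <- featureNames[tree$feature[node] + 1L]
      lines <<- c(lines, sprintf(
        "%sif %s <= %.6g | gini=%.4f n=%d [%s]",
        pad, nm, tree$threshold[node], tree$gini[node], tree$n[node],
        counts))
      rec(tree$left[node] + 1L, depth + 1)
      rec(tree$right[node] + 1L, depth + 1)
    }
  }
  rec(1L, 0L)
  lines
}
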