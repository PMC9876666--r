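#' Softmax probabilities
#'
#' Max-shift-stabilized softmax of a score vector (or row-wise of a score
#' matrix); output entries are positive and sum to 1.
#'
#' @param score numeric K-vector or n x K matrix of real-valued scores.
#' @return probability vector / matrix of the same shape.
#' @examples
#' softmaxProb(c(log(2), 0, 0)) # 0.5, 0.25, 0.25
#' @export
softmaxProb <- function(score) {
  if (is.matrix(score)) {
    e <- exp(score - apply(score, 1, max))
    return(e / rowSums(e))
  }
  e <- exp(score - max(score))
  e / sum(e)
}

#' Multiclass log-likelihood loss
#'
#' Cross-entropy of the true class: \eqn{-\sum_k y_k \log p_k}, with
#' probabilities clipped at 1e-12.
#'
#' @param yOnehot one-hot K-vector (or n x K matrix).
#' @param p probability K-vector (or n x K matrix).
#' @return non-negative loss (per-sample vector for matrix input).
#' @export
sampleLoss <- function(yOnehot, p) {
  p <- pmax(p, 1e-12)
  if (is.matrix(p)) return(-rowSums(yOnehot * log(p)))
  -sum(yOnehot * log(p))
}

#' Negative gradient of the log-likelihood loss
#'
#' \eqn{r_k = y_k - p_k}; components sum to 0 for one-hot targets.
#'
#' @param yOnehot one-hot K-vector (or n x K matrix).
#' @param p probability vector/matrix.
#' @return residual vector/matrix of the same shape.
#' @export
negativeGradient <- function(yOnehot, p) yOnehot - p

#' Gradient-boosting leaf values
#'
#' For the residual K-vectors routed to a leaf, the leaf's output is
#' \deqn{c_k = \frac{K-1}{K} \frac{\sum_i r_{ik}}{\sum_i |r_{ik}|(1-|r_{ik}|)},}
#' the standard multiclass Newton step; the absolute value accommodates
#' signed residuals, and a denominator below 1e-12 yields 0 (converged
#' leaf).
#'
#' @param residuals matrix with one residual K-vector per row (a single
#'   vector is treated as one row).
#' @param K number of classes.
#' @return numeric K-vector of leaf values.
#' @export
leafValues <- function(residuals, K) {
  r <- matrix(residuals, ncol = K)
  num <- colSums(r)
  den <- colSums(abs(r) * (1 - abs(r)))
  out <- numeric(K)
  ok <- den >= 1e-12
  out[ok] <- ((K - 1) / K) * num[ok] / den[ok]
  out
}

#' Coverage probability of the feature resampling
#'
#' Probability that a given secondary feature is selected at least once
#' across h independent masks with per-feature keep probability eta:
#' \eqn{1 - (1-\eta)^h}.
#'
#' @param eta keep probability in (0,1].
#' @param h number of repetitions (>= 1).
#' @return probability in (0,1].
#' @export
coverageProbability <- function(eta, h) {
  if (eta <= 0 || eta > 1) stop("eta must lie in (0,1]")
  if (h < 1) stop("h must be >= 1")
  1 - (1 - eta)^h
}

#' Fit the boosted two-tree feature set
#'
#' Fits one multiclass decision tree on the important indicators; its
#' real-valued score vector is the log of the leaf's class-frequency
#' vector (clipped at 1e-6), so the softmax reproduces the leaf
#' frequencies. The per-sample negative gradients of the log-likelihood
#' loss then become the targets of h correction trees: for each
#' repetition a Bernoulli(eta) feature mask is drawn, the masked
#' secondary indicators are encoded by the information-bottleneck
#' encoder, and a multi-output regression tree with multiclass
#' gradient-boosting leaf values is fit on the latent codes.
#'
#' @param train labeled, preprocessed [MultiviewTable-class].
#' @param split an [ImportantSplit-class].
#' @param enc an [IBEncoder-class] fitted on the split's secondary
#'   indicators.
#' @param eta per-feature mask keep probability (default 0.5).
#' @param h number of repetitions (default 200).
#' @param seed master seed; each repetition draws a distinct derived seed.
#' @param tree1MaxDepth,tree1MinNode shape of the important-indicator tree.
#' @param tree2MaxDepth,tree2MinNode shape of the correction trees.
#' @return A [BoostedFeatureSet-class].
#' @export
fitBoostPairs <- function(train, split, enc, eta = 0.5, h = 200L,
                          seed = 1L, tree1MaxDepth = 5L,
                          tree1MinNode = 5L, tree2MaxDepth = 5L,
                          tree2MinNode = 5L) {
  if (h < 1) stop("h must be >= 1")
  if (eta <= 0 || eta > 1) stop("eta must lie in (0,1]")
  y <- classLabels(train)
  if (!length(y)) stop("labels are required")
  K <- nClasses(train)
  x <- values(train)
  xv <- x[, split@important, drop = FALSE]
  xs <- x[, split@secondary, drop = FALSE]
  if (!identical(colnames(xs), enc@inputNames)) {
    stop("encoder was fitted on a different secondary schema")
  }

  tree1 <- fitClassTree(xv, y, K, maxDepth = tree1MaxDepth,
                        minNode = tree1MinNode,
                        seed = deriveSeed(seed, 11L))
  yhat <- tree1Scores(tree1, xv)
  p <- softmaxProb(yhat)
  r <- negativeGradient(oneHot(y, K), p)

  ds <- ncol(xs)
  pairs <- vector("list", h)
  for (rep_ in seq_len(h)) {
    repSeed <- deriveSeed(seed, 100L, rep_)
    mask <- withSeed(repSeed, stats::runif(ds) < eta)
    tz <- encodeSecondary(enc, xs, mask)
    tree2 <- fitRegTree(tz, r, maxDepth = tree2MaxDepth,
                        minNode = tree2MinNode, seed = repSeed)
    leaf <- treeLeafIndex(tree2, tz)
    lv <- matrix(0, length(tree2$n), K)
    for (lf in unique(leaf)) {
      lv[lf, ] <- leafValues(r[leaf == lf, , drop = FALSE], K)
    }
    pairs[[rep_]] <- list(mask = mask, tree2 = tree2, leafValues = lv,
                          seed = repSeed)
  }
  new("BoostedFeatureSet", tree1 = tree1, pairs = pairs,
      eta = as.numeric(eta), h = as.integer(h), K = K,
      importantNames = split@important, secondaryNames = split@secondary,
      seed = as.integer(seed))
}

#' Score vectors of the important-indicator tree
#'
#' The real-valued output the softmax converts to class probabilities:
#' the log of the leaf class-frequency vector, clipped at 1e-6.
#'
#' @param tree1 the first tree of a [BoostedFeatureSet-class] (or the set
#'   itself).
#' @param xv matrix of important-indicator values.
#' @return numeric n x K score matrix.
#' @export
tree1Scores <- function(tree1, xv) {
  if (is(tree1, "BoostedFeatureSet")) tree1 <- tree1@tree1
  log(pmax(treeProba(tree1, alignColumns(xv, tree1$featureNames)), 1e-6))
}

#' Build the z2 correction-feature block
#'
#' Routes each sample through every repetition's correction tree and emits
#' the leaf's K-vector of gradient-boosting values; concatenation over the
#' h repetitions gives \eqn{D = hK} columns.
#'
#' @param set a fitted [BoostedFeatureSet-class].
#' @param enc the [IBEncoder-class] used at fit time.
#' @param t a [MultiviewTable-class] with the fit-time indicator schema.
#' @param split the fit-time [ImportantSplit-class].
#' @return A [ClassVectorBlock-class] with source \code{"z2"} and columns
#'   \code{z2_rep<r>_c<k>}.
#' @export
transformZ2 <- function(set, enc, t, split) {
  x <- values(t)
  miss <- setdiff(split@secondary, colnames(x))
  if (length(miss)) {
    stop("table lacks secondary column(s): ", paste(miss, collapse = ", "))
  }
  xs <- x[, split@secondary, drop = FALSE]
  n <- nrow(xs)
  K <- set@K
  blocks <- vector("list", set@h)
  for (rep_ in seq_len(set@h)) {
    pr <- set@pairs[[rep_]]
    tz <- encodeSecondary(enc, xs, pr$mask)
    leaf <- treeLeafIndex(pr$tree2, tz)
    b <- pr$leafValues[leaf, , drop = FALSE]
    colnames(b) <- sprintf("z2_rep%d_c%d", rep_, seq_len(K))
    blocks[[rep_]] <- b
  }
  new("ClassVectorBlock", values = do.call(cbind, blocks), source = "z2",
      K = K)
}

setMethod("show", "BoostedFeatureSet", function(object) {
  cat(sprintf(
    "BoostedFeatureSet: h = %d repetitions, eta = %g, K = %d\n",
    object@h, object@eta, object@K))
  cat(sprintf("important: %d indicators; secondary: %d indicators\n",
              length(object@importantNames),
              length(object@secondaryNames)))
  cat(sprintf("feature coverage probability: %.6f\n",
              coverageProbability(object@eta, object@h)))
})
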