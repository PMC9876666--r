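#' Multiview deep forest configuration
#'
#' Defaults follow the model's published hyperparameter table: two feature
#' extraction forests per view subset with 300 trees each, h = 200
#' resampling repetitions with eta = 0.5, beta = 0.1, latent width 10,
#' and four 300-tree forests per cascade level. The tree-score weight
#' alpha defaults to -0.5 (penalize impure trees).
#'
#' @param treesPerForest trees per extraction forest.
#' @param cascadeTrees trees per cascade forest (before pruning).
#' @param cascadeForests forests per cascade level.
#' @param h resampling repetitions of the boosted transform.
#' @param eta per-feature resampling keep probability.
#' @param beta information-bottleneck compression multiplier.
#' @param latentDim latent width |z|.
#' @param topK indicators taken by Gini score.
#' @param expertList expert-designated important indicators.
#' @param alpha leaf-impurity weight of the tree score.
#' @param cvFolds cross-fitting folds.
#' @param patience,maxLevels cascade growth policy.
#' @param epochs,hidden,learningRate encoder training knobs.
#' @param tree1MaxDepth,tree1MinNode,tree2MaxDepth,tree2MinNode boosted
#'   tree shapes.
#' @param useZ1,useZ2,prune module toggles (the ablation axes).
#' @param seed master seed.
#' @param ... overrides stored verbatim.
#' @return a list of class \code{mvdfConfig}.
#' @export
mvdfConfig <- function(treesPerForest = 300L, cascadeTrees = 300L,
                       cascadeForests = 4L, h = 200L, eta = 0.5,
                       beta = 0.1, latentDim = 10L, topK = 5L,
                       expertList = character(0), alpha = -0.5,
                       cvFolds = 3L, patience = 1L, maxLevels = 10L,
                       epochs = 200L, hidden = 64L, learningRate = 0.01,
                       tree1MaxDepth = 5L, tree1MinNode = 5L,
                       tree2MaxDepth = 5L, tree2MinNode = 5L,
                       useZ1 = TRUE, useZ2 = TRUE, prune = TRUE,
                       seed = 1L, ...) {
  cfg <- list(treesPerForest = as.integer(treesPerForest),
              cascadeTrees = as.integer(cascadeTrees),
              cascadeForests = as.integer(cascadeForests),
              h = as.integer(h), eta = eta, beta = beta,
              latentDim = as.integer(latentDim), topK = as.integer(topK),
              expertList = expertList, alpha = alpha,
              cvFolds = as.integer(cvFolds),
              patience = as.integer(patience),
              maxLevels = as.integer(maxLevels),
              epochs = as.integer(epochs), hidden = as.integer(hidden),
              learningRate = learningRate,
              tree1MaxDepth = as.integer(tree1MaxDepth),
              tree1MinNode = as.integer(tree1MinNode),
              tree2MaxDepth = as.integer(tree2MaxDepth),
              tree2MinNode = as.integer(tree2MinNode),
              useZ1 = useZ1, useZ2 = useZ2, prune = prune,
              seed = as.integer(seed))
  extra <- list(...)
  cfg[names(extra)] <- extra
  structure(cfg, class = "mvdfConfig")
}

#' Fit a multiview deep forest
#'
#' Runs the full pipeline on a preprocessed, labeled table: multiview
#' class-vector extraction (z1), Gini-importance plus expert selection of
#' important indicators, information-bottleneck compression of the
#' secondary indicators, boosted two-tree correction features (z2), and
#' the pruned cascade on \code{Z = [z1 | z2 | X]}. The \code{useZ1},
#' \code{useZ2} and \code{prune} toggles drop the corresponding module
#' (the ablation axes); the extractors are always fitted because the
#' importance split needs their Gini-split forests.
#'
#' @param train a labeled, preprocessed [MultiviewTable-class].
#' @param config an [mvdfConfig()] list.
#' @return An [MVDFModel-class].
#' @export
mvdfFit <- function(train, config = mvdfConfig()) {
  y <- classLabels(train)
  if (!length(y)) stop("labels are required")
  seed <- config$seed
  ex <- fitExtractors(train, nTrees = config$treesPerForest,
                      cvFolds = config$cvFolds,
                      seed = deriveSeed(seed, 21L))
  vim <- giniImportance(ex)
  split <- selectImportant(vim, expertList = config$expertList,
                           topK = config$topK)

  z1 <- if (config$useZ1) transformZ1(ex, train, isTraining = TRUE)

  enc <- NULL
  bset <- NULL
  z2 <- NULL
  if (config$useZ2) {
    if (!length(split@secondary)) {
      stop("no secondary indicators left to compress")
    }
    xs <- values(train)[, split@secondary, drop = FALSE]
    enc <- fitIBEncoder(xs, y, latentDim = config$latentDim,
                        beta = config$beta, epochs = config$epochs,
                        hidden = config$hidden,
                        learningRate = config$learningRate,
                        seed = deriveSeed(seed, 22L))
    bset <- fitBoostPairs(train, split, enc, eta = config$eta,
                          h = config$h, seed = deriveSeed(seed, 23L),
                          tree1MaxDepth = config$tree1MaxDepth,
                          tree1MinNode = config$tree1MinNode,
                          tree2MaxDepth = config$tree2MaxDepth,
                          tree2MinNode = config$tree2MinNode)
    z2 <- transformZ2(bset, enc, train, split)
  }

  z <- assembleZ(z1, z2, train)
  cascade <- growCascade(z, y, K = nClasses(train),
                         nForests = config$cascadeForests,
                         treesPerForest = config$cascadeTrees,
                         cvFolds = config$cvFolds, alpha = config$alpha,
                         prune = config$prune, patience = config$patience,
                         maxLevels = config$maxLevels,
                         seed = deriveSeed(seed, 24L))
  new("MVDFModel", extractors = ex, importance = vim, split = split,
      encoder = enc, boostSet = bset, cascade = cascade,
      config = unclass(config), labelLevels = labelLevels(train),
      indicatorNames = indicatorNames(train))
}

assembleZ <- function(z1, z2, t) {
  parts <- list()
  if (!is.null(z1)) parts$z1 <- z1@values
  if (!is.null(z2)) parts$z2 <- z2@values
  parts$x <- values(t)
  do.call(cbind, unname(parts))
}

#' Predict with a fitted multiview deep forest
#'
#' @param model an [MVDFModel-class].
#' @param t a preprocessed [MultiviewTable-class] with the fit-time
#'   indicator schema.
#' @param type \code{"class"} (original label values) or \code{"prob"}.
#' @return character vector of labels, or an n x K probability matrix.
#' @export
mvdfPredict <- function(model, t, type = c("class", "prob")) {
  type <- match.arg(type)
  cfg <- model@config
  z1 <- if (cfg$useZ1) transformZ1(model@extractors, t)
  z2 <- if (cfg$useZ2) {
    transformZ2(model@boostSet, model@encoder, t, model@split)
  }
  z <- assembleZ(z1, z2, t)
  p <- cascadePredictProba(model@cascade, z)
  colnames(p) <- model@labelLevels
  if (type == "prob") return(p)
  model@labelLevels[rowArgmax(p)]
}

#' Classification metrics
#'
#' Accuracy, per-class precision/recall/F1 and the confusion matrix, the
#' layout used for survival-class evaluation throughout the package.
#'
#' @param truth true labels (any atomic type).
#' @param predicted predicted labels on the same coding.
#' @return list with \code{accuracy}, \code{perClass} data.frame and
#'   \code{confusion} table.
#' @export
mvdfEvaluate <- function(truth, predicted) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  lev <- sort(unique(c(truth, predicted)))
  cm <- table(factor(truth, lev), factor(predicted, lev))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = mean(truth == predicted),
       perClass = data.frame(class = lev, precision = unname(prec),
                             recall = unname(rec), f1 = unname(f1)),
       confusion = cm)
}

#' Ablation harness
#'
#' Re-fits the model with each module toggled — the multiview z1 block,
#' the information-bottleneck boosted z2 block, and cascade pruning —
#' and reports recall/precision/F1 per class plus accuracy for each
#' configuration: the plain cascade baseline, each single module, and the
#' full model.
#'
#' @param train,test preprocessed labeled [MultiviewTable-class] pair.
#' @param config base [mvdfConfig()].
#' @param configurations named list of toggle lists
#'   (\code{useZ1}/\code{useZ2}/\code{prune}); a default set of five is
#'   provided.
#' @return data.frame with columns configuration, class, recall,
#'   precision, f1, accuracy.
#' @export
mvdfAblate <- function(train, test, config = mvdfConfig(),
                       configurations = NULL) {
  if (is.null(configurations)) {
    configurations <- list(
      cascade_baseline = list(useZ1 = FALSE, useZ2 = FALSE, prune = FALSE),
      multiview_z1 = list(useZ1 = TRUE, useZ2 = FALSE, prune = FALSE),
      ib_boost_z2 = list(useZ1 = FALSE, useZ2 = TRUE, prune = FALSE),
      pruning = list(useZ1 = FALSE, useZ2 = FALSE, prune = TRUE),
      full_mvdf = list(useZ1 = TRUE, useZ2 = TRUE, prune = TRUE))
  }
  rows <- list()
  for (nm in names(configurations)) {
    cfg <- config
    cfg[names(configurations[[nm]])] <- configurations[[nm]]
    model <- mvdfFit(train, cfg)
    pred <- mvdfPredict(model, test)
    ev <- mvdfEvaluate(labelLevels(test)[classLabels(test)], pred)
    df <- ev$perClass
    rows[[nm]] <- data.frame(configuration = nm, class = df$class,
                             recall = df$recall, precision = df$precision,
                             f1 = df$f1, accuracy = ev$accuracy)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

setMethod("show", "MVDFModel", function(object) {
  cat("MVDFModel\n")
  cat(sprintf("  indicators: %d | classes: %s\n",
              length(object@indicatorNames),
              paste(object@labelLevels, collapse = "/")))
  cat(sprintf("  modules: z1=%s z2=%s prune=%s\n",
              object@config$useZ1, object@config$useZ2,
              object@config$prune))
  cat(sprintf("  important indicators: %s\n",
              paste(object@split@important, collapse = ", ")))
  cat(sprintf("  cascade: %d level(s), CV accuracy %s\n",
              length(object@cascade@levels),
              paste(sprintf("%.4f", object@cascade@cvAccuracy),
                    collapse = ", ")))
})
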