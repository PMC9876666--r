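#' @import methods
NULL

#' MultiviewTable: a cohort with a view partition
#'
#' The universal input object: a samples x indicators numeric matrix, a
#' partition of the indicators into views, optional class labels, and a
#' missingness mask. Cells flagged in \code{missingMask} hold \code{NA}
#' until imputed.
#'
#' @slot values numeric matrix, samples x indicators, with column names.
#' @slot viewOf integer vector named by indicator, giving the view id in
#'   \code{1..m} of each indicator.
#' @slot viewNames character vector of length m naming the views.
#' @slot labels integer vector of class ids in \code{1..K}, or
#'   \code{integer(0)} for unlabeled data.
#' @slot labelLevels character vector of the original label values, in the
#'   sorted order that defines the class ids.
#' @slot missingMask logical matrix congruent with \code{values}.
#'
#' @seealso [multiviewTable()], [readMultiviewTable()], [generateCohort()]
#' @export
setClass("MultiviewTable",
  representation(
    values = "matrix",
    viewOf = "integer",
    viewNames = "character",
    labels = "integer",
    labelLevels = "character",
    missingMask = "matrix"
  ),
  prototype(
    values = matrix(numeric(0), 0, 0),
    viewOf = integer(0),
    viewNames = character(0),
    labels = integer(0),
    labelLevels = character(0),
    missingMask = matrix(logical(0), 0, 0)
  )
)

setValidity("MultiviewTable", function(object) {
  v <- object@values
  msgs <- character(0)
  if (is.null(colnames(v)) && ncol(v) > 0) {
    msgs <- c(msgs, "values must have column names (indicator names)")
  }
  if (!identical(dim(v), dim(object@missingMask))) {
    msgs <- c(msgs, "missingMask must be congruent with values")
  }
  if (ncol(v) > 0) {
    if (!setequal(names(object@viewOf), colnames(v)) ||
        length(object@viewOf) != ncol(v)) {
      msgs <- c(msgs, "every indicator must belong to exactly one view")
    }
    m <- length(object@viewNames)
    if (m < 1) msgs <- c(msgs, "at least one view is required")
    if (length(object@viewOf) &&
        !all(object@viewOf %in% seq_len(max(1L, m)))) {
      msgs <- c(msgs, "view ids must lie in 1..m")
    }
  }
  if (length(object@labels)) {
    if (length(object@labels) != nrow(v)) {
      msgs <- c(msgs, "labels must have one entry per sample")
    }
    K <- length(object@labelLevels)
    if (K < 2) msgs <- c(msgs, "at least two classes are required")
    if (!all(object@labels %in% seq_len(max(1L, K)))) {
      msgs <- c(msgs, "class ids must lie in 1..K")
    }
  }
  if (length(v) && any(!is.finite(v[!object@missingMask]))) {
    msgs <- c(msgs, "non-finite values outside the missing mask")
  }
  if (length(msgs)) msgs else TRUE
})

#' Preprocessing configuration
#'
#' Controls imputation (sex-stratified means for designated indicators, a
#' unified constant for the rest), normalization and the stratified split.
#'
#' @slot sexIndicator indicator used to stratify imputation, or
#'   \code{character(0)}.
#' @slot sexStratifiedIndicators indicators imputed by within-stratum mean.
#' @slot unifiedFillValue constant fill for all other missing cells.
#' @slot normalization one of \code{"minmax"}, \code{"zscore"},
#'   \code{"none"}.
#' @slot testFraction fraction of each class held out, strictly in (0,1).
#' @slot splitSeed RNG seed for the split.
#' @seealso [preprocessConfig()]
#' @export
setClass("PreprocessConfig",
  representation(
    sexIndicator = "character",
    sexStratifiedIndicators = "character",
    unifiedFillValue = "numeric",
    normalization = "character",
    testFraction = "numeric",
    splitSeed = "integer"
  ),
  prototype(
    sexIndicator = character(0),
    sexStratifiedIndicators = character(0),
    unifiedFillValue = 0,
    normalization = "minmax",
    testFraction = 0.3,
    splitSeed = 1L
  )
)

setValidity("PreprocessConfig", function(object) {
  msgs <- character(0)
  if (length(object@testFraction) != 1 || object@testFraction <= 0 ||
      object@testFraction >= 1) {
    msgs <- c(msgs, "testFraction must lie strictly between 0 and 1")
  }
  if (!object@normalization %in% c("minmax", "zscore", "none")) {
    msgs <- c(msgs, "normalization must be minmax, zscore or none")
  }
  if (length(msgs)) msgs else TRUE
})

#' Specification of a synthetic multiview cohort
#'
#' Describes the generative model of [generateCohort()]: class-conditional
#' Gaussian informative indicators, correlated redundant copies, pure-noise
#' filler, optional binarization, expert "important" indicators with a
#' doubled effect, and MCAR missingness.
#'
#' @slot nSamples number of patients.
#' @slot classPriors class probabilities, summing to 1.
#' @slot viewSizes indicator count per view.
#' @slot informativePerView informative indicators in each view.
#' @slot effectSize class-mean separation in within-class SD units.
#' @slot redundancyRho correlation of redundant copies with their source.
#' @slot importantIndicators indicators given twice the effect size.
#' @slot missingRate MCAR missingness rate in [0,1).
#' @slot binaryFraction fraction of columns thresholded at their median.
#' @slot seed RNG seed.
#' @seealso [syntheticSpec()], [generateCohort()]
#' @export
setClass("SyntheticSpec",
  representation(
    nSamples = "integer",
    classPriors = "numeric",
    viewSizes = "integer",
    informativePerView = "integer",
    effectSize = "numeric",
    redundancyRho = "numeric",
    importantIndicators = "character",
    missingRate = "numeric",
    binaryFraction = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msgs <- character(0)
  if (abs(sum(object@classPriors) - 1) > 1e-9) {
    msgs <- c(msgs, "class priors must sum to 1")
  }
  if (length(object@classPriors) < 2) {
    msgs <- c(msgs, "at least two classes are required")
  }
  if (any(object@viewSizes < 1)) msgs <- c(msgs, "empty view")
  if (any(object@informativePerView > object@viewSizes)) {
    msgs <- c(msgs, "informativePerView exceeds a view size")
  }
  if (object@missingRate < 0 || object@missingRate >= 1) {
    msgs <- c(msgs, "missingRate must lie in [0,1)")
  }
  if (object@binaryFraction < 0 || object@binaryFraction > 1) {
    msgs <- c(msgs, "binaryFraction must lie in [0,1]")
  }
  if (object@redundancyRho < 0 || object@redundancyRho >= 1) {
    msgs <- c(msgs, "redundancyRho must lie in [0,1)")
  }
  if (object@nSamples < 1) msgs <- c(msgs, "nSamples must be positive")
  if (length(msgs)) msgs else TRUE
})

#' A block of concatenated class vectors
#'
#' Holds the learned representation blocks: \code{z1} (multiview forest
#' class vectors; every consecutive K-slice is a probability vector) or
#' \code{z2} (boosted correction vectors, unconstrained reals).
#'
#' @slot values numeric matrix, samples x D.
#' @slot source \code{"z1"} or \code{"z2"}.
#' @slot K number of classes.
#' @export
setClass("ClassVectorBlock",
  representation(values = "matrix", source = "character", K = "integer")
)

setValidity("ClassVectorBlock", function(object) {
  msgs <- character(0)
  K <- object@K
  if (!object@source %in% c("z1", "z2")) {
    msgs <- c(msgs, "source must be z1 or z2")
  }
  if (ncol(object@values) %% K != 0) {
    msgs <- c(msgs, "width must be a multiple of K")
  }
  if (identical(object@source, "z1") && nrow(object@values) > 0) {
    for (b in seq_len(ncol(object@values) / K)) {
      sl <- object@values[, (b - 1) * K + seq_len(K), drop = FALSE]
      if (any(sl < -1e-9) || any(abs(rowSums(sl) - 1) > 1e-9)) {
        msgs <- c(msgs, sprintf("K-slice %d is not a probability vector", b))
        break
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Fitted multiview feature extractors
#'
#' One completely-random forest (kind A) and one Gini-split random forest
#' (kind B) per non-empty view subset, each with cross-fitting fold models
#' for leakage-free training-set class vectors.
#'
#' @slot extractors list of per-(subset, kind) fitted extractors.
#' @slot subsets list of integer view-id sets, in stable order.
#' @slot foldAssign fold id per training sample.
#' @slot K number of classes.
#' @slot cvFolds number of cross-fitting folds.
#' @slot viewOf the training table's indicator-to-view map.
#' @slot viewNames view names.
#' @slot nTrees trees per forest.
#' @slot seed master seed.
#' @export
setClass("MultiviewExtractors",
  representation(
    extractors = "list", subsets = "list", foldAssign = "integer",
    K = "integer", cvFolds = "integer", viewOf = "integer",
    viewNames = "character", nTrees = "integer", seed = "integer"
  )
)

#' Gini importance scores
#'
#' Total weighted impurity decrease attributable to each indicator across
#' all splits of the Gini-split (kind B) forests. Indicators never used in
#' a split score exactly 0.
#'
#' @slot vim named numeric vector over all indicators.
#' @slot sourceForests identifiers of the forests scanned.
#' @export
setClass("GiniImportance",
  representation(vim = "numeric", sourceForests = "character")
)

setValidity("GiniImportance", function(object) {
  if (any(!is.finite(object@vim))) "non-finite importance" else TRUE
})

#' Partition into important and secondary indicators
#'
#' @slot important ordered important indicators (top-k by importance plus
#'   the expert list).
#' @slot secondary the complement, in table order.
#' @slot expertList the expert-designated indicators.
#' @export
setClass("ImportantSplit",
  representation(
    important = "character", secondary = "character",
    expertList = "character"
  )
)

setValidity("ImportantSplit", function(object) {
  msgs <- character(0)
  if (length(intersect(object@important, object@secondary))) {
    msgs <- c(msgs, "important and secondary overlap")
  }
  if (!all(object@expertList %in% object@important)) {
    msgs <- c(msgs, "expert indicators must be important")
  }
  if (length(msgs)) msgs else TRUE
})

#' Variational information-bottleneck encoder
#'
#' A stochastic Gaussian encoder T | X^s with a categorical decoder for the
#' class label, trained to maximize a lower bound on I(T;Y) minus beta
#' times a KL upper bound on I(X^s;T). Inference uses the posterior mean,
#' so encoding is deterministic.
#'
#' @slot params list of weight matrices and biases.
#' @slot latentDim latent width |z|.
#' @slot beta compression multiplier (>= 0).
#' @slot hidden hidden-layer width.
#' @slot K number of classes.
#' @slot history per-epoch data.frame: loss, crossEntropy, kl, iTY, iXT.
#' @slot inputNames secondary indicator names, fixing the input schema.
#' @slot seed RNG seed.
#' @export
setClass("IBEncoder",
  representation(
    params = "list", latentDim = "integer", beta = "numeric",
    hidden = "integer", K = "integer", history = "data.frame",
    inputNames = "character", seed = "integer"
  )
)

setValidity("IBEncoder", function(object) {
  msgs <- character(0)
  if (object@latentDim < 1) msgs <- c(msgs, "latentDim must be >= 1")
  if (object@beta < 0) msgs <- c(msgs, "beta must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Boosted two-tree feature set
#'
#' A single multiclass tree over the important indicators plus h correction
#' trees over masked-and-encoded secondary indicators, each with multiclass
#' gradient-boosting leaf values; every correction tree contributes one
#' K-vector per sample to the z2 block.
#'
#' @slot tree1 classification tree over the important indicators.
#' @slot pairs list of h (mask, correction tree, leaf-value matrix) records.
#' @slot eta per-feature mask keep probability in (0,1].
#' @slot h number of repetitions.
#' @slot K number of classes.
#' @slot importantNames,secondaryNames fit-time schema.
#' @slot seed master seed.
#' @export
setClass("BoostedFeatureSet",
  representation(
    tree1 = "list", pairs = "list", eta = "numeric", h = "integer",
    K = "integer", importantNames = "character",
    secondaryNames = "character", seed = "integer"
  )
)

setValidity("BoostedFeatureSet", function(object) {
  msgs <- character(0)
  if (length(object@pairs) != object@h) {
    msgs <- c(msgs, "number of pairs must equal h")
  }
  if (object@eta <= 0 || object@eta > 1) {
    msgs <- c(msgs, "eta must lie in (0,1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Pruned cascade-forest model
#'
#' A sequence of levels, each holding four forests (two completely-random,
#' two Gini-split) whose trees were pruned by the score-based keep
#' probability; the last level's four class vectors are averaged for the
#' final prediction.
#'
#' @slot levels list of fitted levels (each: 4 slots of fold models).
#' @slot K number of classes.
#' @slot alpha leaf-impurity weight of the tree score.
#' @slot schema column names of the assembled input Z.
#' @slot cvAccuracy cross-validated accuracy per grown level.
#' @slot bestLevel the level the model is truncated at.
#' @slot growth growth policy (patience, maxLevels, cvFolds, prune flag).
#' @slot seed master seed.
#' @export
setClass("CascadeModel",
  representation(
    levels = "list", K = "integer", alpha = "numeric", schema = "character",
    cvAccuracy = "numeric", bestLevel = "integer", growth = "list",
    seed = "integer"
  )
)

setValidity("CascadeModel", function(object) {
  msgs <- character(0)
  if (length(object@levels) < 1) msgs <- c(msgs, "at least one level")
  if (object@bestLevel < 1 || object@bestLevel > length(object@levels)) {
    msgs <- c(msgs, "bestLevel out of range")
  }
  if (length(msgs)) msgs else TRUE
})

#' Fitted end-to-end multiview deep forest
#'
#' Bundles every fitted stage: the multiview extractors (z1), the
#' importance split, the information-bottleneck encoder and boosted
#' feature set (z2), and the pruned cascade, together with the resolved
#' configuration.
#'
#' @slot extractors fitted [MultiviewExtractors-class].
#' @slot importance fitted [GiniImportance-class].
#' @slot split [ImportantSplit-class].
#' @slot encoder [IBEncoder-class] or NULL when z2 is disabled.
#' @slot boostSet [BoostedFeatureSet-class] or NULL.
#' @slot cascade [CascadeModel-class].
#' @slot config resolved configuration list.
#' @slot labelLevels original label values defining the class ids.
#' @slot indicatorNames fit-time indicator schema.
#' @export
setClass("MVDFModel",
  representation(
    extractors = "ANY", importance = "ANY", split = "ANY",
    encoder = "ANY", boostSet = "ANY", cascade = "ANY",
    config = "list", labelLevels = "character",
    indicatorNames = "character"
  )
)
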