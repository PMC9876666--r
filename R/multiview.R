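#' Enumerate non-empty view subsets
#'
#' All \eqn{2^m - 1} non-empty subsets of the view ids, ordered by size
#' and then lexicographically, so feature-column order is stable across
#' runs.
#'
#' @param m number of views (>= 1).
#' @return list of integer vectors of view ids.
#' @examples
#' enumerateViewSubsets(2) # {1}, {2}, {1,2}
#' @export
enumerateViewSubsets <- function(m) {
  if (!is.numeric(m) || length(m) != 1 || m < 1) {
    stop("m must be a positive integer")
  }
  m <- as.integer(m)
  out <- list()
  for (size in seq_len(m)) {
    cmb <- utils::combn(m, size)
    for (j in seq_len(ncol(cmb))) out[[length(out) + 1L]] <- cmb[, j]
  }
  out
}

subsetTag <- function(s) paste(s, collapse = "")

#' Fit the multiview feature extractors
#'
#' For every non-empty subset of views, trains one completely-random
#' forest (kind A, grown to pure leaves) and one Gini-split random forest
#' (kind B) on the subset's columns — \eqn{2(2^m-1)} extractors in total.
#' Each extractor also keeps \code{cvFolds} fold models so that
#' training-set class vectors can be produced by cross-fitting, the
#' leakage control the cascade depends on.
#'
#' @param train a labeled, preprocessed [MultiviewTable-class].
#' @param nTrees trees per forest (default 300).
#' @param cvFolds cross-fitting folds (default 3).
#' @param seed master seed.
#' @return A [MultiviewExtractors-class].
#' @export
fitExtractors <- function(train, nTrees = 300L, cvFolds = 3L, seed = 1L) {
  y <- classLabels(train)
  if (!length(y)) stop("labels are required to fit extractors")
  K <- nClasses(train)
  m <- nViews(train)
  x <- values(train)
  vOf <- viewOf(train)
  subsets <- enumerateViewSubsets(m)
  foldAssign <- stratifiedFolds(y, cvFolds, deriveSeed(seed, 1L))

  extractors <- list()
  for (si in seq_along(subsets)) {
    s <- subsets[[si]]
    cols <- names(vOf)[vOf %in% s]
    xs <- x[, cols, drop = FALSE]
    for (kind in c("A", "B")) {
      koff <- if (kind == "A") 0L else 500L
      full <- fitForest(xs, y, K, kind = kind, nTrees = nTrees,
                        seed = deriveSeed(seed, si, koff, 0L))
      foldModels <- lapply(seq_len(cvFolds), function(f) {
        idx <- foldAssign != f
        fitForest(xs[idx, , drop = FALSE], y[idx], K, kind = kind,
                  nTrees = nTrees, seed = deriveSeed(seed, si, koff, f))
      })
      extractors[[length(extractors) + 1L]] <- list(
        subset = s, kind = kind, columns = cols, full = full,
        foldModels = foldModels)
    }
  }
  new("MultiviewExtractors", extractors = extractors, subsets = subsets,
      foldAssign = foldAssign, K = K, cvFolds = as.integer(cvFolds),
      viewOf = vOf, viewNames = viewNames(train),
      nTrees = as.integer(nTrees), seed = as.integer(seed))
}

#' Build the z1 class-vector block
#'
#' Concatenates the K-dimensional class vectors of all extractors:
#' \eqn{D = 2K(2^m-1)} columns. For training data
#' (\code{isTraining = TRUE}) each sample's vector comes from the fold
#' model that did not train on it; new data is pushed through the
#' full-data models.
#'
#' @param ex a fitted [MultiviewExtractors-class].
#' @param t a [MultiviewTable-class] with the fit-time view schema.
#' @param isTraining use cross-fitted fold models (requires \code{t} to be
#'   the training table).
#' @return A [ClassVectorBlock-class] with source \code{"z1"} and columns
#'   \code{z1_<kind>_s<subset>_c<k>}.
#' @export
transformZ1 <- function(ex, t, isTraining = FALSE) {
  if (!identical(ex@viewOf[sort(names(ex@viewOf))],
                 viewOf(t)[sort(names(viewOf(t)))])) {
    stop("view schema of the table does not match the extractors")
  }
  x <- values(t)
  n <- nrow(x)
  if (isTraining && n != length(ex@foldAssign)) {
    stop("isTraining requires the original training table")
  }
  K <- ex@K
  blocks <- vector("list", length(ex@extractors))
  for (i in seq_along(ex@extractors)) {
    e <- ex@extractors[[i]]
    xs <- x[, e$columns, drop = FALSE]
    if (isTraining) {
      p <- matrix(NA_real_, n, K)
      for (f in seq_len(ex@cvFolds)) {
        held <- ex@foldAssign == f
        p[held, ] <- predictForestProba(e$foldModels[[f]],
                                        xs[held, , drop = FALSE])
      }
    } else {
      p <- predictForestProba(e$full, xs)
    }
    colnames(p) <- sprintf("z1_%s_s%s_c%d", e$kind, subsetTag(e$subset),
                           seq_len(K))
    blocks[[i]] <- p
  }
  out <- do.call(cbind, blocks)
  new("ClassVectorBlock", values = out, source = "z1", K = K)
}
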