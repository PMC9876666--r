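#' Gini importance of indicators
#'
#' For every node split on indicator i, the contribution is the node's
#' Gini impurity minus the sample-fraction-weighted impurities of its two
#' children; an indicator's score is the sum of its contributions over all
#' Gini-split (kind B) forests. Completely random trees carry no
#' importance information and are skipped. Indicators never used in a
#' split score exactly 0.
#'
#' @param forests a fitted [MultiviewExtractors-class] (its kind-B full
#'   models are scanned), a single \code{mvdfForest}, or a list of
#'   \code{mvdfForest} objects.
#' @param indicatorNames all indicator names (defaults to the extractor
#'   schema), so unused indicators appear with score 0.
#' @return A [GiniImportance-class].
#' @export
giniImportance <- function(forests, indicatorNames = NULL) {
  if (is(forests, "MultiviewExtractors")) {
    if (is.null(indicatorNames)) indicatorNames <- names(forests@viewOf)
    fl <- lapply(Filter(function(e) e$kind == "B", forests@extractors),
                 function(e) e$full)
    src <- vapply(Filter(function(e) e$kind == "B", forests@extractors),
                  function(e) sprintf("B_s%s", subsetTag(e$subset)), "")
  } else if (inherits(forests, "mvdfForest")) {
    fl <- list(forests)
    src <- "B"
  } else {
    fl <- forests
    src <- sprintf("B_%d", seq_along(fl))
  }
  if (is.null(indicatorNames)) {
    indicatorNames <- unique(unlist(lapply(fl, `[[`, "featureNames")))
  }
  vim <- stats::setNames(numeric(length(indicatorNames)), indicatorNames)
  for (forest in fl) {
    fn <- forest$featureNames
    for (tree in forest$trees) {
      internal <- which(tree$feature >= 0L)
      if (!length(internal)) next
      l <- tree$left[internal] + 1L
      r <- tree$right[internal] + 1L
      nP <- tree$n[internal]
      dec <- tree$gini[internal] -
        (tree$n[l] / nP) * tree$gini[l] -
        (tree$n[r] / nP) * tree$gini[r]
      f <- fn[tree$feature[internal] + 1L]
      agg <- tapply(dec, f, sum)
      vim[names(agg)] <- vim[names(agg)] + agg
    }
  }
  new("GiniImportance", vim = vim, sourceForests = as.character(src))
}

#' Select important indicators
#'
#' The important set is the union of the top-k indicators by Gini score
#' (ties broken by name) and the expert-designated list; the secondary set
#' is the complement, in table order.
#'
#' @param vim a [GiniImportance-class].
#' @param expertList expert-designated indicator names.
#' @param topK indicators taken by score (default 5).
#' @return An [ImportantSplit-class].
#' @export
selectImportant <- function(vim, expertList = character(0), topK = 5L) {
  if (topK < 1) stop("topK must be >= 1")
  scores <- vim@vim
  absent <- setdiff(expertList, names(scores))
  if (length(absent)) {
    stop("expert indicator(s) absent from the table: ",
         paste(absent, collapse = ", "))
  }
  ord <- order(-scores, names(scores))
  top <- names(scores)[ord][seq_len(min(topK, length(scores)))]
  important <- c(top, setdiff(expertList, top))
  secondary <- setdiff(names(scores), important)
  new("ImportantSplit", important = important, secondary = secondary,
      expertList = as.character(expertList))
}

#' Export an importance table
#'
#' @param vim a [GiniImportance-class].
#' @param split optional [ImportantSplit-class] to flag expert indicators.
#' @param path optional CSV output path.
#' @return data.frame (indicator, vim, rank, expertFlag), best first.
#' @export
importanceTable <- function(vim, split = NULL, path = NULL) {
  ord <- order(-vim@vim, names(vim@vim))
  df <- data.frame(indicator = names(vim@vim)[ord],
                   vim = unname(vim@vim[ord]),
                   rank = seq_along(ord),
                   expertFlag = if (is.null(split)) FALSE else
                     names(vim@vim)[ord] %in% split@expertList)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
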