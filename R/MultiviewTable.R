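#' Construct a MultiviewTable
#'
#' @param values numeric matrix (samples x indicators) with column names.
#'   \code{NA} cells are flagged as missing.
#' @param views either a named list \code{list(viewName = c(indicator,
#'   ...))} covering every column, or a vector of view ids/names named by
#'   indicator.
#' @param labels optional vector of class labels (any atomic type); class
#'   ids are assigned by sorted unique value.
#' @param labelLevels optional explicit level ordering; defaults to the
#'   sorted unique labels.
#' @param missingMask optional logical matrix; defaults to
#'   \code{is.na(values)}.
#' @return A [MultiviewTable-class].
#' @examples
#' x <- cbind(a = c(1, 2), b = c(3, 4))
#' tab <- multiviewTable(x, list(v1 = "a", v2 = "b"), labels = c("x", "y"))
#' nViews(tab)
#' @export
multiviewTable <- function(values, views, labels = NULL, labelLevels = NULL,
                           missingMask = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.list(views)) {
    vn <- names(views)
    if (is.null(vn)) stop("view list must be named")
    viewOf <- integer(0)
    for (i in seq_along(views)) {
      cols <- as.character(views[[i]])
      v <- rep(i, length(cols))
      names(v) <- cols
      viewOf <- c(viewOf, v)
    }
    viewNames <- vn
  } else {
    u <- unique(as.character(views))
    viewNames <- u
    viewOf <- match(as.character(views), u)
    names(viewOf) <- names(views)
  }
  unmapped <- setdiff(colnames(values), names(viewOf))
  if (length(unmapped)) {
    stop("indicator(s) not mapped to any view: ",
         paste(unmapped, collapse = ", "))
  }
  extra <- setdiff(names(viewOf), colnames(values))
  if (length(extra)) {
    stop("view config names unknown indicator(s): ",
         paste(extra, collapse = ", "))
  }
  viewOf <- viewOf[colnames(values)]
  if (is.null(missingMask)) missingMask <- is.na(values)
  dimnames(missingMask) <- dimnames(values)
  if (is.null(labels)) {
    lab <- integer(0)
    lev <- character(0)
  } else {
    if (is.null(labelLevels)) labelLevels <- sort(unique(as.character(labels)))
    lev <- as.character(labelLevels)
    lab <- match(as.character(labels), lev)
    if (anyNA(lab)) stop("labels outside the declared levels")
  }
  new("MultiviewTable", values = values, viewOf = viewOf,
      viewNames = viewNames, labels = lab, labelLevels = lev,
      missingMask = missingMask)
}

#' @rdname mvdf-accessors
#' @export
setMethod("values", "MultiviewTable", function(object) object@values)

#' @rdname mvdf-accessors
#' @export
setMethod("missingMask", "MultiviewTable", function(object) {
  object@missingMask
})

#' @rdname mvdf-accessors
#' @export
setMethod("viewOf", "MultiviewTable", function(object) object@viewOf)

#' @rdname mvdf-accessors
#' @export
setMethod("viewNames", "MultiviewTable", function(object) object@viewNames)

#' @rdname mvdf-accessors
#' @export
setMethod("nViews", "MultiviewTable", function(object) {
  length(object@viewNames)
})

#' @rdname mvdf-accessors
#' @export
setMethod("nSamples", "MultiviewTable", function(object) {
  nrow(object@values)
})

#' @rdname mvdf-accessors
#' @export
setMethod("nIndicators", "MultiviewTable", function(object) {
  ncol(object@values)
})

#' @rdname mvdf-accessors
#' @export
setMethod("indicatorNames", "MultiviewTable", function(object) {
  colnames(object@values)
})

#' @rdname mvdf-accessors
#' @export
setMethod("classLabels", "MultiviewTable", function(object) object@labels)

#' @rdname mvdf-accessors
#' @export
setMethod("labelLevels", "MultiviewTable", function(object) {
  object@labelLevels
})

#' @rdname mvdf-accessors
#' @export
setMethod("nClasses", "MultiviewTable", function(object) {
  length(object@labelLevels)
})

setMethod("show", "MultiviewTable", function(object) {
  cat(sprintf(
    "MultiviewTable: %d samples x %d indicators in %d view(s)\n",
    nrow(object@values), ncol(object@values), length(object@viewNames)
  ))
  if (length(object@labels)) {
    tab <- table(factor(object@labels, seq_along(object@labelLevels),
                        object@labelLevels))
    cat("classes:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  } else {
    cat("unlabeled\n")
  }
  nm <- sum(object@missingMask)
  cat(sprintf("missing cells: %d (%.1f%%)\n", nm,
              100 * nm / max(1, length(object@values))))
})

# Subset rows of a table, keeping the view partition and label schema.
subsetSamples <- function(t, idx) {
  new("MultiviewTable",
      values = t@values[idx, , drop = FALSE],
      viewOf = t@viewOf, viewNames = t@viewNames,
      labels = if (length(t@labels)) t@labels[idx] else integer(0),
      labelLevels = t@labelLevels,
      missingMask = t@missingMask[idx, , drop = FALSE])
}
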