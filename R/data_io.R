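#' Preprocessing configuration constructor
#'
#' @param sexIndicator optional indicator name used to stratify the
#'   imputation of \code{sexStratifiedIndicators}.
#' @param sexStratifiedIndicators indicators (e.g. height, weight) imputed
#'   with the within-sex mean of observed training values.
#' @param unifiedFillValue constant fill for every other missing cell
#'   (default 0 on the normalized scale).
#' @param normalization \code{"minmax"} (training range to [0,1], the
#'   default), \code{"zscore"}, or \code{"none"}.
#' @param testFraction per-class fraction held out by [stratifiedSplit()].
#' @param splitSeed RNG seed of the split.
#' @return A [PreprocessConfig-class].
#' @export
preprocessConfig <- function(sexIndicator = character(0),
                             sexStratifiedIndicators = character(0),
                             unifiedFillValue = 0,
                             normalization = "minmax",
                             testFraction = 0.3, splitSeed = 1L) {
  new("PreprocessConfig",
      sexIndicator = as.character(sexIndicator),
      sexStratifiedIndicators = as.character(sexStratifiedIndicators),
      unifiedFillValue = as.numeric(unifiedFillValue),
      normalization = normalization,
      testFraction = as.numeric(testFraction),
      splitSeed = as.integer(splitSeed))
}

readViewConfig <- function(viewConfig) {
  if (is.character(viewConfig) && length(viewConfig) == 1) {
    if (grepl("\\.json$", viewConfig, ignore.case = TRUE)) {
      viewConfig <- jsonlite::read_json(viewConfig, simplifyVector = TRUE)
    } else {
      viewConfig <- yaml::read_yaml(viewConfig)
    }
  }
  if (!is.list(viewConfig) || is.null(names(viewConfig))) {
    stop("view config must be a named list {view: [indicator, ...]}")
  }
  lapply(viewConfig, as.character)
}

#' Read a multiview cohort from CSV/TSV
#'
#' Reads a header-ed delimited table, assigns every non-label column to a
#' view via the view configuration, flags empty/NA cells in the missing
#' mask, and encodes the label column into class ids \code{1..K} by sorted
#' unique value.
#'
#' @param path CSV (or TSV, by extension) file with a header row.
#' @param viewConfig named list \code{list(view = c(column, ...))}, or the
#'   path of a YAML/JSON file holding one.
#' @param labelColumn name of the class-label column, or \code{NULL} for
#'   unlabeled data.
#' @return A [MultiviewTable-class].
#' @export
readMultiviewTable <- function(path, viewConfig, labelColumn = "label") {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) == 0) stop("empty input table: ", path)
  views <- readViewConfig(viewConfig)
  labels <- NULL
  if (!is.null(labelColumn) && labelColumn %in% names(df)) {
    labels <- df[[labelColumn]]
    df[[labelColumn]] <- NULL
  } else if (!is.null(labelColumn)) {
    labelColumn <- NULL
  }
  mapped <- unlist(views, use.names = FALSE)
  unmapped <- setdiff(names(df), mapped)
  if (length(unmapped)) {
    stop("column(s) not mapped to any view: ",
         paste(unmapped, collapse = ", "))
  }
  x <- as.matrix(as.data.frame(lapply(df, as.numeric),
                               check.names = FALSE))
  rownames(x) <- NULL
  multiviewTable(x, views, labels = labels)
}

#' Write a cohort as CSV plus a view-config YAML
#'
#' Values round-trip through [readMultiviewTable()] losslessly at 10
#' significant digits; missing cells are written as empty fields.
#'
#' @param t a [MultiviewTable-class].
#' @param path output CSV path.
#' @param viewConfigPath optional YAML path for the view partition.
#' @param labelColumn name for the label column.
#' @return Invisibly, \code{path}.
#' @export
writeMultiviewTable <- function(t, path, viewConfigPath = NULL,
                                labelColumn = "label") {
  x <- values(t)
  x[missingMask(t)] <- NA
  df <- as.data.frame(signif(x, 10), check.names = FALSE)
  if (length(classLabels(t))) {
    df[[labelColumn]] <- labelLevels(t)[classLabels(t)]
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(viewConfigPath)) {
    views <- split(indicatorNames(t), viewNames(t)[viewOf(t)])
    views <- views[unique(viewNames(t)[viewOf(t)])]
    yaml::write_yaml(lapply(views, as.list), viewConfigPath)
  }
  invisible(path)
}

#' Impute missing values
#'
#' Sex-stratified indicators are filled with the within-stratum mean of the
#' observed values; every other missing cell receives the unified fill
#' value. Filling statistics are learned from the data at hand only when
#' \code{stats} is \code{NULL} (the training call) and can be re-applied to
#' held-out data, so the test set never contributes to them.
#'
#' @param t a [MultiviewTable-class].
#' @param cfg a [PreprocessConfig-class].
#' @param stats statistics from a previous (training) call, or \code{NULL}
#'   to learn them from \code{t}.
#' @return \code{list(table = imputed table, stats = fill statistics)}.
#' @export
imputeMissing <- function(t, cfg = preprocessConfig(), stats = NULL) {
  x <- values(t)
  mask <- missingMask(t)
  sexInd <- cfg@sexIndicator
  strat <- intersect(cfg@sexStratifiedIndicators, colnames(x))
  if (length(sexInd) && !sexInd %in% colnames(x)) {
    stop("sex indicator not found: ", sexInd)
  }
  if (is.null(stats)) {
    stats <- list(unifiedFillValue = cfg@unifiedFillValue,
                  sexIndicator = sexInd, stratMeans = list(),
                  overallMeans = list())
    if (length(sexInd) && length(strat)) {
      if (any(mask[, sexInd])) {
        stop("sex indicator must be complete before imputation")
      }
      sex <- as.character(x[, sexInd])
      for (ind in strat) {
        obs <- !mask[, ind]
        stats$overallMeans[[ind]] <- mean(x[obs, ind])
        mns <- tapply(x[obs, ind], sex[obs], mean)
        stats$stratMeans[[ind]] <- mns
      }
    }
  }
  if (length(stats$sexIndicator) && length(stats$stratMeans)) {
    sex <- as.character(x[, stats$sexIndicator])
    for (ind in names(stats$stratMeans)) {
      mis <- which(mask[, ind])
      if (!length(mis)) next
      fill <- stats$stratMeans[[ind]][sex[mis]]
      bad <- is.na(fill)
      if (any(bad)) {
        warning("stratum without observed values for '", ind,
                "'; falling back to overall mean")
        fill[bad] <- stats$overallMeans[[ind]]
      }
      x[mis, ind] <- fill
      mask[mis, ind] <- FALSE
    }
  }
  x[mask] <- stats$unifiedFillValue
  mask[] <- FALSE
  out <- t
  out@values <- x
  out@missingMask <- mask
  validObject(out)
  list(table = out, stats = stats)
}

#' Normalize indicator scales
#'
#' Min-max maps each indicator's training range to [0,1] (constant columns
#' map to 0); z-score centers and scales. The returned scaler re-applies
#' the training statistics to new data, which may therefore fall outside
#' [0,1]; values are not clipped.
#'
#' @param t an imputed [MultiviewTable-class].
#' @param cfg a [PreprocessConfig-class] (its \code{normalization} field).
#' @param scaler scaler state from a previous (training) call, or
#'   \code{NULL} to fit one on \code{t}.
#' @return \code{list(table = normalized table, scaler = scaler state)}.
#' @export
normalizeTable <- function(t, cfg = preprocessConfig(), scaler = NULL) {
  x <- values(t)
  if (any(missingMask(t))) stop("impute before normalizing")
  if (is.null(scaler)) {
    method <- cfg@normalization
    scaler <- switch(method,
      minmax = list(method = "minmax", min = apply(x, 2, min),
                    range = apply(x, 2, max) - apply(x, 2, min)),
      zscore = list(method = "zscore", mean = colMeans(x),
                    sd = apply(x, 2, stats::sd)),
      none = list(method = "none"))
  }
  out <- t
  if (scaler$method == "minmax") {
    rg <- ifelse(scaler$range > 0, scaler$range, 1)
    out@values <- sweep(sweep(x, 2, scaler$min, "-"), 2, rg, "/")
  } else if (scaler$method == "zscore") {
    sd <- ifelse(scaler$sd > 0, scaler$sd, 1)
    out@values <- sweep(sweep(x, 2, scaler$mean, "-"), 2, sd, "/")
  }
  validObject(out)
  list(table = out, scaler = scaler)
}

#' Stratified train/test split
#'
#' Per class c, exactly \code{round(testFraction * n_c)} samples are drawn
#' into the test set; deterministic for a given seed.
#'
#' @param t a labeled [MultiviewTable-class].
#' @param cfg a [PreprocessConfig-class] (\code{testFraction},
#'   \code{splitSeed}), or pass \code{testFraction}/\code{seed} directly.
#' @param testFraction,seed overrides of the config fields.
#' @return \code{list(train = ..., test = ...)} of [MultiviewTable-class].
#' @export
stratifiedSplit <- function(t, cfg = preprocessConfig(),
                            testFraction = cfg@testFraction,
                            seed = cfg@splitSeed) {
  y <- classLabels(t)
  if (!length(y)) stop("labels are required for a stratified split")
  if (testFraction <= 0 || testFraction >= 1) {
    stop("testFraction must lie strictly between 0 and 1")
  }
  testIdx <- integer(0)
  withSeed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      if (length(idx) < 2) {
        stop("class ", labelLevels(t)[cl], " has fewer than 2 samples")
      }
      nTest <- round(testFraction * length(idx))
      testIdx <- c(testIdx, sample(idx, nTest))
    }
  })
  testIdx <- sort(testIdx)
  list(train = subsetSamples(t, setdiff(seq_len(nSamples(t)), testIdx)),
       test = subsetSamples(t, testIdx))
}

#' Fit-and-apply preprocessing
#'
#' Convenience wrapper: learns imputation statistics and the scaler on the
#' training table, applies both, and returns a state object that
#' [preprocessApply()] re-applies to held-out data.
#'
#' @param train a [MultiviewTable-class].
#' @param cfg a [PreprocessConfig-class].
#' @return \code{list(table, state)}.
#' @export
preprocessFit <- function(train, cfg = preprocessConfig()) {
  imp <- imputeMissing(train, cfg, stats = NULL)
  nrm <- normalizeTable(imp$table, cfg, scaler = NULL)
  list(table = nrm$table,
       state = list(cfg = cfg, stats = imp$stats, scaler = nrm$scaler))
}

#' @rdname preprocessFit
#' @param state the \code{state} element returned by [preprocessFit()].
#' @param t a table to transform with the trained statistics.
#' @export
preprocessApply <- function(state, t) {
  imp <- imputeMissing(t, state$cfg, stats = state$stats)
  normalizeTable(imp$table, state$cfg, scaler = state$scaler)$table
}
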