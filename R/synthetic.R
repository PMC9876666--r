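#' Synthetic cohort specification
#'
#' Defaults mirror the shape of the gastric-cancer cohort the model was
#' designed around: 939 patients, 61 indicators in 5 views, 3 survival
#' classes with priors 223:219:497, mixed continuous/binary indicators,
#' cross-view redundancy and missing values.
#'
#' @param nSamples cohort size.
#' @param classPriors class probabilities (sum to 1).
#' @param viewSizes indicators per view.
#' @param informativePerView class-informative indicators per view.
#' @param effectSize separation of adjacent class means, in within-class
#'   SD units.
#' @param redundancyRho correlation of redundant copies with their source
#'   (drawn from another view, emulating cross-view redundancy).
#' @param importantIndicators indicators with a doubled effect size,
#'   standing in for the clinically decisive indicators.
#' @param missingRate MCAR missingness rate applied by [generateCohort()].
#' @param binaryFraction fraction of columns dichotomized at their median
#'   (never redundant columns or their sources, so the redundancy
#'   correlation survives).
#' @param seed RNG seed; cohorts are bit-identical given the spec.
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nSamples = 939,
                          classPriors = c(223, 219, 497) / 939,
                          viewSizes = c(13, 13, 13, 11, 11),
                          informativePerView = 4,
                          effectSize = 1.5,
                          redundancyRho = 0.6,
                          importantIndicators = paste0("v", 1:5, "_inf1"),
                          missingRate = 0.05,
                          binaryFraction = 0.3,
                          seed = 1L) {
  new("SyntheticSpec",
      nSamples = as.integer(nSamples),
      classPriors = as.numeric(classPriors),
      viewSizes = as.integer(viewSizes),
      informativePerView = as.integer(informativePerView),
      effectSize = as.numeric(effectSize),
      redundancyRho = as.numeric(redundancyRho),
      importantIndicators = as.character(importantIndicators),
      missingRate = as.numeric(missingRate),
      binaryFraction = as.numeric(binaryFraction),
      seed = as.integer(seed))
}

# Largest-remainder apportionment of n samples to priors.
apportion <- function(n, priors) {
  raw <- priors * n
  cnt <- floor(raw)
  left <- n - sum(cnt)
  if (left > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(left)]
    cnt[extra] <- cnt[extra] + 1
  }
  as.integer(cnt)
}

#' Generate a synthetic multiview cohort
#'
#' Class labels follow the priors exactly (largest-remainder quota, then a
#' seeded shuffle). Informative indicators are class-conditional Gaussians
#' (unit SD) whose class means are a random permutation of an equispaced
#' grid with step \code{effectSize}; indicators in
#' \code{importantIndicators} use twice that step. Redundant indicators are
#' rho-correlated copies of an informative indicator from another view;
#' the remaining indicators are pure N(0,1) noise. A seeded subset of
#' non-redundant columns is dichotomized at the median, and MCAR
#' missingness at \code{missingRate} is injected last.
#'
#' @param spec a [SyntheticSpec-class].
#' @return A labeled [MultiviewTable-class] with views \code{v1..vm} and
#'   indicators named \code{v<j>_inf<i>}, \code{v<j>_red<i>},
#'   \code{v<j>_noise<i>}.
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  n <- spec@nSamples
  K <- length(spec@classPriors)
  m <- length(spec@viewSizes)
  withSeed(spec@seed, {
    counts <- apportion(n, spec@classPriors)
    y <- sample(rep.int(seq_len(K), counts))

    cols <- list()
    views <- character(0)
    kind <- character(0)        # "inf", "red", "noise"
    srcOf <- character(0)       # source indicator of redundant columns
    grid <- (seq_len(K) - (K + 1) / 2)   # step-1 equispaced class grid

    for (j in seq_len(m)) {
      nInf <- min(spec@informativePerView, spec@viewSizes[j])
      rest <- spec@viewSizes[j] - nInf
      nRed <- if (spec@informativePerView > 0) rest %/% 2 else 0
      nNoise <- rest - nRed
      for (i in seq_len(nInf)) {
        nm <- sprintf("v%d_inf%d", j, i)
        eff <- spec@effectSize *
          (1 + (nm %in% spec@importantIndicators))
        mu <- sample(grid) * eff
        cols[[nm]] <- stats::rnorm(n, mean = mu[y], sd = 1)
        views[nm] <- sprintf("v%d", j)
        kind[nm] <- "inf"
      }
      for (i in seq_len(nRed)) {
        nm <- sprintf("v%d_red%d", j, i)
        srcView <- if (m > 1) (j %% m) + 1 else j
        srcI <- ((i - 1) %% max(1, min(spec@informativePerView,
                                       spec@viewSizes[srcView]))) + 1
        srcOf[nm] <- sprintf("v%d_inf%d", srcView, srcI)
        views[nm] <- sprintf("v%d", j)
        kind[nm] <- "red"
        cols[[nm]] <- NA        # filled after all sources exist
      }
      for (i in seq_len(nNoise)) {
        nm <- sprintf("v%d_noise%d", j, i)
        cols[[nm]] <- stats::rnorm(n)
        views[nm] <- sprintf("v%d", j)
        kind[nm] <- "noise"
      }
    }
    for (nm in names(srcOf)) {
      src <- cols[[srcOf[nm]]]
      z <- (src - mean(src)) / stats::sd(src)
      rho <- spec@redundancyRho
      cols[[nm]] <- rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
    }

    x <- do.call(cbind, cols)
    colnames(x) <- names(cols)

    if (spec@binaryFraction > 0) {
      protected <- union(names(srcOf),
                         unique(srcOf[!is.na(srcOf)]))
      eligible <- setdiff(colnames(x), protected)
      nBin <- min(length(eligible),
                  round(spec@binaryFraction * ncol(x)))
      if (nBin > 0) {
        binCols <- sample(eligible, nBin)
        for (nm in binCols) {
          x[, nm] <- as.numeric(x[, nm] > stats::median(x[, nm]))
        }
      }
    }

    viewList <- split(names(views), views)
    viewList <- viewList[sprintf("v%d", seq_len(m))]
    t <- multiviewTable(x, viewList, labels = y,
                        labelLevels = as.character(seq_len(K)))
    if (spec@missingRate > 0) {
      t <- injectMissingness(t, spec@missingRate,
                             seed = deriveSeed(spec@seed, 7L))
    }
    t
  })
}

#' Inject missing-completely-at-random cells
#'
#' Masks each non-label cell independently with probability \code{rate};
#' columns listed in \code{protect} (e.g. a sex indicator that imputation
#' stratifies on) are never masked.
#'
#' @param t a [MultiviewTable-class].
#' @param rate masking probability in [0,1).
#' @param seed RNG seed.
#' @param protect indicator names never masked.
#' @return The table with masked cells set \code{NA} and flagged.
#' @export
injectMissingness <- function(t, rate, seed = 1L, protect = character(0)) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0,1)")
  if (rate == 0) return(t)
  x <- values(t)
  mask <- missingMask(t)
  withSeed(seed, {
    hit <- matrix(stats::runif(length(x)) < rate, nrow(x), ncol(x))
    hit[, colnames(x) %in% protect] <- FALSE
    x[hit] <- NA
    mask <- mask | hit
  })
  out <- t
  out@values <- x
  out@missingMask <- mask
  validObject(out)
  out
}
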