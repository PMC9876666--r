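test_that("a single perfect split contributes parent Gini minus weighted
           child Ginis, and unused indicators score exactly zero", {
  # one feature separates two balanced classes perfectly; a stump's only
  # split has parent Gini 0.5 and pure children -> contribution 0.5
  x <- cbind(sep = c(0, 0, 0, 0, 1, 1, 1, 1),
             dead = rep(0, 8))
  y <- rep(1:2, each = 4)
  f <- fitForest(x, y, K = 2, kind = "B", nTrees = 1, mtry = 2,
                 maxDepth = 3, bootstrap = FALSE, seed = 1)
  vim <- giniImportance(f)
  expect_equal(unname(vim@vim["sep"]), 0.5, tolerance = 1e-12)
  expect_identical(unname(vim@vim["dead"]), 0)
})

test_that("Gini importance matches the brute-force tree-walk oracle", {
  for (seed in 1:3) {
    t <- preppedCohort(n = 100, seed = seed, viewSizes = c(4, 4),
                       missingRate = 0)
    x <- values(t)
    y <- classLabels(t)
    f <- fitForest(x, y, K = 3, kind = "B", nTrees = 20, seed = seed)
    vim <- giniImportance(f)
    want <- oracleImportance(f, x, y, K = 3)
    expect_equal(vim@vim[sort(names(vim@vim))],
                 want[sort(names(want))], tolerance = 1e-9)
  }
})

test_that("importance from the extractors uses only kind-B forests and
           ranks informative indicators above pure noise", {
  hits <- 0L
  nSeeds <- 30L
  for (s in seq_len(nSeeds)) {
    t <- preppedCohort(n = 250, seed = 400 + s, viewSizes = c(5, 5),
                       informativePerView = 2, missingRate = 0)
    ex <- fitExtractors(t, nTrees = 20, cvFolds = 3, seed = s)
    vim <- giniImportance(ex)
    expect_true(all(grepl("^B", vim@sourceForests)))
    noise <- grep("_noise", names(vim@vim), value = TRUE)
    inf <- grep("_inf", names(vim@vim), value = TRUE)
    if (max(vim@vim[noise]) <= max(vim@vim[inf])) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * nSeeds))
})

test_that("important-indicator selection unions the top-k with the expert
           list deterministically", {
  vim <- new("GiniImportance",
             vim = c(a = 5, b = 4, c = 3, d = 2, e = 1, f = 0.5, g = 0.2,
                     h = 0, i = 0, j = 0),
             sourceForests = "B")
  s1 <- selectImportant(vim, topK = 5)
  expect_identical(s1@important, c("a", "b", "c", "d", "e"))
  expect_length(s1@secondary, 5)

  s2 <- selectImportant(vim, expertList = c("f", "g", "h", "i", "j"),
                        topK = 5)
  expect_length(s2@important, 10)
  expect_length(s2@secondary, 0)

  s3 <- selectImportant(vim, expertList = c("a", "c"), topK = 5)
  expect_identical(s3@important, c("a", "b", "c", "d", "e"))

  expect_error(selectImportant(vim, expertList = "zz"), "zz")
  # ties broken by name: h, i, j all zero
  vimTie <- new("GiniImportance", vim = c(z = 0, y = 0, x = 1),
                sourceForests = "B")
  expect_identical(selectImportant(vimTie, topK = 2)@important,
                   c("x", "y"))
})

test_that("the IB encoder trains deterministically, records both bound
           estimates, and encodes to the configured latent width", {
  t <- preppedCohort(n = 200, seed = 11, viewSizes = c(6, 6),
                     missingRate = 0)
  x <- values(t)[, 1:8]
  y <- classLabels(t)
  enc <- fitIBEncoder(x, y, latentDim = 10, beta = 0.1, epochs = 60,
                      seed = 3)
  expect_s4_class(enc, "IBEncoder")
  expect_equal(nrow(enc@history), 60)
  expect_true(all(c("iTY", "iXT", "loss") %in% names(enc@history)))

  z <- encodeSecondary(enc, x)
  expect_equal(dim(z), c(200, 10))
  expect_identical(z, encodeSecondary(enc, x))         # deterministic
  expect_identical(z, encodeSecondary(enc, x, mask = rep(TRUE, 8)))

  encB <- fitIBEncoder(x, y, latentDim = 10, beta = 0.1, epochs = 60,
                       seed = 3)
  expect_identical(encB@params, enc@params)            # seeded training

  # masked-out features are zeroed before encoding
  mask <- c(TRUE, rep(FALSE, 7))
  x0 <- x
  x0[, 2:8] <- 0
  expect_equal(encodeSecondary(enc, x, mask = mask),
               encodeSecondary(enc, x0), ignore_attr = TRUE)

  expect_error(encodeSecondary(enc, x[, 1:3]), "column")
  expect_error(encodeSecondary(enc, x, mask = c(TRUE, FALSE)), "mask")
})

test_that("beta = 0 removes the compression penalty from the objective", {
  t <- preppedCohort(n = 150, seed = 12, viewSizes = c(5, 5),
                     missingRate = 0)
  x <- values(t)[, 1:6]
  y <- classLabels(t)
  enc0 <- fitIBEncoder(x, y, beta = 0, epochs = 40, seed = 2)
  expect_equal(enc0@history$loss, enc0@history$crossEntropy,
               tolerance = 1e-12)
  expect_error(fitIBEncoder(x, y, beta = -0.1), "beta")
})

test_that("training loss decreases over epochs (5-epoch smoothing)", {
  t <- preppedCohort(n = 200, seed = 13, viewSizes = c(6, 6),
                     missingRate = 0)
  enc <- fitIBEncoder(values(t)[, 1:8], classLabels(t), beta = 0.1,
                      epochs = 100, seed = 4)
  sm <- stats::filter(enc@history$loss, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1])
  # broadly non-increasing: few large upticks after smoothing
  expect_lt(mean(diff(sm) > 0.01), 0.1)
})

test_that("stronger beta compresses more: final I(X;T) bound is lower at
           beta = 1.0 than at beta = 0.01 (median over seeds)", {
  t <- preppedCohort(n = 300, seed = 14, viewSizes = c(6, 6),
                     missingRate = 0)
  x <- values(t)[, 1:9]
  y <- classLabels(t)
  finalIXT <- function(beta, seed) {
    enc <- fitIBEncoder(x, y, beta = beta, epochs = 100, seed = seed)
    utils::tail(enc@history$iXT, 1)
  }
  lo <- sapply(1:3, function(s) finalIXT(0.01, s))
  hi <- sapply(1:3, function(s) finalIXT(1.0, s))
  expect_lt(median(hi), median(lo))
})
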