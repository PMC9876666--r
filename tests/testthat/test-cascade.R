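test_that("tree score is mean true-class probability plus alpha times the
           weighted leaf impurity", {
  t <- preppedCohort(n = 80, seed = 21, viewSizes = c(4, 4),
                     missingRate = 0)
  x <- values(t)
  y <- classLabels(t)
  f <- fitForest(x, y, K = 3, kind = "B", nTrees = 1, maxDepth = 2,
                 minNode = 5, bootstrap = FALSE, seed = 2)
  tree <- f$trees[[1]]

  sc0 <- treeScore(tree, x, y, alpha = 0)
  # oracle: mean over samples of the leaf's true-class frequency
  pr <- mvdf:::treeProba(tree, x)
  expect_equal(sc0$s, mean(pr[cbind(seq_along(y), y)]), tolerance = 1e-12)

  # alpha enters linearly through the leaf-impurity term
  scA <- treeScore(tree, x, y, alpha = -0.5)
  expect_equal(scA$s, sc0$s - 0.5 * scA$giniT, tolerance = 1e-12)
  leaves <- which(tree$feature < 0)
  giniOracle <- sum(tree$n[leaves] / tree$n[1] * tree$gini[leaves])
  expect_equal(scA$giniT, giniOracle, tolerance = 1e-12)

  # a perfectly confident, always-right tree scores 1 at alpha = 0
  xSep <- cbind(s = c(rep(0, 10), rep(1, 10)), junk = rep(0, 20))
  ySep <- rep(1:2, each = 10)
  fSep <- fitForest(xSep, ySep, K = 2, kind = "B", nTrees = 1, mtry = 2,
                    bootstrap = FALSE, seed = 1)
  expect_equal(treeScore(fSep$trees[[1]], xSep, ySep, alpha = 0)$s, 1)

  # two validation samples with true-class probabilities 0.6 and 0.8
  stump <- list(feature = c(0L, -1L, -1L), threshold = c(0.5, 0, 0),
                left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
                n = c(10L, 5L, 5L), gini = c(0.5, 0.48, 0.32),
                counts = rbind(c(5, 5), c(3, 2), c(1, 4)))
  zv <- cbind(v = c(0.2, 0.9))
  expect_equal(treeScore(stump, zv, c(1L, 2L), alpha = 0)$meanTrueProb,
               0.7)
  expect_error(treeScore(stump, zv[0, , drop = FALSE], integer(0)),
               "empty")
})

test_that("keep probabilities are exp(s - max s): best tree 1, ln-2 gap
           halves, equal scores prune nothing", {
  s <- c(1.2, 1.2 - log(2), 0.4)
  p <- keepProbability(s)
  expect_equal(p[1], 1)
  expect_equal(p[2], 0.5)
  expect_equal(keepProbability(rep(0.7, 5)), rep(1, 5))
  expect_error(keepProbability(numeric(0)), "trees")
})

test_that("pruning retains the max-score tree unconditionally, follows the
           Bernoulli expectation, and never empties a forest", {
  t <- preppedCohort(n = 60, seed = 22, viewSizes = c(3, 3),
                     missingRate = 0)
  f <- fitForest(values(t), classLabels(t), K = 3, nTrees = 30, seed = 1)

  # all keep probabilities 1: identical forest
  same <- pruneForest(f, rep(2, 30), seed = 5)
  expect_length(same$trees, 30)

  # expectation check: nearly-zero keep for all but the best
  scores <- c(0, rep(log(1e-4), 299))
  fBig <- f
  fBig$trees <- rep(f$trees, 10)  # 300 stand-in trees
  kept <- sapply(1:200, function(s) {
    length(pruneForest(fBig, scores, seed = s)$trees)
  })
  expect_lt(abs(mean(kept) - (1 + 299 * 1e-4)), 0.5)
  expect_true(all(kept >= 1))
})

test_that("the cascade solves a separable two-class problem, appends 4K
           class-vector columns per level, and is seed-deterministic", {
  set.seed(3)
  n <- 120
  x <- cbind(f1 = c(rnorm(n / 2, -2), rnorm(n / 2, 2)),
             f2 = rnorm(n), f3 = rnorm(n))
  y <- rep(1:2, each = n / 2)
  m <- growCascade(x, y, treesPerForest = 20, cvFolds = 3, seed = 4)
  expect_s4_class(m, "CascadeModel")
  expect_gte(length(m@levels), 1)
  expect_gte(max(m@cvAccuracy), 0.95)

  # level >= 2 input width is |Z| + 4K
  t <- preppedCohort(n = 150, seed = 23, viewSizes = c(4, 4),
                     missingRate = 0)
  m3 <- growCascade(values(t), classLabels(t), treesPerForest = 15,
                    maxLevels = 3, patience = 2, seed = 5)
  if (length(m3@levels) > 1) {
    expect_equal(m3@levels[[2]]$inputWidth,
                 ncol(values(t)) + 4 * 3)
  }

  mA <- growCascade(x, y, treesPerForest = 10, seed = 9)
  mB <- growCascade(x, y, treesPerForest = 10, seed = 9)
  expect_equal(length(mA@levels), length(mB@levels))
  expect_identical(cascadePredict(mA, x), cascadePredict(mB, x))

  yTiny <- c(rep(1, 30), rep(2, 3))
  expect_error(growCascade(x[1:33, ], yTiny, cvFolds = 3), "at least")
})

test_that("prediction aggregates the last level's four class vectors by
           componentwise mean with lowest-id tie-break", {
  # direct aggregation checks on hand-built vectors
  agg <- function(vecs) Reduce(`+`, vecs) / length(vecs)
  expect_equal(agg(rep(list(c(0.1, 0.2, 0.7)), 4)), c(0.1, 0.2, 0.7))
  expect_equal(agg(list(c(1, 0, 0), c(0, 1, 0), c(0, 1, 0), c(0, 0, 1))),
               c(0.25, 0.5, 0.25))
  expect_equal(mvdf:::rowArgmax(rbind(c(0.1, 0.2, 0.7))), 3L)
  expect_equal(mvdf:::rowArgmax(rbind(c(0.4, 0.4, 0.2))), 1L)

  t <- preppedCohort(n = 150, seed = 24, viewSizes = c(4, 4),
                     missingRate = 0)
  m <- growCascade(values(t), classLabels(t), treesPerForest = 15,
                   seed = 6)
  p <- cascadePredictProba(m, values(t))
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_true(all(p >= 0))
  expect_identical(cascadePredict(m, values(t)), mvdf:::rowArgmax(p))

  # convex hull: aggregated probabilities lie within the per-slot range
  lastLevel <- m@levels[[length(m@levels)]]
  slotP <- lapply(seq_along(lastLevel$slots), function(s) {
    fm <- lastLevel$slots[[s]]$foldModels
    Reduce(`+`, lapply(fm, predictForestProba, x = values(t))) / length(fm)
  })
  lo <- Reduce(pmin, slotP)
  hi <- Reduce(pmax, slotP)
  expect_true(all(p >= lo - 1e-12 & p <= hi + 1e-12))

  expect_error(cascadePredictProba(m, values(t)[, 1:3]), "lacks|columns")
})

test_that("decision-path export dumps named splits with conserved class
           counts; a stump yields three nodes", {
  xSep <- cbind(marker = c(rep(0, 6), rep(1, 6)), other = rep(0, 12))
  ySep <- rep(1:2, each = 6)
  f <- fitForest(xSep, ySep, K = 2, nTrees = 1, mtry = 2,
                 bootstrap = FALSE, seed = 1)
  lines <- formatTree(f$trees[[1]], featureNames = colnames(xSep))
  expect_length(lines, 3)
  expect_match(lines[1], "marker")

  t <- preppedCohort(n = 120, seed = 25, viewSizes = c(4, 4),
                     missingRate = 0)
  m <- growCascade(values(t), classLabels(t), treesPerForest = 10,
                   seed = 7)
  dump <- exportDecisionPaths(m, level = 1, forest = 1, fold = 1, tree = 1)
  expect_gt(length(dump), 1)
  # every split line names a real input column
  splitLines <- grep("^\\s*if ", dump, value = TRUE)
  nm <- sub("^\\s*if ([^ ]+) <=.*", "\\1", splitLines)
  expect_true(all(nm %in% c(colnames(values(t)),
                            mvdf:::prevVectorNames(4, 3))))
  # leaf counts sum to the root count
  counts <- as.integer(sub(".* n=(\\d+) .*", "\\1", dump))
  leafN <- counts[grepl("leaf:", dump)]
  expect_equal(sum(leafN), counts[1])

  expect_error(exportDecisionPaths(m, level = 99), "level")
  expect_error(exportDecisionPaths(m, forest = 99), "forest")
})

test_that("pruning with alpha = 0 and equal validation probabilities is a
           no-op", {
  # trees that are all identical stumps get identical scores -> keep all
  x <- cbind(a = c(rep(0, 20), rep(1, 20)), b = rep(0, 40))
  y <- rep(1:2, each = 20)
  f <- fitForest(x, y, K = 2, nTrees = 25, mtry = 2, bootstrap = FALSE,
                 seed = 3)
  sc <- mvdf:::forestTreeScores(f, x, y, alpha = 0)
  expect_true(all(abs(sc$s - sc$s[1]) < 1e-12))
  pruned <- pruneForest(f, sc$s, seed = 11)
  expect_length(pruned$trees, 25)
})
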