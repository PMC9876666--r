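test_that("reading a CSV builds the table, mask, views and classes", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("age,bmi,stage,label",
               "61,24.1,2,<3",
               "55,,3,3-5",
               "70,30.2,1,>5",
               "48,22.0,2,<3"), csv)
  views <- list(demo = c("age", "bmi"), path = "stage")
  t <- readMultiviewTable(csv, views)

  expect_s4_class(t, "MultiviewTable")
  expect_equal(nSamples(t), 4)
  expect_equal(nIndicators(t), 3)
  expect_equal(nViews(t), 2)
  expect_equal(sum(missingMask(t)), 1)           # exactly one empty cell
  expect_true(missingMask(t)[2, "bmi"])
  # label ids by sorted unique value
  expect_equal(labelLevels(t), c("3-5", "<3", ">5"))
  expect_equal(nClasses(t), 3)
  expect_equal(classLabels(t), c(2L, 1L, 3L, 2L))

  # unmapped column is a configuration error naming the column
  expect_error(readMultiviewTable(csv, list(demo = c("age", "bmi"))),
               "stage")
  empty <- tempfile(fileext = ".csv")
  writeLines("age,label", empty)
  expect_error(readMultiviewTable(empty, list(demo = "age")), "empty")
})

test_that("a 5-view config over 61 columns yields m = 5, n = 61", {
  t <- generateCohort(syntheticSpec(nSamples = 20, missingRate = 0,
                                    seed = 1))
  csv <- tempfile(fileext = ".csv")
  vws <- tempfile(fileext = ".yaml")
  writeMultiviewTable(t, csv, viewConfigPath = vws)
  rt <- readMultiviewTable(csv, vws)
  expect_equal(nViews(rt), 5)
  expect_equal(nIndicators(rt), 61)
  expect_equal(nClasses(rt), 3)
  # round-trip is lossless at 10 significant digits
  expect_equal(values(rt), values(t), tolerance = 1e-9)
  expect_equal(classLabels(rt), classLabels(t))
})

test_that("imputation fills sex strata with means and the rest with the
           unified value, learning statistics from training data only", {
  x <- cbind(sex = c(1, 1, 1, 2, 2, 2),
             height = c(170, 180, NA, 150, 160, NA),
             hb = c(NA, 12, 13, 11, NA, 10))
  t <- multiviewTable(x, list(demo = c("sex", "height"), lab = "hb"),
                      labels = c(1, 2, 1, 2, 1, 2))
  cfg <- preprocessConfig(sexIndicator = "sex",
                          sexStratifiedIndicators = "height",
                          unifiedFillValue = 0)
  imp <- imputeMissing(t, cfg)
  v <- values(imp$table)
  expect_equal(unname(v[3, "height"]), 175)              # mean of {170, 180}
  expect_equal(unname(v[6, "height"]), 155)              # mean of {150, 160}
  expect_equal(unname(v[1, "hb"]), 0)                    # unified fill
  expect_equal(unname(v[5, "hb"]), 0)
  expect_false(any(missingMask(imp$table)))

  # idempotence: a second pass is the identity
  imp2 <- imputeMissing(imp$table, cfg)
  expect_identical(values(imp2$table), v)

  # no missing values: output identical to input
  complete <- multiviewTable(v, list(demo = c("sex", "height"),
                                     lab = "hb"), labels = c(1, 2, 1, 2, 1, 2))
  expect_identical(values(imputeMissing(complete, cfg)$table), v)

  # statistics are reapplied, never re-learned, on held-out data
  xTest <- cbind(sex = c(1, 2), height = c(NA, NA), hb = c(NA, 5))
  tTest <- multiviewTable(xTest, list(demo = c("sex", "height"),
                                      lab = "hb"))
  out <- imputeMissing(tTest, cfg, stats = imp$stats)
  expect_equal(values(out$table)[, "height"], c(175, 155),
               ignore_attr = TRUE)

  # a stratum with no observed values falls back to the overall mean
  xBad <- cbind(sex = c(1, 1, 2), height = c(160, 170, NA), hb = 1:3)
  tBad <- multiviewTable(xBad, list(demo = c("sex", "height"),
                                    lab = "hb"))
  statsBad <- suppressWarnings(imputeMissing(tBad, cfg))$stats
  expect_warning(
    outBad <- imputeMissing(tBad, cfg, stats = statsBad),
    "overall mean")
  expect_equal(unname(values(outBad$table)[3, "height"]), 165)
})

test_that("min-max normalization maps the training range to [0,1] and is
           reusable on new data without clipping", {
  x <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  t <- multiviewTable(x, list(v = c("a", "b")))
  cfg <- preprocessConfig(normalization = "minmax")
  nrm <- normalizeTable(t, cfg)
  expect_equal(values(nrm$table)[, "a"], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(values(nrm$table)[, "b"], c(0, 0, 0), ignore_attr = TRUE)

  tNew <- multiviewTable(cbind(a = c(8, 0), b = c(7, 5)), list(v = c("a", "b")))
  out <- normalizeTable(tNew, cfg, scaler = nrm$scaler)
  expect_equal(values(out$table)[, "a"], c(1.5, -0.5), ignore_attr = TRUE)

  none <- normalizeTable(t, preprocessConfig(normalization = "none"))
  expect_identical(values(none$table), values(t))
})

test_that("the stratified split takes round(fraction * n_c) per class,
           is seed-deterministic and preserves proportions", {
  t <- smallCohort(n = 150, seed = 7)
  y <- classLabels(t)
  # engineered class counts 100 / 50
  t2 <- generateCohort(syntheticSpec(nSamples = 150,
                                     classPriors = c(100, 50) / 150,
                                     viewSizes = c(4, 4), missingRate = 0,
                                     importantIndicators = character(0),
                                     seed = 2))
  expect_equal(as.integer(table(classLabels(t2))), c(100, 50))
  sp <- stratifiedSplit(t2, testFraction = 0.3, seed = 11)
  expect_equal(as.integer(table(classLabels(sp$test))), c(30, 15))
  expect_equal(nSamples(sp$train) + nSamples(sp$test), 150)

  # determinism and disjointness
  spB <- stratifiedSplit(t2, testFraction = 0.3, seed = 11)
  expect_identical(values(sp$test), values(spB$test))
  spC <- stratifiedSplit(t2, testFraction = 0.3, seed = 12)
  expect_false(identical(values(sp$test), values(spC$test)))

  # the cohort-scale class counts 223/219/497 give test 67/66/149
  big <- generateCohort(syntheticSpec(nSamples = 939, viewSizes = c(3, 3),
                                      informativePerView = 1,
                                      importantIndicators = character(0),
                                      missingRate = 0, seed = 5))
  expect_equal(as.integer(table(classLabels(big))), c(223, 219, 497))
  spBig <- stratifiedSplit(big, testFraction = 0.3, seed = 1)
  expect_equal(as.integer(table(classLabels(spBig$test))),
               c(67, 66, 149))

  tinyY <- multiviewTable(cbind(a = 1:3), list(v = "a"),
                          labels = c(1, 1, 2))
  expect_error(stratifiedSplit(tinyY, testFraction = 0.3, seed = 1),
               "fewer than 2")
})

test_that("preprocessing state fitted on train is immune to test data", {
  t <- smallCohort(n = 200, seed = 3, missingRate = 0.1)
  sp <- stratifiedSplit(t, testFraction = 0.3, seed = 9)
  cfg <- preprocessConfig()
  fit <- preprocessFit(sp$train, cfg)
  stateBefore <- fit$state

  # mutate the test table wildly; the trained state must not change and
  # the transform of an identical copy must be unaffected
  testA <- sp$test
  testB <- sp$test
  testB@values[!missingMask(testB)] <- testB@values[!missingMask(testB)] * 100
  outA <- preprocessApply(fit$state, testA)
  expect_identical(fit$state, stateBefore)
  outA2 <- preprocessApply(fit$state, testA)
  expect_identical(values(outA), values(outA2))
  expect_false(any(missingMask(outA)))
})
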