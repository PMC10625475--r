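smallConfig <- function(nStages = 150L, seed = 0L)
  gbtConfig(nStages = nStages, maxDepth = 4L, learningRate = 0.1,
            subsample = 0.8, maxFeatures = "sqrt", minSamplesSplit = 2L,
            seed = seed)

test_that("tuned default configurations match the per-method optima", {
  ms <- defaultConfig("multishell")
  expect_identical(ms@nStages, 20000L)
  expect_identical(ms@maxDepth, 10L)
  expect_identical(ms@learningRate, 0.005)
  expect_identical(ms@subsample, 0.6)
  expect_identical(ms@maxFeatures, "sqrt")
  expect_identical(ms@minSamplesSplit, 3L)

  w <- defaultConfig("weighted")
  expect_identical(w@nStages, 30000L)
  expect_identical(w@minSamplesSplit, 2L)
  expect_identical(w@maxDepth, 10L)

  base <- defaultConfig("ecif_baseline")
  expect_identical(base@nStages, 20000L)
  expect_identical(base@maxDepth, 8L)
  expect_identical(base@subsample, 0.7)
  expect_error(defaultConfig("nope"))
})

test_that("config validity rejects nonsense", {
  expect_error(gbtConfig(nStages = 0), "nStages")
  expect_error(gbtConfig(learningRate = 1.5), "learningRate")
  expect_error(gbtConfig(maxFeatures = "log2"), "maxFeatures")
})

test_that("training fits a low-noise linear signal", {
  ds <- makeRegressionDataset(200, nInformative = 3, noiseSd = 0.1,
                              seed = 11)
  model <- trainModel(ds$features, ds$pk, smallConfig(300L))
  sp <- scoringPower(predict(model, ds$features), ds$pk)
  expect_gt(sp$pearson_r, 0.9)
})

test_that("a constant target yields constant predictions", {
  ds <- makeRegressionDataset(50, seed = 2)
  model <- trainModel(ds$features, rep(5.5, 50), smallConfig(20L))
  expect_equal(predict(model, ds$features), rep(5.5, 50),
               tolerance = 1e-6)
})

test_that("training and prediction are deterministic under a fixed seed", {
  ds <- makeRegressionDataset(120, seed = 4)
  m1 <- trainModel(ds$features, ds$pk, smallConfig(80L, seed = 9L))
  m2 <- trainModel(ds$features, ds$pk, smallConfig(80L, seed = 9L))
  expect_identical(predict(m1, ds$features), predict(m2, ds$features))
  m3 <- trainModel(ds$features, ds$pk, smallConfig(80L, seed = 10L))
  expect_false(identical(predict(m1, ds$features),
                         predict(m3, ds$features)))
})

test_that("prediction aligns columns by name and rejects mismatches", {
  ds <- makeRegressionDataset(80, seed = 5)
  model <- trainModel(ds$features, ds$pk, smallConfig(50L))
  straight <- predict(model, ds$features)
  expect_true(all(is.finite(straight)))
  permuted <- ds$features[, sample.int(ncol(ds$features)), drop = FALSE]
  expect_identical(predict(model, permuted), straight)
  expect_error(predict(model, ds$features[, -1, drop = FALSE]),
               "feature name mismatch")
  expect_error(trainModel(ds$features, ds$pk[-1], smallConfig(10L)),
               "misaligned")
})

test_that("models survive a save/load round trip bit-identically", {
  ds <- makeRegressionDataset(60, seed = 6)
  model <- trainModel(ds$features, ds$pk, smallConfig(40L))
  path <- tempfile(fileext = ".json")
  saveModel(model, path)
  back <- loadModel(path)
  expect_identical(featureNames(back), featureNames(model))
  expect_identical(modelConfig(back)@nStages, modelConfig(model)@nStages)
  expect_identical(predict(back, ds$features), predict(model, ds$features))
})

test_that("adding a constant to pk shifts predictions by about it", {
  ds <- makeRegressionDataset(200, nInformative = 2, noiseSd = 0.2,
                              seed = 8)
  cfg <- smallConfig(400L)
  m0 <- trainModel(ds$features, ds$pk, cfg)
  m1 <- trainModel(ds$features, ds$pk + 3, cfg)
  shift <- predict(m1, ds$features) - predict(m0, ds$features)
  expect_equal(mean(shift), 3, tolerance = 0.05)
})

test_that("cross-validation recovers signal, nulls out noise, repeats", {
  ds <- makeRegressionDataset(400, nInformative = 3, noiseSd = 0.1,
                              seed = 13)
  cv <- crossValidate(ds$features, ds$pk, smallConfig(200L),
                      nFolds = 5L, nTrials = 2L, baseSeed = 100L)
  expect_identical(nrow(cv), 10L)
  tm <- attr(cv, "trialMeans")
  expect_identical(nrow(tm), 2L)
  expect_gt(mean(tm$pearson_r), 0.9)

  set.seed(99)
  noise <- rnorm(400)
  cvNull <- crossValidate(ds$features, noise, smallConfig(100L),
                          nFolds = 5L, nTrials = 2L, baseSeed = 100L)
  expect_lt(abs(mean(attr(cvNull, "trialMeans")$pearson_r)), 0.2)

  cv2 <- crossValidate(ds$features, ds$pk, smallConfig(200L),
                       nFolds = 5L, nTrials = 2L, baseSeed = 100L)
  expect_identical(cv$pearson_r, cv2$pearson_r)
  expect_error(crossValidate(ds$features, ds$pk, smallConfig(10L),
                             nFolds = 500L), "exceeds")
})

test_that("the two-stage grid search picks the best condition", {
  ds <- makeRegressionDataset(150, nInformative = 2, noiseSd = 0.3,
                              seed = 21)
  gs <- gridSearchGBT(ds$features, ds$pk, base = smallConfig(60L),
                      stage1 = list(maxDepth = c(2L, 4L)),
                      stage2 = list(subsample = c(0.6, 0.9)),
                      nFolds = 3L, nTrials = 1L, baseSeed = 5L)
  expect_s4_class(gs$best, "GBTConfig")
  expect_identical(nrow(gs$results), 4L)
  expect_true(gs$best@maxDepth %in% c(2L, 4L))
  expect_true(gs$best@subsample %in% c(0.6, 0.9))
})
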