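test_that("scoring power matches closed-form calculations", {
  expect_equal(scoringPower(1:4 + 0, 1:4 + 0),
               list(pearson_r = 1, rmse = 0, n = 4L))
  centered <- c(-2, -1, 1, 2)
  expect_equal(scoringPower(-centered, centered)$pearson_r, -1)
  # printed 4-point toy {(1,2),(2,2),(3,4),(4,4)}
  p <- c(1, 2, 3, 4); e <- c(2, 2, 4, 4)
  sp <- scoringPower(p, e)
  expect_equal(sp$pearson_r, cov(p, e) / (sd(p) * sd(e)))
  expect_equal(sp$rmse, sqrt(mean(c(1, 0, 1, 0))))
  expect_warning(spz <- scoringPower(rep(1, 4), e), "zero variance")
  expect_true(is.na(spz$pearson_r))
  expect_error(scoringPower(1:2, 1:2), "n >= 3")
})

test_that("enrichment factor follows the top-fraction definition", {
  scores <- c(100, seq(99, 1))
  labels <- c(TRUE, rep(FALSE, 90), rep(TRUE, 9))
  ef <- enrichmentFactor(scores, labels, 0.01)
  expect_equal(ef$ef_value, 10)          # (1/1)/(10/100)
  expect_identical(ef$n_top, 1)
  expect_equal(enrichmentFactor(scores, labels, 1)$ef_value, 1)
  expect_error(enrichmentFactor(scores, rep(FALSE, 100)), "no actives")
  expect_error(enrichmentFactor(scores, labels, 0), "fraction")
})

test_that("random scores have null EF expectation 1 (Monte Carlo)", {
  set.seed(2024)
  n <- 200; labels <- rep(c(TRUE, FALSE), c(20, 180))
  reps <- 2000
  efs <- vapply(seq_len(reps), function(i)
    enrichmentFactor(rnorm(n), labels, 0.01)$ef_value, 0)
  se <- sd(efs) / sqrt(reps)
  expect_lt(abs(mean(efs) - 1), 3 * se)
})

test_that("template aggregation reports mean and SD, SD 0 for singletons", {
  one <- aggregateTemplates(3.2)
  expect_identical(one$sd, 0)
  expect_identical(one$n_templates, 1L)
  expect_equal(aggregateTemplates(c(2, 4))$mean, 3)
  agg <- aggregateTemplates(c(1, 2, 3))
  expect_equal(agg$mean, 2)
  expect_equal(agg$sd, sd(c(1, 2, 3)))
  expect_error(aggregateTemplates(numeric(0)), "no templates")
})

test_that("bootstrap comparison separates good from noise models", {
  set.seed(10)
  n <- 100
  y <- rnorm(n, 6, 1.5)
  good <- y + rnorm(n, 0, 0.3)
  noise <- rnorm(n, 6, 1.5)
  bc <- bootstrapCompare(good, noise, y, nBoot = 500L, seed = 3L)
  expect_lt(bc$r$p_value, 1e-3)
  expect_gt(bc$r$cliffs_delta, 0.9)
  expect_gt(bc$r$mean_a, bc$r$mean_b)

  same <- bootstrapCompare(good, good, y, nBoot = 200L, seed = 3L)
  expect_equal(same$r$cliffs_delta, 0, tolerance = 1e-12)
  expect_gt(same$r$p_value, 0.9)

  again <- bootstrapCompare(good, noise, y, nBoot = 500L, seed = 3L)
  expect_identical(bc$r$p_value, again$r$p_value)
  expect_identical(bc$rmse$cliffs_delta, again$rmse$cliffs_delta)
})

test_that("seed-ensemble comparison reports t, Bonferroni p and Cohen's d", {
  same <- seedEnsembleCompare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$cohens_d, 0)
  expect_equal(same$p_corrected, 1)

  set.seed(7)
  a <- rnorm(5000); b <- rnorm(5000, 1.5)
  cmp <- seedEnsembleCompare(a, b, nComparisons = 3L)
  expect_equal(cmp$cohens_d, -1.5, tolerance = 0.05)
  expect_lt(cmp$p_corrected, 1e-10)
  expect_equal(cmp$p_corrected, min(1, cmp$p_value * 3))
  raw <- seedEnsembleCompare(a, b, nComparisons = 1L)
  expect_identical(raw$p_corrected, raw$p_value)
  expect_error(seedEnsembleCompare(1, c(1, 2)), "at least 2")
})

test_that("permutation importance recovers the informative features", {
  ds <- makeRegressionDataset(250, nInformative = 2, noiseSd = 0.2,
                              seed = 31)
  cfg <- gbtConfig(nStages = 200L, maxDepth = 4L, learningRate = 0.1,
                   subsample = 0.8, seed = 0L)
  model <- trainModel(ds$features, ds$pk, cfg)
  imp <- permutationImportance(model, ds$features, ds$pk, nRepeats = 5L,
                               seed = 1L)
  expect_identical(sort(imp$feature), sort(colnames(ds$features)))
  expect_true(all(ds$informative %in% imp$feature[1:5]))
  # constant columns have importance exactly zero
  feats <- ds$features; feats$count_080 <- 0
  m2 <- trainModel(feats, ds$pk, cfg)
  imp2 <- permutationImportance(m2, feats, ds$pk, nRepeats = 3L, seed = 1L)
  expect_identical(imp2$importance_mean[imp2$feature == "count_080"], 0)
  imp3 <- permutationImportance(model, ds$features, ds$pk, nRepeats = 5L,
                                seed = 1L)
  expect_identical(imp$importance_mean, imp3$importance_mean)
})

test_that("per-shell ablation finds the shell carrying the signal", {
  vocab <- buildVocabulary()
  scheme <- shellScheme(6, 2)
  set.seed(41)
  n <- 200
  # synthetic multi-shelled matrix over a tiny pair subset
  pairSub <- pairNames(vocab)[1:12]
  cols <- as.vector(t(outer(pairSub, formatBound(shellBounds(scheme)),
                            paste, sep = "-")))
  m <- matrix(rpois(n * length(cols), 1), n,
              dimnames = list(NULL, cols))
  shell2 <- grep("-4.5$", cols)
  pk <- 5 + rowSums(m[, shell2[1:3], drop = FALSE]) + rnorm(n, 0, 0.2)
  cfg <- gbtConfig(nStages = 120L, maxDepth = 3L, learningRate = 0.1,
                   subsample = 0.9, seed = 0L)
  ab <- perShellAblation(m, pk, scheme, cfg, nFolds = 3L, nTrials = 1L)
  expect_identical(nrow(ab), 3L)
  expect_identical(sum(ab$n_features), length(cols))  # column partition
  expect_identical(which.max(ab$mean_r), 2L)
  # a band covering all shells behaves like the full-feature run
  full <- perShellAblation(m, pk, scheme, cfg,
                           bands = list(1:3), nFolds = 3L, nTrials = 1L)
  cv <- crossValidate(m, pk, cfg, nFolds = 3L, nTrials = 1L)
  expect_equal(full$mean_r, mean(attr(cv, "trialMeans")$pearson_r),
               tolerance = 1e-9)
})
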