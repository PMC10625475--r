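#' Construct a GBT configuration
#'
#' @param nStages boosting stages.
#' @param maxDepth maximum tree depth.
#' @param learningRate shrinkage.
#' @param subsample row-subsampling fraction per stage.
#' @param maxFeatures \code{"sqrt"} (random sqrt(p) features per split) or
#'   \code{"all"}.
#' @param minSamplesSplit minimum samples to split an internal node
#'   (recorded in the configuration; the tree backend approximates it, see
#'   the methods vignette).
#' @param seed integer seed controlling row/feature subsampling.
#' @return a [GBTConfig-class].
#' @export
gbtConfig <- function(nStages = 20000L, maxDepth = 8L, learningRate = 0.005,
                      subsample = 0.7, maxFeatures = "sqrt",
                      minSamplesSplit = 2L, seed = 0L) {
  new("GBTConfig", nStages = as.integer(nStages),
      maxDepth = as.integer(maxDepth), learningRate = learningRate,
      subsample = subsample, maxFeatures = maxFeatures,
      minSamplesSplit = as.integer(minSamplesSplit),
      loss = "least_squares", seed = as.integer(seed))
}

#' Tuned default configurations per feature method
#'
#' The cross-validated optima: multi-shelled features pair with 20000
#' stages, depth 10, learning rate 0.005, subsample 0.6, sqrt feature
#' sampling and min-samples-split 3; weighted features with 30000 stages
#' and min-samples-split 2 (otherwise identical); the single-threshold
#' baseline uses 20000 stages, depth 8 and subsample 0.7.
#'
#' @param method \code{"multishell"}, \code{"weighted"} or
#'   \code{"ecif_baseline"}.
#' @param seed seed stored in the configuration (default 0).
#' @return a [GBTConfig-class].
#' @examples
#' defaultConfig("multishell")
#' @export
defaultConfig <- function(method = c("multishell", "weighted",
                                     "ecif_baseline"), seed = 0L) {
  method <- match.arg(method)
  switch(method,
    multishell = gbtConfig(20000L, 10L, 0.005, 0.6, "sqrt", 3L, seed),
    weighted = gbtConfig(30000L, 10L, 0.005, 0.6, "sqrt", 2L, seed),
    ecif_baseline = gbtConfig(20000L, 8L, 0.005, 0.7, "sqrt", 2L, seed))
}

asFeatureMatrix <- function(features) {
  m <- as.matrix(features)
  storage.mode(m) <- "double"
  if (is.null(colnames(m))) stop("feature matrix must have column names")
  if (anyDuplicated(colnames(m))) stop("duplicated feature names")
  m
}

xgbParams <- function(config, p) {
  colsample <- if (config@maxFeatures == "sqrt") max(sqrt(p) / p, 1 / p)
               else 1
  list(objective = "reg:squarederror", eta = config@learningRate,
       max_depth = config@maxDepth, subsample = config@subsample,
       colsample_bynode = colsample, nthread = 1L,
       seed = config@seed, tree_method = "hist")
}

#' Train a gradient-boosted affinity model
#'
#' Fits a least-squares boosted tree ensemble on an assembled feature
#' matrix against pK values (pK = -log10 of Ki or Kd). Training is
#' deterministic given (data, config, seed).
#'
#' @param features matrix or data.frame of features, rows = complexes,
#'   named columns.
#' @param pk numeric vector of pK values, aligned with the rows.
#' @param config a [GBTConfig-class].
#' @return an [EcifModel-class].
#' @seealso [predict,EcifModel-method], [crossValidate()]
#' @export
trainModel <- function(features, pk, config = defaultConfig("multishell")) {
  m <- asFeatureMatrix(features)
  if (nrow(m) != length(pk))
    stop("features (", nrow(m), " rows) and pk (", length(pk),
         ") are misaligned")
  if (anyNA(m) || anyNA(pk)) stop("features and pk must not contain nulls")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config@seed)
  booster <- xgboost::xgb.train(
    params = xgbParams(config, ncol(m)),
    data = xgboost::xgb.DMatrix(m, label = pk),
    nrounds = config@nStages, verbose = 0)
  raw <- xgboost::xgb.save.raw(booster, raw_format = "ubj")
  new("EcifModel", config = config, featureNames = colnames(m),
      booster = raw,
      trainInfo = list(n = nrow(m), p = ncol(m),
                       pkMean = mean(pk),
                       timestamp = format(Sys.time(), tz = "UTC")))
}

boosterOf <- function(model) xgboost::xgb.load.raw(model@booster)

#' Predict pK for new complexes
#'
#' Columns of \code{newdata} are re-aligned to the model's feature-name
#' order; names are authoritative, so a permuted column order yields
#' identical predictions. A missing or unknown feature name is an error
#' reporting the first mismatch.
#'
#' @param object an [EcifModel-class].
#' @param newdata matrix or data.frame with named feature columns.
#' @param ... ignored.
#' @return numeric vector of predicted pK values, one per row.
#' @export
setMethod("predict", "EcifModel", function(object, newdata, ...) {
  m <- asFeatureMatrix(newdata)
  want <- object@featureNames
  missing <- setdiff(want, colnames(m))
  if (length(missing))
    stop("feature name mismatch: model expects '", missing[1L],
         "' which is absent from newdata (", length(missing),
         " missing in total)")
  m <- m[, want, drop = FALSE]
  stats::predict(boosterOf(object), xgboost::xgb.DMatrix(m))
})

#' Save / load a trained model as a single portable JSON file
#'
#' The file embeds the configuration, the feature-name order and the
#' serialized ensemble, so a reloaded model predicts bit-identically.
#'
#' @param model an [EcifModel-class].
#' @param path output file path.
#' @return \code{saveModel}: \code{path}, invisibly.
#' @export
saveModel <- function(model, path) {
  payload <- list(
    format = "msecif-model-1",
    config = list(nStages = model@config@nStages,
                  maxDepth = model@config@maxDepth,
                  learningRate = model@config@learningRate,
                  subsample = model@config@subsample,
                  maxFeatures = model@config@maxFeatures,
                  minSamplesSplit = model@config@minSamplesSplit,
                  seed = model@config@seed),
    featureNames = model@featureNames,
    trainInfo = model@trainInfo[c("n", "p", "pkMean", "timestamp")],
    booster = jsonlite::base64_enc(model@booster))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @return \code{loadModel}: an [EcifModel-class].
#' @export
loadModel <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "msecif-model-1"))
    stop("'", path, "' is not an msecif model file")
  cfg <- payload$config
  new("EcifModel",
      config = gbtConfig(cfg$nStages, cfg$maxDepth, cfg$learningRate,
                         cfg$subsample, cfg$maxFeatures,
                         cfg$minSamplesSplit, cfg$seed),
      featureNames = payload$featureNames,
      booster = jsonlite::base64_dec(payload$booster),
      trainInfo = as.list(payload$trainInfo))
}

#' Repeated-seed k-fold cross-validation
#'
#' Runs \code{nTrials} independent repetitions of \code{nFolds}-fold
#' cross-validation; trial t uses seed \code{baseSeed + t} to shuffle the
#' rows before splitting them into contiguous blocks (no stratification).
#' Pearson's R and RMSE are reported per fold; trial means are the
#' quantity used to compare feature/hyperparameter conditions.
#'
#' @param features feature matrix/data.frame with named columns.
#' @param pk aligned pK vector.
#' @param config a [GBTConfig-class]; the per-fold models use its stages,
#'   depth, and sampling settings.
#' @param nFolds number of folds (default 10).
#' @param nTrials number of repetitions with different seeds (default 10).
#' @param baseSeed base random seed (default 1).
#' @return data.frame with columns \code{trial}, \code{fold}, \code{seed},
#'   \code{pearson_r}, \code{rmse}, and attribute \code{"trialMeans"}
#'   (per-trial mean R and RMSE).
#' @export
crossValidate <- function(features, pk, config, nFolds = 10L,
                          nTrials = 10L, baseSeed = 1L) {
  m <- asFeatureMatrix(features)
  n <- nrow(m)
  if (nFolds < 2L) stop("nFolds must be >= 2")
  if (nFolds > n) stop("nFolds (", nFolds, ") exceeds the number of rows (",
                       n, ")")
  res <- vector("list", nTrials * nFolds)
  k <- 0L
  for (trial in seq_len(nTrials)) {
    seed <- baseSeed + trial
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    idx <- sample.int(n)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    # contiguous blocks over the shuffled index
    bounds <- floor(seq(0, n, length.out = nFolds + 1L))
    for (fold in seq_len(nFolds)) {
      test <- idx[(bounds[fold] + 1L):bounds[fold + 1L]]
      train <- setdiff(seq_len(n), test)
      cfg <- config
      cfg@seed <- as.integer(seed)
      fit <- trainModel(m[train, , drop = FALSE], pk[train], cfg)
      pred <- predict(fit, m[test, , drop = FALSE])
      k <- k + 1L
      sp <- scoringPower(pred, pk[test])
      res[[k]] <- data.frame(trial = trial, fold = fold, seed = seed,
                             pearson_r = sp$pearson_r, rmse = sp$rmse)
    }
  }
  out <- do.call(rbind, res)
  tm <- stats::aggregate(cbind(pearson_r, rmse) ~ trial, out, mean)
  attr(out, "trialMeans") <- tm
  out
}

#' Two-stage GBT hyperparameter grid search
#'
#' Stage one scans \code{nStages}, \code{learningRate} and \code{maxDepth}
#' with the remaining settings fixed; stage two fixes the stage-one optimum
#' and scans \code{minSamplesSplit}, \code{maxFeatures} and
#' \code{subsample}. Conditions are ranked by mean cross-validated
#' Pearson's R.
#'
#' @param features,pk training data.
#' @param base a [GBTConfig-class] providing the fixed settings.
#' @param stage1,stage2 named lists of candidate values for the stage's
#'   parameters (missing entries keep the base value).
#' @param nFolds,nTrials,baseSeed cross-validation settings (kept small by
#'   callers when the grid is large).
#' @return list with \code{best} (a [GBTConfig-class]) and \code{results}
#'   (one row per condition with mean R and RMSE).
#' @export
gridSearchGBT <- function(features, pk, base = defaultConfig("ecif_baseline"),
                          stage1 = list(), stage2 = list(),
                          nFolds = 10L, nTrials = 2L, baseSeed = 1L) {
  evalConfig <- function(cfg) {
    cv <- crossValidate(features, pk, cfg, nFolds = nFolds,
                        nTrials = nTrials, baseSeed = baseSeed)
    tm <- attr(cv, "trialMeans")
    c(pearson_r = mean(tm$pearson_r), rmse = mean(tm$rmse))
  }
  expandStage <- function(cfg, grid, fields) {
    grid <- grid[names(grid) %in% fields]
    if (!length(grid)) return(list(cfg))
    combos <- expand.grid(grid, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(combos)), function(i) {
      out <- cfg
      for (f in names(combos)) slot(out, f) <-
          if (f %in% c("nStages", "maxDepth", "minSamplesSplit"))
            as.integer(combos[i, f]) else combos[i, f]
      out
    })
  }
  runStage <- function(cfgs) {
    scores <- t(vapply(cfgs, evalConfig, c(pearson_r = 0, rmse = 0)))
    list(best = cfgs[[which.max(scores[, "pearson_r"])]], scores = scores)
  }
  s1 <- runStage(expandStage(base, stage1,
                             c("nStages", "learningRate", "maxDepth")))
  s2 <- runStage(expandStage(s1$best, stage2,
                             c("minSamplesSplit", "maxFeatures",
                               "subsample")))
  results <- rbind(data.frame(stage = 1L, s1$scores),
                   data.frame(stage = 2L, s2$scores))
  list(best = s2$best, results = results)
}
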