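#' Scoring power: Pearson's R and RMSE
#'
#' The linear correlation between predicted and experimental pK and the
#' root-mean-square error, the two scoring-power metrics used on crystal
#' structures.
#'
#' @param predicted numeric vector of predicted pK.
#' @param experimental numeric vector of experimental pK, same length.
#' @return list with \code{pearson_r} (NA with a warning when either
#'   vector has zero variance), \code{rmse} and \code{n}.
#' @examples
#' scoringPower(c(1, 2, 3, 4), c(2, 2, 4, 4))
#' @export
scoringPower <- function(predicted, experimental) {
  if (length(predicted) != length(experimental))
    stop("predicted and experimental must have equal length")
  if (length(predicted) < 3L) stop("need n >= 3 for a defined correlation")
  if (anyNA(predicted) || anyNA(experimental))
    stop("inputs must not contain nulls")
  r <- if (stats::sd(predicted) == 0 || stats::sd(experimental) == 0) {
    warning("zero variance: Pearson's R is undefined")
    NA_real_
  } else stats::cor(predicted, experimental)
  list(pearson_r = r,
       rmse = sqrt(mean((predicted - experimental)^2)),
       n = length(predicted))
}

#' Enrichment factor at a top fraction
#'
#' Ranks compounds by descending score (higher predicted affinity =
#' better; ties keep stable input order), takes the top
#' \code{ceiling(fraction * n)} compounds, and reports the active rate in
#' that top set relative to the overall active rate. A random ranking has
#' expected EF 1; the maximum is \code{1/fraction} when actives saturate
#' the top set.
#'
#' @param scores numeric score vector.
#' @param activeLabels logical vector, TRUE for actives.
#' @param fraction top fraction in (0, 1]; default 0.01 (EF1\%).
#' @return list with \code{ef_fraction}, \code{ef_value},
#'   \code{n_compounds}, \code{n_actives}, \code{n_top}.
#' @examples
#' sc <- c(10, 9:1, rep(0, 90))
#' enrichmentFactor(sc, c(TRUE, rep(FALSE, 9), rep(c(TRUE, FALSE),
#'                  c(9, 81))), 0.01)$ef_value   # 10
#' @export
enrichmentFactor <- function(scores, activeLabels, fraction = 0.01) {
  n <- length(scores)
  if (length(activeLabels) != n)
    stop("scores and activeLabels must have equal length")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  nActives <- sum(activeLabels)
  if (nActives == 0L) stop("no actives: enrichment factor is undefined")
  nTop <- ceiling(fraction * n)
  top <- order(-scores)[seq_len(nTop)]  # stable for tied scores
  list(ef_fraction = fraction,
       ef_value = (sum(activeLabels[top]) / nTop) / (nActives / n),
       n_compounds = n, n_actives = nActives, n_top = nTop)
}

#' Aggregate per-template enrichment factors
#'
#' Targets with several protein templates are screened once per template;
#' the summary is the arithmetic mean and sample standard deviation of the
#' per-template EF values (SD 0 for a single template).
#'
#' @param efs numeric vector of per-template EF values.
#' @return list with \code{mean}, \code{sd}, \code{n_templates}.
#' @export
aggregateTemplates <- function(efs) {
  if (length(efs) == 0L) stop("no templates supplied")
  list(mean = mean(efs),
       sd = if (length(efs) > 1L) stats::sd(efs) else 0,
       n_templates = length(efs))
}

#' Bootstrap comparison of two models on one test set
#'
#' Resamples complexes (rows) with replacement \code{nBoot} times; each
#' replicate yields Pearson's R and RMSE for both models on the same
#' resampled indices. The two replicate distributions are compared per
#' metric with a two-sided Mann-Whitney U test, and Cliff's delta
#' (computed from the U statistic) quantifies the effect size.
#'
#' @param predsA,predsB predicted pK vectors of the two models.
#' @param experimental experimental pK vector, aligned.
#' @param nBoot number of bootstrap replicates (default 10000).
#' @param seed random seed.
#' @return list with per-metric components \code{r} and \code{rmse}, each
#'   holding \code{p_value}, \code{cliffs_delta}, \code{mean_a},
#'   \code{mean_b}, plus \code{n_boot}.
#' @export
bootstrapCompare <- function(predsA, predsB, experimental, nBoot = 10000L,
                             seed = 1L) {
  n <- length(experimental)
  if (length(predsA) != n || length(predsB) != n)
    stop("prediction vectors must align with experimental values")
  if (n < 10L) stop("too few complexes for bootstrap resampling")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rA <- rB <- eA <- eB <- numeric(nBoot)
  for (b in seq_len(nBoot)) {
    i <- sample.int(n, n, replace = TRUE)
    y <- experimental[i]
    rA[b] <- suppressWarnings(stats::cor(predsA[i], y))
    rB[b] <- suppressWarnings(stats::cor(predsB[i], y))
    eA[b] <- sqrt(mean((predsA[i] - y)^2))
    eB[b] <- sqrt(mean((predsB[i] - y)^2))
  }
  cmp <- function(a, b) {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    u <- wt$statistic[[1]]
    list(p_value = wt$p.value,
         cliffs_delta = 2 * u / (length(a) * length(b)) - 1,
         mean_a = mean(a), mean_b = mean(b))
  }
  list(r = cmp(rA, rB), rmse = cmp(eA, eB), n_boot = nBoot)
}

#' Compare two seed-ensembles of metric values
#'
#' For ensembles of models differing only in random seed, compares the two
#' per-seed metric samples with an independent two-sample t-test,
#' Bonferroni-corrects the p-value for the number of comparisons made, and
#' reports the pooled-SD Cohen's d effect size.
#'
#' @param metricsA,metricsB numeric vectors of per-seed metric values.
#' @param nComparisons Bonferroni correction factor (default 1).
#' @return list with \code{t_statistic}, \code{p_value} (raw),
#'   \code{p_corrected} (capped at 1), \code{cohens_d}, \code{df}.
#' @examples
#' seedEnsembleCompare(rnorm(100), rnorm(100, 1))
#' @export
seedEnsembleCompare <- function(metricsA, metricsB, nComparisons = 1L) {
  if (length(metricsA) < 2L || length(metricsB) < 2L)
    stop("need at least 2 values per sample")
  tt <- stats::t.test(metricsA, metricsB, var.equal = TRUE)
  nA <- length(metricsA); nB <- length(metricsB)
  sp <- sqrt(((nA - 1) * stats::var(metricsA) +
              (nB - 1) * stats::var(metricsB)) / (nA + nB - 2))
  d <- if (sp == 0) 0 else (mean(metricsA) - mean(metricsB)) / sp
  list(t_statistic = tt$statistic[[1]],
       p_value = tt$p.value,
       p_corrected = min(1, tt$p.value * nComparisons),
       cohens_d = d, df = tt$parameter[[1]])
}

#' Permutation feature importance
#'
#' For each feature, shuffles that column \code{nRepeats} times (leaving
#' the rest intact) and reports the mean and SD of the drop in the model's
#' R-squared score on the supplied data. Features the ensemble never
#' splits on have importance exactly 0.
#'
#' @param model an [EcifModel-class].
#' @param features feature matrix/data.frame with the model's columns.
#' @param pk aligned pK vector.
#' @param nRepeats independent shuffles per feature (default 30).
#' @param seed random seed.
#' @return data.frame with columns \code{feature}, \code{importance_mean},
#'   \code{importance_sd}, sorted by decreasing mean importance.
#' @export
permutationImportance <- function(model, features, pk, nRepeats = 30L,
                                  seed = 1L) {
  m <- asFeatureMatrix(features)
  missing <- setdiff(model@featureNames, colnames(m))
  if (length(missing))
    stop("feature name mismatch: '", missing[1L], "' absent from features")
  m <- m[, model@featureNames, drop = FALSE]
  booster <- boosterOf(model)
  score <- function(mat) {
    pred <- stats::predict(booster, xgboost::xgb.DMatrix(mat))
    1 - sum((pk - pred)^2) / sum((pk - mean(pk))^2)
  }
  base <- score(m)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- nrow(m)
  p <- ncol(m)
  mu <- sd <- numeric(p)
  varying <- which(apply(m, 2L, function(v) any(v != v[1L])))
  for (j in varying) {
    drops <- numeric(nRepeats)
    for (r in seq_len(nRepeats)) {
      mp <- m
      mp[, j] <- m[sample.int(n), j]
      drops[r] <- base - score(mp)
    }
    mu[j] <- mean(drops); sd[j] <- stats::sd(drops)
  }
  out <- data.frame(feature = colnames(m), importance_mean = mu,
                    importance_sd = sd, stringsAsFactors = FALSE)
  out[order(-out$importance_mean), , drop = FALSE]
}

#' Per-shell ablation of multi-shelled features
#'
#' Splits a multi-shelled feature matrix by shell bound and, for each band
#' of contiguous shells, cross-validates a model trained on that band's
#' columns only (no ligand descriptors), isolating how much each distance
#' range contributes to prediction.
#'
#' @param features multi-shelled feature matrix (columns named
#'   \code{"<pair>-<bound>"}).
#' @param pk aligned pK vector.
#' @param scheme the [ShellScheme-class] the features were computed under.
#' @param config a [GBTConfig-class] for the per-band models.
#' @param bands list of integer vectors of contiguous shell indices;
#'   default: one band per shell.
#' @param nFolds,nTrials,baseSeed cross-validation settings.
#' @return data.frame with one row per band: \code{band}, \code{bounds},
#'   \code{n_features}, \code{mean_r}, \code{mean_rmse}.
#' @export
perShellAblation <- function(features, pk, scheme, config,
                             bands = NULL, nFolds = 5L, nTrials = 2L,
                             baseSeed = 1L) {
  m <- asFeatureMatrix(features)
  bounds <- shellBounds(scheme)
  lab <- formatBound(bounds)
  shellOf <- match(sub("^.*-", "", colnames(m)), lab)
  if (anyNA(shellOf))
    stop("column names do not end in a shell bound of the scheme")
  if (is.null(bands)) bands <- as.list(seq_along(bounds))
  res <- lapply(seq_along(bands), function(k) {
    cols <- which(shellOf %in% bands[[k]])
    if (!length(cols)) stop("band ", k, " selects no columns")
    cv <- crossValidate(m[, cols, drop = FALSE], pk, config,
                        nFolds = nFolds, nTrials = nTrials,
                        baseSeed = baseSeed)
    tm <- attr(cv, "trialMeans")
    data.frame(band = k,
               bounds = paste(lab[bands[[k]]], collapse = ","),
               n_features = length(cols),
               mean_r = mean(tm$pearson_r), mean_rmse = mean(tm$rmse),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
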