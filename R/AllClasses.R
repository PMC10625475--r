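#' @import methods
NULL

#' Shell scheme: ordered distance-shell upper bounds
#'
#' A shell scheme partitions the interatomic-distance axis (0, threshold]
#' into consecutive shells. Bounds start at \code{minShell}, advance by a
#' constant \code{step}, and are capped so the final bound equals
#' \code{threshold} exactly; the terminal shell may therefore be narrower
#' than \code{step}. Shell k is the half-open interval
#' (bounds[k-1], bounds[k]], with bounds[0] = 0.
#'
#' @slot minShell numeric(1). Upper bound of the innermost shell, in Angstrom.
#' @slot step numeric(1). Constant shell width, in Angstrom.
#' @slot threshold numeric(1). Outer distance threshold, in Angstrom.
#' @slot bounds numeric. Strictly increasing shell upper bounds ending at
#'   \code{threshold}.
#'
#' @seealso [shellScheme()]
#' @export
setClass("ShellScheme",
  representation(minShell = "numeric", step = "numeric",
                 threshold = "numeric", bounds = "numeric"))

setValidity("ShellScheme", function(object) {
  b <- object@bounds
  if (length(object@minShell) != 1L || length(object@step) != 1L ||
      length(object@threshold) != 1L)
    return("minShell, step and threshold must be scalars")
  if (object@step <= 0) return("step must be > 0")
  if (object@minShell <= 0 || object@minShell >= object@threshold)
    return("minShell must satisfy 0 < minShell < threshold")
  if (length(b) < 1L || any(diff(b) <= 0))
    return("bounds must be strictly increasing")
  if (abs(b[1L] - object@minShell) > 1e-9)
    return("bounds[1] must equal minShell")
  if (abs(b[length(b)] - object@threshold) > 1e-9)
    return("last bound must equal threshold")
  if (length(b) > 2L &&
      any(abs(diff(b)[-(length(b) - 1L)] - object@step) > 1e-9))
    return("interior bounds must advance by step")
  TRUE
})

#' Pair vocabulary: the fixed protein x ligand atom-type cross product
#'
#' The vocabulary fixes feature order and dimensionality: every ordered
#' combination of a protein-side and a ligand-side atom type, joined by a
#' hyphen. The packaged reference lists give 22 protein and 70 ligand types,
#' hence 1540 pair names, for both the six-element and the
#' aromaticity-free five-element variant.
#'
#' @slot variant character(1), \code{"five_element"} or \code{"six_element"}.
#' @slot proteinTypes character. Sorted protein-side atom types.
#' @slot ligandTypes character. Sorted ligand-side atom types.
#' @slot pairNames character. \code{length(proteinTypes) * length(ligandTypes)}
#'   pair names in deterministic protein-major lexicographic order.
#'
#' @seealso [buildVocabulary()]
#' @export
setClass("PairVocabulary",
  representation(variant = "character", proteinTypes = "character",
                 ligandTypes = "character", pairNames = "character"))

setValidity("PairVocabulary", function(object) {
  if (!object@variant %in% c("five_element", "six_element"))
    return("variant must be 'five_element' or 'six_element'")
  if (anyDuplicated(object@proteinTypes)) return("duplicated protein types")
  if (anyDuplicated(object@ligandTypes)) return("duplicated ligand types")
  if (length(object@pairNames) !=
      length(object@proteinTypes) * length(object@ligandTypes))
    return("pairNames must be the full cross product")
  TRUE
})

#' Gradient-boosted tree configuration
#'
#' Hyperparameters of the boosted regression ensemble, recorded in the
#' vocabulary of classical gradient boosting: number of boosting stages,
#' tree depth, learning rate, row subsampling fraction, the feature
#' subsampling rule used at each split ("sqrt" or "all"), and the minimum
#' number of samples required to split a node.
#'
#' @slot nStages integer(1). Boosting stages (trees).
#' @slot maxDepth integer(1). Maximum tree depth.
#' @slot learningRate numeric(1). Shrinkage in (0, 1].
#' @slot subsample numeric(1). Fraction of rows fed to each stage, in (0, 1].
#' @slot maxFeatures character(1). \code{"sqrt"} or \code{"all"}.
#' @slot minSamplesSplit integer(1). Minimum samples to split a node.
#' @slot loss character(1). Only \code{"least_squares"}.
#' @slot seed integer(1). Random seed for subsampling.
#'
#' @seealso [gbtConfig()], [defaultConfig()]
#' @export
setClass("GBTConfig",
  representation(nStages = "integer", maxDepth = "integer",
                 learningRate = "numeric", subsample = "numeric",
                 maxFeatures = "character", minSamplesSplit = "integer",
                 loss = "character", seed = "integer"))

setValidity("GBTConfig", function(object) {
  if (object@nStages < 1L) return("nStages must be >= 1")
  if (object@maxDepth < 1L) return("maxDepth must be >= 1")
  if (object@learningRate <= 0 || object@learningRate > 1)
    return("learningRate must be in (0, 1]")
  if (object@subsample <= 0 || object@subsample > 1)
    return("subsample must be in (0, 1]")
  if (!object@maxFeatures %in% c("sqrt", "all"))
    return("maxFeatures must be 'sqrt' or 'all'")
  if (object@minSamplesSplit < 2L) return("minSamplesSplit must be >= 2")
  if (object@loss != "least_squares") return("loss must be 'least_squares'")
  TRUE
})

#' Fitted boosted-tree affinity model
#'
#' Wraps the fitted ensemble together with the exact feature-name order it
#' expects and the configuration it was trained under. Prediction requires
#' the same feature names; columns are re-aligned by name.
#'
#' @slot config A [GBTConfig-class].
#' @slot featureNames character. Ordered feature names seen at training.
#' @slot booster raw. Serialized ensemble (UBJSON bytes).
#' @slot trainInfo list. Training metadata (n rows, data hash, timestamp).
#'
#' @seealso [trainModel()], [predict,EcifModel-method]
#' @export
setClass("EcifModel",
  representation(config = "GBTConfig", featureNames = "character",
                 booster = "raw", trainInfo = "list"))

setValidity("EcifModel", function(object) {
  if (length(object@featureNames) < 1L) return("featureNames is empty")
  if (anyDuplicated(object@featureNames)) return("duplicated feature names")
  if (length(object@booster) == 0L) return("empty booster payload")
  TRUE
})
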