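#' @rdname ShellScheme-class
#' @param object a \code{ShellScheme}
#' @export
setGeneric("shellBounds", function(object) standardGeneric("shellBounds"))

#' @rdname ShellScheme-class
#' @export
setGeneric("shellThreshold", function(object) standardGeneric("shellThreshold"))

#' @rdname ShellScheme-class
#' @export
setGeneric("shellStep", function(object) standardGeneric("shellStep"))

#' @rdname PairVocabulary-class
#' @param object a \code{PairVocabulary}
#' @export
setGeneric("pairNames", function(object) standardGeneric("pairNames"))

#' @rdname PairVocabulary-class
#' @export
setGeneric("proteinTypes", function(object) standardGeneric("proteinTypes"))

#' @rdname PairVocabulary-class
#' @export
setGeneric("ligandTypes", function(object) standardGeneric("ligandTypes"))

#' @rdname PairVocabulary-class
#' @export
setGeneric("typeVariant", function(object) standardGeneric("typeVariant"))

#' @rdname EcifModel-class
#' @param object an \code{EcifModel}
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))

#' @rdname EcifModel-class
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))

#' @export
setMethod("shellBounds", "ShellScheme", function(object) object@bounds)

#' @export
setMethod("shellThreshold", "ShellScheme", function(object) object@threshold)

#' @export
setMethod("shellStep", "ShellScheme", function(object) object@step)

#' @export
setMethod("pairNames", "PairVocabulary", function(object) object@pairNames)

#' @export
setMethod("proteinTypes", "PairVocabulary", function(object) object@proteinTypes)

#' @export
setMethod("ligandTypes", "PairVocabulary", function(object) object@ligandTypes)

#' @export
setMethod("typeVariant", "PairVocabulary", function(object) object@variant)

#' @export
setMethod("featureNames", "EcifModel", function(object) object@featureNames)

#' @export
setMethod("modelConfig", "EcifModel", function(object) object@config)

setMethod("show", "ShellScheme", function(object) {
  cat("ShellScheme:", length(object@bounds), "shells over (0,",
      object@threshold, "] A\n")
  cat("  bounds:", paste(formatBound(object@bounds), collapse = ", "), "\n")
  cat("  minShell:", object@minShell, "A, step:", object@step, "A\n")
})

setMethod("show", "PairVocabulary", function(object) {
  cat("PairVocabulary (", object@variant, "): ",
      length(object@proteinTypes), " protein x ",
      length(object@ligandTypes), " ligand = ",
      length(object@pairNames), " pair names\n", sep = "")
})

setMethod("show", "GBTConfig", function(object) {
  cat("GBTConfig: ", object@nStages, " stages, depth ", object@maxDepth,
      ", lr ", object@learningRate, ", subsample ", object@subsample,
      ", maxFeatures '", object@maxFeatures, "', minSamplesSplit ",
      object@minSamplesSplit, ", seed ", object@seed, "\n", sep = "")
})

setMethod("show", "EcifModel", function(object) {
  cat("EcifModel:", length(object@featureNames), "features,",
      object@config@nStages, "boosting stages\n")
  cat("  trained on", object@trainInfo$n %||% NA, "complexes\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
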