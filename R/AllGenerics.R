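#' @include AllClasses.R
NULL

#' Accessors
#'
#' Accessor generics for the package's S4 containers.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("probeCounts", function(x) standardGeneric("probeCounts"))

#' @rdname accessors
#' @export
setGeneric("posControlCounts", function(x) standardGeneric("posControlCounts"))

#' @rdname accessors
#' @export
setGeneric("outcomes", function(x) standardGeneric("outcomes"))

#' @rdname accessors
#' @export
setGeneric("groundTruthProbes", function(x) standardGeneric("groundTruthProbes"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("trainingLabel", function(x) standardGeneric("trainingLabel"))

#' @rdname accessors
#' @export
setGeneric("variableSet", function(x) standardGeneric("variableSet"))

#' @rdname accessors
#' @export
setGeneric("decisions", function(x) standardGeneric("decisions"))

#' @rdname accessors
#' @export
setGeneric("selectionProportions", function(x) standardGeneric("selectionProportions"))

#' @rdname accessors
#' @export
setGeneric("retainedFeatures", function(x) standardGeneric("retainedFeatures"))

#' @rdname accessors
#' @export
setGeneric("riskScores", function(x) standardGeneric("riskScores"))

#' @rdname accessors
#' @export
setGeneric("curveTable", function(x) standardGeneric("curveTable"))

## ---- methods -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("probeCounts", "UrineCohort", function(x) {
  m <- SummarizedExperiment::assay(x, "counts")
  m[grepl("^probe_", rownames(m)), , drop = FALSE]
})

#' @rdname accessors
#' @export
setMethod("posControlCounts", "UrineCohort", function(x) {
  m <- SummarizedExperiment::assay(x, "counts")
  m[grepl("^posctl_", rownames(m)), , drop = FALSE]
})

#' @rdname accessors
#' @export
setMethod("outcomes", "UrineCohort", function(x) {
  factor(SummarizedExperiment::colData(x)$outcome, levels = OUTCOME_LEVELS)
})

#' @rdname accessors
#' @export
setMethod("outcomes", "FeatureMatrix", function(x) x@outcome)

#' @rdname accessors
#' @export
setMethod("groundTruthProbes", "UrineCohort", function(x) {
  S4Vectors::metadata(x)$informativeProbes
})

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("trainingLabel", "FeatureMatrix", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("variableSet", "FeatureMatrix", function(x) x@variableSet)

#' @rdname accessors
#' @export
setMethod("decisions", "BorutaRun", function(x) x@decision)

#' @rdname accessors
#' @export
setMethod("selectionProportions", "StabilityReport", function(x) x@selectionProportion)

#' @rdname accessors
#' @export
setMethod("retainedFeatures", "StabilityReport", function(x) x@retained)

#' @rdname accessors
#' @export
setMethod("riskScores", "RiskScoreSet", function(x) {
  data.frame(sample_id = x@sampleId, variant = x@variant, risk = x@risk,
             oob_trees = x@oobTrees, flagged = x@flagged,
             stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("curveTable", "DecisionCurve", function(x) x@curve)

## ---- show ----------------------------------------------------------------

setMethod("show", "CohortDesign", function(object) {
  cat("CohortDesign:", sum(object@nPerClass), "samples (",
      paste(names(object@nPerClass), object@nPerClass, collapse = ", "),
      ")\n  probes:", object@nProbes, "cf-RNA +",
      length(object@posControlLevels), "positive controls;",
      nrow(object@informativeProbes), "informative\n  seed:", object@seed, "\n")
})

setMethod("show", "UrineCohort", function(object) {
  cat("UrineCohort with", ncol(object), "samples,",
      sum(grepl("^probe_", rownames(object))), "cf-RNA probes,",
      sum(grepl("^posctl_", rownames(object))), "positive controls\n")
  if (ncol(object) > 0) print(table(outcome = outcomes(object)))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix [", object@variableSet, "]: ", nrow(object@values),
      " samples x ", ncol(object@values), " features\n", sep = "")
})

setMethod("show", "BorutaRun", function(object) {
  cat("BorutaRun:", object@iterations, "iterations;")
  print(table(decision = object@decision))
})

setMethod("show", "StabilityReport", function(object) {
  cat("StabilityReport: B =", object@B, "resamples, threshold",
      object@threshold, "\n  retained", length(object@retained), "of",
      length(object@selectionProportion), "features\n")
})

setMethod("show", "RiskModel", function(object) {
  cat("RiskModel [", object@variant, "]: ", length(object@features),
      " features, ", object@params$nTrees, " trees\n", sep = "")
})

setMethod("show", "RiskScoreSet", function(object) {
  cat("RiskScoreSet [", object@variant, "]: ", length(object@risk),
      " samples; risk in [", round(min(object@risk, na.rm = TRUE), 3), ", ",
      round(max(object@risk, na.rm = TRUE), 3), "]\n", sep = "")
})

setMethod("show", "DecisionCurve", function(object) {
  cat("DecisionCurve [", object@endpoint, "]: ",
      length(unique(object@curve$threshold)), " thresholds x ",
      length(unique(object@curve$strategy)), " strategies\n", sep = "")
})
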