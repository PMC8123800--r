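#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Biopsy outcome categories
#'
#' Ordered outcome levels used throughout the package: unbiopsied patients
#' with no evidence of cancer (PSA < 4 ng/mL, \code{"NEC"}), biopsied
#' patients with a negative finding, and the four Gleason categories of a
#' positive initial TRUS biopsy.
#'
#' @export
OUTCOME_LEVELS <- c("NEC", "BiopsyNegative", "Gs6", "Gs3+4", "Gs4+3", "Gs8plus")

#' Model variable sets
#'
#' The four comparator variable sets: standard-of-care clinical variables
#' (\code{"SoC"}), the EN2 ELISA alone (\code{"Engrailed"}), the cf-RNA
#' probe panel alone (\code{"ExoRNA"}) and the fully integrated set
#' (\code{"ExoGrail"}).
#'
#' @export
VARIANTS <- c("SoC", "Engrailed", "ExoRNA", "ExoGrail")

#' CohortDesign: parameters of the synthetic urine-cohort generator
#'
#' Encodes the statistical structure of a post-DRE urine biomarker cohort:
#' per-class sample counts, log-normal PSA and EN2 marker families
#' moment-matched to published cohort summaries, negative-binomial cf-RNA
#' probe counts with planted log2 class shifts, positive-control probes at
#' fixed expected levels, and a per-sample lane factor that the
#' positive-control normalisation is meant to remove.
#'
#' @slot nPerClass named integer, samples per outcome class (plus
#'   \code{metastatic} extras used to exercise exclusion rules).
#' @slot ageParams list with \code{noCancer}/\code{cancer} mean and sd (years).
#' @slot psaParams per-class log-scale location/scale and truncation bounds
#'   for serum PSA (ng/mL).
#' @slot en2Params per-class log-scale location/scale for the EN2 ELISA.
#' @slot nProbes total number of cf-RNA gene-probes.
#' @slot informativeProbes numeric matrix (probes x outcome classes) of log2
#'   mean shifts for the planted informative probes.
#' @slot baselineLog2Range range of per-probe baseline log2 expected counts.
#' @slot countDispersion negative-binomial size parameter for probe counts.
#' @slot posControlLevels expected counts of the positive-control probes.
#' @slot laneSdLog log-scale sd of the per-sample technical lane factor.
#' @slot dreProbs category probabilities for the DRE prostate-size estimate,
#'   rows \code{noCancer}/\code{cancer}.
#' @slot urineVolParams log-scale location/scale of collected urine volume (mL).
#' @slot seed integer seed that fully determines the generated cohort.
#'
#' @seealso [cohortDesign()], [generateCohort()]
#' @export
setClass("CohortDesign", representation(
  nPerClass = "integer",
  ageParams = "list",
  psaParams = "data.frame",
  en2Params = "data.frame",
  nProbes = "integer",
  informativeProbes = "matrix",
  baselineLog2Range = "numeric",
  countDispersion = "numeric",
  posControlLevels = "numeric",
  laneSdLog = "numeric",
  dreProbs = "matrix",
  urineVolParams = "numeric",
  seed = "integer"
))

setValidity("CohortDesign", function(object) {
  msg <- character()
  if (any(object@nPerClass < 0L)) msg <- c(msg, "class counts must be >= 0")
  if (!all(names(object@nPerClass) == c(OUTCOME_LEVELS, "metastatic")))
    msg <- c(msg, "nPerClass must be named by outcome class plus 'metastatic'")
  if (object@nProbes < nrow(object@informativeProbes))
    msg <- c(msg, "more informative probes than probes")
  if (!all(is.finite(object@informativeProbes)))
    msg <- c(msg, "informative shifts must be finite")
  if (!identical(colnames(object@informativeProbes), OUTCOME_LEVELS))
    msg <- c(msg, "informative shift columns must be the outcome classes")
  if (object@countDispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  if (any(object@posControlLevels <= 0)) msg <- c(msg, "positive-control levels must be > 0")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "a single integer seed is required")
  if (length(msg)) msg else TRUE
})

#' UrineCohort: a urinary biomarker cohort
#'
#' A \linkS4class{SummarizedExperiment} whose assay \code{"counts"} holds raw
#' NanoString-style probe counts (cf-RNA probes prefixed \code{probe_},
#' positive controls prefixed \code{posctl_}; probes x samples) and whose
#' \code{colData} carries the clinical record for each patient: age, serum
#' PSA, DRE prostate-size category, urine volume, the EN2 ELISA
#' concentration, biopsy outcome, metastasis flag and weeks since any recent
#' biopsy.
#'
#' @seealso [generateCohort()], [readCohort()], [applyExclusions()]
#' @export
setClass("UrineCohort", contains = "SummarizedExperiment")

setValidity("UrineCohort", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("age", "psa", "dre_size", "urine_volume", "en2", "outcome",
            "metastatic", "recent_biopsy_weeks")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) return(paste("missing colData columns:", paste(miss, collapse = ", ")))
  counts <- SummarizedExperiment::assay(object, "counts")
  if (any(counts < 0)) msg <- c(msg, "probe counts must be non-negative")
  if (!all(grepl("^(probe_|posctl_)", rownames(object))))
    msg <- c(msg, "row names must be prefixed probe_ or posctl_")
  if (ncol(object) > 0) {
    if (any(!is.finite(cd$psa)) || any(cd$psa <= 0)) msg <- c(msg, "psa must be > 0")
    if (!all(as.character(cd$outcome) %in% OUTCOME_LEVELS))
      msg <- c(msg, "invalid outcome level")
    bad <- as.character(cd$outcome) == "NEC" & cd$psa >= 4
    if (any(bad)) msg <- c(msg, "NEC implies PSA < 4 ng/mL")
  }
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: predictors plus the continuous training label
#'
#' Samples x features numeric matrix for one model variable set, with cf-RNA
#' features on the positive-control-normalised log2 scale, the continuous
#' training label L in {0, 0.5, 1} derived from biopsy outcome, and the
#' retained categorical outcome for evaluation.
#'
#' @slot values numeric matrix, samples x features.
#' @slot label numeric training label per sample.
#' @slot outcome factor of biopsy outcome per sample.
#' @slot variableSet which variable set the columns represent.
#'
#' @seealso [buildFeatureMatrix()], [assignTrainingLabel()]
#' @export
setClass("FeatureMatrix", representation(
  values = "matrix", label = "numeric", outcome = "factor",
  variableSet = "character"
))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  n <- nrow(object@values)
  if (length(object@label) != n) msg <- c(msg, "label length != sample count")
  if (length(object@outcome) != n) msg <- c(msg, "outcome length != sample count")
  if (n > 0 && any(!is.finite(object@values))) msg <- c(msg, "non-finite feature values")
  if (n > 0 && !all(object@label %in% c(0, 0.5, 1)))
    msg <- c(msg, "label must be in {0, 0.5, 1}")
  if (length(msg)) msg else TRUE
})

#' BorutaRun: result of a single Boruta feature-selection run
#'
#' @slot decision named factor with levels Confirmed/Rejected/Tentative.
#' @slot importance named numeric; mean normalised permutation importance
#'   (Z-score against the shadow-importance distribution) over the
#'   iterations in which the feature was still undecided.
#' @slot iterations number of iterations used.
#'
#' @seealso [borutaOnce()]
#' @export
setClass("BorutaRun", representation(
  decision = "factor", importance = "numeric", iterations = "integer"
))

#' StabilityReport: bootstrap-resampled Boruta selection
#'
#' Per-feature selection proportions over B bootstrap resamples of the
#' cohort, the per-resample normalised importances, and the retained set at
#' the configured threshold.
#'
#' @slot selectionProportion named numeric in [0, 1].
#' @slot importance B x features matrix of per-resample mean importance Z.
#' @slot retained features with selection proportion >= threshold.
#' @slot B number of bootstrap resamples.
#' @slot threshold retention fraction (inclusive).
#' @slot seed root seed of the resample schedule.
#'
#' @seealso [stabilitySelect()], [importanceTrajectory()]
#' @export
setClass("StabilityReport", representation(
  selectionProportion = "numeric", importance = "matrix",
  retained = "character", B = "integer", threshold = "numeric",
  seed = "integer"
))

setValidity("StabilityReport", function(object) {
  pf <- object@selectionProportion
  if (any(pf < 0 | pf > 1)) return("selection proportions must be in [0, 1]")
  exp_ret <- names(pf)[pf >= object@threshold]
  if (!setequal(object@retained, exp_ret))
    return("retained set inconsistent with threshold")
  TRUE
})

#' RiskModel: a fitted random-forest risk model
#'
#' Regression forest on the continuous Gleason-derived label with per-tree
#' in-bag bookkeeping retained for out-of-bag risk scoring.
#'
#' @slot forest the fitted ranger forest.
#' @slot features predictor names used.
#' @slot variant variable-set name.
#' @slot params hyper-parameters (trees, subsample fraction, mtry, leaf size).
#' @slot seed seed the in-bag schedule was derived from.
#'
#' @seealso [trainRiskModel()], [oobScores()]
#' @export
setClass("RiskModel", representation(
  forest = "ANY", features = "character", variant = "character",
  params = "list", seed = "integer"
))

#' RiskScoreSet: per-sample out-of-bag risk scores
#'
#' @slot sampleId sample identifiers.
#' @slot risk out-of-bag risk in [0, 1] (NA when flagged).
#' @slot oobTrees number of trees for which the sample was out of bag.
#' @slot flagged TRUE when a sample was in bag in every tree.
#' @slot variant variable-set name.
#'
#' @seealso [oobScores()], [riskScores()]
#' @export
setClass("RiskScoreSet", representation(
  sampleId = "character", risk = "numeric", oobTrees = "integer",
  flagged = "logical", variant = "character"
))

setValidity("RiskScoreSet", function(object) {
  ok <- is.na(object@risk) | (object@risk >= 0 & object@risk <= 1)
  if (!all(ok)) return("risk scores must lie in [0, 1]")
  if (any(!object@flagged & object@oobTrees < 1L))
    return("unflagged samples need >= 1 out-of-bag tree")
  TRUE
})

#' DecisionCurve: thresholds x strategies table of (standardised) net benefit
#'
#' @slot curve data.frame with columns threshold, strategy, nb, snb.
#' @slot endpoint binary biopsy endpoint evaluated.
#' @slot prevalence mean positive fraction over the resamples used.
#' @slot scheme the prevalence-matching resampling scheme (list), if any.
#'
#' @seealso [dcaCurves()]
#' @export
setClass("DecisionCurve", representation(
  curve = "data.frame", endpoint = "character", prevalence = "numeric",
  scheme = "list"
))
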