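#' @include AllClasses.R AllGenerics.R
NULL

# Explicit per-tree in-bag sets (subsampling without replacement), drawn
# from the shared seed and depending only on n, the tree count and the
# fraction -- never on the feature columns. This is what guarantees that
# every model variant trains on identical resamples.
.inbagSchedule <- function(n, nTrees, sampleFraction, seed) {
  k <- max(1L, floor(n * sampleFraction))
  withSeed(subSeed(seed, "inbag"), lapply(seq_len(nTrees), function(t) {
    inb <- integer(n)
    inb[sample.int(n, k)] <- 1L
    inb
  }))
}

#' Train a random-forest risk model
#'
#' Fits a regression forest on the continuous Gleason-derived training
#' label using per-tree subsampling without replacement, keeping the
#' per-tree in-bag sets for out-of-bag risk scoring. Defaults follow the
#' reference configuration: 401 trees, 63.2% subsample fraction (the
#' without-replacement counterpart of a bootstrap-sized sample), regression
#' mtry \code{floor(p/3)} (minimum 1) and minimum node size 5. A
#' single-feature set (the EN2-only model) is permitted; every split then
#' uses that one feature, making the forest effectively a bagged stump
#' ensemble.
#'
#' @param x a [FeatureMatrix-class]
#' @param features predictors to use (default: all columns, typically the
#'   retained set of a [StabilityReport-class])
#' @param nTrees number of trees (default 401)
#' @param sampleFraction per-tree subsample fraction (default 0.632)
#' @param minNodeSize minimum terminal node size (default 5)
#' @param mtry candidate features per split (default \code{floor(p/3)})
#' @param seed integer seed; the in-bag schedule and the forest are fully
#'   determined by it
#' @return a [RiskModel-class]
#' @export
trainRiskModel <- function(x, features = colnames(featureValues(x)),
                           nTrees = 401, sampleFraction = 0.632,
                           minNodeSize = 5, mtry = NULL, seed = 1L) {
  stopifnot(is(x, "FeatureMatrix"), nTrees >= 1)
  if (!length(features)) stop("selected feature set is empty")
  miss <- setdiff(features, colnames(x@values))
  if (length(miss)) stop("features absent from matrix: ",
                         paste(miss, collapse = ", "))
  vals <- x@values[, features, drop = FALSE]
  if (nrow(vals) != length(x@label)) stop("feature/label length mismatch")
  if (is.null(mtry)) mtry <- max(1L, floor(length(features) / 3))
  inbag <- .inbagSchedule(nrow(vals), nTrees, sampleFraction, seed)
  forest <- ranger::ranger(
    x = as.data.frame(vals, check.names = FALSE), y = x@label,
    num.trees = nTrees, mtry = mtry, min.node.size = minNodeSize,
    replace = FALSE, sample.fraction = sampleFraction,
    inbag = inbag, keep.inbag = TRUE,
    num.threads = 1, seed = subSeed(seed, "forest"), verbose = FALSE)
  new("RiskModel", forest = forest, features = features,
      variant = x@variableSet,
      params = list(nTrees = nTrees, sampleFraction = sampleFraction,
                    minNodeSize = minNodeSize, mtry = mtry),
      seed = as.integer(seed))
}

#' Out-of-bag risk scores
#'
#' Computes each sample's risk as the equally weighted mean of the
#' predictions of the trees whose in-bag set excludes that sample. Because
#' tree leaves average a label taking values in {0, 0.5, 1}, the risk is
#' bounded in [0, 1]. A sample that was in bag in every tree has no
#' out-of-bag prediction: it is flagged, its risk set to NA, and it should
#' be excluded from downstream metrics.
#'
#' @param model a [RiskModel-class]
#' @param x the [FeatureMatrix-class] the model was trained on
#' @return a [RiskScoreSet-class]
#' @export
oobScores <- function(model, x) {
  stopifnot(is(model, "RiskModel"), is(x, "FeatureMatrix"))
  vals <- x@values[, model@features, drop = FALSE]
  preds <- stats::predict(model@forest,
                          data = as.data.frame(vals, check.names = FALSE),
                          predict.all = TRUE, num.threads = 1)$predictions
  inbag <- do.call(cbind, model@forest$inbag.counts)  # n x trees
  oob <- inbag == 0L
  nOob <- rowSums(oob)
  risk <- rowSums(preds * oob) / pmax(nOob, 1L)
  flagged <- nOob == 0L
  risk[flagged] <- NA_real_
  if (any(flagged))
    warning(sum(flagged), " sample(s) in bag in every tree; flagged")
  ids <- rownames(x@values) %||% sprintf("S%03d", seq_len(nrow(x@values)))
  new("RiskScoreSet", sampleId = ids, risk = risk,
      oobTrees = as.integer(nOob), flagged = flagged,
      variant = model@variant)
}

#' Run the full selection-plus-scoring pipeline for each model variant
#'
#' For each requested variable set: build the feature matrix, run
#' bootstrap-resampled Boruta stability selection, train the forest on the
#' retained features and emit out-of-bag risk scores. All variants share
#' one seed, so the bootstrap resample schedule used for feature selection
#' and the per-tree in-bag schedule used for training are identical across
#' variants. If stability selection retains nothing for a variant, the
#' feature with the highest selection proportion is used (with a warning)
#' so the comparator can still be scored.
#'
#' @param cohort a [UrineCohort-class] (exclusions already applied)
#' @param variants subset of [VARIANTS]
#' @param B,threshold,alpha,maxIter stability-selection settings, see
#'   [stabilitySelect()]
#' @param nTrees,sampleFraction forest settings, see [trainRiskModel()]
#' @param seed shared root seed
#' @return named list (per variant) of lists with elements
#'   \code{stability}, \code{model}, \code{scores}
#' @export
runAllVariants <- function(cohort, variants = VARIANTS, B = 1000,
                           threshold = 0.9, alpha = 0.01, maxIter = 100,
                           nTrees = 401, sampleFraction = 0.632, seed = 1L) {
  stopifnot(all(variants %in% VARIANTS))
  out <- list()
  for (v in variants) {
    res <- tryCatch({
      fm <- buildFeatureMatrix(cohort, v)
      rep <- stabilitySelect(fm, B = B, threshold = threshold, alpha = alpha,
                             maxIter = maxIter,
                             rfParams = list(nTrees = nTrees,
                                             sampleFraction = sampleFraction),
                             seed = seed)
      feats <- retainedFeatures(rep)
      if (!length(feats)) {
        feats <- names(which.max(selectionProportions(rep)))
        warning("variant ", v, ": no feature reached the stability ",
                "threshold; using the top-ranked feature ", feats)
      }
      model <- trainRiskModel(fm, feats, nTrees = nTrees,
                              sampleFraction = sampleFraction, seed = seed)
      list(stability = rep, model = model, scores = oobScores(model, fm))
    }, error = function(e) stop("variant ", v, ": ", conditionMessage(e),
                                call. = FALSE))
    out[[v]] <- res
  }
  out
}
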