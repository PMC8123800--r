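#' @include AllClasses.R AllGenerics.R
NULL

# One ranger regression forest used inside Boruta; permutation importance
# (increase in out-of-bag MSE) as the accuracy-decrease measure.
.borutaForest <- function(X, y, rfParams, seed) {
  ranger::ranger(
    x = as.data.frame(X, check.names = FALSE), y = y,
    num.trees = rfParams$nTrees %||% 401,
    mtry = max(1L, floor(ncol(X) / 3)),
    min.node.size = rfParams$minNodeSize %||% 5,
    replace = FALSE,
    sample.fraction = rfParams$sampleFraction %||% 0.632,
    importance = "permutation",
    num.threads = 1, seed = seed, verbose = FALSE)
}

# Permute a feature column at the level of distinct source samples. When a
# matrix contains bootstrap-duplicated rows, `groups` carries the source
# sample of each row: duplicates then receive identical shadow values, so a
# shadow can "memorise" the label through duplicated rows exactly as well as
# a real null feature can, keeping the two exchangeable under resampling.
# With all-distinct groups this is an ordinary column permutation.
.groupPermute <- function(x, groups, seed) {
  ug <- unique(groups)
  if (length(ug) == length(x)) {
    return(withSeed(seed, x[sample.int(length(x))]))
  }
  valg <- x[match(ug, groups)]
  withSeed(seed, valg[sample.int(length(ug))][match(groups, ug)])
}

.borutaEngine <- function(X, y, alpha = 0.01, maxIter = 100,
                          rfParams = list(), seed = 1L, groups = NULL) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples")
  if (ncol(X) < 1L) stop("need at least 1 feature")
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite input values")
  if (length(unique(y)) < 2L)
    stop("degenerate input: training label takes a single value")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  feats <- colnames(X)
  if (is.null(feats)) feats <- colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (anyDuplicated(feats)) stop("feature names must be unique")
  if (is.null(groups)) groups <- seq_len(nrow(X))
  inputOrder <- feats
  # canonical column order: with feature-keyed shadow seeds this makes the
  # decisions invariant to the order the features were supplied in
  X <- X[, order(feats), drop = FALSE]
  feats <- colnames(X)

  decision <- setNames(rep("Tentative", ncol(X)), feats)
  hits <- setNames(integer(ncol(X)), feats)
  zSum <- setNames(numeric(ncol(X)), feats)
  zN <- setNames(integer(ncol(X)), feats)
  iter <- 0L

  while (any(decision == "Tentative") && iter < maxIter) {
    iter <- iter + 1L
    und <- names(decision)[decision == "Tentative"]
    conf <- names(decision)[decision == "Confirmed"]

    # shadows rebuilt each iteration for the undecided features, cycled up
    # to a minimum of five so the max-shadow benchmark stays stable late in
    # a run; Confirmed features stay in the forest but need no shadow.
    src <- rep(und, length.out = max(length(und), 5L))
    copy <- stats::ave(seq_along(src), src, FUN = seq_along)
    Xs <- vapply(seq_along(src), function(j) {
      .groupPermute(X[, src[j]], groups, subSeed(seed, iter, src[j], copy[j]))
    }, numeric(nrow(X)))
    colnames(Xs) <- paste0(".shadow.", seq_along(src))

    fit <- .borutaForest(cbind(X[, c(und, conf), drop = FALSE], Xs), y,
                         rfParams, seed = subSeed(seed, iter, "forest"))
    imp <- fit$variable.importance
    shadowImp <- imp[colnames(Xs)]
    realImp <- imp[und]
    sdS <- sd(shadowImp)
    if (!is.finite(sdS) || sdS == 0) sdS <- 1e-12
    z <- (realImp - mean(shadowImp)) / sdS
    zSum[und] <- zSum[und] + z
    zN[und] <- zN[und] + 1L
    hits[und] <- hits[und] + (realImp > max(shadowImp))

    # normal (Z) approximation of the binomial hit count under p = 1/2
    zStat <- (hits[und] - iter / 2) / sqrt(iter / 4)
    confirm <- pnorm(zStat, lower.tail = FALSE) <= alpha
    reject <- pnorm(zStat) <= alpha
    decision[und][confirm] <- "Confirmed"
    decision[und][reject & !confirm] <- "Rejected"
  }

  new("BorutaRun",
      decision = factor(decision, levels = c("Confirmed", "Rejected",
                                             "Tentative"))[inputOrder],
      importance = ifelse(zN > 0, zSum / pmax(zN, 1L), NA_real_)[inputOrder],
      iterations = iter)
}

#' Run the Boruta feature-selection algorithm once
#'
#' Iteratively compares each feature's permutation importance in a random
#' forest against "shadow" features (independently permuted copies of the
#' undecided columns). At each iteration a feature scores a hit when its
#' importance exceeds the maximal shadow importance; features whose hit
#' count is significantly above chance (one-sided Z approximation of the
#' binomial at \code{alpha}) are Confirmed, significantly below are
#' Rejected and dropped from subsequent iterations. Features undecided at
#' \code{maxIter} remain Tentative. The reported importance is the mean
#' Z-score of a feature's importance against the shadow-importance
#' distribution.
#'
#' @param x a [FeatureMatrix-class], or a numeric matrix (then supply
#'   \code{label})
#' @param label numeric training label (matrix method only)
#' @param alpha decision significance level (default 0.01)
#' @param maxIter maximum Boruta iterations (default 100)
#' @param rfParams list of forest settings: \code{nTrees} (401),
#'   \code{minNodeSize} (5), \code{sampleFraction} (0.632)
#' @param seed integer seed
#' @param groups optional source-sample identifier per row. On data that
#'   contains bootstrap duplicates, shadows are permuted across distinct
#'   source samples so duplicated rows keep identical shadow values; this
#'   keeps null features and shadows exchangeable under resampling.
#' @param ... passed through
#' @return a [BorutaRun-class]
#' @examples
#' x <- matrix(rnorm(600), 100, 6, dimnames = list(NULL, paste0("f", 1:6)))
#' y <- assignTrainingLabel(rep(c("NEC", "Gs8plus"), each = 50))
#' x[, 1] <- y  # an exact copy of the label
#' decisions(borutaOnce(x, label = y, rfParams = list(nTrees = 100), seed = 1))
#' @export
setGeneric("borutaOnce", function(x, ...) standardGeneric("borutaOnce"))

#' @rdname borutaOnce
#' @export
setMethod("borutaOnce", "FeatureMatrix", function(x, alpha = 0.01,
    maxIter = 100, rfParams = list(), seed = 1L, groups = NULL, ...) {
  .borutaEngine(x@values, x@label, alpha, maxIter, rfParams, seed, groups)
})

#' @rdname borutaOnce
#' @export
setMethod("borutaOnce", "matrix", function(x, label, alpha = 0.01,
    maxIter = 100, rfParams = list(), seed = 1L, groups = NULL, ...) {
  .borutaEngine(x, label, alpha, maxIter, rfParams, seed, groups)
})

# Bootstrap resample schedule shared across model variants: depends only on
# the sample count and the seed, never on the feature columns.
.resampleSchedule <- function(n, B, seed) {
  withSeed(subSeed(seed, "resamples"),
           matrix(sample.int(n, n * B, replace = TRUE), nrow = B))
}

#' Bootstrap-resampled Boruta stability selection
#'
#' Runs [borutaOnce()] on \code{B} bootstrap resamples (with replacement,
#' size n) of the cohort and records, per feature, the proportion of
#' resamples in which it was Confirmed. Features Confirmed in at least
#' \code{threshold} of resamples form the retained set. The resample index
#' schedule is derived only from \code{seed} and the sample count, so every
#' model variable set sees identical resamples under the same seed.
#'
#' @param x a [FeatureMatrix-class]
#' @param B number of bootstrap resamples (1000 in the reference analysis;
#'   scale down for exploratory runs)
#' @param threshold retention fraction, inclusive (default 0.9)
#' @param alpha,maxIter,rfParams,seed passed to [borutaOnce()]; each
#'   resample b runs with seed \code{xor(seed, b)}
#' @return a [StabilityReport-class]
#' @seealso [importanceTrajectory()]
#' @export
stabilitySelect <- function(x, B = 1000, threshold = 0.9, alpha = 0.01,
                            maxIter = 100, rfParams = list(), seed = 1L) {
  stopifnot(is(x, "FeatureMatrix"), B >= 1, threshold > 0, threshold <= 1)
  n <- nrow(x@values)
  feats <- colnames(x@values)
  idx <- .resampleSchedule(n, B, seed)
  conf <- matrix(0, B, length(feats), dimnames = list(NULL, feats))
  impM <- matrix(NA_real_, B, length(feats), dimnames = list(NULL, feats))
  for (b in seq_len(B)) {
    run <- .borutaEngine(x@values[idx[b, ], , drop = FALSE],
                         x@label[idx[b, ]], alpha, maxIter, rfParams,
                         seed = xorSeed(seed, b), groups = idx[b, ])
    conf[b, ] <- as.character(run@decision) == "Confirmed"
    impM[b, ] <- run@importance
  }
  pf <- colMeans(conf)
  new("StabilityReport", selectionProportion = pf, importance = impM,
      retained = feats[pf >= threshold], B = as.integer(B),
      threshold = threshold, seed = as.integer(seed))
}

#' Per-feature selection summary table
#'
#' Summarises a [StabilityReport-class] as one row per feature: selection
#' proportion and the median/IQR of its normalised importance across
#' resamples, sorted by selection proportion then median importance.
#' Features rejected in every resample (selection proportion 0) are
#' omitted.
#'
#' @param report a [StabilityReport-class]
#' @return data.frame with columns \code{feature},
#'   \code{selection_proportion}, \code{importance_median},
#'   \code{importance_q25}, \code{importance_q75}
#' @export
importanceTrajectory <- function(report) {
  stopifnot(is(report, "StabilityReport"))
  pf <- report@selectionProportion
  keep <- names(pf)[pf > 0]
  if (!length(keep)) {
    return(data.frame(feature = character(), selection_proportion = numeric(),
                      importance_median = numeric(), importance_q25 = numeric(),
                      importance_q75 = numeric(), stringsAsFactors = FALSE))
  }
  qs <- apply(report@importance[, keep, drop = FALSE], 2, function(v)
    quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE))
  out <- data.frame(feature = keep, selection_proportion = pf[keep],
                    importance_median = qs[2, ], importance_q25 = qs[1, ],
                    importance_q75 = qs[3, ], stringsAsFactors = FALSE,
                    row.names = NULL)
  out[order(-out$selection_proportion, -out$importance_median), , drop = FALSE]
}
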