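#' @include AllClasses.R
NULL

#' Net benefit of a biopsy strategy
#'
#' \code{NB = tp/n - (fp/n) * p_t / (1 - p_t)}: the true-positive rate
#' minus the false-positive rate weighted by the odds of the decision
#' threshold \code{p_t}, the disease probability at which patient and
#' clinician are indifferent between biopsy and no biopsy.
#'
#' @param tp,fp true and false positive counts
#' @param n total patients
#' @param pt decision threshold in (0, 1)
#' @return net benefit (vectorised over \code{pt})
#' @examples
#' netBenefit(25, 15, 100, 0.2)  # 0.2125
#' @export
netBenefit <- function(tp, fp, n, pt) {
  if (any(pt <= 0 | pt >= 1)) stop("decision threshold must be in (0, 1)")
  if (any(tp + fp > n)) stop("tp + fp cannot exceed n")
  tp / n - (fp / n) * pt / (1 - pt)
}

#' Standardised net benefit
#'
#' Net benefit divided by disease prevalence, so a perfect classifier
#' scores 1 and "treat none" scores 0 at every threshold.
#'
#' @param nb net benefit
#' @param prevalence disease prevalence (> 0)
#' @return standardised net benefit
#' @export
standardisedNetBenefit <- function(nb, prevalence) {
  if (any(prevalence <= 0)) stop("prevalence must be > 0")
  nb / prevalence
}

#' Prevalence-matching resampling scheme
#'
#' Target outcome mix used to reweight a development cohort to a general
#' biopsied population: the control-arm distribution of a large PSA-testing
#' trial, 60.6% no evidence of cancer, 23.6% Gleason 6, 8.7% Gleason 7 and
#' 7.1% Gleason >= 8, drawn as resamples of 197 patients.
#'
#' @param proportions named numeric summing to 1: \code{noCancer},
#'   \code{gs6}, \code{gs7}, \code{gs8}
#' @param n resample size (default 197)
#' @param nResamples number of resamples (default 1000)
#' @return list scheme
#' @export
prevalenceScheme <- function(proportions = c(noCancer = 0.606, gs6 = 0.236,
                                             gs7 = 0.087, gs8 = 0.071),
                             n = 197L, nResamples = 1000L) {
  stopifnot(abs(sum(proportions) - 1) < 1e-9, n >= 1)
  stopifnot(identical(sort(names(proportions)),
                      sort(c("noCancer", "gs6", "gs7", "gs8"))))
  list(proportions = proportions, n = as.integer(n),
       nResamples = as.integer(nResamples))
}

# largest-remainder rounding of share * n to integers totalling exactly n
.largestRemainder <- function(shares, n) {
  raw <- shares * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

.capStrata <- function(outcome) {
  outcome <- as.character(outcome)
  list(noCancer = which(outcome %in% c("NEC", "BiopsyNegative")),
       gs6 = which(outcome == "Gs6"),
       gs7 = which(outcome %in% c("Gs3+4", "Gs4+3")),
       gs8 = which(outcome == "Gs8plus"))
}

#' Stratified resampling to a target outcome prevalence
#'
#' Draws \code{nResamples} index vectors of exactly \code{n} samples from
#' the cohort, stratified so each resample matches the target outcome mix
#' (largest-remainder rounding of \code{share * n}). The Gleason 7 stratum
#' pools Gleason 3+4 and 4+3 patients and draws uniformly from the pool,
#' preserving their cohort ratio in expectation. Fully reproducible from
#' the seed.
#'
#' @param outcome character or factor of [OUTCOME_LEVELS]
#' @param scheme a [prevalenceScheme()]
#' @param seed integer seed
#' @return integer matrix, \code{nResamples} x \code{n}, of sample indices
#' @export
capResample <- function(outcome, scheme = prevalenceScheme(), seed = 1L) {
  strata <- .capStrata(outcome)
  counts <- .largestRemainder(scheme$proportions[names(strata)], scheme$n)
  empty <- names(strata)[counts > 0 & vapply(strata, length, 1L) == 0L]
  if (length(empty)) stop("empty stratum in source cohort: ",
                          paste(empty, collapse = ", "))
  withSeed(subSeed(seed, "cap"), {
    t(vapply(seq_len(scheme$nResamples), function(b) {
      unlist(lapply(seq_along(strata), function(s) {
        sample(strata[[s]], counts[s], replace = TRUE)
      }), use.names = FALSE)
    }, integer(scheme$n)))
  })
}

#' Prevalence-adjusted decision curves
#'
#' For each prevalence-matched resample, classifies positive at each
#' decision threshold (score >= threshold), computes the (standardised)
#' net benefit of every model strategy plus the treat-all and treat-none
#' references, and averages across resamples.
#'
#' @param scores named list of per-sample risk score vectors (one per model
#'   strategy), aligned with \code{outcome}
#' @param outcome character or factor of [OUTCOME_LEVELS]
#' @param endpoint binary endpoint, see [binaryEndpoint()]
#' @param scheme a [prevalenceScheme()]; use \code{NULL} to evaluate the
#'   cohort as-is (a single "resample" of all samples)
#' @param thresholds decision-threshold grid (default 0.01 to 0.50 by 0.01)
#' @param seed integer seed for the resampler
#' @return a [DecisionCurve-class]
#' @export
dcaCurves <- function(scores, outcome, endpoint = "Gs>=3+4",
                      scheme = prevalenceScheme(),
                      thresholds = seq(0.01, 0.5, by = 0.01), seed = 1L) {
  stopifnot(is.list(scores), length(names(scores)) == length(scores))
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie in (0, 1)")
  idx <- if (is.null(scheme)) {
    matrix(seq_along(outcome), nrow = 1)
  } else {
    capResample(outcome, scheme, seed)
  }
  strategies <- c(names(scores), "treat-all", "treat-none")
  nbAcc <- matrix(0, length(thresholds), length(strategies),
                  dimnames = list(NULL, strategies))
  snbAcc <- nbAcc
  prevAcc <- 0
  for (b in seq_len(nrow(idx))) {
    i <- idx[b, ]
    lab <- binaryEndpoint(outcome[i], endpoint)
    n <- length(i); prev <- mean(lab)
    prevAcc <- prevAcc + prev
    for (v in names(scores)) {
      sc <- scores[[v]][i]
      posAt <- outer(sc, thresholds, `>=`)
      tp <- colSums(posAt & lab); fp <- colSums(posAt & !lab)
      nb <- netBenefit(tp, fp, n, thresholds)
      nbAcc[, v] <- nbAcc[, v] + nb
      snbAcc[, v] <- snbAcc[, v] + standardisedNetBenefit(nb, prev)
    }
    nbAll <- netBenefit(sum(lab), sum(!lab), n, thresholds)
    nbAcc[, "treat-all"] <- nbAcc[, "treat-all"] + nbAll
    snbAcc[, "treat-all"] <- snbAcc[, "treat-all"] +
      standardisedNetBenefit(nbAll, prev)
  }
  B <- nrow(idx)
  curve <- data.frame(
    threshold = rep(thresholds, length(strategies)),
    strategy = rep(strategies, each = length(thresholds)),
    nb = as.vector(nbAcc / B), snb = as.vector(snbAcc / B),
    stringsAsFactors = FALSE)
  new("DecisionCurve", curve = curve, endpoint = endpoint,
      prevalence = prevAcc / B,
      scheme = if (is.null(scheme)) list() else scheme)
}

#' Net reduction in biopsies per 100 patients
#'
#' Converts a net-benefit advantage over a reference strategy into avoided
#' biopsies: \code{(nbModel - nbReference) * (1 - pt) / pt}, expressed per
#' 100 patients. The reference is typically the treat-all strategy (biopsy
#' every patient with PSA >= 4 ng/mL) or the standard-of-care model.
#'
#' @param nbModel,nbReference net benefits at threshold \code{pt}
#' @param pt decision threshold in (0, 1)
#' @return biopsies avoided per 100 patients (vectorised)
#' @examples
#' nbM <- netBenefit(25, 15, 100, 0.2)
#' nbAll <- netBenefit(30, 70, 100, 0.2)
#' biopsyNetReduction(nbM, nbAll, 0.2)
#' @export
biopsyNetReduction <- function(nbModel, nbReference, pt) {
  if (any(pt <= 0 | pt >= 1)) stop("decision threshold must be in (0, 1)")
  (nbModel - nbReference) * (1 - pt) / pt * 100
}

#' Biopsy-reduction curves from a decision curve
#'
#' Tabulates [biopsyNetReduction()] for every model strategy of a
#' [DecisionCurve-class] against a chosen reference strategy across the
#' threshold grid.
#'
#' @param dc a [DecisionCurve-class]
#' @param reference reference strategy name (default \code{"treat-all"};
#'   the standard-of-care model name is the other common choice)
#' @return data.frame with \code{threshold}, \code{strategy},
#'   \code{reduction_per_100}
#' @export
reductionCurves <- function(dc, reference = "treat-all") {
  stopifnot(is(dc, "DecisionCurve"))
  cv <- dc@curve
  if (!reference %in% cv$strategy) stop("unknown reference strategy")
  ref <- cv[cv$strategy == reference, ]
  out <- lapply(setdiff(unique(cv$strategy), c(reference, "treat-none")),
    function(v) {
      m <- cv[cv$strategy == v, ]
      data.frame(threshold = m$threshold, strategy = v,
                 reduction_per_100 = biopsyNetReduction(
                   m$nb, ref$nb[match(m$threshold, ref$threshold)],
                   m$threshold),
                 stringsAsFactors = FALSE)
    })
  do.call(rbind, out)
}
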