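#' @include AllClasses.R
NULL

#' Binary biopsy endpoints
#'
#' Dichotomises the categorical biopsy outcome at the three clinically
#' relevant thresholds: \code{"any-cancer"} (any positive biopsy),
#' \code{"Gs>=3+4"} (Gleason 3+4 or higher, i.e. excluding Gleason 6) and
#' \code{"Gs>=4+3"} (Gleason 4+3 or higher). Unbiopsied NEC and
#' biopsy-negative patients are negative under every endpoint.
#'
#' @param outcome character or factor of [OUTCOME_LEVELS]
#' @param endpoint one of \code{"any-cancer"}, \code{"Gs>=3+4"},
#'   \code{"Gs>=4+3"}
#' @return logical vector
#' @examples
#' binaryEndpoint(c("Gs6", "Gs3+4", "BiopsyNegative"), "Gs>=3+4")
#' @export
binaryEndpoint <- function(outcome, endpoint = c("any-cancer", "Gs>=3+4",
                                                 "Gs>=4+3")) {
  endpoint <- match.arg(endpoint)
  outcome <- as.character(outcome)
  bad <- setdiff(unique(outcome), OUTCOME_LEVELS)
  if (length(bad)) stop("unknown outcome: ", paste(bad, collapse = ", "))
  pos <- switch(endpoint,
                "any-cancer" = c("Gs6", "Gs3+4", "Gs4+3", "Gs8plus"),
                "Gs>=3+4" = c("Gs3+4", "Gs4+3", "Gs8plus"),
                "Gs>=4+3" = c("Gs4+3", "Gs8plus"))
  outcome %in% pos
}

#' Area under the ROC curve
#'
#' Mann-Whitney concordance probability: the fraction of
#' positive/negative score pairs in which the positive scores higher, ties
#' counted one half. Computed from midranks.
#'
#' @param scores numeric risk scores
#' @param labels logical (or 0/1) class labels
#' @return AUC in [0, 1]
#' @examples
#' auc(c(0.9, 0.7, 0.6, 0.8), c(TRUE, TRUE, FALSE, FALSE))  # 0.75
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' AUC with stratified bootstrap confidence interval
#'
#' Resamples positives and negatives separately with replacement and takes
#' percentile 2.5/97.5 bounds (inverse-ECDF quantiles) of the resampled
#' AUCs.
#'
#' @param scores,labels as in [auc()]
#' @param nResamples number of stratified bootstrap resamples (default 1000)
#' @param seed integer seed
#' @param endpoint optional endpoint tag stored in the result
#' @return data.frame with \code{auc}, \code{ci_lower}, \code{ci_upper},
#'   \code{n_resamples}, \code{stratified}, \code{endpoint}
#' @export
aucCI <- function(scores, labels, nResamples = 1000, seed = 1L,
                  endpoint = NA_character_) {
  stopifnot(nResamples >= 2)
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  pos <- scores[labels]; neg <- scores[!labels]
  est <- auc(scores, labels)
  boots <- withSeed(subSeed(seed, "aucci"), vapply(seq_len(nResamples),
    function(b) {
      p <- sample(pos, length(pos), replace = TRUE)
      n <- sample(neg, length(neg), replace = TRUE)
      auc(c(p, n), c(rep(TRUE, length(p)), rep(FALSE, length(n))))
    }, numeric(1)))
  ci <- quantile(boots, c(0.025, 0.975), type = 1, names = FALSE)
  data.frame(endpoint = endpoint, auc = est, ci_lower = ci[1],
             ci_upper = ci[2], n_resamples = nResamples, stratified = TRUE)
}

#' Paired bootstrap test for an AUC difference
#'
#' Compares two paired score vectors on identical samples: resamples the
#' samples (stratified by class so both classes persist), recomputes the
#' AUC difference per resample, and reports a two-sided p-value from the
#' normal approximation of the resampled difference distribution
#' (mean/SD).
#'
#' @param scoresA,scoresB paired risk scores on the same samples
#' @param labels logical class labels
#' @param nResamples bootstrap resamples (default 1000)
#' @param seed integer seed
#' @return list with \code{delta} (observed AUC difference A - B),
#'   \code{p_value}, \code{n_resamples}
#' @export
aucDifferenceTest <- function(scoresA, scoresB, labels, nResamples = 1000,
                              seed = 1L) {
  if (length(scoresA) != length(scoresB) ||
      length(scoresA) != length(labels))
    stop("inputs must be paired on identical samples")
  labels <- as.logical(labels)
  keep <- !is.na(scoresA) & !is.na(scoresB) & !is.na(labels)
  scoresA <- scoresA[keep]; scoresB <- scoresB[keep]; labels <- labels[keep]
  delta <- auc(scoresA, labels) - auc(scoresB, labels)
  iPos <- which(labels); iNeg <- which(!labels)
  ds <- withSeed(subSeed(seed, "aucdiff"), vapply(seq_len(nResamples),
    function(b) {
      i <- c(sample(iPos, length(iPos), replace = TRUE),
             sample(iNeg, length(iNeg), replace = TRUE))
      auc(scoresA[i], labels[i]) - auc(scoresB[i], labels[i])
    }, numeric(1)))
  s <- sd(ds)
  p <- if (!is.finite(s) || s == 0) {
    if (mean(ds) == 0) 1 else 0
  } else {
    2 * pnorm(-abs(mean(ds) / s))
  }
  list(delta = delta, p_value = p, n_resamples = nResamples)
}

#' Proportional-odds effect of a risk score
#'
#' Fits an ordinal logistic (proportional-odds) regression of the graded
#' biopsy outcome on the risk score and reports the odds ratio per 0.1
#' increase in risk, \code{exp(0.1 * beta)}, with a delta-method Wald
#' interval. Outcome grades: no cancer (NEC pooled with biopsy-negative),
#' Gleason 6, Gleason 3+4, Gleason >= 4+3.
#'
#' @param scores numeric risk scores
#' @param outcome character or factor of [OUTCOME_LEVELS]
#' @param per report the OR per this increment of risk (default 0.1)
#' @param level confidence level (default 0.95)
#' @return data.frame with \code{beta}, \code{se}, \code{or},
#'   \code{ci_lower}, \code{ci_upper}, \code{per}, \code{converged}
#' @export
proportionalOddsOR <- function(scores, outcome, per = 0.1, level = 0.95) {
  grade <- .ordinalGrade(outcome)
  if (nlevels(droplevels(grade)) < 3L)
    stop("need >= 3 ordered outcome levels present")
  fit <- tryCatch(
    MASS::polr(grade ~ scores, Hess = TRUE,
               data = data.frame(grade = grade, scores = scores)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(data.frame(beta = NA_real_, se = NA_real_, or = NA_real_,
                      ci_lower = NA_real_, ci_upper = NA_real_, per = per,
                      converged = FALSE))
  }
  beta <- unname(coef(fit)["scores"])
  se <- sqrt(diag(vcov(fit)))["scores"]
  z <- qnorm(1 - (1 - level) / 2)
  data.frame(beta = beta, se = unname(se), or = exp(per * beta),
             ci_lower = exp(per * (beta - z * se)),
             ci_upper = exp(per * (beta + z * se)),
             per = per, converged = fit$convergence == 0)
}

.ordinalGrade <- function(outcome) {
  outcome <- as.character(outcome)
  g <- ifelse(outcome %in% c("NEC", "BiopsyNegative"), "NoCancer",
       ifelse(outcome == "Gs6", "Gs6",
       ifelse(outcome == "Gs3+4", "Gs3+4", "Gs4+3plus")))
  factor(g, levels = c("NoCancer", "Gs6", "Gs3+4", "Gs4+3plus"),
         ordered = TRUE)
}

#' BCa bootstrap interval for a mean difference
#'
#' Estimates the mean difference between a group and a reference group
#' with a bias-corrected and accelerated (BCa) bootstrap interval: both
#' groups are resampled independently, the bias correction z0 comes from
#' the position of the observed difference in the resample distribution,
#' and the acceleration from the jackknife skewness over all observations.
#' With a degenerate resample distribution the interval collapses to the
#' point estimate; with a group of size 1 the acceleration is undefined
#' and a percentile interval is returned with a warning.
#'
#' @param group,reference numeric value vectors
#' @param nResamples bootstrap resamples (default 1000)
#' @param seed integer seed
#' @param level confidence level (default 0.95)
#' @return data.frame with \code{delta}, \code{ci_lower}, \code{ci_upper},
#'   \code{n_resamples}, \code{method}
#' @export
meanDiffBCa <- function(group, reference, nResamples = 1000, seed = 1L,
                        level = 0.95) {
  stopifnot(length(group) >= 1, length(reference) >= 1)
  n1 <- length(group); n2 <- length(reference)
  delta <- mean(group) - mean(reference)
  boots <- withSeed(subSeed(seed, "bca"), {
    g <- matrix(sample(group, n1 * nResamples, replace = TRUE), nrow = nResamples)
    r <- matrix(sample(reference, n2 * nResamples, replace = TRUE), nrow = nResamples)
    rowMeans(g) - rowMeans(r)
  })
  alpha <- c((1 - level) / 2, 1 - (1 - level) / 2)
  if (sd(boots) == 0) {
    return(data.frame(delta = delta, ci_lower = boots[1], ci_upper = boots[1],
                      n_resamples = nResamples, method = "degenerate"))
  }
  if (n1 < 2 || n2 < 2) {
    warning("group of size 1: acceleration undefined, percentile interval")
    ci <- quantile(boots, alpha, type = 1, names = FALSE)
    return(data.frame(delta = delta, ci_lower = ci[1], ci_upper = ci[2],
                      n_resamples = nResamples, method = "percentile"))
  }
  z0 <- qnorm(mean(boots < delta) + 0.5 * mean(boots == delta))
  # jackknife over all observations of both groups
  jack <- c(vapply(seq_len(n1), function(i) mean(group[-i]) - mean(reference),
                   numeric(1)),
            vapply(seq_len(n2), function(i) mean(group) - mean(reference[-i]),
                   numeric(1)))
  d <- mean(jack) - jack
  accel <- sum(d^3) / (6 * sum(d^2)^1.5)
  if (!is.finite(z0) || !is.finite(accel)) {
    ci <- quantile(boots, alpha, type = 1, names = FALSE)
    return(data.frame(delta = delta, ci_lower = ci[1], ci_upper = ci[2],
                      n_resamples = nResamples, method = "percentile"))
  }
  zA <- qnorm(alpha)
  adj <- pnorm(z0 + (z0 + zA) / (1 - accel * (z0 + zA)))
  ci <- quantile(boots, adj, type = 1, names = FALSE)
  data.frame(delta = delta, ci_lower = ci[1], ci_upper = ci[2],
             n_resamples = nResamples, method = "bca")
}

#' Threshold achieving a target sensitivity, with spillover
#'
#' Finds the risk threshold (classify positive when score >= threshold)
#' that still classifies at least \code{targetSens} of the positives
#' correctly -- the highest such threshold, i.e. the k-th largest positive
#' score with \code{k = ceiling(targetSens * nPos)} -- and reports the
#' spillover: the fraction of negatives at or above it.
#'
#' @param scores numeric risk scores
#' @param labels logical class labels
#' @param targetSens target sensitivity in (0, 1]
#' @return list with \code{threshold}, \code{sensitivity}, \code{spillover}
#' @export
thresholdForSensitivity <- function(scores, labels, targetSens) {
  stopifnot(targetSens > 0, targetSens <= 1)
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  if (!length(pos) || !length(neg))
    stop("both classes must be present")
  k <- ceiling(targetSens * length(pos))
  thr <- sort(pos, decreasing = TRUE)[k]
  list(threshold = thr, sensitivity = mean(pos >= thr),
       spillover = mean(neg >= thr))
}
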