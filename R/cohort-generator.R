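#' @include AllClasses.R
NULL

# default per-class PSA families (ng/mL, log-normal), moment-matched to the
# published cohort summary: no-cancer group median 6.10 (IQR 3.70-8.80) once
# unbiopsied NEC (all PSA < 4) and biopsy-negative patients are pooled;
# cancer group median 10.35 (IQR 6.82-16.48) split with a mild monotone
# grade trend. sdlog from IQR ratio: log(q75/q25)/1.349. Non-metastatic PSA
# truncated below 100 ng/mL (higher values are a metastasis exclusion).
.defaultPsaParams <- function() {
  data.frame(
    row.names = OUTCOME_LEVELS,
    meanlog = log(c(2.4, 7.0, 8.5, 10.5, 12.0, 14.0)),
    sdlog   = c(0.45, 0.55, 0.64, 0.64, 0.64, 0.64),
    lo      = c(0.3, 1.0, 4.0, 4.0, 4.0, 4.0),
    hi      = c(3.99, 99, 99, 99, 99, 99)
  )
}

# EN2 ELISA (arbitrary ng/L-scale units): right-skewed, monotone increasing
# with grade; magnitudes chosen to give the single-marker model moderate
# discrimination, as reported for urinary EN2.
.defaultEn2Params <- function() {
  data.frame(
    row.names = OUTCOME_LEVELS,
    meanlog = c(3.0, 3.1, 3.5, 3.8, 4.0, 4.2),
    sdlog   = rep(0.8, 6)
  )
}

.defaultDreProbs <- function() {
  matrix(c(0.17, 0.44, 0.27, 0.12,
           0.10, 0.49, 0.29, 0.12),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("noCancer", "cancer"),
                         c("Small", "Medium", "Large", "Unknown")))
}

#' Planted log2 shift matrix for informative probes
#'
#' Builds the (probes x outcome classes) matrix of log2 mean shifts used to
#' plant signal in the synthetic cf-RNA counts. The default profile is
#' monotone in Gleason grade, scaled so the highest class carries
#' \code{delta} log2 units.
#'
#' @param probes probe names (default: an 11-gene panel mirroring the scale
#'   of published urinary cf-RNA signatures) or an integer count.
#' @param delta log2 shift of the most aggressive class.
#' @param profile length-6 per-class multiplier of \code{delta}, ordered as
#'   [OUTCOME_LEVELS].
#' @return numeric matrix with \code{colnames = OUTCOME_LEVELS}.
#' @export
plantedShifts <- function(probes = NULL, delta = 2,
                          profile = c(0, 0, 0.5, 0.75, 0.9, 1)) {
  if (is.null(probes)) {
    probes <- c("ERG_exons4_5", "ERG_exons6_7", "GJB1", "HOXC6", "HPN",
                "NKAIN1", "PCA3", "PPFIA2", "RPLP2", "TMEM45B",
                "TMPRSS2_ERG")
  }
  if (is.numeric(probes) && length(probes) == 1L) {
    probes <- sprintf("INF%02d", seq_len(probes))
  }
  stopifnot(length(profile) == 6L, all(is.finite(profile)), is.finite(delta))
  m <- outer(rep(delta, length(probes)), profile)
  dimnames(m) <- list(probes, OUTCOME_LEVELS)
  m
}

#' Configure the synthetic cohort generator
#'
#' Returns a validated [CohortDesign-class]. Defaults emulate the structure
#' of a 207-patient single-site post-DRE urine cohort: the published class
#' counts (25 unbiopsied NEC, 52 biopsy-negative, 30 Gleason 6, 48 Gleason
#' 3+4, 24 Gleason 4+3, 28 Gleason >= 8), log-normal PSA and EN2
#' moment-matched to the cohort's median/IQR, 167 cf-RNA probes with an
#' 11-probe planted panel, six positive-control probes, and a per-sample
#' technical lane factor.
#'
#' @param nPerClass named integer counts; names [OUTCOME_LEVELS] plus
#'   \code{metastatic} (extra bone-scan-positive / PSA > 100 patients used
#'   to exercise exclusion rules; default 0).
#' @param ageParams list with elements \code{noCancer} and \code{cancer},
#'   each \code{c(mean, sd)} in years.
#' @param psaParams,en2Params per-class data.frames (see defaults).
#' @param nProbes number of cf-RNA probes.
#' @param informativeProbes shift matrix from [plantedShifts()].
#' @param baselineLog2Range range the per-probe baseline log2 expected
#'   counts are drawn from.
#' @param countDispersion negative-binomial size for probe counts.
#' @param posControlLevels expected counts of positive-control probes.
#' @param laneSdLog log-scale sd of the per-sample lane factor.
#' @param dreProbs DRE size probabilities (rows noCancer/cancer).
#' @param urineVolParams c(meanlog, sdlog) for urine volume (mL).
#' @param seed integer; fully determines the cohort.
#' @return a [CohortDesign-class]
#' @examples
#' design <- cohortDesign(seed = 1)
#' design
#' @export
cohortDesign <- function(nPerClass = c(NEC = 25L, BiopsyNegative = 52L,
                                       Gs6 = 30L, `Gs3+4` = 48L,
                                       `Gs4+3` = 24L, Gs8plus = 28L,
                                       metastatic = 0L),
                         ageParams = list(noCancer = c(65.2, 8.1),
                                          cancer = c(69.7, 7.7)),
                         psaParams = .defaultPsaParams(),
                         en2Params = .defaultEn2Params(),
                         nProbes = 167L,
                         informativeProbes = plantedShifts(),
                         baselineLog2Range = c(4, 9),
                         countDispersion = 2,
                         posControlLevels = c(16384, 4096, 1024, 256, 64, 16),
                         laneSdLog = 0.3,
                         dreProbs = .defaultDreProbs(),
                         urineVolParams = c(log(25), 0.4),
                         seed = 1L) {
  full <- setNames(integer(7), c(OUTCOME_LEVELS, "metastatic"))
  nPerClass <- unlist(nPerClass)
  if (is.null(names(nPerClass)) || !all(names(nPerClass) %in% names(full)))
    stop("nPerClass must be named by outcome class (plus optional 'metastatic')")
  full[names(nPerClass)] <- as.integer(nPerClass)
  if (any(is.na(full)) || any(full < 0L)) stop("class counts must be non-negative")
  ok <- vapply(list(psaParams$meanlog, psaParams$sdlog, en2Params$meanlog,
                    en2Params$sdlog, baselineLog2Range, countDispersion,
                    laneSdLog, urineVolParams), function(v) all(is.finite(v)),
               logical(1))
  if (!all(ok)) stop("non-finite generator parameters")
  new("CohortDesign",
      nPerClass = full, ageParams = ageParams, psaParams = psaParams,
      en2Params = en2Params, nProbes = as.integer(nProbes),
      informativeProbes = informativeProbes,
      baselineLog2Range = baselineLog2Range,
      countDispersion = countDispersion,
      posControlLevels = posControlLevels, laneSdLog = laneSdLog,
      dreProbs = dreProbs, urineVolParams = urineVolParams,
      seed = as.integer(seed))
}

# truncated log-normal draws via the probability-integral transform, so the
# draw count per sample is fixed and seeds map 1:1 onto samples
.rlnormTrunc <- function(n, meanlog, sdlog, lo, hi) {
  u <- runif(n, plnorm(lo, meanlog, sdlog), plnorm(hi, meanlog, sdlog))
  qlnorm(u, meanlog, sdlog)
}

#' Generate a synthetic urine cohort
#'
#' Draws a cohort under a [CohortDesign-class]: class counts are exact,
#' PSA/EN2/urine volume are class-wise log-normal, DRE size categorical, and
#' cf-RNA probe counts negative-binomial with planted log2 class shifts on
#' the informative probes. All counts (positive controls included) are
#' scaled by a per-sample technical lane factor, which positive-control
#' normalisation later removes. Metastatic extras are drawn as high-grade
#' patients with a positive bone scan and PSA above 100 ng/mL. The same
#' seed reproduces the cohort exactly.
#'
#' @param design a [CohortDesign-class]
#' @return a [UrineCohort-class]; the design and the ground-truth
#'   informative probe names are kept in \code{metadata()}.
#' @examples
#' cohort <- generateCohort(cohortDesign(seed = 42))
#' cohort
#' @export
generateCohort <- function(design) {
  stopifnot(is(design, "CohortDesign"))
  validObject(design)
  withSeed(design@seed, .generateCohortImpl(design))
}

.generateCohortImpl <- function(design) {
  nInf <- nrow(design@informativeProbes)
  infNames <- paste0("probe_", rownames(design@informativeProbes))
  nNoise <- design@nProbes - nInf
  probeNames <- c(infNames,
                  if (nNoise > 0) sprintf("probe_G%03d", seq_len(nNoise)))
  posNames <- sprintf("posctl_P%02d", seq_along(design@posControlLevels))

  baseLog2 <- runif(design@nProbes, design@baselineLog2Range[1],
                    design@baselineLog2Range[2])
  names(baseLog2) <- probeNames

  shift <- matrix(0, design@nProbes, 6,
                  dimnames = list(probeNames, OUTCOME_LEVELS))
  if (nInf > 0) shift[infNames, ] <- design@informativeProbes

  classes <- c(OUTCOME_LEVELS, "metastatic")
  nTot <- sum(design@nPerClass)
  cls <- rep(classes, design@nPerClass)
  outcome <- ifelse(cls == "metastatic", "Gs8plus", cls)
  isCancer <- outcome %in% c("Gs6", "Gs3+4", "Gs4+3", "Gs8plus")

  age <- numeric(nTot); psa <- numeric(nTot); en2 <- numeric(nTot)
  for (k in classes) {
    i <- which(cls == k)
    if (!length(i)) next
    out <- if (k == "metastatic") "Gs8plus" else k
    ap <- if (out %in% c("NEC", "BiopsyNegative")) design@ageParams$noCancer
          else design@ageParams$cancer
    age[i] <- pmin(pmax(rnorm(length(i), ap[1], ap[2]), 40), 95)
    if (k == "metastatic") {
      psa[i] <- .rlnormTrunc(length(i), log(180), 0.5, 101, 2000)
    } else {
      pp <- design@psaParams[out, ]
      psa[i] <- .rlnormTrunc(length(i), pp$meanlog, pp$sdlog, pp$lo, pp$hi)
    }
    ep <- design@en2Params[out, ]
    en2[i] <- rlnorm(length(i), ep$meanlog, ep$sdlog)
  }

  dre <- character(nTot)
  for (st in c("noCancer", "cancer")) {
    i <- which(if (st == "cancer") isCancer else !isCancer)
    if (!length(i)) next
    dre[i] <- sample(colnames(design@dreProbs), length(i), replace = TRUE,
                     prob = design@dreProbs[st, ])
  }
  urineVol <- rlnorm(nTot, design@urineVolParams[1], design@urineVolParams[2])
  lane <- rlnorm(nTot, 0, design@laneSdLog)

  counts <- matrix(0L, design@nProbes + length(posNames), nTot,
                   dimnames = list(c(probeNames, posNames), NULL))
  if (nTot > 0) {
    mu <- 2^(baseLog2 + shift[, outcome, drop = FALSE])  # probes x samples
    mu <- sweep(mu, 2, lane, `*`)
    counts[probeNames, ] <- rnbinom(length(mu), mu = mu,
                                    size = design@countDispersion)
    muP <- outer(design@posControlLevels, lane)
    counts[posNames, ] <- pmax(1L, rnbinom(length(muP), mu = muP, size = 50))
  }

  ids <- sprintf("S%03d", seq_len(nTot))
  colnames(counts) <- ids
  cd <- S4Vectors::DataFrame(
    age = age, psa = psa,
    dre_size = factor(dre, levels = colnames(design@dreProbs)),
    urine_volume = urineVol, en2 = en2,
    outcome = factor(outcome, levels = OUTCOME_LEVELS),
    metastatic = cls == "metastatic",
    recent_biopsy_weeks = rep(NA_real_, nTot),
    row.names = ids)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd,
    rowData = S4Vectors::DataFrame(
      is_pos_control = grepl("^posctl_", rownames(counts)),
      row.names = rownames(counts)),
    metadata = list(design = design, informativeProbes = infNames,
                    seed = design@seed))
  new("UrineCohort", se)
}
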