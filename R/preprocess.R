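#' @include AllClasses.R
NULL

#' Apply cohort exclusion criteria
#'
#' Excludes patients with a recent prostate biopsy or TURP (under 6 weeks
#' before sampling), or metastatic disease (positive bone scan, or serum
#' PSA above 100 ng/mL). Every exclusion is logged with its reasons.
#'
#' @param cohort a [UrineCohort-class]
#' @return list with \code{cohort} (retained samples) and \code{log}
#'   (data.frame of \code{sample_id}, \code{reason}; one row per excluded
#'   sample, reasons semicolon-joined).
#' @examples
#' x <- generateCohort(cohortDesign(nPerClass = c(NEC = 5L, Gs6 = 5L,
#'                                                metastatic = 2L), seed = 1))
#' applyExclusions(x)$log
#' @export
applyExclusions <- function(cohort) {
  stopifnot(is(cohort, "UrineCohort"))
  cd <- SummarizedExperiment::colData(cohort)
  if (any(!is.finite(cd$psa))) stop("missing or non-finite PSA")
  recent <- !is.na(cd$recent_biopsy_weeks) & cd$recent_biopsy_weeks < 6
  bone <- !is.na(cd$metastatic) & cd$metastatic
  highPsa <- cd$psa > 100
  drop <- recent | bone | highPsa
  reason <- vapply(seq_len(ncol(cohort)), function(i) {
    paste(c(if (recent[i]) "recent_biopsy_lt_6wk",
            if (bone[i]) "bone_scan_positive",
            if (highPsa[i]) "psa_gt_100"), collapse = ";")
  }, character(1))
  log <- data.frame(sample_id = colnames(cohort)[drop],
                    reason = reason[drop], stringsAsFactors = FALSE)
  list(cohort = cohort[, !drop], log = log)
}

#' Positive-control normalisation factors
#'
#' Per-sample geometric mean of the positive-control counts, the cohort
#' reference (geometric mean of those per-sample geometric means) and the
#' resulting scale factor \code{reference / sample geometric mean}.
#'
#' @param cohort a [UrineCohort-class]
#' @return data.frame with \code{sample_id}, \code{geo_mean},
#'   \code{reference}, \code{scale_factor}
#' @export
normalisationFactors <- function(cohort) {
  pos <- posControlCounts(cohort)
  if (nrow(pos) == 0L) stop("no positive-control (posctl_) rows")
  bad <- colnames(pos)[apply(pos <= 0, 2, any)]
  if (length(bad)) stop("non-positive positive-control count in sample(s): ",
                        paste(bad, collapse = ", "))
  g <- apply(pos, 2, geomMean)
  ref <- geomMean(g)
  data.frame(sample_id = colnames(pos), geo_mean = g, reference = ref,
             scale_factor = ref / g, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Normalise cf-RNA probe counts
#'
#' Scales each sample's probe counts by its positive-control scale factor
#' (geometric-mean scaling to the cohort reference) and applies
#' \code{log2(x + pseudocount)}. Scaling one sample's counts and controls
#' by a common factor leaves that sample's normalised values unchanged up
#' to the cohort reference, which shifts by \code{log2(c)/n}; supply a
#' fixed \code{reference} to remove even that dependence (e.g. when
#' normalising new samples against an established cohort).
#'
#' @param cohort a [UrineCohort-class]
#' @param pseudocount added before log2 (default 1; urinary cf-RNA counts
#'   contain zeros)
#' @param reference optional fixed cohort reference geometric mean; default
#'   is the geometric mean of the per-sample positive-control geometric
#'   means of \code{cohort}
#' @return samples x probes matrix of normalised log2 values
#' @export
normaliseCounts <- function(cohort, pseudocount = 1, reference = NULL) {
  probes <- probeCounts(cohort)
  if (ncol(probes) == 0L)
    return(matrix(numeric(0), 0, nrow(probes),
                  dimnames = list(NULL, rownames(probes))))
  nf <- normalisationFactors(cohort)
  sf <- if (is.null(reference)) nf$scale_factor else reference / nf$geo_mean
  scaled <- sweep(probes, 2, sf, `*`)
  t(log2(scaled + pseudocount))
}

#' Continuous training label from biopsy outcome
#'
#' Maps biopsy outcome onto the continuous training scale L used by the
#' regression forests: no evidence of cancer (unbiopsied NEC and
#' biopsy-negative) to 0, Gleason 6 and Gleason 3+4 to 0.5, and Gleason
#' 4+3 or higher to 1. The scale encodes that patients sharing a TRUS
#' Gleason score do not share identical tumour-pattern proportions; it is
#' used only for training, never as an evaluation endpoint.
#'
#' @param outcome character or factor of [OUTCOME_LEVELS]
#' @return numeric vector in {0, 0.5, 1}
#' @examples
#' assignTrainingLabel(c("NEC", "Gs3+4", "Gs8plus"))
#' @export
assignTrainingLabel <- function(outcome) {
  map <- c(NEC = 0, BiopsyNegative = 0, Gs6 = 0.5, `Gs3+4` = 0.5,
           `Gs4+3` = 1, Gs8plus = 1)
  outcome <- as.character(outcome)
  bad <- setdiff(unique(outcome), names(map))
  if (length(bad)) stop("unknown outcome category: ", paste(bad, collapse = ", "))
  unname(map[outcome])
}

# DRE prostate-size impression as a single ordered numeric code; "Unknown"
# kept as its own (lowest) level rather than imputed
.encodeDre <- function(dre) {
  codes <- c(Unknown = 0, Small = 1, Medium = 2, Large = 3)
  out <- codes[as.character(dre)]
  out[is.na(out)] <- 0
  unname(out)
}

#' Build the predictor matrix for a model variable set
#'
#' Assembles the samples x features numeric matrix for one comparator
#' variable set: \code{"SoC"} (age, serum PSA, DRE size code, urine
#' volume), \code{"Engrailed"} (EN2 ELISA only), \code{"ExoRNA"}
#' (normalised log2 cf-RNA probes only) or \code{"ExoGrail"} (all of the
#' above). The continuous training label and the categorical outcome are
#' attached for training and evaluation respectively.
#'
#' @param cohort a [UrineCohort-class]
#' @param variableSet one of [VARIANTS]
#' @param pseudocount passed to [normaliseCounts()]
#' @return a [FeatureMatrix-class]
#' @examples
#' fm <- buildFeatureMatrix(generateCohort(cohortDesign(seed = 1)), "ExoGrail")
#' dim(featureValues(fm))
#' @export
buildFeatureMatrix <- function(cohort, variableSet = VARIANTS,
                               pseudocount = 1) {
  variableSet <- match.arg(variableSet)
  stopifnot(is(cohort, "UrineCohort"))
  cd <- SummarizedExperiment::colData(cohort)
  n <- ncol(cohort)

  clin <- cbind(age = cd$age, psa = cd$psa,
                dre_size = .encodeDre(cd$dre_size),
                urine_volume = cd$urine_volume)
  en2 <- cbind(en2 = cd$en2)
  vals <- switch(variableSet,
    SoC = clin,
    Engrailed = en2,
    ExoRNA = if (n > 0) normaliseCounts(cohort, pseudocount) else
      matrix(numeric(0), 0, sum(grepl("^probe_", rownames(cohort)))),
    ExoGrail = {
      rna <- if (n > 0) normaliseCounts(cohort, pseudocount) else
        matrix(numeric(0), 0, sum(grepl("^probe_", rownames(cohort))))
      cbind(clin, en2, rna)
    })
  vals <- as.matrix(vals)
  rownames(vals) <- colnames(cohort)
  new("FeatureMatrix", values = vals,
      label = if (n > 0) assignTrainingLabel(cd$outcome) else numeric(0),
      outcome = factor(as.character(cd$outcome), levels = OUTCOME_LEVELS),
      variableSet = variableSet)
}
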