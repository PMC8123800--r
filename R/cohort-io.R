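#' @include AllClasses.R
NULL

#' Write a cohort to a delimited table
#'
#' Writes one row per sample (UTF-8 CSV with header): clinical columns,
#' outcome and flags, then raw probe counts (columns prefixed
#' \code{probe_}) and positive controls (prefixed \code{posctl_}). A JSON
#' sidecar (\code{<file>.json}) records the generator seed and the
#' ground-truth informative probe set when the cohort is synthetic.
#'
#' @param cohort a [UrineCohort-class]
#' @param file output CSV path
#' @param sidecar JSON sidecar path, or NA to skip
#' @return \code{file}, invisibly
#' @export
writeCohort <- function(cohort, file, sidecar = paste0(file, ".json")) {
  stopifnot(is(cohort, "UrineCohort"))
  if (ncol(cohort) == 0L) stop("refusing to write an empty cohort")
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  counts <- t(SummarizedExperiment::assay(cohort, "counts"))
  df <- cbind(sample_id = rownames(cd), cd, as.data.frame(counts))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  if (!is.na(sidecar)) {
    md <- S4Vectors::metadata(cohort)
    side <- list(seed = md$seed, informative_probes = md$informativeProbes,
                 n_samples = ncol(cohort),
                 n_probes = sum(grepl("^probe_", rownames(cohort))))
    if (!is.null(md$design)) {
      d <- md$design
      side$design <- list(n_per_class = as.list(d@nPerClass),
                          n_probes = d@nProbes,
                          count_dispersion = d@countDispersion,
                          lane_sdlog = d@laneSdLog)
    }
    jsonlite::write_json(side, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

#' Read a cohort table
#'
#' Reads a delimited cohort table written by [writeCohort()] (or any table
#' with the same schema) back into a [UrineCohort-class], validating the
#' clinical schema and probe columns.
#'
#' @param file CSV path
#' @param sidecar JSON sidecar path; read if it exists
#' @return a [UrineCohort-class]
#' @export
readCohort <- function(file, sidecar = paste0(file, ".json")) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "age", "psa", "dre_size", "urine_volume", "en2",
            "outcome", "metastatic", "recent_biopsy_weeks")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("cohort table missing columns: ",
                         paste(miss, collapse = ", "))
  probeCols <- grep("^(probe_|posctl_)", colnames(df), value = TRUE)
  if (!length(probeCols)) stop("cohort table has no probe_/posctl_ columns")
  counts <- t(as.matrix(df[, probeCols, drop = FALSE]))
  colnames(counts) <- df$sample_id
  cd <- S4Vectors::DataFrame(
    age = df$age, psa = df$psa,
    dre_size = factor(df$dre_size,
                      levels = c("Small", "Medium", "Large", "Unknown")),
    urine_volume = df$urine_volume, en2 = df$en2,
    outcome = factor(df$outcome, levels = OUTCOME_LEVELS),
    metastatic = as.logical(df$metastatic),
    recent_biopsy_weeks = as.numeric(df$recent_biopsy_weeks),
    row.names = df$sample_id)
  md <- list()
  if (!is.na(sidecar) && file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    md$seed <- side$seed
    md$informativeProbes <- side$informative_probes
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd,
    rowData = S4Vectors::DataFrame(
      is_pos_control = grepl("^posctl_", rownames(counts)),
      row.names = rownames(counts)),
    metadata = md)
  new("UrineCohort", se)
}

#' Write / read a feature matrix
#'
#' CSV round-trip for a [FeatureMatrix-class]: feature columns at full
#' precision plus \code{.label} and \code{.outcome} columns.
#'
#' @param x a [FeatureMatrix-class]
#' @param file CSV path
#' @return \code{file} (write) or a [FeatureMatrix-class] (read)
#' @export
writeFeatureMatrix <- function(x, file) {
  stopifnot(is(x, "FeatureMatrix"))
  df <- data.frame(sample_id = rownames(x@values), x@values,
                   .label = x@label, .outcome = as.character(x@outcome),
                   check.names = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE), file,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname writeFeatureMatrix
#' @param variableSet variable-set tag for the reconstructed object
#' @export
readFeatureMatrix <- function(file, variableSet = "custom") {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  featCols <- setdiff(colnames(df), c("sample_id", ".label", ".outcome"))
  vals <- as.matrix(df[, featCols, drop = FALSE])
  rownames(vals) <- df$sample_id
  new("FeatureMatrix", values = vals, label = as.numeric(df$.label),
      outcome = factor(df$.outcome, levels = OUTCOME_LEVELS),
      variableSet = variableSet)
}
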