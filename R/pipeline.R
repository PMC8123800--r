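#' @include AllClasses.R
NULL

#' Discrimination metrics for a set of risk-score vectors
#'
#' AUC with stratified bootstrap confidence intervals for every model
#' variant at every binary endpoint.
#'
#' @param scores named list of per-sample risk scores
#' @param outcome character or factor of [OUTCOME_LEVELS]
#' @param endpoints endpoints to evaluate
#' @param nResamples bootstrap resamples per interval
#' @param seed integer seed
#' @return data.frame, one row per variant x endpoint
#' @export
evaluateScores <- function(scores, outcome,
                           endpoints = c("any-cancer", "Gs>=3+4", "Gs>=4+3"),
                           nResamples = 1000, seed = 1L) {
  rows <- lapply(names(scores), function(v) {
    do.call(rbind, lapply(endpoints, function(ep) {
      lab <- binaryEndpoint(outcome, ep)
      cbind(variant = v,
            aucCI(scores[[v]], lab, nResamples,
                  seed = subSeed(seed, v, ep), endpoint = ep))
    }))
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' End-to-end analysis of a cohort: exclusion filtering, per-variant
#' stability selection and forest training with out-of-bag risk scoring,
#' discrimination metrics, the proportional-odds effect of the integrated
#' model, and prevalence-adjusted decision-curve analysis with biopsy
#' reduction curves. When \code{outputDir} is given, artefacts are written
#' there: \code{risk_scores.csv}, per-variant
#' \code{stability_<variant>.csv}, \code{metrics.json},
#' \code{dca_<endpoint>.csv}, \code{reduction_<endpoint>.csv} and a
#' \code{manifest.json} naming the seed and a hash of the configuration.
#'
#' @param cohort a [UrineCohort-class] or the path of a cohort CSV
#' @param outputDir directory for artefacts, or NULL to skip writing
#' @param variants variable sets to run, see [VARIANTS]
#' @param B stability-selection resamples
#' @param threshold stability retention threshold
#' @param nTrees trees per forest
#' @param nResamples bootstrap resamples for evaluation and DCA
#' @param scheme prevalence scheme for DCA, see [prevalenceScheme()]
#' @param endpoints endpoints for DCA curves
#' @param thresholds DCA decision-threshold grid
#' @param seed root seed; every stage derives its stream from it
#' @return list with \code{exclusions}, \code{variants} (per-variant
#'   stability/model/scores), \code{metrics}, \code{ordinal}, \code{dca},
#'   \code{reductions}, \code{manifest}
#' @export
runPipeline <- function(cohort, outputDir = NULL, variants = VARIANTS,
                        B = 1000, threshold = 0.9, nTrees = 401,
                        nResamples = 1000, scheme = prevalenceScheme(),
                        endpoints = c("any-cancer", "Gs>=3+4", "Gs>=4+3"),
                        thresholds = seq(0.01, 0.5, by = 0.01), seed) {
  if (missing(seed)) stop("an explicit seed is required")
  if (is.character(cohort)) cohort <- readCohort(cohort)
  stopifnot(is(cohort, "UrineCohort"))

  excl <- applyExclusions(cohort)
  fits <- runAllVariants(excl$cohort, variants = variants, B = B,
                         threshold = threshold, nTrees = nTrees, seed = seed)
  outc <- outcomes(excl$cohort)
  scores <- lapply(fits, function(f) f$scores@risk)

  metrics <- evaluateScores(scores, outc, endpoints = endpoints,
                            nResamples = nResamples,
                            seed = subSeed(seed, "metrics"))
  ordinal <- if ("ExoGrail" %in% names(scores) &&
                 nlevels(droplevels(.ordinalGrade(outc))) >= 3) {
    proportionalOddsOR(scores$ExoGrail, outc)
  }
  if (!is.null(scheme)) {
    scheme$nResamples <- as.integer(nResamples)
  }
  dca <- lapply(setNames(endpoints, endpoints), function(ep) {
    dcaCurves(scores, outc, endpoint = ep, scheme = scheme,
              thresholds = thresholds, seed = subSeed(seed, "dca", ep))
  })
  reductions <- lapply(dca, reductionCurves)

  cfg <- list(variants = variants, B = B, threshold = threshold,
              nTrees = nTrees, nResamples = nResamples,
              thresholds = range(thresholds), endpoints = endpoints,
              scheme = scheme)
  manifest <- list(seed = seed, config = cfg,
                   config_hash = .configHash(cfg),
                   n_samples = ncol(excl$cohort),
                   n_excluded = nrow(excl$log),
                   package_version = as.character(utils::packageVersion("urotriage")))

  result <- list(exclusions = excl$log, variants = fits, metrics = metrics,
                 ordinal = ordinal, dca = dca, reductions = reductions,
                 manifest = manifest)
  if (!is.null(outputDir)) .writeArtefacts(result, scores, outputDir)
  result
}

.configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.writeArtefacts <- function(result, scores, outputDir) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  sc <- do.call(rbind, lapply(result$variants, function(f)
    riskScores(f$scores)))
  utils::write.csv(sc, file.path(outputDir, "risk_scores.csv"),
                   row.names = FALSE)
  for (v in names(result$variants)) {
    utils::write.csv(importanceTrajectory(result$variants[[v]]$stability),
                     file.path(outputDir, paste0("stability_", v, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(metrics = result$metrics, ordinal = result$ordinal,
         exclusions = result$exclusions),
    file.path(outputDir, "metrics.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  for (ep in names(result$dca)) {
    tag <- gsub("[^A-Za-z0-9]+", "_", ep)
    utils::write.csv(curveTable(result$dca[[ep]]),
                     file.path(outputDir, paste0("dca_", tag, ".csv")),
                     row.names = FALSE)
    utils::write.csv(result$reductions[[ep]],
                     file.path(outputDir, paste0("reduction_", tag, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$manifest,
                       file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outputDir)
}
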