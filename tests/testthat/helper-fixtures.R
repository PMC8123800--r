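# Fixture builders shared across the suite. All data are generated in code.

# Small balanced design: quick to generate, strong planted signal by default.
smallDesign <- function(seed, nProbes = 12L, nInformative = 3L, delta = 2,
                        profile = c(0, 0, 0.5, 0.75, 0.9, 1),
                        nPerClass = c(NEC = 10L, BiopsyNegative = 10L,
                                      Gs6 = 10L, `Gs3+4` = 10L,
                                      `Gs4+3` = 10L, Gs8plus = 10L)) {
  cohortDesign(nPerClass = nPerClass, nProbes = nProbes,
               informativeProbes = plantedShifts(nInformative, delta = delta,
                                                 profile = profile),
               seed = seed)
}

# Build a UrineCohort directly from parts, for hand-crafted examples.
makeCohort <- function(counts, psa = NULL, outcome = NULL, en2 = NULL,
                       metastatic = NULL, recentBiopsyWeeks = NULL) {
  n <- ncol(counts)
  ids <- colnames(counts) %||% sprintf("S%03d", seq_len(n))
  colnames(counts) <- ids
  cd <- S4Vectors::DataFrame(
    age = rep(65, n),
    psa = psa %||% rep(8, n),
    dre_size = factor(rep("Medium", n),
                      levels = c("Small", "Medium", "Large", "Unknown")),
    urine_volume = rep(25, n),
    en2 = en2 %||% rep(30, n),
    outcome = factor(outcome %||% rep("BiopsyNegative", n),
                     levels = OUTCOME_LEVELS),
    metastatic = metastatic %||% rep(FALSE, n),
    recent_biopsy_weeks = recentBiopsyWeeks %||% rep(NA_real_, n),
    row.names = ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd,
    rowData = S4Vectors::DataFrame(
      is_pos_control = grepl("^posctl_", rownames(counts)),
      row.names = rownames(counts)))
  new("UrineCohort", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FeatureMatrix from a plain matrix + label (outcome inferred from label).
makeFM <- function(x, label, variableSet = "ExoRNA") {
  outcome <- c("NEC", "Gs6", "Gs8plus")[match(label, c(0, 0.5, 1))]
  if (is.null(rownames(x))) rownames(x) <- sprintf("S%03d", seq_len(nrow(x)))
  new("FeatureMatrix", values = x, label = label,
      outcome = factor(outcome, levels = OUTCOME_LEVELS),
      variableSet = variableSet)
}

# quick labelled score fixture for evaluation tests
twoClassScores <- function(n, d, seed) {
  withr::with_seed(seed, {
    list(scores = c(rnorm(n, d), rnorm(n, 0)),
         labels = rep(c(TRUE, FALSE), each = n))
  })
}
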