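test_that("binary endpoints follow the Gleason threshold definitions", {
  expect_false(binaryEndpoint("Gs6", "Gs>=3+4"))
  expect_true(binaryEndpoint("Gs6", "any-cancer"))
  expect_false(binaryEndpoint("BiopsyNegative", "any-cancer"))
  expect_false(binaryEndpoint("NEC", "Gs>=4+3"))
  expect_true(all(vapply(c("any-cancer", "Gs>=3+4", "Gs>=4+3"),
                         function(ep) binaryEndpoint("Gs8plus", ep),
                         logical(1))))
  expect_false(binaryEndpoint("Gs3+4", "Gs>=4+3"))
  expect_true(binaryEndpoint("Gs3+4", "Gs>=3+4"))
  expect_error(binaryEndpoint("Gs9", "any-cancer"), "unknown outcome")
})

test_that("AUC equals the concordance probability, ties counted half", {
  expect_equal(auc(c(0.9, 0.7, 0.6, 0.8), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(auc(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc(c(0.5, 0.5), c(TRUE, FALSE)), 0.5)  # all ties
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("midrank AUC matches exhaustive pair enumeration and pROC", {
  pairAUC <- function(s, y) {
    pos <- s[y]; neg <- s[!y]
    g <- outer(pos, neg, `>`); t <- outer(pos, neg, `==`)
    (sum(g) + 0.5 * sum(t)) / (length(pos) * length(neg))
  }
  for (case in 1:25) {
    set.seed(case)
    n <- sample(6:30, 1)
    s <- round(runif(n), 2)  # ties likely
    y <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    expect_equal(auc(s, y), pairAUC(s, y))
  }
  skip_if_not_installed("pROC")
  set.seed(99)
  s <- rnorm(80); y <- rep(c(TRUE, FALSE), 40)
  expect_equal(auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("AUC is invariant under monotone transforms and complements", {
  set.seed(3)
  s <- rnorm(60); y <- rep(c(TRUE, FALSE), 30)
  expect_equal(auc(exp(s), y), auc(s, y))
  expect_equal(auc(qnorm(pnorm(s)), y), auc(s, y))
  expect_equal(auc(s, y) + auc(-s, y), 1)  # tie-free scores
})

test_that("stratified bootstrap CI behaves at the edges", {
  # perfect separation: interval collapses at 1
  ci <- aucCI(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE), nResamples = 50,
              seed = 1)
  expect_equal(c(ci$auc, ci$ci_lower, ci$ci_upper), c(1, 1, 1))
  # two resamples: inverse-ECDF quantiles give their min and max
  tc <- twoClassScores(30, 1, seed = 5)
  ci2 <- aucCI(tc$scores, tc$labels, nResamples = 2, seed = 2)
  expect_lte(ci2$ci_lower, ci2$ci_upper)
  ci2b <- aucCI(tc$scores, tc$labels, nResamples = 2, seed = 2)
  expect_identical(ci2, ci2b)  # seeded reproducibility
  expect_true(ci$stratified)
})

test_that("paired AUC bootstrap test honours its identities", {
  tc <- twoClassScores(50, 1, seed = 7)
  same <- aucDifferenceTest(tc$scores, tc$scores, tc$labels,
                            nResamples = 100, seed = 1)
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)

  other <- withr::with_seed(8, rnorm(100))
  ab <- aucDifferenceTest(tc$scores, other, tc$labels, nResamples = 200,
                          seed = 3)
  ba <- aucDifferenceTest(other, tc$scores, tc$labels, nResamples = 200,
                          seed = 3)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$p_value, ba$p_value)
  expect_error(aucDifferenceTest(tc$scores, other[1:50], tc$labels),
               "paired")
})

test_that("proportional-odds OR is scale-consistent and near 1 under the null", {
  grades <- rep(c("NEC", "BiopsyNegative", "Gs6", "Gs3+4", "Gs4+3",
                  "Gs8plus"), each = 60)
  s <- withr::with_seed(11, runif(length(grades)))
  null <- proportionalOddsOR(s, grades)
  expect_true(null$converged)
  expect_lt(abs(log(null$or)), 0.35)  # OR per 0.1 ~ 1 under the null
  # per-1.0 OR on a x10 scale equals per-0.1 OR on the original scale
  withSignal <- withr::with_seed(12,
    runif(length(grades)) + 0.15 * as.numeric(urotriage:::.ordinalGrade(grades)))
  a <- proportionalOddsOR(withSignal, grades, per = 0.1)
  b <- proportionalOddsOR(withSignal * 10, grades, per = 1.0)
  expect_equal(a$or, b$or, tolerance = 1e-4)
  expect_error(proportionalOddsOR(s[1:120], rep(c("NEC", "Gs6"), each = 60)),
               "3 ordered")
})

test_that("BCa interval edges: identical, constant and singleton groups", {
  g <- withr::with_seed(1, rnorm(40))
  same <- meanDiffBCa(g, g, nResamples = 400, seed = 2)
  expect_equal(same$delta, 0)
  expect_lte(same$ci_lower, 0)
  expect_gte(same$ci_upper, 0)

  const <- meanDiffBCa(rep(2, 10), rep(1.5, 10), nResamples = 100, seed = 3)
  expect_equal(const$delta, 0.5)
  expect_equal(const$ci_lower, 0.5)
  expect_equal(const$ci_upper, 0.5)

  expect_warning(one <- meanDiffBCa(3, g, nResamples = 100, seed = 4),
                 "size 1")
  expect_equal(one$method, "percentile")
})

test_that("BCa agrees with the boot package on a common dataset", {
  skip_if_not_installed("boot")
  set.seed(20)
  g <- rnorm(60, 0.5); r <- rnorm(60, 0)
  mine <- meanDiffBCa(g, r, nResamples = 4000, seed = 5)
  dat <- data.frame(v = c(g, r), grp = rep(c(1, 0), each = 60))
  bt <- boot::boot(dat, function(d, i) {
    di <- d[i, ]; mean(di$v[di$grp == 1]) - mean(di$v[di$grp == 0])
  }, R = 4000, strata = dat$grp)
  bci <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  expect_lt(abs(mine$ci_lower - bci[1]), 0.06)
  expect_lt(abs(mine$ci_upper - bci[2]), 0.06)
})

test_that("sensitivity threshold and spillover are exact on a crafted ROC", {
  pos <- seq(0.05, 0.95, by = 0.1)   # 10 positives
  neg <- c(0.02, 0.04, 0.06, 0.08, 0.12, 0.2, 0.3, 0.4, 0.05, 0.01)
  res <- thresholdForSensitivity(c(pos, neg),
                                 rep(c(TRUE, FALSE), each = 10), 0.9)
  expect_equal(res$threshold, sort(pos, decreasing = TRUE)[9])  # 0.15
  expect_gte(res$sensitivity, 0.9)
  expect_equal(res$spillover, mean(neg >= res$threshold))  # 3/10

  perfect <- thresholdForSensitivity(c(1, 1, 0, 0),
                                     c(TRUE, TRUE, FALSE, FALSE), 0.9)
  expect_equal(perfect$spillover, 0)
  all9 <- thresholdForSensitivity(c(pos, neg),
                                  rep(c(TRUE, FALSE), each = 10), 1)
  expect_equal(all9$threshold, min(pos))
})

test_that("evaluateScores tabulates every variant at every endpoint", {
  co <- generateCohort(smallDesign(seed = 17))
  lab <- outcomes(co)
  sc <- list(a = withr::with_seed(1, runif(60)),
             b = withr::with_seed(2, runif(60)))
  tab <- evaluateScores(sc, lab, nResamples = 50, seed = 1)
  expect_equal(nrow(tab), 6)
  expect_setequal(unique(tab$variant), c("a", "b"))
  expect_true(all(tab$ci_lower <= tab$auc & tab$auc <= tab$ci_upper))
})
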