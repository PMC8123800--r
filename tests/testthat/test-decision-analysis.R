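test_that("net benefit and sNB match hand-computed oracles", {
  expect_equal(netBenefit(25, 15, 100, 0.2), 0.2125)
  expect_equal(standardisedNetBenefit(0.2125, 0.3), 0.2125 / 0.3)
  # treat-all breaks even at the prevalence threshold
  expect_equal(netBenefit(30, 70, 100, 0.3), 0)
  # perfect classifier: NB = prevalence at every threshold
  for (pt in c(0.05, 0.2, 0.45)) {
    expect_equal(netBenefit(30, 0, 100, pt), 0.3)
    expect_equal(standardisedNetBenefit(netBenefit(30, 0, 100, pt), 0.3), 1)
  }
  expect_error(netBenefit(10, 5, 100, 0), "threshold")
  expect_error(netBenefit(80, 30, 100, 0.2), "exceed")
  expect_error(standardisedNetBenefit(0.1, 0), "prevalence")
})

test_that("biopsy net reduction reproduces the worked arithmetic chain", {
  nbModel <- netBenefit(25, 15, 100, 0.2)        # 0.2125
  nbAll <- netBenefit(30, 70, 100, 0.2)          # 0.125
  expect_equal(biopsyNetReduction(nbModel, nbAll, 0.2), 35)
  expect_equal(biopsyNetReduction(nbAll, nbAll, 0.2), 0)
  expect_equal(biopsyNetReduction(nbAll, nbModel, 0.2), -35)
  # invariant to adding a constant to both net benefits
  expect_equal(biopsyNetReduction(nbModel + 0.1, nbAll + 0.1, 0.2), 35)
})

test_that("prevalence scheme validates its proportions", {
  sch <- prevalenceScheme()
  expect_equal(sum(sch$proportions), 1)
  expect_equal(sch$n, 197L)
  expect_error(prevalenceScheme(c(noCancer = 0.5, gs6 = 0.2, gs7 = 0.2,
                                  gs8 = 0.2)), "1")
})

test_that("largest-remainder stratum counts total exactly n", {
  counts <- urotriage:::.largestRemainder(prevalenceScheme()$proportions, 197)
  expect_equal(counts, c(119L, 47L, 17L, 14L))
  expect_equal(sum(counts), 197L)
})

test_that("the CAP resampler is exact in size, seeded, and on-target", {
  co <- generateCohort(cohortDesign(seed = 2))
  out <- outcomes(co)
  sch <- prevalenceScheme(nResamples = 200L)
  idx <- capResample(out, sch, seed = 9)
  expect_equal(dim(idx), c(200, 197))
  expect_identical(idx, capResample(out, sch, seed = 9))
  expect_false(identical(idx, capResample(out, sch, seed = 10)))

  # realised composition of each resample matches the rounded strata
  drawn <- out[idx[1, ]]
  expect_equal(sum(drawn %in% c("NEC", "BiopsyNegative")), 119)
  expect_equal(sum(drawn == "Gs6"), 47)
  expect_equal(sum(drawn %in% c("Gs3+4", "Gs4+3")), 17)
  expect_equal(sum(drawn == "Gs8plus"), 14)
  expect_equal(length(drawn), 197)
  # mean realised proportions sit on the configured targets
  gs6frac <- vapply(seq_len(nrow(idx)), function(b)
    mean(out[idx[b, ]] == "Gs6"), numeric(1))
  expect_lt(abs(mean(gs6frac) - 0.236), 0.01)
  noCancer <- vapply(seq_len(nrow(idx)), function(b)
    mean(out[idx[b, ]] %in% c("NEC", "BiopsyNegative")), numeric(1))
  expect_lt(abs(mean(noCancer) - 0.606), 0.01)
  # Gs7 stratum pools 3+4 and 4+3
  gs7 <- mean(out[idx[2, ]] %in% c("Gs3+4", "Gs4+3"))
  expect_equal(gs7, 17 / 197)
})

test_that("an empty source stratum is reported by name", {
  out <- rep(c("NEC", "Gs6", "Gs3+4"), each = 20)  # no Gs8plus
  expect_error(capResample(out, prevalenceScheme(nResamples = 2L)), "gs8")
})

test_that("treat-all sNB follows its closed form on the whole grid", {
  co <- generateCohort(cohortDesign(seed = 4))
  out <- outcomes(co)
  sc <- list(model = withr::with_seed(1, runif(length(out))))
  th <- seq(0.01, 0.5, by = 0.01)
  dc <- dcaCurves(sc, out, endpoint = "any-cancer",
                  scheme = prevalenceScheme(nResamples = 50L),
                  thresholds = th, seed = 3)
  cv <- curveTable(dc)
  prev <- (47 + 17 + 14) / 197  # fixed by the stratified resample design
  allRow <- cv[cv$strategy == "treat-all", ]
  expect_equal(allRow$snb, 1 - ((1 - prev) / prev) * th / (1 - th),
               tolerance = 1e-12)
  expect_true(all(cv[cv$strategy == "treat-none", ]$snb == 0))
  expect_true(all(cv$snb <= 1 + 1e-12))
})

test_that("perfect scores reach sNB = 1 below the minimum positive score", {
  co <- generateCohort(cohortDesign(seed = 5))
  out <- outcomes(co)
  perfect <- as.numeric(binaryEndpoint(out, "Gs>=3+4"))
  dc <- dcaCurves(list(oracle = perfect), out, endpoint = "Gs>=3+4",
                  scheme = prevalenceScheme(nResamples = 20L),
                  thresholds = c(0.05, 0.25, 0.45), seed = 1)
  cv <- curveTable(dc)
  expect_equal(cv[cv$strategy == "oracle", ]$snb, rep(1, 3))
})

test_that("reduction curves vanish against an identical reference", {
  co <- generateCohort(cohortDesign(seed = 6))
  out <- outcomes(co)
  s <- withr::with_seed(2, runif(length(out)))
  dc <- dcaCurves(list(a = s, b = s), out, endpoint = "any-cancer",
                  scheme = prevalenceScheme(nResamples = 10L),
                  thresholds = c(0.1, 0.2), seed = 2)
  red <- reductionCurves(dc, reference = "a")
  expect_equal(red[red$strategy == "b", ]$reduction_per_100, c(0, 0))
  expect_error(reductionCurves(dc, reference = "zz"), "unknown reference")
})

test_that("null scores cannot systematically beat treat-all at low thresholds", {
  co <- generateCohort(cohortDesign(seed = 7))
  out <- outcomes(co)
  noise <- withr::with_seed(3, runif(length(out)))
  dc <- dcaCurves(list(noise = noise), out, endpoint = "any-cancer",
                  scheme = prevalenceScheme(nResamples = 100L),
                  thresholds = 0.05, seed = 4)
  cv <- curveTable(dc)
  expect_lte(cv$snb[cv$strategy == "noise"],
             cv$snb[cv$strategy == "treat-all"] + 0.05)
})
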