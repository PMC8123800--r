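fastRF <- list(nTrees = 150)

noisyCopyFM <- function(seed, n = 100, pNoise = 10) {
  withr::with_seed(seed, {
    y <- rep(c(0, 0.5, 1), length.out = n)
    x <- cbind(copy = y, matrix(rnorm(n * pNoise), n,
                                dimnames = list(NULL, paste0("noise", 1:pNoise))))
    makeFM(x, y)
  })
}

test_that("an exact copy of the label is Confirmed", {
  run <- borutaOnce(noisyCopyFM(1), rfParams = fastRF, maxIter = 30, seed = 2)
  expect_equal(as.character(decisions(run)["copy"]), "Confirmed")
})

test_that("pure-noise features are almost never Confirmed", {
  confirmed <- numeric(3)
  for (s in 1:3) {
    x <- withr::with_seed(s, matrix(rnorm(100 * 15), 100,
                                    dimnames = list(NULL, paste0("n", 1:15))))
    y <- rep(c(0, 0.5, 1), length.out = 100)
    run <- borutaOnce(x, label = y, rfParams = fastRF, maxIter = 30, seed = s)
    confirmed[s] <- mean(decisions(run) == "Confirmed")
  }
  expect_lte(mean(confirmed), 0.05)
})

test_that("degenerate inputs raise informative errors", {
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(borutaOnce(x, label = rep(0.5, 20)), "single value")
  xb <- x; xb[1, 1] <- NA
  expect_error(borutaOnce(xb, label = rep(c(0, 1), 10)), "non-finite")
  expect_error(borutaOnce(x, label = rep(c(0, 1), 10), alpha = 2), "alpha")
})

test_that("decisions are invariant to feature column order", {
  fm <- noisyCopyFM(4, n = 120, pNoise = 8)
  run1 <- borutaOnce(fm, rfParams = fastRF, maxIter = 25, seed = 9)
  shuf <- withr::with_seed(1, sample(ncol(featureValues(fm))))
  fm2 <- makeFM(featureValues(fm)[, shuf], trainingLabel(fm))
  run2 <- borutaOnce(fm2, rfParams = fastRF, maxIter = 25, seed = 9)
  expect_equal(as.character(decisions(run1)[colnames(featureValues(fm2))]),
               as.character(decisions(run2)))
})

test_that("a B=1 stability run reproduces the single Boruta decision", {
  fm <- noisyCopyFM(5, n = 80, pNoise = 5)
  seed <- 17
  rep1 <- stabilitySelect(fm, B = 1, threshold = 0.9, rfParams = fastRF,
                          maxIter = 25, seed = seed)
  idx <- urotriage:::.resampleSchedule(80, 1, seed)[1, ]
  run <- borutaOnce(featureValues(fm)[idx, ], label = trainingLabel(fm)[idx],
                    rfParams = fastRF, maxIter = 25,
                    seed = urotriage:::xorSeed(seed, 1), groups = idx)
  expect_equal(unname(selectionProportions(rep1)),
               as.numeric(decisions(run) == "Confirmed"))
})

test_that("stability selection is deterministic and monotone in threshold", {
  fm <- noisyCopyFM(6, n = 80, pNoise = 5)
  r1 <- stabilitySelect(fm, B = 5, threshold = 0.5, rfParams = fastRF,
                        maxIter = 20, seed = 3)
  r2 <- stabilitySelect(fm, B = 5, threshold = 0.9, rfParams = fastRF,
                        maxIter = 20, seed = 3)
  expect_identical(selectionProportions(r1), selectionProportions(r2))
  expect_true(all(retainedFeatures(r2) %in% retainedFeatures(r1)))
})

test_that("the resample schedule depends only on n and seed", {
  expect_identical(urotriage:::.resampleSchedule(50, 4, 7),
                   urotriage:::.resampleSchedule(50, 4, 7))
  expect_false(identical(urotriage:::.resampleSchedule(50, 4, 7),
                         urotriage:::.resampleSchedule(50, 4, 8)))
})

test_that("threshold boundary is inclusive at >=", {
  pf <- c(a = 0.94, b = 0.899, c = 0.90)
  rep <- new("StabilityReport", selectionProportion = pf,
             importance = matrix(NA_real_, 1, 3,
                                 dimnames = list(NULL, names(pf))),
             retained = c("a", "c"), B = 1000L, threshold = 0.9, seed = 1L)
  expect_setequal(retainedFeatures(rep), c("a", "c"))
  expect_error(validObject(new("StabilityReport", selectionProportion = pf,
                               importance = matrix(NA_real_, 1, 3),
                               retained = c("a", "b", "c"), B = 1000L,
                               threshold = 0.9, seed = 1L)),
               "inconsistent")
})

test_that("importance trajectory sorts by stability and drops never-selected", {
  fm <- noisyCopyFM(8, n = 100, pNoise = 6)
  rep <- stabilitySelect(fm, B = 4, rfParams = fastRF, maxIter = 20, seed = 5)
  tab <- importanceTrajectory(rep)
  expect_true(all(tab$selection_proportion > 0))
  expect_equal(tab$feature[1], "copy")
  expect_true(!is.unsorted(rev(tab$selection_proportion)))

  empty <- new("StabilityReport",
               selectionProportion = c(x = 0, y = 0),
               importance = matrix(NA_real_, 2, 2,
                                   dimnames = list(NULL, c("x", "y"))),
               retained = character(), B = 2L, threshold = 0.9, seed = 1L)
  expect_equal(nrow(importanceTrajectory(empty)), 0)

  one <- new("StabilityReport", selectionProportion = c(solo = 1),
             importance = matrix(2.5, 3, 1, dimnames = list(NULL, "solo")),
             retained = "solo", B = 3L, threshold = 0.9, seed = 1L)
  expect_equal(importanceTrajectory(one)$importance_median, 2.5)
})
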