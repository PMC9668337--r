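# Correlation matrices, Glass's delta, truncation sweeps, permutation
# nulls.

test_that("correlation matrix is Pearson across features with matched
           subjects", {
  set.seed(5)
  F1 <- matrix(rnorm(20 * 100), 20, 100)
  expect_equal(diag(correlationMatrix(F1, F1)), rep(1, 20))
  F2 <- matrix(rnorm(20 * 100), 20, 100)
  C <- correlationMatrix(F1, F2)
  expect_lt(abs(mean(C[row(C) != col(C)])), 0.02)
  expect_true(all(abs(C) <= 1 + 1e-12))
  bad <- F1; bad[7, ] <- 2
  expect_error(correlationMatrix(bad, F2), "subject 7")
  expect_error(correlationMatrix(F1, F2[1:10, ]), "same N")
})

test_that("Glass's delta matches hand-computed moments", {
  C <- matrix(0, 3, 3)
  diag(C) <- 0.9
  C[row(C) != col(C)] <- c(0.3, 0.3, 0.3, -0.1, -0.1, -0.1)
  # between: mean 0.1, var 0.24/5, sd sqrt(0.048)
  expect_equal(glassDelta(C), 0.8 / sqrt(0.048), tolerance = 1e-12)
  # direct arithmetic example: (0.9 - 0.1) / 0.2 = 4
  expect_equal((mean(diag(C)) - 0.1) / 0.2, 4)
  # same-distribution within/between: score near zero in expectation
  set.seed(8)
  scores <- replicate(200, glassDelta(matrix(rnorm(25, 0, 0.3), 5, 5)))
  expect_lt(abs(mean(scores)), 0.15)
  # pooled-SD variant agrees in sign, similar magnitude
  cohort <- featureCohort(seed = 2)
  C2 <- correlationMatrix(cohort$t1, cohort$t2)
  g <- glassDelta(C2); gp <- glassDelta(C2, pooled = TRUE)
  expect_gt(g * gp, 0)
  expect_lt(abs(g - gp) / g, 0.6)
  expect_error(glassDelta(matrix(1, 4, 4)), "zero SD")
})

test_that("score is invariant to affine feature rescaling and joint
           subject permutation", {
  cohort <- featureCohort(seed = 3)
  s0 <- identifiabilityScore(cohort$t1, cohort$t2)@score
  s1 <- identifiabilityScore(3 * cohort$t1 + 2, 3 * cohort$t2 + 2)@score
  expect_equal(s0, s1, tolerance = 1e-12)
  set.seed(1); pm <- sample(nrow(cohort$t1))
  s2 <- identifiabilityScore(cohort$t1[pm, ], cohort$t2[pm, ])@score
  expect_equal(s0, s2, tolerance = 1e-12)
})

test_that("sweep finds the injected scale and handles degenerate small
           truncations", {
  # subject signal at coarse indices; noisier fine scales, as when
  # measurement noise grows at fine spatial scales
  cohort <- featureCohort(N = 24, signalIdx = 2:25, seed = 4,
                          fineNoiseSD = 1.5)
  sw <- identifiabilitySweep(cohort$t1, cohort$t2, kMax = 150)
  expect_s4_class(sw, "SweepCurve")
  # signal confined to indices <= 25 (within group 4): the peak sits at
  # or before the end of group 5 and the curve declines afterwards
  expect_lte(sw@peakK, cumulativeCount(5))
  expect_gt(sw@peakScore, tail(sw@scores, 1))
  expect_gt(sw@peakScore, 2)
  # group means exist for groups fully inside the sweep range
  expect_true(all(paste0("L", 1:11) %in% names(sw@groupMeans)))
  # ties and bounds
  expect_error(identifiabilitySweep(cohort$t1, cohort$t2, kMax = 200),
               "exceeds")
  # literal first-two-eigenvalues convention: degenerate +/-1
  # correlations still yield defined scores
  swLit <- identifiabilitySweep(cohort$t1, cohort$t2, kMin = 2,
                                kMax = 10, includeFirst = TRUE)
  expect_true(swLit@includeFirst)
  expect_true(is.finite(swLit@scores[1]))
})

test_that("identifiability increases with the signal-to-noise ratio", {
  ratios <- c(0.5, 2, 8)
  scores <- vapply(seq_along(ratios), function(i) {
    cohort <- featureCohort(N = 20, signalSD = ratios[i], noiseSD = 1,
                            seed = 99)
    identifiabilityScore(cohort$t1[, 2:80], cohort$t2[, 2:80])@score
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("permutation null separates signal from shuffled labels", {
  cohort <- featureCohort(N = 18, signalSD = 1.5, noiseSD = 0.3,
                          seed = 6)
  pn <- permutationNull(cohort$t1, cohort$t2, kMax = 100, nPerm = 500,
                        seed = 3)
  expect_equal(pn$p, 1 / 501)
  expect_equal(pn$pRaw, 0)
  expect_gt(pn$observedPeak, max(pn$nullPeaks))
  # a label-shuffled "observed" cohort is indistinguishable from the null
  set.seed(10); pm <- sample(nrow(cohort$t2))
  pn0 <- permutationNull(cohort$t1, cohort$t2[pm, ], kMax = 100,
                         nPerm = 300, seed = 4)
  expect_gt(pn0$p, 0.05)
  expect_error(permutationNull(cohort$t1, cohort$t2, nPerm = 0), "nPerm")
})

test_that("permutation p-values are calibrated under the null", {
  # null cohorts: no subject signal at all
  ps <- vapply(1:40, function(i) {
    set.seed(300 + i)
    t1 <- matrix(rnorm(12 * 60), 12, 60)
    t2 <- matrix(rnorm(12 * 60), 12, 60)
    permutationNull(t1, t2, kMax = 60, nPerm = 99, seed = i)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.3)    # roughly uniform, not concentrated at 0
  expect_lt(mean(ps), 0.75)
  expect_lte(mean(ps <= 0.05), 0.2)
})

test_that("cross-feature identifiability reuses the same machinery", {
  cohort <- featureCohort(seed = 7)
  a <- crossFeatureIdentifiability(cohort$t1, cohort$t2)
  b <- identifiabilityScore(cohort$t1, cohort$t2)
  expect_equal(a@score, b@score)
  # independent feature sets: near-zero score
  set.seed(12)
  A <- matrix(rnorm(20 * 80), 20, 80); B <- matrix(rnorm(20 * 80), 20, 80)
  expect_lt(abs(crossFeatureIdentifiability(A, B)@score), 1)
  expect_error(crossFeatureIdentifiability(A, B[1:5, ]), "same N")
})
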