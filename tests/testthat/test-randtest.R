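test_that("the Monte-Carlo p-value implements the plain tie-inclusive estimator", {
  # constant statistic over all sequences: every draw ties, p = 1
  tr <- trialData(rep(1:2, each = 4), rep(1, 8), doses = c(0, 10))
  ra <- randomAllocation(c(0, 10), c(4, 4))
  cand <- candidateSet(linear = drShape("linear"))
  rt <- randomizationTest(tr, ra, "S2", "mle", "gaussian", cand,
                          nrand = 200, seed = 1)
  expect_equal(rt$pValue, 1)
  # with the add-one correction the p-value shifts to (count+1)/(nrand+1)
  rtc <- randomizationTest(tr, ra, "S2", "mle", "gaussian", cand,
                           nrand = 200, seed = 1, correction = TRUE)
  expect_equal(rtc$pValue, 201 / 201)
  # p = count/nrand exactly
  set.seed(4)
  tr2 <- trialData(rep(1:2, each = 4), rnorm(8), doses = c(0, 10))
  rt2 <- randomizationTest(tr2, ra, "S2", "mle", "gaussian", cand,
                           nrand = 137, seed = 2)
  expect_equal(rt2$pValue,
               sum(rt2$nullDraws >= rt2$statistic) / 137)
  expect_equal(rt2$nrand, 137)
})

test_that("Monte-Carlo p-values converge to the exact enumeration p-value", {
  # n = 8, RA(4,4): the reference set has exactly 70 sequences
  set.seed(12)
  y <- rnorm(8, mean = c(0, 0, 0, 0, 1, 1, 1, 1))
  zobs <- c(1L, 1L, 2L, 1L, 2L, 2L, 1L, 2L)
  ra <- randomAllocation(c(0, 10), c(4, 4))
  cand <- candidateSet(linear = drShape("linear"))
  tr <- trialData(zobs, y, doses = c(0, 10))
  r <- MCPModRand:::residualFit(tr, "gaussian", "mle")
  seqs <- enumerateReferenceSet(ra)
  stats <- vapply(seq_len(nrow(seqs)), function(i)
    statisticS2(r, seqs[i, ], cand, c(0, 10)), numeric(1))
  obs <- statisticS2(r, zobs, cand, c(0, 10))
  pExact <- mean(stats >= obs)
  rt <- randomizationTest(tr, ra, "S2", "mle", "gaussian", cand,
                          nrand = 1e5, seed = 3)
  se <- sqrt(pExact * (1 - pExact) / 1e5)
  expect_lt(abs(rt$pValue - pExact), 3 * se + 1e-12)
  expect_equal(rt$statistic, obs, tolerance = 1e-12)
})

test_that("full-enumeration tests are valid at every level for every outcome", {
  # exhaustive check on a small instance: for each outcome vector, the
  # exact randomization test rejects with probability at most alpha
  ra <- randomAllocation(c(0, 10, 20), c(2, 2, 2))
  cand <- candidateSet(linear = drShape("linear"),
                       emax = drShape("emax", theta2 = 5))
  seqs <- enumerateReferenceSet(ra)  # 90 sequences
  set.seed(21)
  outcomes <- rbind(matrix(rbinom(5 * 6, 1, 0.5), 5),
                    matrix(rnorm(5 * 6), 5))
  for (row in seq_len(nrow(outcomes))) {
    y <- outcomes[row, ]
    r <- y - mean(y)
    stats <- MCPModRand:::s2_stat_batch_cpp(
      seqs, r, shapeMatrix(cand, c(0, 10, 20)), FALSE,
      t(unclass(contrastsFromGroupSizes(cand, c(0, 10, 20), c(2, 2, 2)))))
    pvals <- vapply(stats, function(s) mean(stats >= s), numeric(1))
    for (alpha in c(0.05, 0.1, 0.2, 0.5))
      expect_lte(mean(pvals < alpha), alpha + 1e-12)
  }
})

test_that("randomization p-values are uniform under the strong null", {
  # outcomes generated independently of Z: p-values stochastically dominate
  # (discrete) uniform; Kolmogorov-Smirnov distance consistent with that
  set.seed(33)
  ra <- randomAllocation(c(0, 10, 25, 100), c(7, 14, 14, 14))
  cand <- smallCandidates()
  pv <- numeric(400)
  for (i in seq_along(pv)) {
    y <- rbinom(49, 1, 0.3)
    x <- rnorm(49)
    tr <- trialData(sampleSequence(ra), y, matrix(x), c(0, 10, 25, 100))
    pv[i] <- randomizationTest(tr, ra, "S2", "mle", "binomial", cand,
                               nrand = 200)$pValue
  }
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 1e-4)
  expect_lt(abs(mean(pv < 0.1) - 0.1), 3 * sqrt(0.1 * 0.9 / 400) + 1 / 200)
})

test_that("the five tests reproduce frozen p-values on the printed fixture", {
  tr <- toyTrial()
  proc <- randomAllocation(tr$doses, c(3, 6, 5, 7))
  cand <- defaultCandidateSet()
  p <- vapply(1:5, runNamedTest, numeric(1), data = tr, proc = proc,
              candidates = cand, family = "binomial", nrand = 400,
              seed = 2024)
  # golden values computed from this fixture at the frozen seed
  expect_equal(p[1], 0.08090351, tolerance = 1e-6)
  expect_equal(p[2:5], c(0.0125, 0.1025, 0.06, 0.1125), tolerance = 1e-12)
})
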