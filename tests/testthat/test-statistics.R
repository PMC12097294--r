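test_that("S1 reduces to the two-sample z-statistic for one linear contrast", {
  set.seed(3)
  z <- rep(1:2, each = 8)
  y <- rnorm(16, mean = c(0, 1)[z])
  tr <- trialData(z, y, doses = c(0, 100))
  lin <- candidateSet(linear = drShape("linear"))
  s1 <- statisticS1(tr, lin, family = "gaussian")
  # z-statistic: difference in means over its model-based standard error
  fit <- lm(y ~ 0 + factor(z))
  est <- coef(fit)
  se <- sqrt(sum(diag(vcov(fit))))
  expect_equal(s1, unname((est[2] - est[1]) / se), tolerance = 1e-8)
})

test_that("S1 is zero for constant group means and matches a from-scratch oracle", {
  lin <- candidateSet(linear = drShape("linear"))
  zc <- rep(1:2, each = 4)
  trc <- trialData(zc, rep(2.5, 8), doses = c(0, 100))
  expect_equal(statisticS1(trc, lin, family = "gaussian"), 0,
               tolerance = 1e-10)

  # from-scratch recomputation on the printed toy fixture: independent glm
  # fit, population averaging, contrast formula and max - all in R
  tr <- toyTrial()
  cand <- defaultCandidateSet()
  for (recompute in c(FALSE, TRUE)) {
    s1 <- statisticS1(tr, cand, "binomial", "mle",
                      recomputeContrasts = recompute)
    g <- glm(tr$y ~ 0 + factor(tr$z) + tr$x, family = binomial())
    delta <- coef(g)[1:4]
    beta <- coef(g)[5]
    muHat <- unname(delta + mean(tr$x) * beta)
    L <- cbind(diag(4), rep(mean(tr$x), 4))
    S <- L %*% vcov(g) %*% t(L)
    mu0 <- shapeMatrix(cand, tr$doses)
    stats <- vapply(seq_len(ncol(mu0)), function(m) {
      cc <- if (recompute) oracleContrast(mu0[, m], S)
            else oracleContrast(mu0[, m], diag(1 / tabulate(tr$z, 4)))
      sum(cc * muHat) / sqrt(drop(t(cc) %*% S %*% cc))
    }, numeric(1))
    expect_equal(s1, max(stats), tolerance = 1e-6, info = recompute)
  }
})

test_that("S2 matches a hand-rolled group-summary computation on the fixture", {
  tr <- toyTrial()
  cand <- defaultCandidateSet()
  s2 <- statisticS2(tr, candidates = cand, family = "binomial",
                    method = "mle")
  # oracle: covariate-only glm, residuals, group summaries, Eq-style formula
  g <- glm(tr$y ~ tr$x, family = binomial())
  r <- tr$y - fitted(g)
  rbar <- tapply(r, tr$z, mean)
  s2j <- tapply(r, tr$z, var)
  nj <- tabulate(tr$z, 4)
  mu0 <- shapeMatrix(cand, tr$doses)
  stats <- vapply(seq_len(ncol(mu0)), function(m) {
    cc <- oracleContrast(mu0[, m], diag(1 / nj))
    sum(cc * rbar) / sqrt(sum(cc^2 * s2j / nj))
  }, numeric(1))
  expect_equal(s2, max(stats), tolerance = 1e-8)
})

test_that("S2 depends on the assignment only through group summaries", {
  tr <- toyTrial()
  cand <- smallCandidates()
  r <- MCPModRand:::residualFit(tr, "binomial", "mle")
  s2 <- statisticS2(r, tr$z, cand, tr$doses)
  # permuting patients within arms leaves the statistic unchanged
  set.seed(2)
  perm <- unlist(lapply(split(seq_along(tr$z), tr$z), sample))
  expect_equal(statisticS2(r[perm], tr$z[perm], cand, tr$doses), s2,
               tolerance = 1e-12)
  # gaussian residuals: adding a constant to all outcomes cancels out
  y <- rnorm(21)
  trg <- trialData(tr$z, y, doses = tr$doses)
  trg7 <- trialData(tr$z, y + 7, doses = tr$doses)
  expect_equal(statisticS2(trg, candidates = cand, family = "gaussian"),
               statisticS2(trg7, candidates = cand, family = "gaussian"),
               tolerance = 1e-9)
})

test_that("population test p-values match closed forms and quadrature", {
  # M = 1: one-sided normal p-value
  set.seed(8)
  z <- rep(1:2, each = 30)
  y <- rnorm(60, mean = c(0, 0.6)[z])
  tr <- trialData(z, y, doses = c(0, 100))
  lin <- candidateSet(linear = drShape("linear"))
  pt <- populationTest(tr, lin, family = "gaussian")
  expect_equal(pt$pValue, 1 - pnorm(pt$statistic), tolerance = 1e-5)

  # M = 2, rho = 0.5, t = 2: against direct bivariate-normal quadrature
  R <- matrix(c(1, 0.5, 0.5, 1), 2)
  pmv <- 1 - mvtnorm::pmvnorm(upper = c(2, 2), corr = R,
                              algorithm = mvtnorm::GenzBretz(abseps = 1e-6))[1]
  quad <- 1 - integrate(function(x)
    dnorm(x) * pnorm((2 - 0.5 * x) / sqrt(1 - 0.25)),
    -Inf, 2, rel.tol = 1e-10)$value
  expect_equal(pmv, quad, tolerance = 1e-4)

  # orthogonal contrasts: p = 1 - Phi(t)^M
  pInd <- 1 - mvtnorm::pmvnorm(upper = rep(1.5, 3), corr = diag(3))[1]
  expect_equal(pInd, 1 - pnorm(1.5)^3, tolerance = 1e-5)
})

test_that("the five named tests dispatch to the documented pipelines", {
  tr <- toyTrial()
  proc14 <- permutedBlocks(tr$doses, c(1, 2, 2, 2), 2)
  # n mismatch is caught
  expect_error(runNamedTest(2, tr, proc14, smallCandidates()), "sample sizes")
  proc21 <- randomAllocation(tr$doses, c(3, 6, 5, 7))
  expect_error(runNamedTest(7, tr, proc21, smallCandidates()), "unknown")
  cand <- smallCandidates()
  p1 <- runNamedTest(1, tr, proc21, cand)
  expect_identical(p1, populationTest(tr, cand)$pValue)
  # same seed: test 2 vs 4 differ only through the estimator
  p2 <- runNamedTest(2, tr, proc21, cand, nrand = 50, seed = 5)
  p4 <- runNamedTest(4, tr, proc21, cand, nrand = 50, seed = 5)
  expect_true(p2 >= 0 && p2 <= 1 && p4 >= 0 && p4 <= 1)
  # test 1 on a two-arm gaussian toy equals the z-test p-value
  set.seed(10)
  z <- rep(1:2, each = 10)
  y <- rnorm(20, mean = c(0, 1)[z])
  t2 <- trialData(z, y, doses = c(0, 100))
  lin <- candidateSet(linear = drShape("linear"))
  p <- runNamedTest(1, t2, NULL, lin, family = "gaussian")
  fit <- lm(y ~ 0 + factor(z))
  zstat <- unname(diff(coef(fit)) / sqrt(sum(diag(vcov(fit)))))
  expect_equal(p, 1 - pnorm(zstat), tolerance = 1e-5)
})
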