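test_that("Firth estimates maximize the penalized likelihood (numerical oracle)", {
  # independent check: BFGS on the penalized log-likelihood written in R
  set.seed(13)
  worstGap <- 0
  for (rep in 1:30) {
    n <- 20
    k <- 3
    z <- sample(1:k, n, replace = TRUE)
    while (length(unique(z)) < k) z <- sample(1:k, n, replace = TRUE)
    x <- rnorm(n)
    y <- rbinom(n, 1, 0.4)
    D <- cbind(outer(z, 1:k, "==") * 1, x)
    ours <- drop(MCPModRand:::firth_fit_cpp(D, y)$coefficients)
    opt <- optim(rep(0, k + 1), function(b) -oraclePenLogLik(b, D, y),
                 method = "BFGS",
                 control = list(reltol = 1e-16, maxit = 2000))
    expect_lt(max(abs(ours - opt$par)), 1e-5)
    gap <- oraclePenLogLik(ours, D, y) - (-opt$value)
    worstGap <- min(worstGap, gap)
  }
  # our optimum is never below the independent optimizer's
  expect_gt(worstGap, -1e-8)
})

test_that("Firth estimates are finite under separation, warm starts agree", {
  # canonical complete separation: y = 1 iff dose > 0
  z <- rep(1:2, each = 5)
  y <- as.numeric(z > 1)
  tr <- trialData(z, y, doses = c(0, 10))
  fitF <- fitGlm(tr, "binomial", "firth")
  expect_true(all(is.finite(fitF$delta)))
  expect_equal(fitF$separation, "complete")
  fitM <- fitGlm(tr, "binomial", "mle")
  expect_equal(fitM$separation, "complete")
  expect_false(fitM$converged)
  # warm starting does not move the optimum
  set.seed(17)
  for (i in 1:10) {
    D <- cbind(1, matrix(rnorm(30), 15, 2))
    y <- rbinom(15, 1, 0.5)
    cold <- drop(MCPModRand:::firth_fit_cpp(D, y)$coefficients)
    warm <- drop(MCPModRand:::firth_fit_cpp(D, y,
                                            start = cold + rnorm(3))$coefficients)
    expect_equal(cold, warm, tolerance = 1e-6)
  }
})

test_that("Firth fits are finite on every separated null replicate", {
  set.seed(23)
  scen <- binaryScenario(pbd49(), pTop = 0.2)
  nsep <- 0
  for (i in 1:120) {
    tr <- generateTrial(scen)
    if (detectSeparation(tr) == "none") next
    nsep <- nsep + 1
    f <- fitGlm(tr, "binomial", "firth", separationCheck = "none")
    expect_true(all(is.finite(c(f$delta, f$beta, f$muHat))))
    expect_true(all(is.finite(f$S)))
  }
  expect_gt(nsep, 10)  # separation is common at n = 49
})

test_that("symmetric data give a zero dose effect under both estimators", {
  # two arms with mirrored successes/failures
  z <- rep(1:2, each = 4)
  y <- c(1, 1, 0, 0, 1, 1, 0, 0)
  tr <- trialData(z, y, doses = c(0, 10))
  for (m in c("mle", "firth")) {
    f <- fitGlm(tr, "binomial", m)
    expect_equal(unname(f$delta[2] - f$delta[1]), 0, tolerance = 1e-8)
  }
})

test_that("gaussian fits reproduce ordinary least squares", {
  set.seed(5)
  z <- rep(1:3, times = c(4, 5, 6))
  x <- matrix(rnorm(30), 15, 2)
  y <- rnorm(15, mean = z)
  tr <- trialData(z, y, x, doses = c(0, 10, 20))
  f <- fitGlm(tr, "gaussian", "mle")
  lmfit <- lm(y ~ 0 + factor(z) + x)
  expect_equal(unname(c(f$delta, f$beta)), unname(coef(lmfit)),
               tolerance = 1e-10)
  expect_equal(unname(f$vcov), unname(vcov(lmfit)), tolerance = 1e-8)
})

test_that("ML and Firth agree on large balanced samples", {
  set.seed(71)
  n <- 4000
  z <- rep(1:4, each = n / 4)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.3 * (z - 1) + 0.5 * x))
  tr <- trialData(z, y, matrix(x), doses = c(0, 10, 25, 100))
  fm <- fitGlm(tr, "binomial", "mle", separationCheck = "none")
  ff <- fitGlm(tr, "binomial", "firth", separationCheck = "none")
  # the Jeffreys correction is O(1/n): differences of order 1e-3 at n = 4000
  expect_equal(unname(fm$delta), unname(ff$delta), tolerance = 5e-3)
  expect_equal(unname(fm$beta), unname(ff$beta), tolerance = 5e-3)
})

test_that("population-average means apply the L V L' mapping", {
  tr <- toyTrial()
  f <- fitGlm(tr, "binomial", "firth")
  # no covariates: muHat equals delta and S the delta covariance block
  tr0 <- trialData(tr$z, tr$y, NULL, tr$doses)
  f0 <- fitGlm(tr0, "binomial", "firth")
  expect_equal(unname(f0$muHat), unname(f0$delta))
  expect_equal(f0$S, f0$vcov[1:4, 1:4])
  # centering the covariate leaves the population-average means unchanged
  trc <- trialData(tr$z, tr$y, scale(tr$x, scale = FALSE), tr$doses)
  fc <- fitGlm(trc, "binomial", "firth")
  expect_equal(fc$muHat, f$muHat, tolerance = 1e-6)
  # two-arm binomial MLE: S diagonal equals 1/(n_j phat_j (1 - phat_j))
  z2 <- rep(1:2, times = c(6, 8))
  y2 <- c(1, 1, 0, 0, 1, 0, 1, 1, 1, 0, 0, 1, 0, 1)
  t2 <- trialData(z2, y2, doses = c(0, 10))
  f2 <- fitGlm(t2, "binomial", "mle")
  phat <- tapply(y2, z2, mean)
  nj <- tabulate(z2)
  expect_equal(unname(diag(f2$S)),
               as.numeric(1 / (nj * phat * (1 - phat))), tolerance = 1e-6)
})

test_that("degenerate designs are rejected with informative errors", {
  expect_error(fitGlm(trialData(c(1, 1, 1), c(0, 1, 0), doses = c(0, 10))),
               "empty arm")
  x <- matrix(c(1, 2, 3, 4, 2, 4, 6, 8), 4, 2)  # collinear covariates
  tr <- trialData(c(1, 1, 2, 2), c(0, 1, 0, 1), x, doses = c(0, 10))
  expect_error(fitGlm(tr), "collinear")
  expect_error(fitGlm(trialData(c(1, 2), c(0.5, 1), doses = c(0, 10)),
                      "binomial"), "0/1")
})
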