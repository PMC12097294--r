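# Shared fixtures, generated in code.

trialDoses <- c(0, 10, 25, 100)

# the 1:2:2:2 block-of-7 design of the motivating trial
pbd49 <- function() permutedBlocks(trialDoses, c(1, 2, 2, 2), 7)
ra49 <- function() randomAllocation(trialDoses, c(7, 14, 14, 14))

# small deterministic binary trial (n = 21, arms 3/5/5/8) with one covariate
toyTrial <- function() {
  z <- c(1, 2, 3, 4, 2, 3, 4, 4, 1, 2, 3, 4, 2, 3, 4, 4, 1, 2, 3, 4, 4)
  y <- c(0, 0, 1, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 0, 1, 1, 1, 0, 1, 1, 0)
  x <- round(sin(1:21 * 2.3) * 1.2, 3)  # fixed, covariate-like values
  trialData(z, y, matrix(x, ncol = 1, dimnames = list(NULL, "x")),
            trialDoses)
}

# candidate set with a couple of shapes (fast paths in small tests)
smallCandidates <- function() {
  candidateSet(emax = drShape("emax", theta2 = 10),
               linear = drShape("linear"))
}

# independent R-only implementation of the optimal-contrast formula
oracleContrast <- function(mu0, S) {
  Si <- solve(S)
  one <- rep(1, length(mu0))
  c0 <- Si %*% (mu0 - one * drop(t(one) %*% Si %*% mu0) /
                  drop(t(one) %*% Si %*% one))
  c0 <- drop(c0) / sqrt(sum(c0^2))
  if (sum(c0 * mu0) < 0) c0 <- -c0
  c0
}

# penalized log-likelihood (independent of the C++ path)
oraclePenLogLik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  W <- mu * (1 - mu)
  info <- crossprod(X * sqrt(W))
  sum(y * eta - log1p(exp(eta))) +
    0.5 * determinant(info, logarithm = TRUE)$modulus
}
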