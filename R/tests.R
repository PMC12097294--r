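# The five dose-response tests: the population-based generalized MCP-Mod
# multiple-contrast test, and Monte-Carlo randomization tests combining two
# statistics (model-based S1, residual-based S2) with two estimators
# (ML, Firth).

familyCode <- function(family) match(family, c("binomial", "gaussian")) - 1L
methodCode <- function(method) match(method, c("mle", "firth")) - 1L

# residuals of the covariate-only fit y ~ alpha + x'beta on the response
# scale: r_i = y_i - g(alpha + x_i'beta)
residualFit <- function(data, family, method) {
  X <- cbind(`(Intercept)` = rep(1, data$n), data$x)
  if (family == "gaussian") {
    fit <- stats::lm.fit(X, data$y)
    return(data$y - drop(X %*% fit$coefficients))
  }
  coefs <- if (method == "firth") {
    drop(firth_fit_cpp(X, data$y)$coefficients)
  } else {
    suppressWarnings(glm.fit(X, data$y, family = binomial()))$coefficients
  }
  data$y - plogis(drop(X %*% coefs))
}

# k x M standardized candidate means for a data set
candidateMu0 <- function(candidates, doses) shapeMatrix(candidates, doses)

#' Model-based max-contrast statistic S1
#'
#' Fits the dose-intercept GLM, forms population-average group means
#' `muHat` with covariance `S`, and returns
#' `max_m c_m' muHat / sqrt(c_m' S c_m)` over the candidate contrasts.
#'
#' @param data a [trialData()].
#' @param candidates a [candidateSet()].
#' @param family `"binomial"` or `"gaussian"`.
#' @param method `"mle"` or `"firth"`.
#' @param recomputeContrasts if `TRUE`, derive the contrasts from the
#'   estimated covariance `S` of this fit; the default (`FALSE`) fixes them
#'   at design stage from the realized group sizes, the usual
#'   pre-specification of a multiple-contrast test.
#' @return the statistic (a scalar).
#' @export
statisticS1 <- function(data, candidates, family = c("binomial", "gaussian"),
                        method = c("mle", "firth"),
                        recomputeContrasts = FALSE) {
  family <- match.arg(family)
  method <- match.arg(method)
  mu0 <- candidateMu0(candidates, data$doses)
  Cfix <- fixedContrastMatrix(candidates, data, recomputeContrasts)
  Z <- matrix(data$z, nrow = 1)
  drop(s1_stat_batch_cpp(Z, data$y, covMatrix(data), mu0,
                         familyCode(family), methodCode(method),
                         recomputeContrasts, Cfix))
}

covMatrix <- function(data) {
  if (is.null(data$x)) matrix(0, data$n, 0) else as.matrix(data$x)
}

fixedContrastMatrix <- function(candidates, data, recompute) {
  if (recompute) return(matrix(0, data$k, length(candidates)))
  cnt <- armCounts(data$z, data$k)
  if (any(cnt == 0)) return(matrix(0, data$k, length(candidates)))
  t(unclass(contrastsFromGroupSizes(candidates, data$doses, cnt)))
}

#' Residual-based max-contrast statistic S2
#'
#' Computes, from the residuals of a covariate-only fit, the statistic
#' `max_m c_m' rbar_Z / sqrt(sum_j c_{m,j}^2 s_j^2 / n_j)` where `rbar_Z`
#' are per-arm residual means, `s_j^2` the within-arm empirical variances,
#' and the contrasts come from the realized per-arm sample sizes.
#'
#' @param residuals residual vector (see Details), or a [trialData()] in
#'   which case the covariate-only fit is performed internally.
#' @param z assignment sequence (ignored when `residuals` is a
#'   `trialData`).
#' @param candidates a [candidateSet()].
#' @param doses dose grid (ignored when `residuals` is a `trialData`).
#' @param family,method family and estimator of the covariate-only fit
#'   when `residuals` is a `trialData`.
#' @return the statistic (a scalar).
#' @export
statisticS2 <- function(residuals, z = NULL, candidates, doses = NULL,
                        family = "binomial", method = "mle") {
  if (inherits(residuals, "trialData")) {
    data <- residuals
    z <- data$z
    doses <- data$doses
    residuals <- residualFit(data, family, method)
  }
  mu0 <- candidateMu0(candidates, doses)
  k <- length(doses)
  cnt <- armCounts(z, k)
  Cfix <- if (all(cnt > 0))
    t(unclass(contrastsFromGroupSizes(candidates, doses, cnt)))
  else matrix(0, k, length(candidates))
  Z <- matrix(as.integer(z), nrow = 1)
  drop(s2_stat_batch_cpp(Z, residuals, mu0, any(cnt == 0), Cfix))
}

#' Population-based generalized MCP-Mod test
#'
#' Refers the observed max-contrast statistic S1 to the distribution of the
#' maximum of M correlated standard normals, with correlation
#' `R_{mm'} = c_m' S c_{m'} / sqrt(c_m' S c_m * c_{m'}' S c_{m'})`; the
#' one-sided p-value is computed by multivariate-normal tail integration.
#'
#' @inheritParams statisticS1
#' @return list with `statistic`, `pValue`, `contrasts`, `fit`.
#' @export
populationTest <- function(data, candidates,
                           family = c("binomial", "gaussian"),
                           method = c("mle", "firth")) {
  family <- match.arg(family)
  method <- match.arg(method)
  fit <- fitGlm(data, family, method)
  S <- fit$S
  C <- optimalContrasts(candidates, data$doses, regularizeCov(S))
  Cm <- t(unclass(C))                      # k x M
  num <- drop(crossprod(Cm, fit$muHat))
  den <- sqrt(pmax(diag(crossprod(Cm, S %*% Cm)), 1e-300))
  tstats <- num / den
  tmax <- max(tstats)
  B <- S %*% Cm
  R <- crossprod(Cm, B) / tcrossprod(den)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  p <- 1 - maxNormalCdf(tmax, R)
  list(statistic = tmax, pValue = max(0, min(1, p)), tStats = tstats,
       contrasts = C, fit = fit)
}

# P(max of M correlated standard normals <= t).  The quasi-Monte-Carlo
# integration runs under a fixed local RNG state so p-values are
# deterministic and the caller's stream is untouched.
maxNormalCdf <- function(t, R) {
  M <- nrow(R)
  if (!is.finite(t)) return(as.numeric(t > 0))
  if (M == 1) return(pnorm(t))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(190748)
  as.numeric(mvtnorm::pmvnorm(lower = rep(-Inf, M), upper = rep(t, M),
                              corr = R,
                              algorithm = mvtnorm::GenzBretz(abseps = 1e-5,
                                                             maxpts = 50000)))
}

# guard against numerically singular estimated covariances (separated ML
# fits): add a tiny ridge so contrast construction stays defined
regularizeCov <- function(S, eps = 1e-10) {
  d <- mean(diag(S))
  if (!is.finite(d) || d <= 0) d <- 1
  S + diag(eps * d, nrow(S))
}

#' Monte-Carlo randomization test
#'
#' Holds the observed outcomes (and, for the residual-based statistic, the
#' covariate-only fit) fixed, redraws `nrand` assignment sequences from the
#' trial's randomization distribution, recomputes the statistic for each
#' draw, and estimates the one-sided p-value as
#' `p = #(S(Z_l) >= S(Z_obs)) / nrand` (ties count toward the numerator; no
#' +1 correction unless `correction = TRUE`).
#'
#' @param data a [trialData()].
#' @param proc the `randProcedure` that generated `data$z`.
#' @param statistic `"S1"` (model-based, refit per draw) or `"S2"`
#'   (residual-based, one covariate-only fit).
#' @param method estimator: `"mle"` or `"firth"`.
#' @param family `"binomial"` or `"gaussian"`.
#' @param candidates a [candidateSet()].
#' @param nrand number of re-randomizations.
#' @param seed optional integer seed.
#' @param recomputeContrasts for S1: re-derive contrasts from each draw's
#'   estimated covariance instead of fixing them at design stage from the
#'   group sizes (default `FALSE`; fixed design-stage contrasts are the
#'   usual pre-specification and are what the published operating
#'   characteristics reflect).
#' @param correction add-one p-value `(count + 1)/(nrand + 1)` instead of
#'   the plain Monte-Carlo estimator (default `FALSE`).
#' @return object of class `randTestResult`.
#' @export
randomizationTest <- function(data, proc, statistic = c("S1", "S2"),
                              method = c("mle", "firth"),
                              family = c("binomial", "gaussian"),
                              candidates, nrand = 1000, seed = NULL,
                              recomputeContrasts = FALSE,
                              correction = FALSE) {
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  family <- match.arg(family)
  stopifnot(inherits(proc, "randProcedure"), nrand >= 1)
  if (proc$n != data$n) stop("procedure and data sample sizes differ")
  if (!is.null(seed)) set.seed(seed)
  mu0 <- candidateMu0(candidates, data$doses)
  Zdraws <- sampleSequence(proc, nseq = nrand)
  if (nrand == 1) Zdraws <- matrix(Zdraws, nrow = 1)
  Zall <- rbind(matrix(data$z, nrow = 1), Zdraws)
  fixedCounts <- proc$kind != "CR"

  if (statistic == "S1") {
    Cfix <- fixedContrastMatrix(candidates, data, recomputeContrasts)
    stats <- s1_stat_batch_cpp(Zall, data$y, covMatrix(data), mu0,
                               familyCode(family), methodCode(method),
                               recomputeContrasts, Cfix)
  } else {
    r <- residualFit(data, family, method)
    cnt <- armCounts(data$z, data$k)
    Cfix <- if (fixedCounts && all(cnt > 0))
      t(unclass(contrastsFromGroupSizes(candidates, data$doses, cnt)))
    else matrix(0, data$k, length(candidates))
    stats <- s2_stat_batch_cpp(Zall, r, mu0, !fixedCounts, Cfix)
  }
  obs <- stats[1]
  draws <- stats[-1]
  count <- sum(draws >= obs)
  p <- if (correction) (count + 1) / (nrand + 1) else count / nrand
  structure(list(statistic = obs, nullDraws = draws, pValue = p,
                 nrand = nrand, statisticName = statistic, method = method,
                 family = family, procedure = proc$kind,
                 referenceSetSize = referenceSetSize(proc),
                 correction = correction),
            class = "randTestResult")
}

#' @export
print.randTestResult <- function(x, ...) {
  cat("Monte-Carlo randomization test (", x$statisticName, ", ", x$method,
      ", ", x$procedure, ")\n", sep = "")
  cat(sprintf("  observed statistic = %.4f, nrand = %d, p-value = %.4g\n",
              x$statistic, x$nrand, x$pValue))
  cat("  reference set size:", format(x$referenceSetSize), "\n")
  invisible(x)
}

#' Run one of the five named tests
#'
#' Dispatch by the test numbering used throughout the simulation harness:
#' \describe{
#'   \item{1}{population-based generalized MCP-Mod test (ML)}
#'   \item{2}{randomization test, model-based statistic S1, ML}
#'   \item{3}{randomization test, residual-based statistic S2, ML}
#'   \item{4}{randomization test, S1, Firth-penalized ML}
#'   \item{5}{randomization test, S2, Firth-penalized ML}
#' }
#'
#' @param testId integer 1-5.
#' @param data a [trialData()].
#' @param proc the trial's `randProcedure` (unused for test 1).
#' @param candidates a [candidateSet()].
#' @param family `"binomial"` or `"gaussian"`.
#' @param nrand re-randomizations for tests 2-5.
#' @param seed optional seed for the Monte-Carlo draws.
#' @return the one-sided p-value (scalar).
#' @export
runNamedTest <- function(testId, data, proc, candidates,
                         family = "binomial", nrand = 1000, seed = NULL) {
  if (!testId %in% 1:5) stop("unknown test id: ", testId)
  if (testId == 1)
    return(populationTest(data, candidates, family, "mle")$pValue)
  cfg <- list(`2` = c("S1", "mle"), `3` = c("S2", "mle"),
              `4` = c("S1", "firth"), `5` = c("S2", "firth"))[[
                as.character(testId)]]
  randomizationTest(data, proc, statistic = cfg[1], method = cfg[2],
                    family = family, candidates = candidates, nrand = nrand,
                    seed = seed)$pValue
}
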