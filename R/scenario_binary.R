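# Synthetic binary-endpoint Phase II trial generator: Emax truth on the
# logit scale, one standard-normal covariate with coefficient 0.6, optional
# linear time trend with probability clipping, and the complete-separation
# frequency experiment.

#' Binary trial scenario
#'
#' Describes one data-generating scenario of the binary-endpoint simulation
#' study: an Emax dose-response truth on the logit scale calibrated through
#' (`p0`, `pTop`), a standard-normal covariate entering the linear
#' predictor with coefficient `covariateCoef`, and an optional linear time
#' trend added on the probability scale.
#'
#' @param proc a `randProcedure` (defines doses and n).
#' @param p0 placebo success probability at covariate 0.
#' @param pTop top-dose success probability at covariate 0.
#' @param theta2 ED50 of the Emax truth.
#' @param covariateCoef logit-scale covariate coefficient (0.6 gives the
#'   covariate a discriminative AUC of about 0.66 in the control group).
#' @param timeTrend add the linear ramp `t_i = 0.4 i/n - 0.2` on the
#'   probability scale, clipped to `[0, 1]`.
#' @return object of class `binaryScenario`.
#' @examples
#' proc <- permutedBlocks(c(0, 10, 25, 100), c(1, 2, 2, 2), 7)
#' scen <- binaryScenario(proc, p0 = 0.2, pTop = 0.8)
#' trial <- generateTrial(scen, seed = 1)
#' @export
binaryScenario <- function(proc, p0 = 0.2, pTop = 0.8, theta2 = 10,
                           covariateCoef = 0.6, timeTrend = FALSE) {
  stopifnot(inherits(proc, "randProcedure"))
  if (p0 <= 0 || p0 >= 1 || pTop <= 0 || pTop >= 1)
    stop("success probabilities must lie strictly in (0,1)")
  truth <- calibrateEmaxTruth(p0, pTop, theta2,
                              topDose = max(proc$doses))
  structure(list(proc = proc, p0 = p0, pTop = pTop, theta2 = theta2,
                 covariateCoef = covariateCoef, timeTrend = timeTrend,
                 truth = truth),
            class = "binaryScenario")
}

#' @export
print.binaryScenario <- function(x, ...) {
  cat("Binary scenario: n =", x$proc$n, x$proc$kind,
      "| p0 =", x$p0, "pTop =", x$pTop,
      "| covariate coef =", x$covariateCoef,
      "| time trend:", x$timeTrend, "\n")
  invisible(x)
}

#' Apply the linear time trend to success probabilities
#'
#' `gamma_i^t = clip(gamma_i + 0.4 i/n - 0.2, 0, 1)` with patients indexed
#' by enrollment order.
#'
#' @param gamma vector of success probabilities in enrollment order.
#' @return the trend-adjusted probabilities.
#' @export
applyTimeTrend <- function(gamma) {
  n <- length(gamma)
  t <- 0.4 * seq_len(n) / n - 0.2
  pmin(pmax(gamma + t, 0), 1)
}

#' Generate one synthetic binary trial
#'
#' Draws `Z` from the scenario's randomization procedure, covariates
#' `x_i ~ N(0,1)`, forms `eta_i = f(dose(Z_i)) + covariateCoef * x_i` under
#' the Emax truth, converts to success probabilities with the inverse
#' logit, applies the time trend if enabled, and draws Bernoulli outcomes.
#'
#' @param scen a [binaryScenario()].
#' @param seed optional integer seed.
#' @return a [trialData()] with attribute `"gamma"` (the individual success
#'   probabilities actually used).
#' @export
generateTrial <- function(scen, seed = NULL) {
  stopifnot(inherits(scen, "binaryScenario"))
  if (!is.null(seed)) set.seed(seed)
  proc <- scen$proc
  z <- sampleSequence(proc)
  x <- rnorm(proc$n)
  eta <- evaluateShape(scen$truth, proc$doses[z]) + scen$covariateCoef * x
  gamma <- plogis(eta)
  if (scen$timeTrend) gamma <- applyTimeTrend(gamma)
  y <- rbinom(proc$n, 1, gamma)
  out <- trialData(z, y, matrix(x, ncol = 1, dimnames = list(NULL, "x")),
                   proc$doses)
  attr(out, "gamma") <- gamma
  out
}

#' Discriminative strength (AUC) of the covariate in one arm
#'
#' Under `y ~ Bernoulli(invLogit(logit(p0) + coef * x))` with
#' `x ~ N(0, 1)`, computes `AUC = P(X1 > X0)` where `X1`, `X0` are the
#' covariate conditioned on success and failure.
#'
#' @param coef logit-scale covariate coefficient.
#' @param p0 success probability at covariate 0.
#' @param method `"quadrature"` (default; nested numerical integration) or
#'   `"mc"` (Monte Carlo).
#' @param nmc Monte-Carlo sample size when `method = "mc"`.
#' @return the AUC, a number in (0, 1); 0.5 when `coef = 0`.
#' @export
covariateAuc <- function(coef = 0.6, p0 = 0.2, method = c("quadrature", "mc"),
                         nmc = 1e6) {
  method <- match.arg(method)
  eta0 <- qlogis(p0)
  if (method == "mc") {
    x <- rnorm(nmc)
    y <- rbinom(nmc, 1, plogis(eta0 + coef * x))
    x1 <- x[y == 1]; x0 <- x[y == 0]
    ord <- rank(c(x1, x0), ties.method = "average")
    return((sum(ord[seq_along(x1)]) -
              length(x1) * (length(x1) + 1) / 2) /
             (as.numeric(length(x1)) * length(x0)))
  }
  # P(y=1), conditional densities f1 ~ phi(x) p(x)/P1, f0 ~ phi(x)(1-p(x))/P0
  px <- function(x) plogis(eta0 + coef * x)
  p1 <- integrate(function(x) dnorm(x) * px(x), -Inf, Inf,
                  rel.tol = 1e-10)$value
  # F0 at t: P(X <= t | y = 0)
  F0 <- function(t) integrate(function(x) dnorm(x) * (1 - px(x)), -Inf, t,
                              rel.tol = 1e-9)$value / (1 - p1)
  integrate(Vectorize(function(x) dnorm(x) * px(x) / p1 * F0(x)),
            -Inf, Inf, rel.tol = 1e-7)$value
}

#' Frequency of separation under a null scenario
#'
#' Generates `nsim` trials under the given (typically null, `pTop = p0`)
#' scenario and classifies each trial's dose-intercept + covariate logistic
#' design with the exact linear-programming separation machinery. Three
#' events can be tallied:
#' \describe{
#'   \item{placebo}{the MLE of the placebo-arm intercept does not exist
#'     (LP direction-of-recession check, see [coefMleInfinite()]). The
#'     placebo arm is the smallest under unequal allocation, so this is
#'     the dominant way the logistic fit degenerates in small trials; its
#'     frequency is about 18\% at n = 49 and 3.4\% at n = 98 under the
#'     null trial scenario, vanishing at n = 490.}
#'   \item{complete}{strict complete separation of the whole design (a
#'     hyperplane classifies every outcome without error) — very rare once
#'     a continuous covariate is present.}
#'   \item{any}{complete or quasicomplete separation, i.e. the full MLE
#'     fails to exist in any direction (for example any outcome-pure
#'     arm).}
#' }
#'
#' @param scen a [binaryScenario()].
#' @param nsim number of simulated trials.
#' @param seed optional seed.
#' @param event which event to count (see Details); default `"placebo"`.
#' @return the frequency of the event, with attribute `nsim`.
#' @export
separationFrequency <- function(scen, nsim = 10000, seed = NULL,
                                event = c("placebo", "complete", "any")) {
  event <- match.arg(event)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (s in seq_len(nsim)) {
    trial <- generateTrial(scen)
    hit <- switch(event,
      placebo = {
        ypl <- trial$y[trial$z == 1]
        # outcome-pure placebo arm is the canonical case; the LP decides
        # the remainder exactly
        if (all(ypl == 0) || all(ypl == 1)) TRUE
        else coefMleInfinite(trial, coefIndex = 1)
      },
      complete = detectSeparation(trial, completeOnly = TRUE) == "complete",
      any = detectSeparation(trial) != "none")
    if (hit) hits <- hits + 1L
  }
  structure(hits / nsim, nsim = nsim, event = event)
}
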