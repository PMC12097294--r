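# Candidate dose-response shape functions on the linear-predictor (logit or
# identity) scale, and calibration of the Emax data-generating truth.

#' Validate a dose grid
#'
#' A dose grid is a strictly increasing numeric vector of nonnegative doses
#' whose first element is the placebo dose 0.
#'
#' @param doses numeric vector of doses (mg or other units), placebo first.
#' @return the validated dose vector, invisibly usable as-is.
#' @export
doseGrid <- function(doses) {
  doses <- as.numeric(doses)
  if (length(doses) < 2) stop("a dose grid needs at least two doses")
  if (doses[1] != 0) stop("the first dose must be the placebo dose 0")
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing")
  doses
}

#' Dose-response shape function
#'
#' Construct a candidate shape on the linear-predictor scale. Families:
#' \describe{
#'   \item{emax}{`theta0 + theta1 * x / (theta2 + x)`}
#'   \item{sigmoid_emax}{`theta0 + theta1 * x^h / (theta2^h + x^h)`}
#'   \item{beta}{`theta0 + theta1 * B(delta1, delta2) * (x/scal)^delta1 *
#'     (1 - x/scal)^delta2` with `B(a, b) = (a+b)^(a+b) / (a^a * b^b)`, so
#'     the bracketed term attains maximum 1 at `x = scal * delta1 /
#'     (delta1 + delta2)`}
#'   \item{linear}{`theta0 + theta1 * x`}
#'   \item{log_linear}{`theta0 + theta1 * log(x + c)`; the offset `c`
#'     (default 1) keeps the shape finite at placebo}
#'   \item{flat}{`theta0` at every dose}
#' }
#'
#' @param family one of `"emax"`, `"sigmoid_emax"`, `"beta"`, `"linear"`,
#'   `"log_linear"`, `"flat"`.
#' @param theta0,theta1 location and scale parameters. Contrast construction
#'   is invariant to both, so unit defaults suffice for candidate sets.
#' @param theta2 ED50 (emax, sigmoid_emax).
#' @param h Hill coefficient (sigmoid_emax).
#' @param delta1,delta2 beta-model exponents.
#' @param scal dose-scaling constant of the beta model (its domain is
#'   `[0, scal]`).
#' @param offset log-linear offset `c`.
#' @return an object of class `drShape`.
#' @examples
#' sh <- drShape("emax", theta0 = -1.386, theta1 = 3.05, theta2 = 10)
#' evaluateShape(sh, c(0, 10, 25, 100))
#' @export
drShape <- function(family = c("emax", "sigmoid_emax", "beta", "linear",
                               "log_linear", "flat"),
                    theta0 = 0, theta1 = 1, theta2 = NULL, h = NULL,
                    delta1 = NULL, delta2 = NULL, scal = 120, offset = 1) {
  family <- match.arg(family)
  if (family %in% c("emax", "sigmoid_emax")) {
    if (is.null(theta2) || theta2 <= 0) stop("theta2 > 0 required")
  }
  if (family == "sigmoid_emax" && (is.null(h) || h <= 0))
    stop("Hill coefficient h > 0 required")
  if (family == "beta") {
    if (is.null(delta1) || is.null(delta2) || delta1 <= 0 || delta2 <= 0)
      stop("delta1, delta2 > 0 required")
    if (scal <= 0) stop("scal > 0 required")
  }
  structure(list(family = family, theta0 = theta0, theta1 = theta1,
                 theta2 = theta2, h = h, delta1 = delta1, delta2 = delta2,
                 scal = scal, offset = offset),
            class = "drShape")
}

#' Evaluate a shape function at doses
#'
#' @param shape a [drShape()].
#' @param dose numeric vector of nonnegative doses; for the beta family the
#'   doses must not exceed the scaling constant `scal`.
#' @return linear-predictor values, same length as `dose`.
#' @export
evaluateShape <- function(shape, dose) {
  stopifnot(inherits(shape, "drShape"))
  dose <- as.numeric(dose)
  if (any(dose < 0)) stop("doses must be nonnegative")
  with(shape, switch(family,
    emax = theta0 + theta1 * dose / (theta2 + dose),
    sigmoid_emax = theta0 + theta1 * dose^h / (theta2^h + dose^h),
    beta = {
      if (any(dose > scal))
        stop("beta shape: dose exceeds the scaling constant scal = ", scal)
      u <- dose / scal
      bconst <- (delta1 + delta2)^(delta1 + delta2) /
        (delta1^delta1 * delta2^delta2)
      theta0 + theta1 * bconst * u^delta1 * (1 - u)^delta2
    },
    linear = theta0 + theta1 * dose,
    log_linear = theta0 + theta1 * log(dose + offset),
    flat = rep(theta0, length(dose))
  ))
}

#' @export
print.drShape <- function(x, ...) {
  pars <- x[!vapply(x, is.null, logical(1))]
  pars <- pars[setdiff(names(pars), "family")]
  cat("<drShape ", x$family, "> ",
      paste(names(pars), unlist(pars), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Candidate model set
#'
#' A named collection of dose-response shapes used to build the optimal
#' contrasts of the multiple-contrast test.
#'
#' @param ... named [drShape()] objects (or a single named list of them).
#' @return object of class `candidateSet`.
#' @export
candidateSet <- function(...) {
  models <- list(...)
  if (length(models) == 1 && is.list(models[[1]]) &&
      !inherits(models[[1]], "drShape"))
    models <- models[[1]]
  if (length(models) < 1) stop("at least one candidate model is required")
  if (is.null(names(models)) || any(names(models) == "") ||
      anyDuplicated(names(models)))
    stop("candidate models must have unique names")
  if (!all(vapply(models, inherits, logical(1), "drShape")))
    stop("all candidates must be drShape objects")
  structure(list(models = models), class = "candidateSet")
}

#' @export
print.candidateSet <- function(x, ...) {
  cat("Candidate model set with", length(x$models), "shapes:\n")
  for (nm in names(x$models))
    cat(sprintf("  %-12s %s\n", nm, x$models[[nm]]$family))
  invisible(x)
}

#' @export
length.candidateSet <- function(x) length(x$models)

#' Default candidate set for the binary-endpoint trial
#'
#' Five shapes spanning a range of plausible dose-response relationships on
#' a placebo + (10, 25, 100) mg grid: two Emax models with small and
#' moderate ED50 (the first matching the simulation ground truth), two
#' sigmoid Emax models with different steepness, and one non-monotone beta
#' model. Contrasts are invariant to the location/scale parameters, so all
#' shapes are standardized (`theta0 = 0`, `theta1 = 1`).
#'
#' @param scal beta-model scaling constant (default 120, suited to a top
#'   dose of 100).
#' @return a [candidateSet()].
#' @export
defaultCandidateSet <- function(scal = 120) {
  candidateSet(
    emax1 = drShape("emax", theta2 = 10),
    emax2 = drShape("emax", theta2 = 35),
    sigEmax1 = drShape("sigmoid_emax", theta2 = 25, h = 3),
    sigEmax2 = drShape("sigmoid_emax", theta2 = 60, h = 5),
    betaMod = drShape("beta", delta1 = 1.5, delta2 = 3, scal = scal)
  )
}

#' Candidate set for the continuous-endpoint potential-outcomes study
#'
#' Linear, log-linear, Emax and sigmoid Emax shapes on the
#' (0, 100, 200, 400, 1000) microgram grid. The flat shape enters the
#' continuous study only as a data-generating possibility; it admits no
#' contrast and is therefore not part of the candidate set.
#'
#' @return a [candidateSet()].
#' @export
continuousCandidateSet <- function() {
  candidateSet(
    linear = drShape("linear"),
    logLinear = drShape("log_linear"),
    emax = drShape("emax", theta2 = 150),
    sigEmax = drShape("sigmoid_emax", theta2 = 300, h = 4)
  )
}

#' Matrix of standardized candidate means on a dose grid
#'
#' @param candidates a [candidateSet()].
#' @param doses a dose grid.
#' @return k x M matrix; column m is candidate m evaluated at the doses.
#' @export
shapeMatrix <- function(candidates, doses) {
  stopifnot(inherits(candidates, "candidateSet"))
  doses <- doseGrid(doses)
  vapply(candidates$models, evaluateShape, numeric(length(doses)),
         dose = doses)
}

#' Inverse logit
#'
#' @param eta linear predictor values.
#' @return probabilities in (0, 1); `invLogit(0) = 0.5`.
#' @export
invLogit <- function(eta) plogis(eta)

#' Logit
#' @param p probabilities strictly inside (0, 1).
#' @return log-odds.
#' @export
logit <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("probabilities must lie strictly in (0,1)")
  qlogis(p)
}

#' Calibrate the Emax data-generating truth on the logit scale
#'
#' Solves, in closed form, for the Emax model passing through a placebo
#' success probability `p0` and a top-dose success probability `pTop`:
#' `theta0 = logit(p0)` and
#' `theta1 = (logit(pTop) - logit(p0)) * (theta2 + topDose) / topDose`.
#'
#' @param p0 placebo success probability, in (0, 1).
#' @param pTop success probability at the top dose, in (0, 1).
#' @param theta2 ED50 of the Emax truth (default 10).
#' @param topDose the highest dose (default 100).
#' @return an Emax [drShape()].
#' @examples
#' tr <- calibrateEmaxTruth(0.2, 0.8)
#' c(tr$theta0, tr$theta1)  # approximately -1.39 and 3.05
#' @export
calibrateEmaxTruth <- function(p0, pTop, theta2 = 10, topDose = 100) {
  if (p0 <= 0 || p0 >= 1 || pTop <= 0 || pTop >= 1)
    stop("p0 and pTop must lie strictly in (0,1)")
  stopifnot(theta2 > 0, topDose > 0)
  theta0 <- logit(p0)
  theta1 <- (logit(pTop) - logit(p0)) * (theta2 + topDose) / topDose
  drShape("emax", theta0 = theta0, theta1 = theta1, theta2 = theta2)
}

#' Shape evaluation table
#'
#' Tabulates linear predictors and (for the logit scale) success
#' probabilities across a dose grid, suitable for CSV export.
#'
#' @param candidates a [candidateSet()] or single [drShape()].
#' @param doses dose grid.
#' @param file optional path; when given the table is written as CSV.
#' @return data.frame with columns model, dose, linpred, prob.
#' @export
shapeTable <- function(candidates, doses, file = NULL) {
  if (inherits(candidates, "drShape"))
    candidates <- candidateSet(shape = candidates)
  mu <- shapeMatrix(candidates, doses)
  out <- data.frame(
    model = rep(colnames(mu), each = nrow(mu)),
    dose = rep(doses, ncol(mu)),
    linpred = as.vector(mu),
    prob = as.vector(plogis(mu))
  )
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
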