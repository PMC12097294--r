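# Potential-outcomes engine for a continuous endpoint: each patient gets an
# individual dose-response curve evaluated at every dose, generated either
# pseudo-randomly or by inverse-CDF mapping of a Richtmyer low-discrepancy
# sequence.  A realized trial observes one column per patient, selected by
# the assignment sequence.

#' Richtmyer low-discrepancy sequence
#'
#' Point l, dimension j is `frac(l * sqrt(p_j))` for the j-th prime `p_j`.
#'
#' @param npoints number of points.
#' @param dim dimension (at most 100).
#' @return `npoints x dim` matrix with entries in (0, 1).
#' @examples
#' richtmyerSequence(3, 1)  # frac(sqrt(2)), frac(2 sqrt(2)), frac(3 sqrt(2))
#' @export
richtmyerSequence <- function(npoints, dim) {
  primes <- primes_upto(600)
  if (dim > length(primes))
    stop("dimension ", dim, " exceeds the available prime table (",
         length(primes), ")")
  l <- seq_len(npoints)
  out <- outer(l, sqrt(primes[seq_len(dim)]))
  out - floor(out)
}

#' Individual dose-response curve model (continuous endpoint)
#'
#' A synthetic stand-in generating individual Emax dose-response curves for
#' a visual-acuity-like endpoint (ETDRS letter score, 0-70): the month-12
#' outcome of patient i at dose d is
#' `clip(intercept + baselineSlope * baseline_i + b0_i +
#'       (emax + b1_i) * d / (ed50 + d) + noise, 0, 70)`
#' with between-patient random effects `b0 ~ N(0, sdE0^2)`,
#' `b1 ~ N(0, sdEmax^2)`, residual noise per patient-dose cell, and
#' baselines drawn from `N(baselineMean, baselineSd^2)` truncated to
#' `[5, 65]`.
#'
#' @param e0 population intercept of the month-12 score beyond the baseline
#'   carry-over (letters).
#' @param baselineSlope carry-over of the baseline score into the month-12
#'   score.
#' @param emax population maximal drug effect (letters).
#' @param ed50 dose giving half the maximal effect (micrograms).
#' @param sdE0,sdEmax between-patient random-effect standard deviations.
#' @param sdNoise residual standard deviation per patient-dose outcome.
#' @param baselineMean,baselineSd baseline score distribution.
#' @param doses dose grid in micrograms.
#' @return object of class `curveModel`.
#' @export
curveModel <- function(e0 = 5, baselineSlope = 0.9, emax = 12, ed50 = 150,
                       sdE0 = 6, sdEmax = 5, sdNoise = 4,
                       baselineMean = 35, baselineSd = 10,
                       doses = c(0, 100, 200, 400, 1000)) {
  stopifnot(ed50 > 0, sdE0 >= 0, sdEmax >= 0, sdNoise >= 0, baselineSd >= 0)
  structure(list(e0 = e0, baselineSlope = baselineSlope, emax = emax,
                 ed50 = ed50, sdE0 = sdE0, sdEmax = sdEmax,
                 sdNoise = sdNoise, baselineMean = baselineMean,
                 baselineSd = baselineSd, doses = doseGrid(doses)),
            class = "curveModel")
}

# standard normal draws from uniforms, truncated-normal helper
truncNorm <- function(u, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + u * (phi - plo), mean, sd)
}

#' Generate a potential-outcomes table
#'
#' Draws per-patient curve parameters and evaluates the individual curve at
#' every dose, so each patient carries an outcome for every treatment. With
#' `quasirandom = TRUE` the underlying uniforms come from a Richtmyer
#' sequence (dimensions: baseline, two random effects, one noise term per
#' dose), mapped through inverse CDFs; otherwise they are pseudo-random.
#'
#' @param model a [curveModel()].
#' @param n number of patients.
#' @param quasirandom use the Richtmyer sequence (default `TRUE`).
#' @param seed optional seed (used for the pseudo-random path and for the
#'   random offset of the quasi-random sequence start).
#' @return object of class `poTable`: list with `outcomes` (n x k matrix),
#'   `baseline` (length n), `doses`.
#' @export
generatePotentialOutcomes <- function(model, n = 50, quasirandom = TRUE,
                                      seed = NULL) {
  stopifnot(inherits(model, "curveModel"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  k <- length(model$doses)
  dim <- 3 + k
  U <- if (quasirandom) richtmyerSequence(n, dim)
       else matrix(runif(n * dim), n, dim)
  # guard the inverse CDF against exact 0/1
  U <- pmin(pmax(U, 1e-12), 1 - 1e-12)
  baseline <- truncNorm(U[, 1], model$baselineMean, model$baselineSd, 5, 65)
  b0 <- qnorm(U[, 2], 0, model$sdE0)
  b1 <- qnorm(U[, 3], 0, model$sdEmax)
  effect <- outer(model$emax + b1, model$doses / (model$ed50 + model$doses))
  noise <- qnorm(U[, 3 + seq_len(k), drop = FALSE], 0, model$sdNoise)
  y <- model$e0 + model$baselineSlope * baseline + b0 + effect + noise
  y <- pmin(pmax(y, 0), 70)
  colnames(y) <- paste0("d", model$doses)
  structure(list(outcomes = y, baseline = baseline, doses = model$doses,
                 n = n),
            class = "poTable")
}

#' @export
print.poTable <- function(x, ...) {
  cat("Potential-outcomes table:", x$n, "patients x", length(x$doses),
      "doses\n")
  cat("  mean curve:", paste(sprintf("%.1f", colMeans(x$outcomes)),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Derive the three study scenarios from a potential-outcomes table
#'
#' Scenario 1 leaves the table unchanged. Scenario 2 reorders patients by
#' ascending baseline, so enrollment order correlates with health (a
#' positive time trend). Scenario 3 imposes the sharp null: every patient's
#' outcome under every dose is replaced by their placebo outcome, making
#' observed outcomes independent of treatment by construction.
#'
#' @param table a `poTable`.
#' @param scenarioId 1, 2 or 3.
#' @return a `poTable`.
#' @export
makeScenario <- function(table, scenarioId) {
  stopifnot(inherits(table, "poTable"))
  if (!scenarioId %in% 1:3) stop("unknown scenario id: ", scenarioId)
  if (scenarioId == 1) return(table)
  if (scenarioId == 2) {
    ord <- order(table$baseline)
    table$outcomes <- table$outcomes[ord, , drop = FALSE]
    table$baseline <- table$baseline[ord]
    return(table)
  }
  table$outcomes <- matrix(table$outcomes[, 1], table$n,
                           length(table$doses),
                           dimnames = dimnames(table$outcomes))
  table
}

#' Read / write a potential-outcomes table as CSV
#'
#' Columns: patient, baseline, one column per dose.
#' @param table a `poTable`.
#' @param file path.
#' @return the data.frame written (write) or a `poTable` (read).
#' @export
writePoTable <- function(table, file) {
  df <- data.frame(patient = seq_len(table$n), baseline = table$baseline,
                   table$outcomes, check.names = FALSE)
  write.csv(df, file, row.names = FALSE)
  invisible(df)
}

#' @rdname writePoTable
#' @param doses dose grid of the table being read.
#' @export
readPoTable <- function(file, doses) {
  df <- read.csv(file, check.names = FALSE)
  y <- as.matrix(df[paste0("d", doses)])
  structure(list(outcomes = unname(y) + 0, baseline = df$baseline,
                 doses = doseGrid(doses), n = nrow(df)),
            class = "poTable")
}

#' Simulate one continuous-endpoint trial from a potential-outcomes table
#'
#' Draws an assignment sequence, reveals for each patient the potential
#' outcome of their assigned dose, and runs the requested gaussian-family
#' test (baseline as covariate when `withCovariate`).
#'
#' @param table a `poTable` (n patients).
#' @param proc a `randProcedure` with matching n and doses.
#' @param withCovariate include the baseline as covariate.
#' @param test `"randomization"` (residual-based statistic by default) or
#'   `"population"`.
#' @param statistic statistic for the randomization test (`"S2"` default,
#'   or `"S1"`).
#' @param candidates candidate set (default [continuousCandidateSet()]).
#' @param nrand re-randomizations for the randomization test.
#' @param seed optional seed.
#' @return the one-sided p-value.
#' @export
simulateContinuousTrial <- function(table, proc, withCovariate = TRUE,
                                    test = c("randomization", "population"),
                                    statistic = c("S2", "S1"),
                                    candidates = continuousCandidateSet(),
                                    nrand = 1000, seed = NULL) {
  test <- match.arg(test)
  statistic <- match.arg(statistic)
  stopifnot(inherits(table, "poTable"), proc$n == table$n)
  if (!is.null(seed)) set.seed(seed)
  z <- sampleSequence(proc)
  y <- table$outcomes[cbind(seq_len(table$n), z)]
  x <- if (withCovariate)
    matrix(table$baseline, ncol = 1, dimnames = list(NULL, "baseline"))
  else NULL
  data <- trialData(z, y, x, table$doses)
  if (test == "population")
    return(populationTest(data, candidates, family = "gaussian")$pValue)
  randomizationTest(data, proc, statistic = statistic, method = "mle",
                    family = "gaussian", candidates = candidates,
                    nrand = nrand)$pValue
}
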