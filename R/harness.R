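# Operating-characteristics harness: runs scenario grids of the binary
# simulation study, tabulating rejection rates (power / type-I error) for
# any subset of the five tests on shared simulated trials.

trialProcedure <- function(procKind, n, doses = c(0, 10, 25, 100),
                           ratio = c(1, 2, 2, 2), blockLength = 7) {
  switch(procKind,
    CR = completeRandomization(doses, n),
    RA = randomAllocation(doses, n * ratio / sum(ratio)),
    PBD = permutedBlocks(doses, ratio, n / blockLength),
    stop("unknown procedure kind: ", procKind))
}

#' The scenario grid of the binary simulation study
#'
#' Builds the data.frame of data-generating scenarios: sample sizes 49, 98
#' and 490 (1:2:2:2 allocation, blocks of length 7), randomization
#' procedures RA and PBD (plus CR at n = 490 only, where arm-emptiness is
#' no longer a practical concern), with and without the linear time trend.
#' Null scenarios set all arms to `p0`; alternatives use the top-dose
#' probabilities 0.8, 0.61 and 0.364 that equalize the asymptotic
#' population-based power across sample sizes.
#'
#' @param hypothesis `"alternative"` or `"null"`.
#' @return data.frame with columns n, proc, trend, p0, pTop.
#' @export
scenarioTable <- function(hypothesis = c("alternative", "null")) {
  hypothesis <- match.arg(hypothesis)
  pTop <- c(`49` = 0.8, `98` = 0.61, `490` = 0.364)
  rows <- list()
  for (n in c(49, 98, 490)) {
    procs <- if (n == 490) c("RA", "PBD", "CR") else c("RA", "PBD")
    for (proc in procs)
      for (trend in c(FALSE, TRUE))
        rows[[length(rows) + 1]] <- data.frame(
          n = n, proc = proc, trend = trend, p0 = 0.2,
          pTop = if (hypothesis == "null") 0.2
                 else unname(pTop[as.character(n)]))
  }
  do.call(rbind, rows)
}

#' Read / write a scenario grid as a YAML config
#'
#' @param scenarios data.frame as returned by [scenarioTable()].
#' @param file path.
#' @return the data.frame (read) or `invisible(file)` (write).
#' @export
writeScenarioConfig <- function(scenarios, file) {
  yaml::write_yaml(lapply(seq_len(nrow(scenarios)),
                          function(i) as.list(scenarios[i, ])), file)
  invisible(file)
}

#' @rdname writeScenarioConfig
#' @export
readScenarioConfig <- function(file) {
  lst <- yaml::read_yaml(file)
  do.call(rbind, lapply(lst, as.data.frame))
}

# deterministic per-replicate seeds below 2^31
deriveSeeds <- function(seed, nsim) {
  set.seed(seed)
  sample.int(2147483646L, nsim, replace = FALSE)
}

#' Simulate operating characteristics over a scenario grid
#'
#' For every scenario x test combination, simulates `nsim` trials, applies
#' the test, and tabulates the fraction of one-sided p-values below
#' `alpha`. Per-replicate seeds derive deterministically from the master
#' seed, and all requested tests see identical simulated trials, so results
#' are reproducible and comparable across tests.
#'
#' @param scenarios data.frame with columns n, proc, trend, p0, pTop (see
#'   [scenarioTable()]), or a YAML path readable by
#'   [readScenarioConfig()].
#' @param tests integer vector with elements in 1..5 (see
#'   [runNamedTest()]).
#' @param nsim simulated trials per scenario.
#' @param nrand re-randomizations per randomization test.
#' @param alpha one-sided significance level.
#' @param seed master seed.
#' @param candidates candidate set (default [defaultCandidateSet()]).
#' @param doses dose grid.
#' @param ratio allocation ratio.
#' @param blockLength PBD block length.
#' @return data.frame of class `ocTable`: one row per scenario x test with
#'   the rejection rate and its Monte-Carlo standard error.
#' @export
runGrid <- function(scenarios, tests = 1:5, nsim = 10000, nrand = 1000,
                    alpha = 0.1, seed = 1, candidates = defaultCandidateSet(),
                    doses = c(0, 10, 25, 100), ratio = c(1, 2, 2, 2),
                    blockLength = 7) {
  if (is.character(scenarios)) scenarios <- readScenarioConfig(scenarios)
  stopifnot(all(tests %in% 1:5), nsim >= 1)
  out <- list()
  for (s in seq_len(nrow(scenarios))) {
    sc <- scenarios[s, ]
    proc <- trialProcedure(sc$proc, sc$n, doses, ratio, blockLength)
    scen <- binaryScenario(proc, p0 = sc$p0, pTop = sc$pTop,
                           timeTrend = isTRUE(sc$trend))
    seeds <- deriveSeeds(seed + s - 1, nsim)
    rej <- matrix(0L, nsim, length(tests))
    for (r in seq_len(nsim)) {
      trial <- generateTrial(scen, seed = seeds[r])
      for (tix in seq_along(tests)) {
        p <- runNamedTest(tests[tix], trial, proc, candidates,
                          family = "binomial", nrand = nrand,
                          seed = (seeds[r] + tests[tix]) %% 2147483629)
        rej[r, tix] <- as.integer(p < alpha)
      }
    }
    rate <- colMeans(rej)
    out[[s]] <- data.frame(
      n = sc$n, proc = sc$proc, trend = sc$trend, p0 = sc$p0,
      pTop = sc$pTop, test = tests,
      hypothesis = if (sc$p0 == sc$pTop) "null" else "alternative",
      nsim = nsim, nrand = nrand, alpha = alpha,
      rejectionRate = rate,
      mcStandardError = sqrt(rate * (1 - rate) / nsim))
  }
  structure(do.call(rbind, out), class = c("ocTable", "data.frame"))
}

#' Format an operating-characteristics table
#'
#' Emits the familiar grid (sample size, procedure, trend, test, type-I
#' error or power in percent) with Monte-Carlo standard errors.
#'
#' @param results an `ocTable` from [runGrid()].
#' @param file optional CSV path.
#' @return data.frame, printed percentages rounded to 2 decimals.
#' @export
summarizeOC <- function(results, file = NULL) {
  if (nrow(results) == 0) stop("empty results table")
  out <- data.frame(
    n = results$n, proc = results$proc, trend = results$trend,
    test = results$test, hypothesis = results$hypothesis,
    ratePct = round(100 * results$rejectionRate, 2),
    mcSePct = round(100 * results$mcStandardError, 3))
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
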