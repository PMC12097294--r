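# Optimal contrast vectors for the multiple-contrast test.  For candidate
# mean vector mu0 on the dose grid and group-mean covariance S, the optimal
# contrast is proportional to
#   S^{-1} (mu0 - 1 * (1' S^{-1} mu0) / (1' S^{-1} 1)),
# which maximizes c' mu0 / sqrt(c' S c) among zero-sum (in the S^{-1}-inner
# product) vectors.  Canonical scaling: unit Euclidean norm, sign such that
# c' mu0 > 0 (sensitive to an increasing effect).

#' Optimal contrasts for a candidate model set
#'
#' @param candidates a [candidateSet()].
#' @param doses dose grid (placebo first).
#' @param covariance k x k symmetric positive-definite covariance of the
#'   estimated group means.
#' @return an object of class `contrastSet`: an M x k matrix (rows =
#'   candidate models, columns = doses) with unit-norm rows, plus the
#'   provenance covariance as attribute.
#' @examples
#' cand <- defaultCandidateSet()
#' optimalContrasts(cand, c(0, 10, 25, 100), diag(4))
#' @export
optimalContrasts <- function(candidates, doses, covariance) {
  doses <- doseGrid(doses)
  k <- length(doses)
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(covariance, t(covariance), tolerance = 1e-8)))
    stop("covariance must be symmetric")
  if (nrow(covariance) != k) stop("covariance dimension must match the grid")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) stop("covariance is (numerically) singular")
  mu0 <- shapeMatrix(candidates, doses)
  flat <- apply(mu0, 2, function(v) diff(range(v)) < 1e-12)
  if (any(flat))
    stop("degenerate (flat) candidate shape(s): ",
         paste(colnames(mu0)[flat], collapse = ", "),
         "; flat shapes admit no contrast")
  C <- t(optimal_contrasts_cpp(mu0, covariance))
  rownames(C) <- colnames(mu0)
  colnames(C) <- paste0("d", doses)
  structure(C, class = c("contrastSet", "matrix"),
            covariance = covariance, doses = doses)
}

#' Optimal contrasts from per-group sample sizes
#'
#' Uses the per-arm sample sizes as the weight vector, i.e. the diagonal
#' covariance `diag(1/n_0, ..., 1/n_{k-1})`, as done for the residual-based
#' test statistic.
#'
#' @param candidates a [candidateSet()].
#' @param doses dose grid.
#' @param groupSizes vector of k positive integers.
#' @return a `contrastSet` (see [optimalContrasts()]).
#' @export
contrastsFromGroupSizes <- function(candidates, doses, groupSizes) {
  groupSizes <- as.numeric(groupSizes)
  if (length(groupSizes) != length(doses))
    stop("one sample size per dose is required")
  if (any(groupSizes < 1)) stop("cannot weight an empty arm: group size 0")
  optimalContrasts(candidates, doses, diag(1 / groupSizes))
}

#' @export
print.contrastSet <- function(x, ...) {
  cat("Optimal contrasts (rows = candidate models):\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Export a contrast set as CSV
#' @param x a `contrastSet`.
#' @param file output path.
#' @return the data.frame that was written, invisibly.
#' @export
writeContrasts <- function(x, file) {
  df <- data.frame(model = rownames(x), unclass(x), check.names = FALSE)
  write.csv(df, file, row.names = FALSE)
  invisible(df)
}
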