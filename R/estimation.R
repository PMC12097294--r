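# GLM estimation with dose-specific intercepts and covariates: maximum
# likelihood, Firth-penalized likelihood, exact separation detection, and
# population-average group means with covariance.

#' Trial data container
#'
#' @param z integer assignment sequence (arm indices 1..k) in enrollment
#'   order.
#' @param y outcomes: binary 0/1 or continuous, length n.
#' @param x optional covariate vector or n x p matrix.
#' @param doses dose grid of length k.
#' @return object of class `trialData`.
#' @export
trialData <- function(z, y, x = NULL, doses) {
  z <- as.integer(z)
  doses <- doseGrid(doses)
  k <- length(doses)
  if (length(y) != length(z)) stop("z and y lengths differ")
  if (any(z < 1 | z > k)) stop("arm indices must lie in 1..k")
  if (!is.null(x)) {
    x <- as.matrix(x)
    if (nrow(x) != length(z)) stop("covariate rows must match n")
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  structure(list(z = z, y = as.numeric(y), x = x, doses = doses, k = k,
                 n = length(z)),
            class = "trialData")
}

#' @export
print.trialData <- function(x, ...) {
  cat("Trial data: n =", x$n, ", arms =", x$k,
      ", covariates =", if (is.null(x$x)) 0 else ncol(x$x), "\n")
  cat("  per-arm counts:", paste(armCounts(x$z, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write trial data as CSV
#'
#' Columns: `i` (enrollment index), `arm`, `dose`, `y`, then covariates.
#' @param data a `trialData`.
#' @param file path.
#' @return `writeTrialData` invisibly returns the data.frame written;
#'   `readTrialData` returns a `trialData`.
#' @export
writeTrialData <- function(data, file) {
  df <- data.frame(i = seq_len(data$n), arm = data$z,
                   dose = data$doses[data$z], y = data$y)
  if (!is.null(data$x)) df <- cbind(df, data$x)
  write.csv(df, file, row.names = FALSE)
  invisible(df)
}

#' @rdname writeTrialData
#' @param doses dose grid to validate the file against.
#' @export
readTrialData <- function(file, doses) {
  df <- read.csv(file)
  xcols <- setdiff(names(df), c("i", "arm", "dose", "y"))
  trialData(df$arm, df$y,
            if (length(xcols)) as.matrix(df[xcols]) else NULL, doses)
}

# design matrix [D_Z | X] with one-hot dose intercepts (no global intercept)
designMatrix <- function(data) {
  D <- matrix(0, data$n, data$k)
  D[cbind(seq_len(data$n), data$z)] <- 1
  colnames(D) <- paste0("dose", data$doses)
  if (!is.null(data$x)) cbind(D, data$x) else D
}

#' Detect complete or quasicomplete separation
#'
#' Exact classification of a binary-outcome design by linear-programming
#' feasibility: complete separation holds when some coefficient vector `b`
#' gives `x_i'b > 0` for all successes and `< 0` for all failures;
#' quasicomplete when this is achievable only with weak inequalities (some
#' observations exactly on the hyperplane). Either kind implies the
#' logistic MLE does not exist.
#'
#' @param y binary outcomes (0/1), or a `trialData` whose design (dose
#'   intercepts + covariates) is then checked.
#' @param X design matrix (ignored when `y` is a `trialData`).
#' @param completeOnly if `TRUE`, only the complete/none distinction is
#'   computed (faster; quasicomplete reports as `"none"`).
#' @return one of `"none"`, `"quasicomplete"`, `"complete"`.
#' @export
detectSeparation <- function(y, X = NULL, completeOnly = FALSE) {
  if (inherits(y, "trialData")) {
    X <- designMatrix(y)
    y <- y$y
  }
  if (!all(y %in% c(0, 1))) stop("separation is defined for binary outcomes")
  X <- as.matrix(X)
  code <- separation_lp_cpp(X, as.integer(y), completeOnly)
  c("none", "quasicomplete", "complete")[code + 1]
}

#' Fit the dose-response GLM
#'
#' Fits a generalized linear model with linear predictor
#' `eta_i = d(Z)_i' delta + x_i' beta` (dose-specific intercepts plus
#' covariate effects).
#'
#' For `family = "binomial"`, `method = "mle"` is iteratively reweighted
#' least squares via [stats::glm.fit()]; under separation the estimates do
#' not exist and the returned (finite but drifting) values mirror standard
#' software behavior, with the `separation` flag set from the exact LP
#' check. `method = "firth"` maximizes the Jeffreys-penalized likelihood
#' `l(theta) + log|I(theta)|/2` and always yields finite estimates. For
#' `family = "gaussian"` both methods reduce to ordinary least squares (the
#' Jeffreys penalty does not involve the mean parameters there).
#'
#' @param data a [trialData()].
#' @param family `"binomial"` (logit link) or `"gaussian"` (identity).
#' @param method `"mle"` or `"firth"`.
#' @param separationCheck how to classify separation for the binomial
#'   family: `"auto"` (default) runs the exact LP check only when a cheap,
#'   exact necessary condition on the dose-intercept + single-covariate
#'   design holds (always runs it for other designs); `"full"` always runs
#'   the complete/quasicomplete LP classification; `"complete"` only the
#'   complete/none distinction; `"none"` skips the check.
#' @return object of class `fitResult` with elements `delta` (dose
#'   intercepts), `beta` (covariate coefficients), `muHat`
#'   (population-average group means on the linear-predictor scale), `S`
#'   (their covariance), `vcov` (full coefficient covariance), `converged`,
#'   `separation`, `method`, `family`.
#' @export
fitGlm <- function(data, family = c("binomial", "gaussian"),
                   method = c("mle", "firth"),
                   separationCheck = c("auto", "full", "complete", "none")) {
  stopifnot(inherits(data, "trialData"))
  family <- match.arg(family)
  method <- match.arg(method)
  separationCheck <- match.arg(separationCheck)
  X <- designMatrix(data)
  if (any(armCounts(data$z, data$k) == 0))
    stop("empty arm: every dose group needs at least one patient")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design; collinear columns: ",
         paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]], collapse = ", "))

  separation <- "none"
  if (family == "binomial") {
    if (!all(data$y %in% c(0, 1))) stop("binomial family needs 0/1 outcomes")
    separation <- switch(separationCheck,
      none = "none",
      complete = detectSeparation(data$y, X, completeOnly = TRUE),
      full = detectSeparation(data$y, X),
      auto = if (separationPossible(data)) detectSeparation(data$y, X)
             else "none")
    if (method == "firth") {
      f <- firth_fit_cpp(X, data$y)
      coefs <- drop(f$coefficients)
      V <- f$vcov
      converged <- f$converged
    } else {
      f <- suppressWarnings(glm.fit(X, data$y, family = binomial()))
      coefs <- f$coefficients
      W <- f$weights
      info <- crossprod(X * sqrt(W))
      V <- tryCatch(chol2inv(chol(info)), error = function(e) ginvSym(info))
      converged <- f$converged && separation == "none"
    }
  } else {
    f <- lm_ls(X, data$y)
    coefs <- f$coefficients
    V <- f$vcov
    converged <- TRUE
  }
  names(coefs) <- colnames(X)
  p <- if (is.null(data$x)) 0 else ncol(data$x)
  delta <- coefs[seq_len(data$k)]
  beta <- if (p > 0) coefs[data$k + seq_len(p)] else numeric(0)
  pam <- populationAverageMeans(delta, beta, V, data$x, data$k)
  structure(list(delta = delta, beta = beta, muHat = pam$muHat, S = pam$S,
                 vcov = V, converged = converged, separation = separation,
                 method = method, family = family, doses = data$doses,
                 n = data$n),
            class = "fitResult")
}

#' Does the MLE of a single coefficient exist?
#'
#' A logistic-regression coefficient has an infinite MLE exactly when the
#' cone of directions of recession of the log-likelihood (all `b` with
#' `(2y_i - 1) x_i'b >= 0`) contains a direction moving that coefficient;
#' this is decided exactly by two LP feasibility checks. For a
#' dose-intercept design, the intercept of an outcome-pure arm is the
#' canonical example of a coefficient whose MLE does not exist.
#'
#' @param y binary outcomes (0/1), or a `trialData`.
#' @param X design matrix (ignored for a `trialData`, whose dose-intercept
#'   + covariate design is used).
#' @param coefIndex column index of the coefficient to check (default 1,
#'   the placebo intercept of a `trialData` design).
#' @return `TRUE` when the MLE of that coefficient is infinite.
#' @export
coefMleInfinite <- function(y, X = NULL, coefIndex = 1) {
  if (inherits(y, "trialData")) {
    X <- designMatrix(y)
    y <- y$y
  }
  if (!all(y %in% c(0, 1))) stop("binary outcomes required")
  X <- as.matrix(X)
  stopifnot(coefIndex >= 1, coefIndex <= ncol(X))
  coef_mle_infinite_cpp(X, as.integer(y), as.integer(coefIndex) - 1L)
}

# Exact necessary condition for separation (of either kind) in the
# dose-intercept design with at most one covariate.  With free per-arm
# intercepts, any separating direction b = (delta, beta) must weakly
# separate successes from failures within every mixed arm along the single
# covariate, with a consistent sign of beta across arms; if no arm is pure
# and some mixed arm overlaps strictly in both directions, beta = 0 is
# forced and then every mixed arm forces delta_j = 0, so no separation can
# exist.  Designs with more than one covariate always return TRUE (the LP
# then decides).
separationPossible <- function(data) {
  p <- if (is.null(data$x)) 0 else ncol(data$x)
  if (p > 1) return(TRUE)
  ybyarm <- split(data$y, data$z)
  pure <- vapply(ybyarm, function(v) all(v == 0) || all(v == 1), logical(1))
  if (any(pure)) return(TRUE)
  if (p == 0) return(FALSE)
  x <- drop(data$x)
  up <- dn <- TRUE
  for (arm in unique(data$z)) {
    xs <- x[data$z == arm & data$y == 1]
    xf <- x[data$z == arm & data$y == 0]
    up <- up && (min(xs) >= max(xf))
    dn <- dn && (max(xs) <= min(xf))
  }
  up || dn
}

# least squares with covariance sigma^2 (X'X)^{-1}
lm_ls <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  df <- length(y) - fit$rank
  s2 <- if (df > 0) rss / df else 0
  XtX <- crossprod(X)
  V <- s2 * tryCatch(chol2inv(chol(XtX)), error = function(e) ginvSym(XtX))
  list(coefficients = fit$coefficients, vcov = V, sigma2 = s2)
}

# symmetric pseudo-inverse fallback for near-singular information
ginvSym <- function(M, tol = 1e-12) {
  e <- eigen(M, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values))
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

#' Population-average group means and their covariance
#'
#' On the linear-predictor scale, the population-average estimate for dose j
#' is `delta_j + mean(x)' beta`; its covariance is `L V L'` with
#' `L = [I_k | 1_k xbar']` and `V` the coefficient covariance.
#'
#' @param delta dose intercepts (length k).
#' @param beta covariate coefficients (length p, may be empty).
#' @param V (k+p) x (k+p) coefficient covariance.
#' @param x covariate matrix (or `NULL`).
#' @param k number of dose groups.
#' @return list with `muHat` and `S`.
#' @export
populationAverageMeans <- function(delta, beta, V, x, k) {
  if (length(beta) == 0) {
    return(list(muHat = unname(delta), S = V[seq_len(k), seq_len(k),
                                             drop = FALSE]))
  }
  xbar <- colMeans(as.matrix(x))
  L <- cbind(diag(k), matrix(rep(xbar, each = k), k))
  list(muHat = unname(drop(delta + sum(xbar * beta))),
       S = L %*% V %*% t(L))
}

#' @export
print.fitResult <- function(x, ...) {
  cat("GLM fit (", x$family, ", ", x$method, ")",
      if (!x$converged) "  [not converged]", "\n", sep = "")
  if (x$separation != "none")
    cat("  separation detected:", x$separation, "\n")
  cat("  group means (linear predictor):",
      paste(sprintf("%.3f", x$muHat), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a fit as a coefficient table
#'
#' @param object a `fitResult`.
#' @param file optional CSV path.
#' @param ... unused.
#' @return data.frame with coefficient, estimate, se, method, separation.
#' @export
summary.fitResult <- function(object, file = NULL, ...) {
  est <- c(object$delta, object$beta)
  out <- data.frame(coefficient = names(est), estimate = unname(est),
                    se = sqrt(pmax(0, diag(object$vcov))),
                    method = object$method, separation = object$separation)
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
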