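# Restricted randomization procedures: complete randomization (CR), random
# allocation rule (RA), permuted block design (PBD).  Sequences are integer
# vectors of arm indices 1..k in enrollment order; the dose attached to arm j
# is doses[j].

newProcedure <- function(kind, doses, n, targets = NULL, blockComp = NULL,
                         nBlocks = NULL) {
  structure(list(kind = kind, doses = doseGrid(doses),
                 k = length(doses), n = as.integer(n),
                 targets = targets, blockComp = blockComp,
                 nBlocks = nBlocks),
            class = "randProcedure")
}

#' Complete randomization
#'
#' Every patient is assigned independently and uniformly among the k arms
#' (a k-sided die); arm totals are not controlled.
#'
#' @param doses dose grid (placebo first).
#' @param n total sample size.
#' @return a `randProcedure`.
#' @export
completeRandomization <- function(doses, n) {
  stopifnot(n >= 1)
  newProcedure("CR", doses, n)
}

#' Random allocation rule
#'
#' Uniform draw over all sequences realizing the per-arm target sizes
#' exactly (an urn emptied without replacement).
#'
#' @param doses dose grid.
#' @param targetSizes vector of per-arm totals n_0, ..., n_{k-1}.
#' @return a `randProcedure`.
#' @export
randomAllocation <- function(doses, targetSizes) {
  targetSizes <- as.integer(targetSizes)
  if (length(targetSizes) != length(doses))
    stop("one target size per dose is required")
  if (any(targetSizes < 0)) stop("negative target size")
  newProcedure("RA", doses, sum(targetSizes), targets = targetSizes)
}

#' Permuted block design
#'
#' The random allocation rule applied independently within consecutive
#' blocks of fixed composition; every block realizes the within-block
#' allocation ratio exactly.
#'
#' @param doses dose grid.
#' @param blockComposition per-arm counts m_0, ..., m_{k-1} within one block.
#' @param nBlocks number of consecutive blocks.
#' @return a `randProcedure` with `n = nBlocks * sum(blockComposition)`.
#' @examples
#' # the 1:2:2:2 design with blocks of length 7 and n = 49
#' permutedBlocks(c(0, 10, 25, 100), c(1, 2, 2, 2), 7)
#' @export
permutedBlocks <- function(doses, blockComposition, nBlocks) {
  blockComposition <- as.integer(blockComposition)
  if (length(blockComposition) != length(doses))
    stop("one block count per dose is required")
  if (any(blockComposition < 0)) stop("negative block count")
  stopifnot(nBlocks >= 1)
  newProcedure("PBD", doses, sum(blockComposition) * nBlocks,
               targets = blockComposition * as.integer(nBlocks),
               blockComp = blockComposition, nBlocks = as.integer(nBlocks))
}

#' @export
print.randProcedure <- function(x, ...) {
  cat("<", x$kind, "> n = ", x$n, ", doses = (",
      paste(x$doses, collapse = ", "), ")", sep = "")
  if (x$kind == "RA") cat(", targets = (", paste(x$targets, collapse = ", "),
                          ")", sep = "")
  if (x$kind == "PBD") cat(", ", x$nBlocks, " blocks of (",
                           paste(x$blockComp, collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Sample assignment sequences from a randomization procedure
#'
#' @param proc a `randProcedure`.
#' @param nseq number of sequences to draw.
#' @param seed optional integer seed (set on R's RNG; all sampling streams
#'   through R's generator so results are reproducible).
#' @return if `nseq == 1`, an integer vector of arm indices (1..k) in
#'   enrollment order; else an `nseq x n` integer matrix, one sequence per
#'   row.
#' @export
sampleSequence <- function(proc, nseq = 1, seed = NULL) {
  stopifnot(inherits(proc, "randProcedure"))
  if (!is.null(seed)) set.seed(seed)
  Z <- switch(proc$kind,
    CR = sample_cr_cpp(nseq, proc$n, proc$k),
    RA = sample_ra_cpp(nseq, proc$targets),
    PBD = sample_pbd_cpp(nseq, proc$blockComp, proc$nBlocks))
  if (nseq == 1) as.integer(Z[1, ]) else Z
}

#' Exact reference-set cardinality
#'
#' The number of assignment sequences the procedure can produce, as an exact
#' big natural: `k^n` for CR, the multinomial coefficient
#' `n! / (n_0! ... n_{k-1}!)` for RA, and the per-block multinomial raised to
#' the number of blocks for PBD.
#'
#' @param proc a `randProcedure`.
#' @return a `bigNatural`; use `format()` for all digits and `as.numeric()`
#'   for a double approximation.
#' @examples
#' format(referenceSetSize(permutedBlocks(c(0, 10, 25, 100), c(1, 2, 2, 2), 7)))
#' @export
referenceSetSize <- function(proc) {
  stopifnot(inherits(proc, "randProcedure"))
  switch(proc$kind,
    CR = bi_pow(bigNatural(proc$k), proc$n),
    RA = bi_multinomial(proc$n, proc$targets),
    PBD = bi_pow(bi_multinomial(sum(proc$blockComp), proc$blockComp),
                 proc$nBlocks))
}

# realized per-arm counts of a sequence
armCounts <- function(z, k) tabulate(z, nbins = k)

validSequence <- function(proc, z) {
  z <- as.integer(z)
  if (length(z) != proc$n || any(z < 1 | z > proc$k)) return(FALSE)
  switch(proc$kind,
    CR = TRUE,
    RA = all(armCounts(z, proc$k) == proc$targets),
    PBD = {
      m <- sum(proc$blockComp)
      all(vapply(seq_len(proc$nBlocks), function(b) {
        blk <- z[((b - 1) * m + 1):(b * m)]
        all(armCounts(blk, proc$k) == proc$blockComp)
      }, logical(1)))
    })
}

#' Probability of an assignment sequence
#'
#' Every sequence in the support is equally likely: `k^{-n}` under CR and
#' `1/|R|` under RA and PBD; sequences outside the support have probability
#' zero.
#'
#' @param proc a `randProcedure`.
#' @param z integer sequence of arm indices.
#' @return the probability as a double.
#' @export
sequenceProbability <- function(proc, z) {
  if (!validSequence(proc, z)) return(0)
  1 / as.numeric(referenceSetSize(proc))
}

# all permutations of a multiset given per-symbol counts, as a matrix
multisetPermutations <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(matrix(integer(0), 1, 0))
  out <- list()
  for (j in which(counts > 0)) {
    cj <- counts
    cj[j] <- cj[j] - 1L
    rest <- multisetPermutations(cj)
    out[[length(out) + 1]] <- cbind(j, rest)
  }
  do.call(rbind, out)
}

#' Enumerate the complete reference set
#'
#' Lists every sequence in the support (for exact small-instance
#' randomization tests and oracle checks). Refuses when the exact count
#' exceeds `maxSize`.
#'
#' @param proc a `randProcedure`.
#' @param maxSize maximum number of sequences to materialize.
#' @return integer matrix, one sequence per row.
#' @export
enumerateReferenceSet <- function(proc, maxSize = 1e6) {
  size <- as.numeric(referenceSetSize(proc))
  if (size > maxSize)
    stop("reference set has ", format(referenceSetSize(proc)),
         " sequences, exceeding maxSize = ", maxSize)
  out <- switch(proc$kind,
    CR = as.matrix(rev(expand.grid(rev(replicate(proc$n, seq_len(proc$k),
                                                 simplify = FALSE))))),
    RA = multisetPermutations(proc$targets),
    PBD = {
      blocks <- multisetPermutations(proc$blockComp)
      idx <- rev(expand.grid(rev(replicate(proc$nBlocks,
                                           seq_len(nrow(blocks)),
                                           simplify = FALSE))))
      do.call(cbind, lapply(seq_len(proc$nBlocks),
                            function(b) blocks[idx[[b]], , drop = FALSE]))
    })
  out <- unname(as.matrix(out))
  storage.mode(out) <- "integer"
  out
}
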