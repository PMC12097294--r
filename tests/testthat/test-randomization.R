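test_that("reference-set sizes are exact for the motivating trial design", {
  # 7 blocks of length 7 at 1:2:2:2 -> 630^7; RA totals (7,14,14,14)
  pbd <- pbd49()
  expect_identical(format(referenceSetSize(pbd)), "39389806391670000000")
  expect_equal(as.numeric(referenceSetSize(pbd)) / 3.94e19, 1,
               tolerance = 0.005)
  ra <- ra49()
  expect_identical(format(referenceSetSize(ra)),
                   "182158430416168427065152000")
  expect_equal(as.numeric(referenceSetSize(ra)) / 1.82e26, 1,
               tolerance = 0.005)
  # CR follows |R| = k^n
  cr <- completeRandomization(trialDoses, 3)
  expect_identical(format(referenceSetSize(cr)), "64")
  # single-arm RA has a single sequence
  expect_identical(
    format(referenceSetSize(randomAllocation(c(0, 1), c(3, 0)))), "1")
})

test_that("enumeration matches the exact counts for random small designs", {
  set.seed(1)
  for (i in 1:12) {
    k <- sample(2:3, 1)
    doses <- c(0, seq_len(k - 1) * 10)
    kind <- sample(c("CR", "RA", "PBD"), 1)
    proc <- switch(kind,
      CR = completeRandomization(doses, sample(2:4, 1)),
      RA = randomAllocation(doses, sample(1:3, k, replace = TRUE)),
      PBD = permutedBlocks(doses, sample(1:2, k, replace = TRUE),
                           sample(1:2, 1)))
    seqs <- enumerateReferenceSet(proc)
    expect_equal(nrow(seqs), as.numeric(referenceSetSize(proc)), info = kind)
    expect_equal(nrow(unique(seqs)), nrow(seqs), info = kind)
    expect_true(all(apply(seqs, 1, MCPModRand:::validSequence, proc = proc)),
                info = kind)
  }
  expect_error(enumerateReferenceSet(pbd49(), maxSize = 100), "exceeding")
})

test_that("sequence probabilities are uniform on the support and sum to one", {
  ra <- randomAllocation(c(0, 10), c(1, 1))
  expect_equal(sequenceProbability(ra, c(1, 2)), 0.5)
  expect_equal(sequenceProbability(ra, c(2, 1)), 0.5)
  expect_equal(sequenceProbability(ra, c(1, 1)), 0)

  ra44 <- randomAllocation(c(0, 10), c(4, 4))
  seqs <- enumerateReferenceSet(ra44)
  expect_equal(nrow(seqs), 70)
  probs <- apply(seqs, 1, sequenceProbability, proc = ra44)
  expect_equal(unique(probs), 1 / 70)
  expect_equal(sum(probs), 1)

  pbd <- permutedBlocks(c(0, 10), c(1, 1), 2)
  expect_equal(nrow(enumerateReferenceSet(pbd)), 4)
  # violating the block composition puts a sequence outside the support
  expect_equal(sequenceProbability(pbd, c(1, 1, 2, 2)), 0)
  expect_equal(sequenceProbability(pbd, c(1, 2, 2, 1)), 0.25)
})

test_that("samplers respect their supports and are seed-reproducible", {
  pbd <- pbd49()
  Z <- sampleSequence(pbd, nseq = 50, seed = 9)
  for (b in 1:7) {
    blk <- Z[, ((b - 1) * 7 + 1):(b * 7), drop = FALSE]
    counts <- t(apply(blk, 1, tabulate, nbins = 4))
    expect_true(all(counts == rep(c(1, 2, 2, 2), each = 50)))
  }
  ra <- ra49()
  Zr <- sampleSequence(ra, nseq = 20, seed = 10)
  expect_true(all(t(apply(Zr, 1, tabulate, nbins = 4)) ==
                    rep(c(7, 14, 14, 14), each = 20)))
  expect_identical(sampleSequence(pbd, nseq = 5, seed = 123),
                   sampleSequence(pbd, nseq = 5, seed = 123))
  # RA with a degenerate urn is deterministic
  expect_identical(sampleSequence(randomAllocation(c(0, 1), c(1, 0)), seed = 1),
                   1L)
})

test_that("RA draws are uniform over the 70 sequences of the (4,4) urn", {
  ra44 <- randomAllocation(c(0, 10), c(4, 4))
  Z <- sampleSequence(ra44, nseq = 1e5, seed = 4)
  keys <- apply(Z, 1, paste, collapse = "")
  counts <- table(keys)
  expect_equal(length(counts), 70)
  chi <- sum((counts - 1e5 / 70)^2 / (1e5 / 70))
  expect_lt(chi, qchisq(1 - 1e-6, df = 69))  # uniform within MC error
})

test_that("CR arm counts are multinomial and supports are nested", {
  cr <- completeRandomization(c(0, 10, 25), 9)
  Z <- sampleSequence(cr, nseq = 2e4, seed = 5)
  counts <- tabulate(Z, nbins = 3)
  chi <- sum((counts - sum(counts) / 3)^2 / (sum(counts) / 3))
  expect_lt(chi, qchisq(1 - 1e-6, df = 2))
  # every PBD sequence is RA-valid; every RA sequence is CR-valid
  pbd <- permutedBlocks(c(0, 10), c(1, 2), 2)
  ra <- randomAllocation(c(0, 10), c(2, 4))
  cr6 <- completeRandomization(c(0, 10), 6)
  seqs <- enumerateReferenceSet(pbd)
  expect_true(all(apply(seqs, 1, MCPModRand:::validSequence, proc = ra)))
  raSeqs <- enumerateReferenceSet(ra)
  expect_true(all(apply(raSeqs, 1, MCPModRand:::validSequence, proc = cr6)))
  expect_false(all(apply(raSeqs, 1, MCPModRand:::validSequence, proc = pbd)))
})

test_that("exact big-natural arithmetic multiplies and formats correctly", {
  b <- MCPModRand:::bigNatural
  expect_identical(format(MCPModRand:::bi_pow(b(630), 7)),
                   "39389806391670000000")
  # 123456789 * 987654321 exceeds 2^53; the exact product ends in ...269
  # while double arithmetic would round it to ...264
  expect_identical(format(MCPModRand:::bi_mul(b(123456789), b(987654321))),
                   "121932631112635269")
  expect_identical(format(MCPModRand:::bi_multinomial(10, c(3, 3, 4))),
                   format(factorial(10) / (6 * 6 * 24), scientific = FALSE))
  expect_true(MCPModRand:::bi_pow(b(2), 10) == b(1024))
})
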