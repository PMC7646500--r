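test_that("mergeReads projects strands and resolves disagreements by quality", {
  cons <- "ACGTACGT"
  fwd <- mkCS("ACGTACGT", quals = 50L, source = "forward")
  one <- mergeReads(fwd, NULL, cons, sampleID = "s", locus = "L")
  expect_identical(paste0(one@bases, collapse = ""), "ACGTACGT")
  expect_true(all(one@support == "forward"))
  expect_false(any(one@conflict))

  # forward A (q50) vs reverse R (q20): forward wins, conflict flagged
  rev_ <- mkCS("ACGRACGT", quals = 20L, source = "reverse")
  both <- mergeReads(fwd, rev_, cons, sampleID = "s", locus = "L")
  expect_identical(both@bases[4], "T")
  expect_true(both@conflict[4])
  expect_identical(sum(both@conflict), 1L)
  expect_true(all(both@support == "both"))
  # quality order flipped: the reverse call wins
  both2 <- mergeReads(mkCS("ACGTACGT", quals = 20L),
                      mkCS("ACGRACGT", quals = 50L, source = "reverse"), cons)
  expect_identical(both2@bases[4], "R")

  # a read from the wrong locus/orientation is rejected
  expect_error(mergeReads(mkCS("GGGGGGGG"), NULL, "ACGTACGT"),
               class = "orientationError")
})

test_that("merged simulated strands reproduce the truth without conflicts", {
  p <- simParams(nAlleles = 8, exonLength = 80, seed = 21, amplitudeNoise = 0.05)
  ref <- makeReference(p)
  sim <- simulateSample(ref, "SYN*03:01", "SYN*07:01", p, seed = 13)
  sc <- mergeReads(callBases(sim$forward),
                   callBases(reverseOrient(sim$reverse), source = "reverse"),
                   consensusSeq(ref, "SYN"), sampleID = "s", locus = "SYN")
  expect_identical(paste0(sc@bases, collapse = ""), sim$truth)
  expect_false(any(sc@conflict))
  expect_true(all(sc@support == "both"))
})

test_that("pairSignature is the positionwise union of the two alleles", {
  expect_identical(pairSignature("AAG", "AGG"), "ARG")
  s <- randSeq(40, c("A", "C", "G", "T"))
  expect_identical(pairSignature(s, s), s)
  # brute-force union oracle on random pairs
  set.seed(3)
  for (k in 1:20) {
    a <- randSeq(15, c("A", "C", "G", "T"))
    b <- randSeq(15, c("A", "C", "G", "T"))
    sig <- strsplit(pairSignature(a, b), "")[[1]]
    ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
    for (j in 1:15)
      expect_identical(sort(iupacDecode(sig[j])),
                       sort(unique(c(ac[j], bc[j]))))
  }
  # gaps and unknowns contribute nothing
  expect_identical(pairSignature("A-G*", "AAG*"), "AAG*")
  expect_identical(pairSignature("A..C", "A..C"), "A..C")
  expect_error(pairSignature("AA", "AAA"), class = "validationError")
})

test_that("enumeratePairs recovers constructed pairs on a toy locus", {
  ref <- toyRef()
  nms <- alleleNames(ref, "TOY")
  # sample = signature of alleles 1 and 3; check all 6 unordered pairs
  sig13 <- pairSignature(alleleSeq(ref, nms[1]), alleleSeq(ref, nms[3]))
  cand <- enumeratePairs(mkSampleConsensus(sig13, locus = "TOY"), ref,
                         maxMismatch = 10L)
  expect_identical(nrow(cand), 6L)
  expect_identical(c(cand$allele1[1], cand$allele2[1]), c(nms[1], nms[3]))
  expect_identical(cand$mismatch_count[1], 0L)
  # oracle: recompute every pair's mismatch count by direct set comparison
  sampleChars <- strsplit(sig13, "")[[1]]
  for (i in seq_len(nrow(cand))) {
    sg <- strsplit(pairSignature(alleleSeq(ref, cand$allele1[i]),
                                 alleleSeq(ref, cand$allele2[i])), "")[[1]]
    expect_identical(cand$mismatch_count[i], sum(sg != sampleChars),
                     info = paste(cand$allele1[i], cand$allele2[i]))
  }

  # homozygote: the sample equals one allele alone
  cand2 <- enumeratePairs(mkSampleConsensus(unname(alleleSeq(ref, nms[2])),
                                            locus = "TOY"), ref)
  expect_identical(c(cand2$allele1[1], cand2$allele2[1]), c(nms[2], nms[2]))
  expect_identical(cand2$mismatch_count[1], 0L)

  # one flipped column demotes the former top pair to one mismatch
  flipped <- sig13
  substr(flipped, 1, 1) <- "C"
  cand3 <- enumeratePairs(mkSampleConsensus(flipped, locus = "TOY"), ref,
                          maxMismatch = 10L)
  row13 <- cand3[cand3$allele1 == nms[1] & cand3$allele2 == nms[3], ]
  expect_identical(row13$mismatch_count, 1L)
  expect_identical(row13$mismatch_positions[[1]], 0L)
})

test_that("every constructed pair is found at zero mismatches", {
  ref <- makeReference(simParams(nAlleles = 8, exonLength = 60, seed = 17))
  nms <- alleleNames(ref, "SYN")
  for (i in seq_along(nms)) for (j in i:length(nms)) {
    sig <- pairSignature(alleleSeq(ref, nms[i]), alleleSeq(ref, nms[j]))
    cand <- enumeratePairs(mkSampleConsensus(sig), ref)
    hit <- cand[cand$allele1 == min(nms[i], nms[j]) &
                  cand$allele2 == max(nms[i], nms[j]), ]
    expect_identical(hit$mismatch_count, 0L, info = paste(nms[i], nms[j]))
    expect_identical(min(cand$mismatch_count), 0L)
  }
})

test_that("uncovered columns are skipped and ranking is deterministic", {
  ref <- toyRef()
  nms <- alleleNames(ref, "TOY")
  sig <- pairSignature(alleleSeq(ref, nms[1]), alleleSeq(ref, nms[2]))
  # mask half the columns: the true pair still scores zero mismatches
  masked <- paste0(substr(sig, 1, 3), "???")
  cand <- enumeratePairs(mkSampleConsensus(masked, locus = "TOY"), ref,
                         maxMismatch = 10L)
  expect_identical(cand$mismatch_count[cand$allele1 == nms[1] &
                                         cand$allele2 == nms[2]], 0L)
  cand2 <- enumeratePairs(mkSampleConsensus(masked, locus = "TOY"), ref,
                          maxMismatch = 10L)
  expect_identical(cand, cand2)
})

test_that("adding reference alleles never hurts the true pair", {
  big <- makeReference(simParams(nAlleles = 12, exonLength = 60, seed = 9))
  nms <- alleleNames(big, "SYN")
  small <- ReferenceSet(big@alleles[1:6, ], big@exonSpans, version = "sub")
  sig <- pairSignature(alleleSeq(big, nms[2]), alleleSeq(big, nms[5]))
  mmOf <- function(r) {
    cand <- enumeratePairs(mkSampleConsensus(sig), r)
    cand$mismatch_count[cand$allele1 == nms[2] & cand$allele2 == nms[5]]
  }
  expect_true(mmOf(big) <= mmOf(small))
})

test_that("rankReport groups by mismatches and flags two-field ambiguity", {
  cand1 <- data.frame(allele1 = "A*01:01:01", allele2 = "A*02:01",
                      mismatch_count = 0L, total_score = 10L,
                      mismatch_positions = I(list(integer(0))))
  r1 <- rankReport(cand1, "s", "A")
  expect_false(isAmbiguous(r1))
  expect_identical(assignment(r1), c("A*01:01", "A*02:01"))
  expect_identical(typingStatus(r1), "typed")

  # two zero-mismatch pairs identical at two-field level stay unambiguous
  cand2 <- rbind(cand1, data.frame(allele1 = "A*01:01:02", allele2 = "A*02:01",
                                   mismatch_count = 0L, total_score = 10L,
                                   mismatch_positions = I(list(integer(0)))))
  expect_false(isAmbiguous(rankReport(cand2, "s", "A")))

  # a second field difference makes the result ambiguous
  cand3 <- rbind(cand1, data.frame(allele1 = "A*01:02", allele2 = "A*02:01",
                                   mismatch_count = 0L, total_score = 10L,
                                   mismatch_positions = I(list(integer(0)))))
  r3 <- rankReport(cand3, "s", "A")
  expect_true(isAmbiguous(r3))
  expect_identical(typingStatus(r3), "ambiguous")

  r0 <- rankReport(cand1[0, ], "s", "A")
  expect_identical(typingStatus(r0), "no_typing")
})
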