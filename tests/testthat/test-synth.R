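test_that("makeReference is deterministic and honours the substitution rate", {
  p <- simParams(nAlleles = 10, exonLength = 50, substitutionRate = 0.02,
                 seed = 7)
  ref1 <- makeReference(p)
  ref2 <- makeReference(p)
  expect_identical(ref1@alleles, ref2@alleles)
  expect_identical(nrow(ref1@alleles), 10L)
  expect_match(alleleNames(ref1, "SYN"), "^SYN\\*[0-9]{2}:01$")
  expect_identical(exonSpans(ref1, "SYN")$exon, c(2L, 3L))

  # rate 0: every allele equals the founder
  r0 <- makeReference(simParams(nAlleles = 5, exonLength = 40,
                                substitutionRate = 0, seed = 1))
  expect_identical(length(unique(r0@alleles$sequence)), 1L)

  # rate 1: each non-founder column is substituted (never equal to founder)
  r1 <- makeReference(simParams(nAlleles = 3, exonLength = 40,
                                substitutionRate = 1, seed = 1))
  f <- strsplit(r1@alleles$sequence[1], "")[[1]]
  a <- strsplit(r1@alleles$sequence[2], "")[[1]]
  expect_true(all(a != f))
})

test_that("simulated samples agree with the pair signature and the seed", {
  p <- simParams(nAlleles = 6, exonLength = 60, seed = 12)
  ref <- makeReference(p)
  s1 <- simulateSample(ref, "SYN*02:01", "SYN*03:01", p, seed = 4)
  expect_identical(s1$truth, pairSignature(alleleSeq(ref, "SYN*02:01"),
                                           alleleSeq(ref, "SYN*03:01")))
  s2 <- simulateSample(ref, "SYN*02:01", "SYN*03:01", p, seed = 4)
  expect_identical(writeABIF(s1$forward), writeABIF(s2$forward))
  expect_identical(writeABIF(s1$reverse), writeABIF(s2$reverse))
  # the reverse trace carries the bottom strand
  expect_identical(sequenceString(callBases(reverseOrient(s1$reverse))),
                   s1$truth)
})

test_that("noise-free balanced traces reproduce the truth end to end", {
  p <- simParams(nAlleles = 6, exonLength = 60, seed = 12, hetBalance = 1,
                 amplitudeNoise = 0)
  ref <- makeReference(p)
  set.seed(99)
  for (k in 1:5) {
    nm <- sample(alleleNames(ref, "SYN"), 2)
    sim <- simulateSample(ref, nm[1], nm[2], p)
    expect_identical(sequenceString(callBases(sim$forward)), sim$truth)
  }
})

test_that("position jitter stays within the caller's distance tolerance", {
  p <- simParams(nAlleles = 4, exonLength = 60, seed = 6, amplitudeNoise = 0,
                 positionJitter = 2L)
  ref <- makeReference(p)
  sim <- simulateSample(ref, "SYN*01:01", "SYN*03:01", p, seed = 8)
  expect_identical(sequenceString(callBases(sim$forward)), sim$truth)
})

test_that("the cis/trans construction creates exactly one extra zero pair", {
  amb <- makeAmbiguousCase(simParams(nAlleles = 4, exonLength = 120,
                                     amplitudeNoise = 0), seed = 3)
  sig <- pairSignature(alleleSeq(amb$reference, amb$truePair[1]),
                       alleleSeq(amb$reference, amb$truePair[2]))
  confSig <- pairSignature(alleleSeq(amb$reference, amb$confoundingPair[1]),
                           alleleSeq(amb$reference, amb$confoundingPair[2]))
  expect_identical(sig, confSig)
  expect_identical(sig, amb$truth)
  # the GSSP region spans the discriminating columns
  expect_true(amb$gssps$start < 60 && amb$gssps$end > 90)
  expect_error(
    suppressWarnings(makeAmbiguousCase(simParams(nAlleles = 4,
                                                 exonLength = 20))),
    class = "constructionError")
})

test_that("degenerate simulation parameters are rejected", {
  expect_error(simParams(nAlleles = 0), class = "validationError")
  expect_error(simParams(substitutionRate = 1.5), class = "validationError")
  expect_error(simParams(hetBalance = -0.1), class = "validationError")
  expect_warning(simParams(peakSpacing = 4L, peakSigma = 2.5),
                 class = "simParamWarning")
})
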