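gsspFixture <- function(seed = 5) {
  makeAmbiguousCase(simParams(nAlleles = 4, exonLength = 120,
                              amplitudeNoise = 0), seed = seed)
}

ambiguitySet <- function(amb) {
  sc <- mergeReads(callBases(amb$forward),
                   callBases(reverseOrient(amb$reverse), source = "reverse"),
                   consensusSeq(amb$reference, "SYN"),
                   sampleID = "amb", locus = "SYN")
  enumeratePairs(sc, amb$reference)
}

test_that("GSSP tables batch-import with per-row validation", {
  ref <- makeReference(simParams(nAlleles = 5, exonLength = 200, seed = 2))
  nms <- alleleNames(ref, "SYN")
  set.seed(1)
  n <- 300L
  starts <- sample(0:350, n, replace = TRUE)
  ends <- starts + sample(10:40, n, replace = TRUE)
  rows <- vapply(seq_len(n), function(i) {
    sel <- substr(alleleSeq(ref, sample(nms, 1)), starts[i] + 1L, ends[i])
    paste(sprintf("G%03d", i), "SYN", 2L, starts[i], ends[i], sel, sep = "\t")
  }, "")
  tsv <- paste(c("gssp_id\tlocus\texon\tstart\tend\tselector", rows),
               collapse = "\n")
  defs <- importGssps(tsv, ref)
  expect_identical(nrow(defs), 300L)

  dup <- paste("gssp_id\tlocus\texon\tstart\tend\tselector",
               "G1\tSYN\t2\t0\t3\tAAA", "G1\tSYN\t2\t5\t8\tAAA", sep = "\n")
  expect_error(importGssps(dup, ref), regexp = "G1",
               class = "duplicateGsspError")
  short <- paste("gssp_id\tlocus\texon\tstart\tend\tselector",
                 "G2\tSYN\t2\t0\t5\tAAA", sep = "\n")
  expect_error(importGssps(short, ref), regexp = "G2", class = "gsspRowError")
  out <- paste("gssp_id\tlocus\texon\tstart\tend\tselector",
               "G3\tSYN\t2\t390\t500\tAAA", sep = "\n")
  expect_error(importGssps(out, ref), class = "gsspRowError")
})

test_that("GSSP reads are identified automatically", {
  amb <- gsspFixture()
  read <- callBases(amb$gsspRead, source = "gssp")
  # add a decoy definition with the same region but an incompatible selector
  decoy <- amb$gssps
  decoy$gssp_id <- "GSSP-DECOY"
  decoy$selector <- paste0(rev(strsplit(decoy$selector, "")[[1]]),
                           collapse = "")
  defs <- rbind(amb$gssps, decoy)
  hit <- identifyGssp(read, defs, amb$reference)
  expect_identical(hit$gssp_id, "GSSP-SYN-E2-01")

  # a read matching no selector is an identification error with near-misses
  junk <- mkCS(strsplit(consensusSeq(amb$reference, "SYN"), "")[[1]][1:60] |>
                 rev() |> paste0(collapse = ""), source = "gssp")
  expect_error(identifyGssp(junk, decoy, amb$reference),
               class = "gsspIdentificationError")
})

test_that("GSSP filtering resolves the constructed cis/trans ambiguity", {
  amb <- gsspFixture()
  cand <- ambiguitySet(amb)
  zero <- cand[cand$mismatch_count == 0L, ]
  expect_identical(nrow(zero), 2L)  # both phase interpretations
  read <- callBases(amb$gsspRead, source = "gssp")
  filt <- filterWithGssp(cand, read, amb$gssps, amb$reference)
  zf <- filt[filt$mismatch_count == 0L, ]
  expect_identical(nrow(zf), 1L)
  expect_identical(sort(c(zf$allele1, zf$allele2)), sort(amb$truePair))
  # ranking order is preserved and the filter is idempotent
  expect_identical(filt, filterWithGssp(filt, read, amb$gssps, amb$reference))
  # soundness: the read's source allele is never filtered away
  expect_true(all(amb$truePair[1] %in% c(filt$allele1, filt$allele2)))
})

test_that("an uninformative GSSP leaves the candidate set unchanged", {
  amb <- gsspFixture()
  cand <- ambiguitySet(amb)
  # selector and read taken from a region where all four alleles agree
  backbone <- alleleSeq(amb$reference, "SYN*01:01")
  uninf <- data.frame(gssp_id = "G-UNINF", locus = "SYN", exon = 2L,
                      start = 100L, end = 120L,
                      selector = substr(backbone, 101L, 120L))
  read <- mkCS(substr(backbone, 101L, 120L), source = "gssp")
  expect_identical(filterWithGssp(cand, read, uninf, amb$reference), cand)
  # and an empty candidate list passes through
  expect_identical(nrow(filterWithGssp(cand[0, ], read, uninf,
                                       amb$reference)), 0L)
})

test_that("heterozygous GSSP reads warn of non-specific amplification", {
  amb <- gsspFixture()
  cand <- ambiguitySet(amb)
  hetRead <- mkCS(gsub("A", "R", substr(alleleSeq(amb$reference, "SYN*01:01"),
                                        41L, 100L)), source = "gssp")
  expect_warning(filterWithGssp(cand, hetRead, amb$gssps, amb$reference,
                                maxHetFrac = 0.1),
                 class = "gsspHeterozygousWarning")
  expect_silent(filterWithGssp(cand, hetRead, amb$gssps, amb$reference,
                               maxHetFrac = 0.5))
})
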