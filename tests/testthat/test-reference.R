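test_that("simple-TSV references parse into shared coordinates", {
  ref <- toyRef()
  expect_identical(loci(ref), "TOY")
  expect_length(alleleNames(ref, "TOY"), 3L)
  es <- exonSpans(ref, "TOY")
  expect_identical(es$exon, 2L)
  expect_identical(es$end - es$start, 6L)
  # multi-exon alleles concatenate in exon order
  tsv <- paste("allele_name\texon\tsequence",
               "X*01:01\t3\tGG", "X*01:01\t2\tAAAA",
               "X*02:01\t2\tAACA", "X*02:01\t3\tGG", sep = "\n")
  ref2 <- parseReference(tsv, "simple-tsv")
  expect_identical(unname(alleleSeq(ref2, "X*01:01")), "AAAAGG")
  expect_identical(exonSpans(ref2, "X")$start, c(0L, 4L))

  ragged <- paste("allele_name\texon\tsequence",
                  "X*01:01\t2\tAAAA", "X*02:01\t2\tAAA", sep = "\n")
  expect_error(parseReference(ragged, "simple-tsv"), regexp = "X\\*0",
               class = "parseError")
  badname <- paste("allele_name\texon\tsequence", "X07\t2\tAAAA", sep = "\n")
  expect_error(parseReference(badname, "simple-tsv"), class = "parseError")
})

test_that("IMGT alignment dialect resolves identity dashes and exons", {
  txt <- paste(
    " cDNA          1",
    " A*01:01:01:01 ACG TCG|C ATT",
    " A*01:02       --- --A|- A--",
    " A*02:01       --- ---|- ---",
    sep = "\n")
  ref <- parseReference(txt, "imgt-alignment", exons = c(2L, 3L))
  expect_identical(unname(alleleSeq(ref, "A*01:01:01:01")), "ACGTCGCATT")
  expect_identical(unname(alleleSeq(ref, "A*01:02")), "ACGTCACATT")
  # an all-dash allele equals the first allele
  expect_identical(unname(alleleSeq(ref, "A*02:01")),
                   unname(alleleSeq(ref, "A*01:01:01:01")))
  es <- exonSpans(ref, "A")
  expect_identical(es$exon, c(2L, 3L))
  expect_identical(es$start, c(0L, 6L))

  ragg <- paste(" A*01:01:01:01 ACGTCG", " A*01:02 ---", sep = "\n")
  expect_error(parseReference(ragg, "imgt-alignment"), regexp = "A\\*01:02",
               class = "parseError")
})

test_that("consensus is the positionwise IUPAC union of observed bases", {
  tsv <- paste("allele_name\texon\tsequence",
               "T*01:01\t2\tAAC", "T*02:01\t2\tAGC", sep = "\n")
  ref <- parseReference(tsv, "simple-tsv")
  expect_identical(consensusSeq(ref, "T"), "ARC")
  # a single allele is its own consensus
  one <- parseReference(paste("allele_name\texon\tsequence",
                              "U*01:01\t2\tACGT", sep = "\n"), "simple-tsv")
  expect_identical(consensusSeq(one, "U"), "ACGT")

  # brute-force column-set oracle on a 20-allele synthetic locus
  ref20 <- makeReference(simParams(nAlleles = 20, exonLength = 40, seed = 8))
  seqs <- lapply(alleleSeq(ref20, alleleNames(ref20, "SYN")),
                 function(s) strsplit(s, "")[[1]])
  cons <- strsplit(consensusSeq(ref20, "SYN"), "")[[1]]
  for (j in seq_along(cons)) {
    colSet <- sort(unique(vapply(seqs, `[`, "", j)))
    expect_identical(sort(iupacDecode(cons[j])), colSet)
  }
  # exon slices agree with the full consensus
  expect_identical(paste0(buildConsensus(ref20, "SYN", 2),
                          buildConsensus(ref20, "SYN", 3)),
                   consensusSeq(ref20, "SYN"))
  expect_error(buildConsensus(ref20, "SYN", 7), class = "coverageError")
})

test_that("consensus is idempotent and compatible with every allele", {
  ref <- makeReference(simParams(nAlleles = 12, exonLength = 50, seed = 4))
  cons <- consensusSeq(ref, "SYN")
  oneElement <- parseReference(
    paste("allele_name\texon\tsequence",
          sprintf("Z*01:01\t2\t%s", cons), sep = "\n"), "simple-tsv")
  expect_identical(consensusSeq(oneElement, "Z"), cons)
  consChars <- strsplit(cons, "")[[1]]
  for (nm in alleleNames(ref, "SYN")) {
    ch <- strsplit(alleleSeq(ref, nm), "")[[1]]
    ok <- mapply(function(a, c) a %in% iupacDecode(c), ch, consChars)
    expect_true(all(ok), info = nm)
  }
})

test_that("unknown '*' stretches contribute no observation to the consensus", {
  tsv <- paste("allele_name\texon\tsequence",
               "V*01:01\t2\tA*C", "V*02:01\t2\tAG*", sep = "\n")
  ref <- parseReference(tsv, "simple-tsv")
  expect_identical(consensusSeq(ref, "V"), "AGC")
})

test_that("twoField truncates names to the clinical resolution", {
  expect_identical(twoField("A*01:01:01:01"), "A*01:01")
  expect_identical(twoField("DRB1*15:02"), "DRB1*15:02")
  expect_identical(twoField(c("B*57:01:02", "C*07:02")),
                   c("B*57:01", "C*07:02"))
  expect_error(twoField("B*07"), class = "validationError")
})

test_that("supportedRegions reflects the per-gene exon coverage model", {
  expect_identical(supportedRegions("HLA-B"), 1:5)
  expect_identical(supportedRegions("HLA-G"), 2:4)
  expect_identical(supportedRegions("HLA-DRB3"), 2:3)
  expect_identical(supportedRegions("drb4"), 2:3)
  expect_warning(out <- supportedRegions("HLA-XX"),
                 class = "unknownLocusWarning")
  expect_length(out, 0L)
})

test_that("reference serialisation round-trips through flat files", {
  ref <- makeReference(simParams(nAlleles = 6, exonLength = 30, seed = 2))
  d <- withr::local_tempdir()
  writeReference(ref, d)
  back <- readReference(d)
  expect_identical(back@alleles, ref@alleles)
  expect_identical(back@consensus, ref@consensus)
  expect_identical(exonSpans(back, "SYN")[c("exon", "start", "end")],
                   exonSpans(ref, "SYN")[c("exon", "start", "end")])
  expect_identical(refVersion(back), refVersion(ref))
})
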