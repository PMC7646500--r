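test_that("peakRange halves the distance to the neighbouring peaks", {
  r <- peakRange(100, 110, 124)
  expect_equal(r$low, 105.0)
  expect_equal(r$high, 117.0)
  # at read ends the missing side falls back to half the mean spacing
  r2 <- peakRange(NULL, 10, 22, meanSpacing = 12)
  expect_equal(r2$low, 4.0)
  expect_equal(r2$high, 16.0)
  expect_error(peakRange(10, 10, 12), class = "validationError")
})

test_that("findSecondaryPeak applies the ratio and distance rules", {
  ch <- matrix(0L, 200, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  # rows are 1-based: position p lives in row p + 1
  ch[110:112, "A"] <- c(900L, 1000L, 900L)  # apex at position 110
  ch[98:100, "A"] <- c(900L, 1000L, 900L)   # neighbouring bases
  ch[122:124, "A"] <- c(900L, 1000L, 900L)
  chrom0 <- Chromatogram(ch, c(98L, 110L, 122L), c("A", "A", "A"),
                         c(50L, 50L, 50L))
  rng <- peakRange(98, 110, 122)

  with350 <- function(pos, height) {
    m <- ch
    m[(pos:(pos + 2L)), "C"] <- as.integer(c(0.8, 1, 0.8) * height)
    Chromatogram(m, chrom0@peakPositions, chrom0@calledBases, chrom0@qualities)
  }
  hit <- findSecondaryPeak(with350(112L, 350L), 2L, rng)
  expect_equal(hit$base, "C")
  expect_equal(hit$height, 350L)
  # ratio fails: 299 is not > 0.3 * 1000
  expect_null(findSecondaryPeak(with350(112L, 299L), 2L, rng))
  # distance fails: apex 6 points away at default distanceUnits = 4
  expect_null(findSecondaryPeak(with350(116L, 350L), 2L, rng))
})

test_that("callBases separates homozygotes and heterozygotes", {
  expect_identical(calledBases(callBases(renderTrace("ACGT"))),
                   c("A", "C", "G", "T"))
  # equal A and G peaks at one position -> R
  cs <- callBases(renderTrace("ARA"))
  expect_identical(calledBases(cs), c("A", "R", "A"))
  expect_identical(cs@secondaryBase[2], "G")
  # a long simulated diploid read is recovered exactly
  p <- simParams(nAlleles = 6, exonLength = 100, seed = 5,
                 amplitudeNoise = 0.05)
  ref <- makeReference(p)
  sim <- simulateSample(ref, "SYN*02:01", "SYN*04:01", p, seed = 9)
  expect_identical(sequenceString(callBases(sim$forward)), sim$truth)
})

test_that("the heterozygote call boundary is sharp in ratio and distance", {
  callMid <- function(ratio, offset, params = hetCallParams())
    calledBases(callBases(traceWithSecondary(ratio, offset), params))[2]
  expect_identical(callMid(0.31, 0L), "M")   # A+C
  expect_identical(callMid(0.29, 0L), "A")
  expect_identical(callMid(0.30, 0L), "A")   # strictly greater than
  expect_identical(callMid(0.80, 4L), "M")
  expect_identical(callMid(0.80, 5L), "A")   # beyond 4 trace points
  # the boundary follows the parameters, not the constants
  expect_identical(callMid(0.29, 0L, hetCallParams(ratioThreshold = 0.25)), "M")
  expect_identical(callMid(0.80, 5L, hetCallParams(distanceUnits = 5L)), "M")
})

test_that("raising the ratio threshold never creates heterozygotes", {
  set.seed(42)
  for (k in 1:5) {
    truth <- randSeq(30, c("A", "C", "G", "T", "R", "Y", "M", "K"))
    chrom <- renderTrace(truth, ratio = stats::runif(1, 0.2, 1))
    loose <- calledBases(callBases(chrom, hetCallParams(ratioThreshold = 0.3)))
    strictr <- calledBases(callBases(chrom, hetCallParams(ratioThreshold = 0.6)))
    hetAt <- function(x) nchar(Biostrings::IUPAC_CODE_MAP[x]) > 1
    expect_true(all(!hetAt(strictr) | hetAt(loose)))
  }
})

test_that("IUPAC encode/decode are mutually inverse over all 15 subsets", {
  subsets <- Filter(length, unlist(lapply(1:4, function(k)
    utils::combn(c("A", "C", "G", "T"), k, simplify = FALSE)),
    recursive = FALSE))
  expect_length(subsets, 15L)
  for (s in subsets) {
    code <- iupacEncode(s)
    expect_identical(iupacDecode(code), sort(s))
  }
  expect_identical(iupacEncode(c("A", "G")), "R")
  expect_identical(iupacEncode("A"), "A")
  expect_identical(iupacEncode(c("A", "C", "G", "T")), "N")
  expect_identical(iupacDecode("N"), c("A", "C", "G", "T"))
  expect_error(iupacDecode("Z"), class = "validationError")
  expect_error(iupacEncode(character(0)), class = "validationError")
})

test_that("simulator het positions follow the ratio/distance boundary", {
  # secondary/primary ratio below threshold -> homozygous everywhere
  p <- simParams(nAlleles = 4, exonLength = 60, seed = 3, hetBalance = 0.25,
                 amplitudeNoise = 0)
  ref <- makeReference(p)
  sim <- simulateSample(ref, "SYN*01:01", "SYN*02:01", p, seed = 2)
  calls <- calledBases(callBases(sim$forward))
  expect_false(any(nchar(Biostrings::IUPAC_CODE_MAP[calls]) > 1))
  truthFirst <- vapply(strsplit(sim$truth, "")[[1]],
                       function(b) iupacDecode(b)[1], "")
  expect_identical(calls, unname(truthFirst))
  # just above threshold -> heterozygous calls reappear
  p2 <- simParams(nAlleles = 4, exonLength = 60, seed = 3, hetBalance = 0.35,
                  amplitudeNoise = 0)
  sim2 <- simulateSample(ref, "SYN*01:01", "SYN*02:01", p2, seed = 2)
  expect_identical(sequenceString(callBases(sim2$forward)), sim2$truth)
})
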