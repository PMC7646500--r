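# Synthetic references and simulated diploid electropherograms.
#
# The simulator renders each called base as a Gaussian peak in its channel
# at regular spacing; a heterozygous column renders two channels with the
# secondary at `hetBalance` times the primary height. Linear superposition
# plus multiplicative per-peak amplitude noise is the simplest model that
# exercises the peak-range/ratio/distance heterozygote rule. Dye blobs,
# mobility shifts and quality decay are deliberately not modelled.

#' Simulation parameters
#'
#' @param nAlleles number of alleles in the synthetic locus (>= 2).
#' @param exonLength columns per exon (the locus has exons 2 and 3).
#' @param substitutionRate per-column substitution probability of each
#'   non-founder allele relative to the founder.
#' @param peakSpacing trace points between consecutive peaks (default 12).
#' @param peakSigma Gaussian peak width in trace points.
#' @param amplitude primary peak height in signal units.
#' @param amplitudeNoise multiplicative per-peak amplitude noise (s.d. as a
#'   fraction of the height).
#' @param hetBalance secondary/primary height ratio at heterozygous
#'   positions (1.0 = perfectly balanced).
#' @param positionJitter uniform peak-position jitter in trace points
#'   (0 = none); exercises the distance criterion of the caller.
#' @param seed integer seed making [makeReference()] deterministic.
#' @return A validated parameter list of class `SimParams`.
#' @export
simParams <- function(nAlleles = 30L, exonLength = 270L,
                      substitutionRate = 0.02, peakSpacing = 12L,
                      peakSigma = 2.5, amplitude = 1000, amplitudeNoise = 0.05,
                      hetBalance = 1.0, positionJitter = 0L, seed = 1L) {
  if (!.isCount(nAlleles) || nAlleles < 1L)
    .err("validationError", "nAlleles must be a positive integer")
  if (!.isCount(exonLength) || exonLength < 1L)
    .err("validationError", "exonLength must be a positive integer")
  for (r in c(substitutionRate, amplitudeNoise))
    if (!is.numeric(r) || r < 0 || r > 1)
      .err("validationError", "rates must lie in [0, 1]")
  if (hetBalance < 0 || hetBalance > 1)
    .err("validationError", "hetBalance must lie in [0, 1]")
  if (peakSpacing <= 2 * peakSigma)
    .warn("simParamWarning", "peakSpacing <= 2*peakSigma: peaks will overlap")
  structure(list(nAlleles = as.integer(nAlleles),
                 exonLength = as.integer(exonLength),
                 substitutionRate = substitutionRate,
                 peakSpacing = as.integer(peakSpacing),
                 peakSigma = peakSigma, amplitude = amplitude,
                 amplitudeNoise = amplitudeNoise, hetBalance = hetBalance,
                 positionJitter = as.integer(positionJitter),
                 seed = as.integer(seed)),
            class = "SimParams")
}

#' Generate a synthetic allele reference
#'
#' One locus ("SYN") with exons 2 and 3, `exonLength` columns each. The
#' founder allele is drawn uniformly over A/C/G/T; every other allele
#' substitutes each column independently with probability
#' `substitutionRate`. Names follow two-field nomenclature
#' (`SYN*01:01`, `SYN*02:01`, ...). Deterministic under `params$seed`.
#'
#' @param params a [simParams()] list.
#' @return A [ReferenceSet-class].
#' @export
makeReference <- function(params = simParams()) {
  if (params$nAlleles < 2L)
    .err("validationError", "a reference needs at least 2 alleles")
  L <- 2L * params$exonLength
  .withSeed(params$seed, {
    founder <- sample(.BASES, L, replace = TRUE)
    seqs <- character(params$nAlleles)
    seqs[1] <- paste0(founder, collapse = "")
    for (i in seq_len(params$nAlleles - 1L) + 1L) {
      ch <- founder
      mut <- which(stats::runif(L) < params$substitutionRate)
      if (length(mut))
        ch[mut] <- vapply(ch[mut], function(b)
          sample(setdiff(.BASES, b), 1L), "")
      seqs[i] <- paste0(ch, collapse = "")
    }
    ReferenceSet(
      data.frame(locus = "SYN",
                 name = sprintf("SYN*%02d:01", seq_len(params$nAlleles)),
                 sequence = seqs),
      data.frame(locus = "SYN", exon = c(2L, 3L),
                 start = c(0L, params$exonLength),
                 end = c(params$exonLength, L)),
      version = sprintf("synthetic-%d", params$seed))
  })
}

# Render a degenerate truth string as a Chromatogram. At heterozygous
# columns the alphabetically first base takes the primary height and the
# other hetBalance x primary; noise is multiplicative per peak.
.renderChromatogram <- function(truth, params, sampleID = "") {
  ch <- .chars(truth)
  n <- length(ch)
  sp <- params$peakSpacing
  pos <- sp * seq_len(n)
  if (params$positionJitter > 0L && n > 0L)
    pos <- pos + sample.int(2L * params$positionJitter + 1L, n,
                            replace = TRUE) - params$positionJitter - 1L
  traceLen <- sp * (n + 1L) + 1L
  sig <- matrix(0, nrow = traceLen, ncol = 4L,
                dimnames = list(NULL, .BASES))
  halfW <- ceiling(4 * params$peakSigma)
  addPeak <- function(base, p, height) {
    t0 <- max(0L, p - halfW)
    t1 <- min(traceLen - 1L, p + halfW)
    t <- t0:t1
    sig[t + 1L, base] <<- sig[t + 1L, base] +
      height * exp(-((t - p)^2) / (2 * params$peakSigma^2))
  }
  noisy <- function(h) {
    if (params$amplitudeNoise <= 0) return(h)
    max(1, h * (1 + params$amplitudeNoise * stats::rnorm(1)))
  }
  for (i in seq_len(n)) {
    bases <- iupacDecode(ch[i])
    addPeak(bases[1], pos[i], noisy(params$amplitude))
    if (length(bases) > 1L)
      for (b in bases[-1L])
        addPeak(b, pos[i], noisy(params$hetBalance * params$amplitude))
  }
  Chromatogram(channels = round(sig), peakPositions = pos,
               calledBases = ch, qualities = rep(50L, n),
               sampleID = sampleID, channelOrder = "GATC")
}

#' Simulate forward/reverse chromatograms for a diploid sample
#'
#' The truth sequence is [pairSignature()] of the two alleles; the forward
#' chromatogram renders it directly and the reverse chromatogram renders
#' its reverse complement (a bottom-strand read, as sequenced — pass it
#' through [reverseOrient()] before calling and merging).
#'
#' @param ref the [ReferenceSet-class] the alleles come from.
#' @param name1,name2 allele names (may be equal for a homozygote).
#' @param params a [simParams()] list (noise, balance, geometry).
#' @param seed optional seed; when given the output is byte-reproducible,
#'   otherwise the current RNG stream is used.
#' @param sampleID sample identifier stamped on the traces.
#' @return list with `forward` and `reverse` [Chromatogram-class]s and the
#'   `truth` degenerate string.
#' @export
simulateSample <- function(ref, name1, name2, params = simParams(),
                           seed = NULL, sampleID = "sim") {
  s1 <- alleleSeq(ref, name1)
  s2 <- alleleSeq(ref, name2)
  truth <- pairSignature(s1, s2)
  .withSeed(seed, {
    fwd <- .renderChromatogram(truth, params, sampleID)
    rev_ <- .renderChromatogram(
      .complementChars(paste0(rev(.chars(truth)), collapse = "")),
      params, sampleID)
    list(forward = fwd, reverse = rev_, truth = truth)
  })
}

#' Construct a cis/trans ambiguity case with a resolving GSSP
#'
#' Builds a minimal reference in which two distinct allele pairs share one
#' signature: over a random backbone, four alleles carry the haplotype
#' patterns A-C, A-T, G-C, G-T at two heterozygous columns, so the "cis"
#' pair (A-C, G-T) and the "trans" pair (A-T, G-C) both produce R and Y at
#' those columns. A GSSP whose selector matches only the first true allele
#' over a window spanning both columns, together with a read simulated from
#' that allele, resolves the ambiguity.
#'
#' @param params a [simParams()] list; `exonLength` must be at least 120
#'   (shorter values are doubled once with a warning before giving up).
#' @param seed seed for the backbone and the simulated reads.
#' @return list with `reference`, `truePair`, `confoundingPair`, `gssps`
#'   (one-row definition table), `gsspRead` ([Chromatogram-class]),
#'   `forward`/`reverse` sample chromatograms and the `truth` string.
#' @export
makeAmbiguousCase <- function(params = simParams(nAlleles = 4L), seed = 1L) {
  if (params$exonLength < 120L) {
    .warn("simParamWarning",
          "exonLength %d too short for the ambiguity construction; doubling",
          params$exonLength)
    params$exonLength <- 2L * params$exonLength
    if (params$exonLength < 120L)
      .err("constructionError",
           "exonLength too short to place the discriminating region")
  }
  L <- 2L * params$exonLength
  c1 <- 60L
  c2 <- 90L
  regionStart <- 40L
  regionEnd <- 100L
  .withSeed(seed, {
    backbone <- sample(.BASES, L, replace = TRUE)
    hap <- list(c("A", "C"), c("A", "T"), c("G", "C"), c("G", "T"))
    seqs <- vapply(hap, function(h) {
      ch <- backbone
      ch[c1 + 1L] <- h[1]
      ch[c2 + 1L] <- h[2]
      paste0(ch, collapse = "")
    }, "")
    ref <- ReferenceSet(
      data.frame(locus = "SYN", name = sprintf("SYN*%02d:01", 1:4),
                 sequence = seqs),
      data.frame(locus = "SYN", exon = c(2L, 3L),
                 start = c(0L, params$exonLength),
                 end = c(params$exonLength, L)),
      version = sprintf("ambiguous-%d", seed))
    truePair <- c("SYN*01:01", "SYN*04:01")       # A-C with G-T
    confoundingPair <- c("SYN*02:01", "SYN*03:01") # A-T with G-C
    gssps <- data.frame(
      gssp_id = "GSSP-SYN-E2-01", locus = "SYN", exon = 2L,
      start = regionStart, end = regionEnd,
      selector = substr(seqs[1], regionStart + 1L, regionEnd))
    gsspRead <- .renderChromatogram(
      substr(seqs[1], regionStart + 1L, regionEnd), params,
      sampleID = "gssp")
    sim <- simulateSample(ref, truePair[1], truePair[2], params,
                          sampleID = "ambiguous")
    c(list(reference = ref, truePair = truePair,
           confoundingPair = confoundingPair, gssps = gssps,
           gsspRead = gsspRead), sim)
  })
}
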