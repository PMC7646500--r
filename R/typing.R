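# Allele-pair enumeration and ranking.
#
# Forward and reverse calls are each aligned once to the locus consensus and
# projected into shared alignment coordinates; all subsequent allele-pair
# comparisons are positionwise in those coordinates (IMGT-style references
# are pre-aligned, so per-pair dynamic programming would be redundant).
# A candidate pair's signature is the positionwise IUPAC union of its two
# alleles — what a heterozygous trace of that genotype should show — and a
# mismatch is any covered column where the sample's code and the signature
# code differ as sets. Candidates are ranked by mismatch count.

#' Merge forward/reverse calls into a sample consensus
#'
#' Each read is semi-globally aligned to the locus consensus and its calls
#' are projected to alignment coordinates. Columns covered by one strand
#' take that strand's call; columns covered by both take the shared call
#' when the strands agree, otherwise the higher-quality call wins and the
#' column is flagged as a conflict (ties go to the forward strand).
#'
#' @param forward,reverse [CalledSequence-class]s (either may be `NULL`;
#'   reverse reads must already be in reference orientation, i.e. called
#'   from a [reverseOrient()]ed chromatogram).
#' @param consensus the locus consensus string in alignment coordinates.
#' @param scheme a [scoringScheme()].
#' @param minScoreFrac reads whose alignment score falls below this fraction
#'   of the maximum attainable (`match2 *` read length) raise an
#'   orientation/locus error — the usual cause is a wrong file.
#' @param sampleID,locus identifiers stored on the result.
#' @return A [SampleConsensus-class].
#' @export
mergeReads <- function(forward = NULL, reverse = NULL, consensus,
                       scheme = scoringScheme(), minScoreFrac = 0.5,
                       sampleID = "", locus = "") {
  if (is.null(forward) && is.null(reverse))
    .err("validationError", "at least one read must be given")
  L <- nchar(consensus)
  bases <- rep(NA_character_, L)
  qual <- rep(NA_integer_, L)
  support <- rep("none", L)
  conflict <- rep(FALSE, L)

  project <- function(cs) {
    aln <- semiglobalAlign(calledBases(cs), consensus, scheme)
    nb <- length(cs@bases)
    if (aln@score < minScoreFrac * scheme$match2 * nb)
      .err("orientationError",
           paste0("read (%s) aligns poorly to the %s consensus ",
                  "(score %d of %d): wrong locus or orientation?"),
           cs@source, locus, aln@score, scheme$match2 * nb)
    keep <- !is.na(aln@queryToRef)
    list(cols = aln@queryToRef[keep] + 1L, bases = cs@bases[keep],
         qual = cs@qualities[keep])
  }

  for (cs in Filter(Negate(is.null), list(forward, reverse))) {
    p <- project(cs)
    strand <- cs@source
    for (k in seq_along(p$cols)) {
      j <- p$cols[k]
      if (support[j] == "none") {
        bases[j] <- p$bases[k]
        qual[j] <- p$qual[k]
        support[j] <- strand
      } else if (support[j] != strand) {
        if (bases[j] != p$bases[k]) {
          conflict[j] <- TRUE
          if (p$qual[k] > qual[j]) {
            bases[j] <- p$bases[k]
            qual[j] <- p$qual[k]
          }
        }
        support[j] <- "both"
      }
    }
  }
  qual[is.na(qual)] <- 0L
  new("SampleConsensus", sampleID = sampleID, locus = locus, bases = bases,
      support = support, conflict = conflict, qualities = qual)
}

#' Combined degenerate signature of an allele pair
#'
#' Positionwise IUPAC union of two aligned allele sequences: the sequence a
#' heterozygous Sanger read of that diploid genotype should show. Columns
#' that are gaps in both alleles stay `.`; a column that is unknown (`*`)
#' in both stays `*` (no constraint); a gap or unknown in only one allele
#' contributes nothing, leaving the other allele's base.
#'
#' @param seq1,seq2 aligned allele sequences (equal length).
#' @param start,end optional 0-based half-open column range.
#' @return The signature string.
#' @examples
#' pairSignature("AAG", "AGG")  # "ARG"
#' @export
pairSignature <- function(seq1, seq2, start = NULL, end = NULL) {
  if (nchar(seq1) != nchar(seq2))
    .err("validationError", "allele sequences differ in alignment length")
  if (!is.null(start)) {
    if (is.null(end)) end <- nchar(seq1)
    if (start < 0 || end > nchar(seq1) || start >= end)
      .err("coverageError", "region [%d,%d) outside the alleles", start, end)
    seq1 <- substr(seq1, start + 1L, end)
    seq2 <- substr(seq2, start + 1L, end)
  }
  m1 <- .seqMasks(seq1)
  m2 <- .seqMasks(seq2)
  star <- is.na(m1) | is.na(m2)
  m1[is.na(m1)] <- 0L
  m2[is.na(m2)] <- 0L
  u <- bitwOr(m1, m2)
  paste0(ifelse(u > 0L, .MASK2CODE[u], ifelse(star, "*", ".")),
         collapse = "")
}

# Mask matrix of a locus' alleles: columns = alleles, rows = alignment
# columns; 0 for gaps, NA for unknown '*'.
.alleleMaskMatrix <- function(ref, locus) {
  nms <- alleleNames(ref, locus)
  vapply(alleleSeq(ref, nms), .seqMasks, integer(nchar(consensusSeq(ref, locus))))
}

#' Enumerate and rank allele-pair candidates
#'
#' Over all unordered pairs (including self-pairs) of the locus' alleles,
#' counts the covered alignment columns where the sample's degenerate code
#' differs, as a set, from the pair's union signature. Columns where the
#' sample is uncovered, or where the signature is unknown (`*`) or all-gap,
#' are skipped. Candidates with at most `maxMismatch` mismatches are
#' returned sorted by mismatch count (ascending), then total column score
#' (descending), then allele names — all zero-mismatch pairs (the ambiguity
#' set) are retained.
#'
#' Alleles whose one-sided incompatibility with the sample (covered columns
#' where the allele's base is outside the sample's code) already exceeds
#' `maxMismatch` are pruned before pairing: every such column is necessarily
#' a mismatch for any pair containing the allele.
#'
#' @param sample a [SampleConsensus-class].
#' @param ref a [ReferenceSet-class] containing the sample's locus.
#' @param maxMismatch candidates above this mismatch count are suppressed
#'   (default 5, a short ranked display list).
#' @param scheme a [scoringScheme()] used for the total column score.
#' @return data.frame with columns `allele1`, `allele2`, `mismatch_count`,
#'   `total_score` and list column `mismatch_positions` (0-based alignment
#'   coordinates).
#' @export
enumeratePairs <- function(sample, ref, maxMismatch = 5L,
                           scheme = scoringScheme()) {
  locus <- sample@locus
  if (!locus %in% loci(ref))
    .err("configurationError", "locus %s absent from reference", locus)
  M <- .alleleMaskMatrix(ref, locus)
  nms <- alleleNames(ref, locus)
  sm <- rep(NA_integer_, nrow(M))
  known <- !is.na(sample@bases)
  sm[known] <- unname(.CODE2MASK[sample@bases[known]])
  covered <- which(!is.na(sm))

  Mc <- M[covered, , drop = FALSE]
  smc <- sm[covered]
  oneSided <- colSums(!is.na(Mc) & Mc > 0L & bitwAnd(Mc, smc) == 0L)
  keep <- which(oneSided <= maxMismatch)

  out <- list()
  for (ii in seq_along(keep)) {
    i <- keep[ii]
    for (j in keep[seq.int(ii, length(keep))]) {
      sig <- bitwOr(Mc[, i], Mc[, j])   # NA ('*') propagates -> skipped
      use <- !is.na(sig) & sig > 0L
      mmCols <- use & sig != smc
      nmm <- sum(mmCols)
      if (nmm > maxMismatch) next
      score <- sum(.maskScore(smc[use], sig[use], scheme))
      out[[length(out) + 1L]] <- list(
        allele1 = min(nms[i], nms[j]), allele2 = max(nms[i], nms[j]),
        mismatch_count = nmm, total_score = score,
        mismatch_positions = covered[mmCols] - 1L)
    }
  }
  if (!length(out))
    return(data.frame(allele1 = character(0), allele2 = character(0),
                      mismatch_count = integer(0), total_score = integer(0),
                      mismatch_positions = I(list())))
  df <- data.frame(
    allele1 = vapply(out, `[[`, "", "allele1"),
    allele2 = vapply(out, `[[`, "", "allele2"),
    mismatch_count = vapply(out, `[[`, 0L, "mismatch_count"),
    total_score = vapply(out, `[[`, 0L, "total_score"),
    mismatch_positions = I(lapply(out, `[[`, "mismatch_positions")))
  df <- df[order(df$mismatch_count, -df$total_score, df$allele1, df$allele2), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Summarise ranked candidates into a typing result
#'
#' Groups candidates by mismatch count and decides ambiguity: the result is
#' unambiguous iff exactly one two-field-distinct pair attains the minimum
#' mismatch count (pairs identical at two-field resolution collapse).
#' An empty candidate list yields a "no_typing" result, not an error.
#'
#' @param candidates candidate data.frame from [enumeratePairs()].
#' @param sampleID,locus identifiers stored on the result.
#' @param coveredColumns number of alignment columns covered by the sample.
#' @param gsspApplied identifiers of GSSPs already applied.
#' @return A [TypingResult-class].
#' @export
rankReport <- function(candidates, sampleID = "", locus = "",
                       coveredColumns = NA_integer_,
                       gsspApplied = character(0)) {
  if (!nrow(candidates))
    return(new("TypingResult", sampleID = sampleID, locus = locus,
               candidates = candidates, minMismatch = NA_integer_,
               ambiguous = NA, assignment = character(0),
               coveredColumns = as.integer(coveredColumns),
               gsspApplied = gsspApplied, status = "no_typing",
               message = "no candidate pair within the mismatch window"))
  mn <- min(candidates$mismatch_count)
  top <- candidates[candidates$mismatch_count == mn, , drop = FALSE]
  tf <- unique(paste(twoField(top$allele1), twoField(top$allele2)))
  ambiguous <- length(tf) > 1L
  new("TypingResult", sampleID = sampleID, locus = locus,
      candidates = candidates, minMismatch = as.integer(mn),
      ambiguous = ambiguous,
      assignment = c(twoField(top$allele1[1]), twoField(top$allele2[1])),
      coveredColumns = as.integer(coveredColumns),
      gsspApplied = gsspApplied,
      status = if (ambiguous) "ambiguous" else "typed",
      message = "")
}
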