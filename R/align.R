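# Degenerate semi-global alignment.
#
# A Sanger read of a diploid template is a string of degenerate bases: each
# position stands for an unordered pair of alleles (a plain base X for the
# homozygous pair (X,X), a 2-fold code like R for the heterozygous pair
# (A,G)). A column is therefore scored as the size of the best one-to-one
# matching between the two pairs it compares: 2 when both alleles match,
# 1 when one does, 0 on mismatch; internal indels cost -1. End gaps are
# free because reads start and end outside the exon of interest and may
# cover it only partially.

#' Scoring scheme of the degenerate aligner
#'
#' @param match2,match1,mismatch per-column scores for 2, 1 and 0 matching
#'   alleles (defaults 2, 1, 0).
#' @param indel linear gap score for internal indels (default -1).
#' @param freeEndGaps whether leading/trailing gaps on either sequence are
#'   free (default `TRUE`).
#' @return A validated scheme list.
#' @export
scoringScheme <- function(match2 = 2L, match1 = 1L, mismatch = 0L,
                          indel = -1L, freeEndGaps = TRUE) {
  if (!(match2 > match1 && match1 > mismatch && mismatch > indel))
    .err("validationError", "need match2 > match1 > mismatch > indel")
  structure(list(match2 = as.integer(match2), match1 = as.integer(match1),
                 mismatch = as.integer(mismatch), indel = as.integer(indel),
                 freeEndGaps = isTRUE(freeEndGaps)),
            class = "ScoringScheme")
}

#' Per-column comparison score of two degenerate bases
#'
#' Each side is read as an unordered allele pair: a plain base X is (X,X), a
#' 2-fold code its two bases. The score is the size of the maximum
#' one-to-one matching between the two pairs (0, 1 or 2). When either side
#' decodes to more than two bases (3/4-fold codes), the score is 1 if the
#' decoded sets intersect, else 0.
#'
#' @param sample,ref single IUPAC characters.
#' @param scheme a [scoringScheme()].
#' @return Integer score.
#' @examples
#' scoreBases("A", "A")  # 2
#' scoreBases("R", "A")  # 1
#' scoreBases("G", "A")  # 0
#' @export
scoreBases <- function(sample, ref, scheme = scoringScheme()) {
  a <- .CODE2MASK[toupper(sample)]
  b <- .CODE2MASK[toupper(ref)]
  if (anyNA(a) || anyNA(b))
    .err("validationError", "scoreBases needs valid IUPAC characters")
  .maskScore(unname(a), unname(b), scheme)
}

# 16 x 16 per-column score table over mask values 0..15 (0 = gap column).
.scoreTable <- function(scheme) {
  g <- expand.grid(a = 0:15, b = 0:15)
  matrix(.maskScore(g$a, g$b, scheme), 16L, 16L)
}

#' Alignment of a degenerate query against a reference
#'
#' Result container of [semiglobalAlign()]. Coordinates are 0-based
#' half-open; `queryToRef` maps every query base to its reference column
#' (`NA` when the base is unaligned or inserted relative to the reference).
#' `mismatchPositions` are the reference coordinates of aligned columns that
#' scored at or below the mismatch value (unknown `*` reference columns are
#' never mismatches).
#' @export
setClass("PairwiseDegenAlignment", representation(
  score = "integer",
  queryStart = "integer", queryEnd = "integer",
  refStart = "integer", refEnd = "integer",
  operations = "data.frame",
  columnQuery = "integer", columnRef = "integer", columnScores = "integer",
  mismatchPositions = "integer",
  queryToRef = "integer",
  queryLength = "integer", refLength = "integer"
))

setMethod("show", "PairwiseDegenAlignment", function(object) {
  cat(sprintf(
    "PairwiseDegenAlignment: score %d, query [%d,%d) vs ref [%d,%d), %d mismatch column(s)\n",
    object@score, object@queryStart, object@queryEnd, object@refStart,
    object@refEnd, length(object@mismatchPositions)))
})

#' Align a degenerate sequence to a reference semi-globally
#'
#' Dynamic-programming alignment maximising the summed per-column
#' [scoreBases()] scores with linear internal gap costs. With
#' `freeEndGaps` (the default) gaps at the beginning or end of either
#' sequence are not penalised. Ties in the traceback prefer a column over a
#' deletion over an insertion, so the result is deterministic.
#'
#' Reference positions may include alignment gap columns (`.`/`-`), which
#' cost nothing to skip, and unknown stretches (`*`), which align neutrally
#' and are never reported as mismatches.
#'
#' @param query degenerate sequence (string or character vector of bases).
#' @param ref reference sequence, possibly degenerate (e.g. a locus
#'   consensus).
#' @param scheme a [scoringScheme()].
#' @return A [PairwiseDegenAlignment-class].
#' @examples
#' semiglobalAlign("ARGT", "AAGT")  # score 7: 2 + 1 + 2 + 2
#' @export
semiglobalAlign <- function(query, ref, scheme = scoringScheme()) {
  qc <- if (length(query) > 1L) toupper(query) else .chars(query)
  rc <- if (length(ref) > 1L) toupper(ref) else .chars(ref)
  if (!length(qc) || !length(rc))
    .err("validationError", "query and ref must be nonempty")
  qm <- .charMasks(qc, what = "query")
  if (anyNA(qm) || any(qm == 0L))
    .err("validationError", "query may not contain gaps or unknown bases")
  rm_ <- .charMasks(rc, what = "reference")
  refStar <- is.na(rm_)
  rm_[refStar] <- 15L  # '*' aligns neutrally, as N
  res <- .semiglobalDP(qm, rm_, .scoreTable(scheme), scheme$indel,
                       scheme$freeEndGaps)
  ops <- res$ops
  opChar <- c("match", "del", "ins")[ops + 1L]
  if (length(res$colScore)) {
    diagIdx <- which(ops == 0L)
    opChar[diagIdx[res$colScore < scheme$match2]] <- "sub"
  }
  rle_ <- rle(opChar)
  mm <- res$colRef[res$colScore <= scheme$mismatch &
                     rm_[res$colRef + 1L] != 0L &
                     !refStar[res$colRef + 1L]]
  qmap <- rep(NA_integer_, length(qm))
  qmap[res$colQuery + 1L] <- res$colRef
  new("PairwiseDegenAlignment", score = as.integer(res$score),
      queryStart = as.integer(res$qstart), queryEnd = as.integer(res$qend),
      refStart = as.integer(res$rstart), refEnd = as.integer(res$rend),
      operations = data.frame(op = rle_$values, length = rle_$lengths),
      columnQuery = as.integer(res$colQuery),
      columnRef = as.integer(res$colRef),
      columnScores = as.integer(res$colScore),
      mismatchPositions = as.integer(mm),
      queryToRef = qmap,
      queryLength = length(qm), refLength = length(rm_))
}

#' Project a query position onto the reference
#'
#' @param aln a [PairwiseDegenAlignment-class].
#' @param queryIndex 0-based query base index; must lie inside the aligned
#'   query span.
#' @return The 0-based reference column aligned to that base, or
#'   `NA_integer_` when the base is inserted relative to the reference.
#' @export
mapToReference <- function(aln, queryIndex) {
  if (!.isCount(queryIndex) || queryIndex < aln@queryStart ||
      queryIndex >= aln@queryEnd)
    .err("validationError",
         "queryIndex %s outside aligned span [%d, %d)",
         format(queryIndex), aln@queryStart, aln@queryEnd)
  aln@queryToRef[queryIndex + 1L]
}
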