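#' Accessors for SangerHLA classes
#'
#' Small generics giving read access to the central objects without touching
#' slots directly.
#'
#' @param x an object of the documented class.
#' @param ... ignored.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleID", function(x, ...) standardGeneric("sampleID"))
#' @rdname accessors
#' @export
setGeneric("traceChannels", function(x, ...) standardGeneric("traceChannels"))
#' @rdname accessors
#' @export
setGeneric("channelOrder", function(x, ...) standardGeneric("channelOrder"))
#' @rdname accessors
#' @export
setGeneric("peakPositions", function(x, ...) standardGeneric("peakPositions"))
#' @rdname accessors
#' @export
setGeneric("calledBases", function(x, ...) standardGeneric("calledBases"))
#' @rdname accessors
#' @export
setGeneric("baseQualities", function(x, ...) standardGeneric("baseQualities"))
#' @rdname accessors
#' @export
setGeneric("isReverse", function(x, ...) standardGeneric("isReverse"))
#' @rdname accessors
#' @export
setGeneric("sourceStrand", function(x, ...) standardGeneric("sourceStrand"))
#' @rdname accessors
#' @export
setGeneric("sequenceString", function(x, ...) standardGeneric("sequenceString"))

setMethod("sampleID", "Chromatogram", function(x, ...) x@sampleID)
setMethod("traceChannels", "Chromatogram", function(x, ...) x@channels)
setMethod("channelOrder", "Chromatogram", function(x, ...) x@channelOrder)
setMethod("peakPositions", "Chromatogram", function(x, ...) x@peakPositions)
setMethod("calledBases", "Chromatogram", function(x, ...) x@calledBases)
setMethod("baseQualities", "Chromatogram", function(x, ...) x@qualities)
setMethod("isReverse", "Chromatogram", function(x, ...) x@isReverse)

setMethod("calledBases", "CalledSequence", function(x, ...) x@bases)
setMethod("baseQualities", "CalledSequence", function(x, ...) x@qualities)
setMethod("peakPositions", "CalledSequence", function(x, ...) x@positions)
setMethod("sourceStrand", "CalledSequence", function(x, ...) x@source)
setMethod("sequenceString", "CalledSequence",
          function(x, ...) paste0(x@bases, collapse = ""))

setMethod("sampleID", "SampleConsensus", function(x, ...) x@sampleID)
setMethod("sampleID", "TypingResult", function(x, ...) x@sampleID)

#' @rdname accessors
#' @export
setGeneric("refVersion", function(x, ...) standardGeneric("refVersion"))
#' @rdname accessors
#' @export
setGeneric("loci", function(x, ...) standardGeneric("loci"))
#' @rdname accessors
#' @export
setGeneric("alleleNames", function(x, locus, ...) standardGeneric("alleleNames"))
#' @rdname accessors
#' @export
setGeneric("alleleSeq", function(x, name, ...) standardGeneric("alleleSeq"))
#' @rdname accessors
#' @export
setGeneric("consensusSeq", function(x, locus, ...) standardGeneric("consensusSeq"))
#' @rdname accessors
#' @export
setGeneric("exonSpans", function(x, locus, ...) standardGeneric("exonSpans"))

setMethod("refVersion", "ReferenceSet", function(x, ...) x@version)
setMethod("loci", "ReferenceSet", function(x, ...) unique(x@alleles$locus))
setMethod("alleleNames", "ReferenceSet", function(x, locus, ...) {
  if (missing(locus)) x@alleles$name
  else x@alleles$name[x@alleles$locus == locus]
})
setMethod("alleleSeq", "ReferenceSet", function(x, name, ...) {
  i <- match(name, x@alleles$name)
  if (anyNA(i)) .err("unknownAlleleError", "unknown allele(s): %s",
                     paste(name[is.na(i)], collapse = ", "))
  stats::setNames(x@alleles$sequence[i], name)
})
setMethod("consensusSeq", "ReferenceSet", function(x, locus, ...) {
  if (!locus %in% names(x@consensus))
    .err("unknownLocusError", "locus %s not in reference", locus)
  unname(x@consensus[locus])
})
setMethod("exonSpans", "ReferenceSet", function(x, locus, ...) {
  es <- x@exonSpans
  if (!missing(locus)) es <- es[es$locus == locus, , drop = FALSE]
  es[order(es$exon), , drop = FALSE]
})

#' @rdname accessors
#' @export
setGeneric("candidates", function(x, ...) standardGeneric("candidates"))
#' @rdname accessors
#' @export
setGeneric("isAmbiguous", function(x, ...) standardGeneric("isAmbiguous"))
#' @rdname accessors
#' @export
setGeneric("assignment", function(x, ...) standardGeneric("assignment"))
#' @rdname accessors
#' @export
setGeneric("minMismatch", function(x, ...) standardGeneric("minMismatch"))
#' @rdname accessors
#' @export
setGeneric("typingStatus", function(x, ...) standardGeneric("typingStatus"))

setMethod("candidates", "TypingResult", function(x, ...) x@candidates)
setMethod("isAmbiguous", "TypingResult", function(x, ...) x@ambiguous)
setMethod("assignment", "TypingResult", function(x, ...) x@assignment)
setMethod("minMismatch", "TypingResult", function(x, ...) x@minMismatch)
setMethod("typingStatus", "TypingResult", function(x, ...) x@status)

#' @rdname accessors
#' @export
setGeneric("typingResults", function(x, ...) standardGeneric("typingResults"))
setMethod("typingResults", "TypingSession", function(x, ...) {
  lapply(x@samples, function(s) s$result)
})

setMethod("show", "Chromatogram", function(object) {
  cat(sprintf("Chromatogram '%s': %d bases, %d trace points, order %s%s\n",
              object@sampleID, length(object@peakPositions),
              nrow(object@channels), object@channelOrder,
              if (object@isReverse) " (reverse-oriented)" else ""))
})

setMethod("show", "CalledSequence", function(object) {
  het <- sum(!is.na(object@secondaryBase))
  s <- paste0(object@bases, collapse = "")
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(sprintf("CalledSequence (%s): %d bases, %d heterozygous\n  %s\n",
              object@source, length(object@bases), het, s))
})

setMethod("show", "ReferenceSet", function(object) {
  cat(sprintf("ReferenceSet '%s': %d allele(s) across %d locus/loci\n",
              object@version, nrow(object@alleles),
              length(unique(object@alleles$locus))))
  for (loc in unique(object@alleles$locus)) {
    es <- exonSpans(object, loc)
    cat(sprintf("  %s: %d alleles, %d columns, exons %s\n", loc,
                sum(object@alleles$locus == loc),
                nchar(object@consensus[loc]),
                paste(es$exon, collapse = ",")))
  }
})

setMethod("show", "SampleConsensus", function(object) {
  cat(sprintf(
    "SampleConsensus '%s' (%s): %d/%d columns covered, %d conflict(s)\n",
    object@sampleID, object@locus, sum(!is.na(object@bases)),
    length(object@bases), sum(object@conflict)))
})

setMethod("show", "TypingResult", function(object) {
  cat(sprintf("TypingResult '%s' %s: %s\n", object@sampleID, object@locus,
              object@status))
  if (nrow(object@candidates)) {
    top <- utils::head(object@candidates, 5)
    for (i in seq_len(nrow(top)))
      cat(sprintf("  %s + %s  mismatches=%d score=%d\n", top$allele1[i],
                  top$allele2[i], top$mismatch_count[i], top$total_score[i]))
    if (length(object@assignment))
      cat(sprintf("  assignment: %s%s\n",
                  paste(object@assignment, collapse = " / "),
                  if (object@ambiguous) " (ambiguous)" else ""))
  }
})

setMethod("show", "TypingSession", function(object) {
  cat(sprintf("TypingSession: %d sample(s), reference '%s', updated %s\n",
              length(object@samples), object@reference@version,
              object@updated))
})
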