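#' Chromatogram: a normalised Sanger trace
#'
#' Holds the four analyzed signal channels of an ABIF electropherogram
#' together with the instrument's base calls: one peak position (trace-point
#' index, 0-based), called base and quality per base. `channelOrder` records
#' the file's filter-wheel dye order (the `FWO_` tag); the `channels` matrix
#' itself is always keyed by nucleotide, columns A, C, G, T.
#'
#' @slot sampleID sample identifier (free text).
#' @slot channels integer matrix, one row per trace point, columns A, C, G, T.
#' @slot channelOrder 4-letter permutation of "ACGT" as stored in the file.
#' @slot peakPositions 0-based trace-point index of each base's peak,
#'   strictly increasing.
#' @slot calledBases character vector of per-base calls (IUPAC alphabet).
#' @slot qualities integer vector of per-base qualities (0-62).
#' @slot isReverse `TRUE` once the object has been flipped into reference
#'   orientation by [reverseOrient()]; `FALSE` for a trace as read from disk.
#'
#' @seealso [readABIF()], [writeABIF()], [reverseOrient()], [callBases()]
#' @export
setClass("Chromatogram", representation(
  sampleID = "character",
  channels = "matrix",
  channelOrder = "character",
  peakPositions = "integer",
  calledBases = "character",
  qualities = "integer",
  isReverse = "logical"
))

setValidity("Chromatogram", function(object) {
  ch <- object@channels
  if (!is.numeric(ch) || ncol(ch) != 4L || !identical(colnames(ch), .BASES))
    return("channels must be a numeric matrix with columns A, C, G, T")
  if (any(ch < 0, na.rm = TRUE)) return("channel signals must be non-negative")
  n <- length(object@peakPositions)
  if (length(object@calledBases) != n || length(object@qualities) != n)
    return("peakPositions, calledBases and qualities must have equal length")
  if (n > 0) {
    if (any(diff(object@peakPositions) <= 0))
      return("peakPositions must be strictly increasing")
    if (min(object@peakPositions) < 0 || max(object@peakPositions) >= nrow(ch))
      return("peakPositions must lie within the trace")
    if (any(object@qualities < 0 | object@qualities > 62))
      return("qualities must be integers in 0..62")
    if (any(!.chars(paste0(object@calledBases, collapse = "")) %in%
            names(.CODE2MASK)))
      return("calledBases must be IUPAC nucleotide codes")
  }
  if (!.isString(object@channelOrder) ||
      !identical(sort(.chars(object@channelOrder)), .BASES))
    return("channelOrder must be a 4-letter permutation of ACGT")
  TRUE
})

#' Construct a Chromatogram
#'
#' @param channels integer matrix (trace points x 4) with columns A, C, G, T,
#'   or a named list of four equal-length signal vectors.
#' @param peakPositions 0-based trace-point indices, one per base.
#' @param calledBases character vector of per-base IUPAC calls (or a single
#'   string, which is split).
#' @param qualities integer per-base qualities in 0-62.
#' @param sampleID sample identifier.
#' @param channelOrder the file's dye order; defaults to the common "GATC".
#' @param isReverse orientation flag, see the class docs.
#' @return A [Chromatogram-class] object.
#' @export
Chromatogram <- function(channels, peakPositions, calledBases, qualities,
                         sampleID = "", channelOrder = "GATC",
                         isReverse = FALSE) {
  if (is.list(channels)) {
    if (!all(.BASES %in% names(channels)))
      .err("validationError", "channel list must be named A, C, G, T")
    channels <- do.call(cbind, lapply(channels[.BASES], as.integer))
  }
  channels <- as.matrix(channels)
  storage.mode(channels) <- "integer"
  colnames(channels) <- .BASES
  if (length(calledBases) == 1L && nchar(calledBases[1]) > 1L)
    calledBases <- .chars(calledBases)
  new("Chromatogram", sampleID = as.character(sampleID), channels = channels,
      channelOrder = toupper(channelOrder),
      peakPositions = as.integer(peakPositions),
      calledBases = toupper(as.character(calledBases)),
      qualities = as.integer(qualities), isReverse = isReverse)
}

#' CalledSequence: degenerate base calls with per-base evidence
#'
#' The product of [callBases()]: an IUPAC string where heterozygous positions
#' carry a 2-fold degenerate code, plus the primary/secondary peak evidence
#' (base and apex height) behind every call.
#'
#' @slot bases per-position IUPAC calls.
#' @slot primaryBase,secondaryBase evidence bases; `secondaryBase` is `NA`
#'   except at 2-fold degenerate positions.
#' @slot primaryHeight,secondaryHeight apex signal heights.
#' @slot qualities per-base qualities.
#' @slot positions trace-point position of each base's primary peak.
#' @slot source one of "forward", "reverse", "gssp".
#' @export
setClass("CalledSequence", representation(
  bases = "character",
  primaryBase = "character",
  secondaryBase = "character",
  primaryHeight = "numeric",
  secondaryHeight = "numeric",
  qualities = "integer",
  positions = "integer",
  source = "character"
))

setValidity("CalledSequence", function(object) {
  n <- length(object@bases)
  if (!all(lengths(list(object@primaryBase, object@secondaryBase,
                        object@primaryHeight, object@secondaryHeight,
                        object@qualities, object@positions)) == n))
    return("all per-base vectors must have the same length")
  if (!object@source %in% c("forward", "reverse", "gssp"))
    return("source must be forward, reverse or gssp")
  m <- unname(.CODE2MASK[object@bases])
  if (anyNA(m)) return("bases must be IUPAC nucleotide codes")
  twofold <- .BITCOUNT[m + 1L] == 2L
  if (any(twofold & is.na(object@secondaryBase)) ||
      any(!twofold & !is.na(object@secondaryBase)))
    return("secondaryBase must be set exactly at 2-fold degenerate positions")
  TRUE
})

#' Construct a CalledSequence
#'
#' @param bases,primaryBase,secondaryBase,primaryHeight,secondaryHeight
#'   per-base vectors, see [CalledSequence-class].
#' @param qualities,positions per-base qualities and trace positions.
#' @param source provenance: "forward", "reverse" or "gssp".
#' @return A [CalledSequence-class].
#' @export
CalledSequence <- function(bases, primaryBase, secondaryBase, primaryHeight,
                           secondaryHeight, qualities, positions,
                           source = "forward") {
  new("CalledSequence", bases = bases, primaryBase = primaryBase,
      secondaryBase = secondaryBase, primaryHeight = as.numeric(primaryHeight),
      secondaryHeight = as.numeric(secondaryHeight),
      qualities = as.integer(qualities), positions = as.integer(positions),
      source = source)
}

#' ReferenceSet: an allele reference in shared alignment coordinates
#'
#' The static allele database: for each locus, all alleles expanded to full
#' explicit sequences over a shared multiple-alignment coordinate system,
#' the exon spans in those coordinates, and a per-locus degenerate consensus
#' (the positionwise IUPAC code of all observed bases).
#'
#' @slot version free-text reference version.
#' @slot alleles data.frame with columns `locus`, `name`, `sequence`
#'   (alignment-length strings over A, C, G, T, '-'/'.', '*').
#' @slot exonSpans data.frame with columns `locus`, `exon`, `start`, `end`
#'   (0-based half-open alignment coordinates).
#' @slot consensus named character vector, locus -> consensus string.
#' @seealso [parseReference()], [buildConsensus()], [makeReference()]
#' @export
setClass("ReferenceSet", representation(
  version = "character",
  alleles = "data.frame",
  exonSpans = "data.frame",
  consensus = "character"
))

setValidity("ReferenceSet", function(object) {
  al <- object@alleles
  if (!all(c("locus", "name", "sequence") %in% names(al)))
    return("alleles must have columns locus, name, sequence")
  for (loc in unique(al$locus)) {
    len <- unique(nchar(al$sequence[al$locus == loc]))
    if (length(len) != 1L)
      return(sprintf("alleles of locus %s differ in alignment length", loc))
    if (!is.na(object@consensus[loc]) && nchar(object@consensus[loc]) != len)
      return(sprintf("consensus length mismatch for locus %s", loc))
  }
  es <- object@exonSpans
  if (nrow(es) && !all(c("locus", "exon", "start", "end") %in% names(es)))
    return("exonSpans must have columns locus, exon, start, end")
  TRUE
})

#' Construct a ReferenceSet from expanded allele sequences
#'
#' @param alleles data.frame with columns `locus`, `name`, `sequence`.
#' @param exonSpans data.frame with columns `locus`, `exon`, `start`, `end`.
#' @param version reference version string.
#' @return A [ReferenceSet-class] with per-locus consensus computed.
#' @export
ReferenceSet <- function(alleles, exonSpans, version = "unversioned") {
  alleles <- as.data.frame(alleles, stringsAsFactors = FALSE)
  alleles$sequence <- toupper(alleles$sequence)
  cons <- vapply(split(alleles$sequence, alleles$locus),
                 .consensusFromSequences, character(1))
  new("ReferenceSet", version = version, alleles = alleles,
      exonSpans = as.data.frame(exonSpans, stringsAsFactors = FALSE),
      consensus = cons)
}

#' SampleConsensus: merged per-sample degenerate sequence
#'
#' Forward/reverse calls projected into reference alignment coordinates and
#' merged. `bases` is `NA` outside coverage; `support` records which strands
#' cover each column; `conflict` flags columns where both strands cover and
#' disagree (the higher-quality call wins).
#' @export
setClass("SampleConsensus", representation(
  sampleID = "character",
  locus = "character",
  bases = "character",
  support = "character",
  conflict = "logical",
  qualities = "integer"
))

setValidity("SampleConsensus", function(object) {
  n <- length(object@bases)
  if (length(object@support) != n || length(object@conflict) != n ||
      length(object@qualities) != n)
    return("bases, support, conflict, qualities must have equal length")
  if (!all(object@support %in% c("none", "forward", "reverse", "both")))
    return("support must be none/forward/reverse/both")
  if (any(object@conflict & object@support != "both"))
    return("conflict may be set only where both strands cover")
  if (any(is.na(object@bases) & object@support != "none"))
    return("covered columns must have a base")
  TRUE
})

#' TypingResult: ranked allele-pair candidates for one sample x locus
#'
#' @slot candidates data.frame of candidate pairs (columns `allele1`,
#'   `allele2`, `mismatch_count`, `total_score`, and a list column
#'   `mismatch_positions`), sorted by (mismatches, -score, names).
#' @slot minMismatch smallest mismatch count seen (`NA` if no candidate).
#' @slot ambiguous `TRUE` when more than one two-field-distinct pair attains
#'   the minimum mismatch count.
#' @slot assignment two-field designations of the top pair (length 2), empty
#'   when nothing was typed.
#' @slot status "typed", "ambiguous", "no_typing" or "error".
#' @export
setClass("TypingResult", representation(
  sampleID = "character",
  locus = "character",
  candidates = "data.frame",
  minMismatch = "integer",
  ambiguous = "logical",
  assignment = "character",
  coveredColumns = "integer",
  gsspApplied = "character",
  status = "character",
  message = "character"
))

#' TypingSession: resumable state of a typing run
#'
#' The dynamic store: per-sample consensus, candidates, applied GSSPs and
#' base edits, plus the reference they were computed against. A session
#' saved with [saveSession()] and reloaded with [loadSession()] reproduces
#' identical [TypingResult-class]s without re-reading any chromatogram.
#' @export
setClass("TypingSession", representation(
  reference = "ReferenceSet",
  samples = "list",
  params = "list",
  created = "character",
  updated = "character"
))
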