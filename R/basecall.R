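# Heterozygote calling from peak geometry.
#
# A diploid template sequenced by Sanger shows two superimposed peaks at
# positions where its two alleles differ. Each called base gets a peak range
# centred on its peak: halfway to the previous peak on the left, halfway to
# the next peak on the right. If a second channel has a local maximum inside
# that range, close enough to the primary apex and tall enough relative to
# it, the position is called heterozygous and reported as the 2-fold IUPAC
# code of the two bases; otherwise it is homozygous.

#' Parameters of the heterozygote caller
#'
#' @param ratioThreshold minimum secondary/primary apex height ratio
#'   (exclusive) for a heterozygous call. Default 0.3.
#' @param distanceUnits maximum distance, in trace points, between the
#'   secondary and primary apexes. Default 4.
#' @param minQuality bases below this quality are never called heterozygous
#'   (0 = no gating, the default).
#' @return A validated parameter list of class `HetCallParams`.
#' @export
hetCallParams <- function(ratioThreshold = 0.3, distanceUnits = 4L,
                          minQuality = 0L) {
  if (!is.numeric(ratioThreshold) || ratioThreshold <= 0 || ratioThreshold >= 1)
    .err("validationError", "ratioThreshold must be in (0, 1)")
  if (!.isCount(distanceUnits))
    .err("validationError", "distanceUnits must be a non-negative integer")
  if (!.isCount(minQuality))
    .err("validationError", "minQuality must be a non-negative integer")
  structure(list(ratioThreshold = ratioThreshold,
                 distanceUnits = as.integer(distanceUnits),
                 minQuality = as.integer(minQuality)),
            class = "HetCallParams")
}

#' Peak range of a base
#'
#' The search window of base *i* extends from halfway between its peak and
#' the previous peak to halfway to the next peak, in real (non-integer)
#' trace-point arithmetic. At the ends of the read the missing neighbour is
#' replaced by a half-window of the mean inter-peak spacing.
#'
#' @param prevPos,nextPos trace-point positions of the neighbouring peaks,
#'   or `NULL`/`NA` at a read end.
#' @param pos trace-point position of the current peak.
#' @param meanSpacing mean inter-peak spacing used for the end fallback.
#' @return A list with numeric `low`, `high` and `center`.
#' @examples
#' peakRange(100, 110, 124)  # low 105, high 117
#' @export
peakRange <- function(prevPos, pos, nextPos, meanSpacing = 12) {
  prevPos <- if (is.null(prevPos) || is.na(prevPos)) NULL else prevPos
  nextPos <- if (is.null(nextPos) || is.na(nextPos)) NULL else nextPos
  if ((!is.null(prevPos) && prevPos >= pos) ||
      (!is.null(nextPos) && nextPos <= pos))
    .err("validationError", "peak positions must be strictly increasing")
  low <- if (is.null(prevPos)) pos - meanSpacing / 2 else pos - (pos - prevPos) / 2
  high <- if (is.null(nextPos)) pos + meanSpacing / 2 else pos + (nextPos - pos) / 2
  list(low = low, high = high, center = pos)
}

# Local maxima (plateaus collapse to their first index) of one channel over
# the trace-point window [lo, hi], compared against the full trace.
.localMaxima <- function(signal, lo, hi) {
  n <- length(signal)
  idx <- seq.int(max(0L, ceiling(lo)), min(n - 1L, floor(hi)))
  if (!length(idx)) return(integer(0))
  v <- signal[idx + 1L]
  left <- ifelse(idx == 0L, -Inf, signal[idx])
  right <- ifelse(idx == n - 1L, -Inf, signal[idx + 2L])
  idx[v > left & v >= right]
}

#' Search a base's peak range for a secondary peak
#'
#' Scans the three non-primary channels for the tallest local maximum whose
#' apex lies inside the base's peak range, within `distanceUnits` trace
#' points of the primary apex, and whose height strictly exceeds
#' `ratioThreshold` times the primary apex height. Ties between channels are
#' broken by greater height, then by channel order A < C < G < T.
#'
#' @param chrom a [Chromatogram-class].
#' @param baseIndex 1-based index of the base to examine.
#' @param range the base's peak range from [peakRange()].
#' @param params a [hetCallParams()] list.
#' @return `NULL`, or a list with `base`, `height` and `position` of the
#'   qualifying secondary peak.
#' @export
findSecondaryPeak <- function(chrom, baseIndex, range,
                              params = hetCallParams()) {
  pos <- chrom@peakPositions[baseIndex]
  heightsAtPos <- chrom@channels[pos + 1L, ]
  primary <- .BASES[which.max(heightsAtPos)]
  primaryHeight <- heightsAtPos[[primary]]
  best <- NULL
  for (b in setdiff(.BASES, primary)) {
    apexes <- .localMaxima(chrom@channels[, b], range$low, range$high)
    apexes <- apexes[abs(apexes - pos) <= params$distanceUnits]
    if (!length(apexes)) next
    h <- chrom@channels[apexes + 1L, b]
    i <- which.max(h)
    if (h[i] > params$ratioThreshold * primaryHeight &&
        (is.null(best) || h[i] > best$height))
      best <- list(base = b, height = unname(h[i]), position = apexes[i])
  }
  best
}

#' Call homozygous/heterozygous bases from a chromatogram
#'
#' For every base the primary channel is the one with the greatest signal at
#' the base's peak position; [findSecondaryPeak()] then decides whether a
#' second allele is present. Heterozygous positions are emitted as the
#' 2-fold IUPAC code of the two bases, homozygous positions as the primary
#' base. Positions where all channels are zero are called `N`.
#'
#' @param chrom a [Chromatogram-class] (reverse reads should already be
#'   passed through [reverseOrient()]).
#' @param params a [hetCallParams()] list.
#' @param source provenance label of the read ("forward", "reverse" or
#'   "gssp"); defaults to "reverse" when `isReverse(chrom)` is `TRUE`.
#' @return A [CalledSequence-class] of the same length as the input base
#'   list (possibly length 0).
#' @export
callBases <- function(chrom, params = hetCallParams(), source = NULL) {
  validObject(chrom)
  if (is.null(source)) source <- if (chrom@isReverse) "reverse" else "forward"
  n <- length(chrom@peakPositions)
  if (n == 0L)
    return(CalledSequence(character(0), character(0), character(0),
                          numeric(0), numeric(0), integer(0), integer(0),
                          source = source))
  pos <- chrom@peakPositions
  meanSpacing <- if (n >= 2L) mean(diff(pos)) else 12
  bases <- primary <- secondary <- character(n)
  ph <- sh <- numeric(n)
  secondary[] <- NA_character_
  sh[] <- NA_real_
  for (i in seq_len(n)) {
    heightsAtPos <- chrom@channels[pos[i] + 1L, ]
    if (all(heightsAtPos == 0L)) {
      bases[i] <- "N"
      primary[i] <- NA_character_
      ph[i] <- 0
      next
    }
    pb <- .BASES[which.max(heightsAtPos)]
    primary[i] <- pb
    ph[i] <- heightsAtPos[[pb]]
    rng <- peakRange(if (i > 1L) pos[i - 1L] else NULL, pos[i],
                     if (i < n) pos[i + 1L] else NULL, meanSpacing)
    sec <- if (chrom@qualities[i] >= params$minQuality)
      findSecondaryPeak(chrom, i, rng, params) else NULL
    if (is.null(sec)) {
      bases[i] <- pb
    } else {
      bases[i] <- iupacEncode(c(pb, sec$base))
      secondary[i] <- sec$base
      sh[i] <- sec$height
    }
  }
  CalledSequence(bases = bases, primaryBase = primary,
                 secondaryBase = secondary, primaryHeight = ph,
                 secondaryHeight = sh, qualities = chrom@qualities,
                 positions = pos, source = source)
}

#' IUPAC-IUB encoding of a base set
#'
#' @param bases a nonempty character vector (subset of A, C, G, T;
#'   duplicates allowed).
#' @return The single-letter IUPAC code of the set, e.g. `c("A","G")` -> "R".
#' @export
iupacEncode <- function(bases) {
  bases <- toupper(bases)
  if (!length(bases) || !all(bases %in% .BASES))
    .err("validationError", "bases must be a nonempty subset of A, C, G, T")
  .MASK2CODE[sum(.BASE_MASK[unique(bases)])]
}

#' Decode an IUPAC code into its base set
#'
#' Inverse of [iupacEncode()]: `iupacDecode("R")` is `c("A","G")`.
#'
#' @param code a single IUPAC nucleotide character.
#' @return Character vector of the bases the code denotes, in A<C<G<T order.
#' @export
iupacDecode <- function(code) {
  code <- toupper(code)
  if (!.isString(code) || is.na(.CODE2MASK[code]))
    .err("validationError", "'%s' is not a valid IUPAC nucleotide code", code)
  .chars(Biostrings::IUPAC_CODE_MAP[[code]])
}

#' Export called bases to FASTA with a quality sidecar
#'
#' Writes the degenerate sequence as single-record FASTA (via Biostrings)
#' and the per-base qualities to `<file>.qual.tsv`.
#'
#' @param cs a [CalledSequence-class].
#' @param file output FASTA path.
#' @param name FASTA record name.
#' @return `file`, invisibly.
#' @export
writeCalledFasta <- function(cs, file, name = "called") {
  seq <- Biostrings::BStringSet(sequenceString(cs))
  names(seq) <- name
  Biostrings::writeXStringSet(seq, file)
  utils::write.table(
    data.frame(position = seq_along(cs@bases) - 1L, base = cs@bases,
               quality = cs@qualities),
    paste0(file, ".qual.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
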