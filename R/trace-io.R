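# ABIF container I/O.
#
# ABIF (.ab1/.fsa) is Applied Biosystems' binary format: a 4-byte "ABIF"
# magic, a 2-byte version, then a directory of typed tag entries (28 bytes
# each, big-endian). Only the tags the typing pipeline needs are supported:
# analyzed traces DATA 9-12, filter-wheel order FWO_, peak locations PLOC,
# base calls PBAS, qualities PCON, and the sample name SMPL. Entries whose
# payload fits in 4 bytes store it inline in the offset field.

.ABIF_TYPES <- c(byte = 1L, char = 2L, short = 4L, long = 5L, pString = 18L)

.beInt <- function(raw, offset, size, n = 1L, signed = TRUE) {
  readBin(raw[(offset + 1L):(offset + size * n)], "integer", n = n,
          size = size, endian = "big", signed = signed)
}

.parseDirEntry <- function(raw, off) {
  list(name = rawToChar(raw[(off + 1L):(off + 4L)]),
       number = .beInt(raw, off + 4L, 4L),
       type = .beInt(raw, off + 8L, 2L),
       esize = .beInt(raw, off + 10L, 2L),
       nelem = .beInt(raw, off + 12L, 4L),
       dsize = .beInt(raw, off + 16L, 4L),
       inline = raw[(off + 21L):(off + 24L)],
       doffset = .beInt(raw, off + 20L, 4L))
}

.entryBytes <- function(raw, e) {
  if (e$dsize <= 0L) return(raw(0))
  if (e$dsize <= 4L) return(e$inline[seq_len(e$dsize)])
  raw[(e$doffset + 1L):(e$doffset + e$dsize)]
}

.entryData <- function(raw, e) {
  b <- .entryBytes(raw, e)
  if (e$type == .ABIF_TYPES[["short"]])
    readBin(b, "integer", n = e$nelem, size = 2L, endian = "big")
  else if (e$type == .ABIF_TYPES[["byte"]])
    readBin(b, "integer", n = e$nelem, size = 1L, signed = FALSE)
  else if (e$type == .ABIF_TYPES[["char"]])
    rawToChar(b)
  else if (e$type == .ABIF_TYPES[["pString"]])
    if (length(b) > 1L) rawToChar(b[-1L]) else ""
  else
    .err("abifFormatError", "unsupported ABIF element type %d for tag %s",
         e$type, e$name)
}

#' Read an ABIF chromatogram
#'
#' Parses an `.ab1`/`.fsa` file (or an in-memory raw vector) into a
#' [Chromatogram-class]. The analyzed traces (`DATA` 9-12) are used, never
#' the raw ones; base-call tags (`PLOC`/`PBAS`/`PCON`) prefer the edited
#' copy (index 2) over the original (index 1) when both are present.
#' Channels are reordered by the file's `FWO_` filter-wheel tag so the
#' returned matrix is always keyed A, C, G, T.
#'
#' @param file path to an ABIF file, or a raw vector with its content.
#' @param strict if `TRUE` (default) a missing quality tag (`PCON`) is an
#'   error; if `FALSE`, qualities are filled with 0 and a warning is raised.
#' @param preferEdited prefer edited base-call tags (index 2) when present.
#' @return A [Chromatogram-class]; `isReverse` is always `FALSE`.
#' @examples
#' sim <- simulateSample(makeReference(simParams(nAlleles = 2, seed = 1)),
#'                       "SYN*01:01", "SYN*02:01",
#'                       simParams(nAlleles = 2, seed = 1), seed = 1)
#' f <- tempfile(fileext = ".ab1")
#' writeABIF(sim$forward, f)
#' readABIF(f)
#' @export
readABIF <- function(file, strict = TRUE, preferEdited = TRUE) {
  if (!is.raw(file) && !file.exists(file))
    .err("fileNotFoundError", "no such file: %s", file)
  raw <- if (is.raw(file)) file else
    readBin(file, "raw", n = file.info(file)$size)
  if (length(raw) < 34L || rawToChar(raw[1:4]) != "ABIF")
    .err("abifFormatError", "not an ABIF stream: bad magic")
  tdir <- .parseDirEntry(raw, 6L)
  entries <- lapply(seq_len(tdir$nelem) - 1L, function(i)
    .parseDirEntry(raw, tdir$doffset + 28L * i))
  keys <- vapply(entries, function(e) sprintf("%s.%d", e$name, e$number), "")
  getTag <- function(name, number, required = TRUE) {
    i <- match(sprintf("%s.%d", name, number), keys)
    if (is.na(i)) {
      if (required)
        .err("abifMissingTagError", "required ABIF tag %s (number %d) absent",
             name, number)
      return(NULL)
    }
    .entryData(raw, entries[[i]])
  }
  getIndexed <- function(name, required = TRUE) {
    idx <- if (preferEdited) c(2L, 1L) else c(1L, 2L)
    for (i in idx) {
      v <- getTag(name, i, required = FALSE)
      if (!is.null(v)) return(v)
    }
    if (required)
      .err("abifMissingTagError", "required ABIF tag %s (number 1 or 2) absent",
           name)
    NULL
  }

  fwo <- toupper(getTag("FWO_", 1L))
  if (!identical(sort(.chars(fwo)), .BASES))
    .err("abifFormatError", "FWO_ tag is not a permutation of ACGT: %s", fwo)
  chans <- lapply(1:4, function(i) getTag("DATA", 8L + i))
  names(chans) <- .chars(fwo)
  ploc <- getIndexed("PLOC")
  pbas <- .chars(getIndexed("PBAS"))
  pcon <- getIndexed("PCON", required = strict)
  if (is.null(pcon)) {
    .warn("abifMissingQualityWarning",
          "quality tag PCON absent; filling qualities with 0")
    pcon <- rep(0L, length(ploc))
  }
  smpl <- getTag("SMPL", 1L, required = FALSE)
  Chromatogram(channels = chans, peakPositions = ploc, calledBases = pbas,
               qualities = pmin(pcon, 62L),
               sampleID = if (is.null(smpl)) "" else smpl,
               channelOrder = fwo, isReverse = FALSE)
}

.beRaw <- function(x, size) {
  writeBin(as.integer(x), raw(), size = size, endian = "big")
}

.dirEntryRaw <- function(name, number, type, esize, nelem, dsize, offsetOrData) {
  inline <- if (dsize <= 4L) {
    pad <- raw(4L - dsize)
    c(offsetOrData, pad)
  } else .beRaw(offsetOrData, 4L)
  c(charToRaw(name), .beRaw(number, 4L), .beRaw(type, 2L), .beRaw(esize, 2L),
    .beRaw(nelem, 4L), .beRaw(dsize, 4L), inline, .beRaw(0L, 4L))
}

#' Write a Chromatogram as a minimal ABIF file
#'
#' Emits a valid ABIF stream containing exactly the tags [readABIF()]
#' requires (`DATA` 9-12, `FWO_`, `PLOC`/`PBAS`/`PCON` index 1, `SMPL`), so
#' that `readABIF(writeABIF(x))` reproduces channels, peak positions, base
#' calls, qualities and channel order exactly. Signals must fit in a signed
#' 16-bit integer (the ABIF trace element type).
#'
#' @param chrom a valid [Chromatogram-class].
#' @param file output path; if `NULL` the raw vector is returned instead.
#' @return The raw ABIF stream, invisibly when written to a file.
#' @export
writeABIF <- function(chrom, file = NULL) {
  validObject(chrom)
  if (nrow(chrom@channels) > 0L && max(chrom@channels) > 32767L)
    .err("validationError",
         "channel signals exceed 32767 and cannot be stored as ABIF shorts")
  if (length(chrom@peakPositions) &&
      max(chrom@peakPositions) > 32767L)
    .err("validationError", "peak positions exceed the ABIF short range")
  fwo <- .chars(chrom@channelOrder)
  ents <- list()
  add <- function(name, number, type, esize, nelem, payload) {
    ents[[length(ents) + 1L]] <<- list(name = name, number = number,
                                       type = type, esize = esize,
                                       nelem = nelem, payload = payload)
  }
  for (i in 1:4)
    add("DATA", 8L + i, .ABIF_TYPES[["short"]], 2L, nrow(chrom@channels),
        .beRaw(chrom@channels[, fwo[i]], 2L))
  add("FWO_", 1L, .ABIF_TYPES[["char"]], 1L, 4L, charToRaw(chrom@channelOrder))
  add("PLOC", 1L, .ABIF_TYPES[["short"]], 2L, length(chrom@peakPositions),
      .beRaw(chrom@peakPositions, 2L))
  add("PBAS", 1L, .ABIF_TYPES[["char"]], 1L, length(chrom@calledBases),
      charToRaw(paste0(chrom@calledBases, collapse = "")))
  add("PCON", 1L, .ABIF_TYPES[["byte"]], 1L, length(chrom@qualities),
      as.raw(chrom@qualities))
  if (nzchar(chrom@sampleID)) {
    s <- charToRaw(chrom@sampleID)
    add("SMPL", 1L, .ABIF_TYPES[["pString"]], 1L, length(s) + 1L,
        c(as.raw(length(s)), s))
  }

  dataStart <- 128L
  blocks <- raw(0)
  dirRaw <- raw(0)
  for (e in ents) {
    dsize <- length(e$payload)
    if (dsize > 4L) {
      off <- dataStart + length(blocks)
      blocks <- c(blocks, e$payload)
      dirRaw <- c(dirRaw, .dirEntryRaw(e$name, e$number, e$type, e$esize,
                                       e$nelem, dsize, off))
    } else {
      dirRaw <- c(dirRaw, .dirEntryRaw(e$name, e$number, e$type, e$esize,
                                       e$nelem, dsize, e$payload))
    }
  }
  dirOffset <- dataStart + length(blocks)
  header <- c(charToRaw("ABIF"), .beRaw(101L, 2L),
              .dirEntryRaw("tdir", 1L, 1023L, 28L, length(ents),
                           28L * length(ents), dirOffset))
  header <- c(header, raw(dataStart - length(header)))
  out <- c(header, blocks, dirRaw)
  if (is.null(file)) return(out)
  writeBin(out, file)
  invisible(out)
}

#' Reverse-complement a chromatogram
#'
#' Flips a trace into the opposite orientation: base calls are
#' reverse-complemented (IUPAC-aware), peak positions mirrored against the
#' trace length, channel arrays reversed with the A/T and C/G channels
#' swapped, and the `isReverse` flag toggled. Applying it twice is the
#' identity. Reads sequenced from the reverse strand must be passed through
#' this before strand merging.
#'
#' @param chrom a [Chromatogram-class].
#' @return The reoriented [Chromatogram-class].
#' @export
reverseOrient <- function(chrom) {
  n <- nrow(chrom@channels)
  ch <- chrom@channels[rev(seq_len(max(n, 0L))), , drop = FALSE]
  ch <- ch[, c("T", "G", "C", "A"), drop = FALSE]
  colnames(ch) <- .BASES
  new("Chromatogram", sampleID = chrom@sampleID, channels = ch,
      channelOrder = chrom@channelOrder,
      peakPositions = rev((n - 1L) - chrom@peakPositions),
      calledBases = rev(.complementChars(chrom@calledBases)),
      qualities = rev(chrom@qualities), isReverse = !chrom@isReverse)
}
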