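# Allele reference parsing and the per-locus degenerate consensus.
#
# Alleles live in shared multiple-alignment coordinates (0-based half-open
# internally). Two input dialects are supported: the IMGT/HLA nucleotide
# alignment text layout (first allele spelled out, '-' = identical to the
# first allele, '.' = alignment gap, '*' = unknown, '|' = exon boundary) and
# a simple TSV with one row per allele x exon.

# Consensus of a set of aligned sequences: per column, the IUPAC code of all
# observed bases; columns with no base are '*' if any allele is unknown
# there, else the gap character '.'.
.consensusFromSequences <- function(seqs) {
  if (!length(seqs)) return("")
  L <- nchar(seqs[1])
  u <- integer(L)
  anyStar <- logical(L)
  for (s in seqs) {
    m <- .seqMasks(s)
    anyStar <- anyStar | is.na(m)
    m[is.na(m)] <- 0L
    u <- bitwOr(u, m)
  }
  out <- ifelse(u > 0L, .MASK2CODE[u], ifelse(anyStar, "*", "."))
  paste0(out, collapse = "")
}

.checkAlleleName <- function(name) {
  ok <- grepl("^[A-Za-z0-9.-]+\\*[0-9]+(:[0-9]+)+[A-Za-z]?$", name)
  if (!all(ok))
    .err("parseError", "unparseable allele name(s): %s",
         paste(utils::head(name[!ok], 3), collapse = ", "))
  invisible(name)
}

.locusOf <- function(name) sub("\\*.*$", "", name)

.parseSimpleTSV <- function(text) {
  df <- utils::read.delim(text = text, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("allele_name", "exon", "sequence")
  if (!all(need %in% names(df)))
    .err("parseError", "simple-tsv reference needs columns %s",
         paste(need, collapse = ", "))
  df$exon <- as.integer(df$exon)
  df$sequence <- toupper(df$sequence)
  .checkAlleleName(unique(df$allele_name))
  df$locus <- .locusOf(df$allele_name)

  alleles <- NULL
  spans <- NULL
  for (loc in unique(df$locus)) {
    d <- df[df$locus == loc, , drop = FALSE]
    exons <- sort(unique(d$exon))
    exonLen <- integer(length(exons))
    nms <- unique(d$allele_name)
    for (k in seq_along(exons)) {
      dk <- d[d$exon == exons[k], , drop = FALSE]
      if (!setequal(dk$allele_name, nms))
        .err("parseError", "locus %s: exon %d missing for some alleles",
             loc, exons[k])
      lens <- unique(nchar(dk$sequence))
      if (length(lens) != 1L) {
        bad <- dk$allele_name[nchar(dk$sequence) != stats::median(nchar(dk$sequence))]
        .err("parseError", "ragged alignment in locus %s exon %d (allele %s)",
             loc, exons[k], bad[1])
      }
      exonLen[k] <- lens
    }
    starts <- cumsum(c(0L, exonLen[-length(exonLen)]))
    spans <- rbind(spans, data.frame(locus = loc, exon = exons,
                                     start = starts, end = starts + exonLen))
    seqs <- vapply(nms, function(nm) {
      dd <- d[d$allele_name == nm, , drop = FALSE]
      paste0(dd$sequence[order(dd$exon)], collapse = "")
    }, character(1))
    alleles <- rbind(alleles, data.frame(locus = loc, name = nms,
                                         sequence = unname(seqs)))
  }
  list(alleles = alleles, exonSpans = spans)
}

.parseIMGT <- function(text, exons = NULL) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  pat <- "^\\s*([A-Za-z0-9.-]+\\*[0-9:]+[A-Za-z]?)\\s+(.+)$"
  hit <- grepl(pat, lines)
  acc <- list()
  order_ <- character(0)
  for (ln in lines[hit]) {
    nm <- sub(pat, "\\1", ln)
    chunk <- gsub("\\s", "", sub(pat, "\\2", ln))
    if (grepl("[^ACGTacgt.*|-]", chunk)) next  # header/coordinate line
    if (is.null(acc[[nm]])) {
      acc[[nm]] <- chunk
      order_ <- c(order_, nm)
    } else acc[[nm]] <- paste0(acc[[nm]], chunk)
  }
  if (!length(order_)) .err("parseError", "no allele rows found in alignment")
  .checkAlleleName(order_)
  lens <- vapply(acc[order_], nchar, integer(1))
  if (length(unique(lens)) != 1L)
    .err("parseError", "ragged alignment length for allele %s",
         order_[which(lens != lens[1])[1]])

  refChars <- .chars(acc[[order_[1]]])
  bound <- which(refChars == "|")
  expand <- function(nm) {
    ch <- .chars(acc[[nm]])
    if (!identical(which(ch == "|"), bound))
      .err("parseError", "exon boundaries of allele %s disagree with %s",
           nm, order_[1])
    ch <- ifelse(ch == "-", refChars, ch)
    ch[ch != "|"]
  }
  seqs <- vapply(order_, function(nm) paste0(expand(nm), collapse = ""),
                 character(1))
  # segment lengths in gapless ('|'-free) coordinates
  segLen <- diff(c(0L, bound - seq_along(bound),
                   length(refChars) - length(bound)))
  if (is.null(exons)) exons <- seq_along(segLen)
  if (length(exons) != length(segLen))
    .err("parseError", "%d exon numbers supplied for %d alignment segments",
         length(exons), length(segLen))
  loci <- .locusOf(order_)
  if (length(unique(loci)) != 1L)
    .err("parseError", "IMGT alignment must contain a single locus")
  starts <- cumsum(c(0L, segLen[-length(segLen)]))
  list(alleles = data.frame(locus = loci, name = order_,
                            sequence = unname(seqs)),
       exonSpans = data.frame(locus = loci[1], exon = as.integer(exons),
                              start = starts, end = starts + segLen))
}

#' Parse an allele reference alignment
#'
#' Reads either the IMGT/HLA nucleotide alignment text layout or the simple
#' TSV dialect (columns `allele_name`, `exon`, `sequence`; one row per
#' allele and exon, sequences in shared alignment coordinates). Identity
#' dashes in the IMGT dialect are resolved against the first allele; every
#' returned allele carries a full explicit sequence.
#'
#' @param text reference file content as a single string, a character vector
#'   of lines, or a path to a file.
#' @param dialect `"simple-tsv"` or `"imgt-alignment"`.
#' @param exons exon numbers of the alignment segments (IMGT dialect only;
#'   defaults to 1..n segments as in the `*_nuc.txt` files).
#' @param version version string stored on the result.
#' @return A [ReferenceSet-class] with per-locus consensus built.
#' @export
parseReference <- function(text, dialect = c("simple-tsv", "imgt-alignment"),
                           exons = NULL, version = "unversioned") {
  dialect <- match.arg(dialect)
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- paste0(readLines(text, warn = FALSE), collapse = "\n")
  if (length(text) > 1L) text <- paste0(text, collapse = "\n")
  parsed <- switch(dialect,
                   "simple-tsv" = .parseSimpleTSV(text),
                   "imgt-alignment" = .parseIMGT(text, exons = exons))
  ReferenceSet(parsed$alleles, parsed$exonSpans, version = version)
}

#' Degenerate consensus of a locus (or one of its exons)
#'
#' Per column, the IUPAC code of the set of non-gap bases observed across
#' the alleles; all-gap columns stay `.` and unknown-only columns become
#' `*`. Unknown stretches (`*` in an allele) contribute no observation.
#'
#' @param ref a [ReferenceSet-class].
#' @param locus locus to summarise.
#' @param exon optional exon number; when given only that exon's columns are
#'   returned.
#' @return The consensus as a single degenerate string.
#' @export
buildConsensus <- function(ref, locus, exon = NULL) {
  seqs <- ref@alleles$sequence[ref@alleles$locus == locus]
  if (!length(seqs)) .err("unknownLocusError", "locus %s not in reference", locus)
  if (is.null(exon)) return(.consensusFromSequences(seqs))
  es <- exonSpans(ref, locus)
  i <- match(exon, es$exon)
  if (is.na(i))
    .err("coverageError", "exon %d is not covered by locus %s", exon, locus)
  .consensusFromSequences(substr(seqs, es$start[i] + 1L, es$end[i]))
}

#' Truncate an allele name to two-field resolution
#'
#' `A*01:01:01:01` becomes `A*01:01` — the protein-level designation used
#' clinically. Vectorised.
#'
#' @param name allele name(s) with at least two colon-separated fields.
#' @return Two-field designation(s).
#' @export
twoField <- function(name) {
  pat <- "^([A-Za-z0-9.-]+\\*)([0-9]+):([0-9]+).*$"
  ok <- grepl(pat, name)
  if (!all(ok))
    .err("validationError", "allele name(s) lack two fields: %s",
         paste(name[!ok], collapse = ", "))
  sub(pat, "\\1\\2:\\3", name)
}

.TABLE1_EXONS <- list(
  "A" = 1:6, "B" = 1:5, "C" = 1:7,
  "DRB1" = 1:4, "DRB3" = 2:3, "DRB4" = 2:3, "DRB5" = 2:3,
  "DQA1" = 1:4, "DQB1" = 1:4, "DPB1" = 1:4, "DPA1" = 1:4,
  "G" = 2:4)

#' Exon regions analysable per HLA gene group
#'
#' The exon coverage model of the engine: which exons of each supported
#' gene group are expected in an SBT run (e.g. exons 2 and 3 carry the
#' peptide-binding groove of the class I genes).
#'
#' @param locus gene name, with or without the `HLA-` prefix.
#' @return Integer vector of exon numbers; empty (with a warning) for an
#'   unknown locus.
#' @examples
#' supportedRegions("HLA-B")  # 1 2 3 4 5
#' @export
supportedRegions <- function(locus) {
  key <- toupper(sub("^HLA-", "", locus, ignore.case = TRUE))
  if (!key %in% names(.TABLE1_EXONS)) {
    .warn("unknownLocusWarning", "locus %s has no exon coverage model", locus)
    return(integer(0))
  }
  .TABLE1_EXONS[[key]]
}

#' Serialise / reload a ReferenceSet as flat files
#'
#' The static allele database is stored transparently as a simple-TSV
#' alignment plus a JSON manifest (`{version, loci, counts}`), so a parsed
#' reference round-trips exactly.
#'
#' @param ref a [ReferenceSet-class].
#' @param dir directory to write `alleles.tsv` and `manifest.json` into
#'   (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- NULL
  for (loc in loci(ref)) {
    es <- exonSpans(ref, loc)
    d <- ref@alleles[ref@alleles$locus == loc, , drop = FALSE]
    for (k in seq_len(nrow(es)))
      rows <- rbind(rows, data.frame(
        allele_name = d$name, exon = es$exon[k],
        sequence = substr(d$sequence, es$start[k] + 1L, es$end[k])))
  }
  utils::write.table(rows, file.path(dir, "alleles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  counts <- vapply(loci(ref), function(l) sum(ref@alleles$locus == l), 0L)
  jsonlite::write_json(
    list(version = ref@version, loci = loci(ref), counts = as.list(counts)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname writeReference
#' @export
readReference <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  parseReference(file.path(dir, "alleles.tsv"), dialect = "simple-tsv",
                 version = man$version)
}
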