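# Group-specific sequencing primer (GSSP) support.
#
# A GSSP amplifies and sequences only one allele group, so its read is a
# single-allele (essentially non-degenerate) sequence that discriminates
# between ambiguous pairs. Definitions are alignment-anchored: a locus, an
# exon, a half-open column region, and a degenerate selector the amplified
# allele must match over that region.

#' Batch-import GSSP definitions from a TSV table
#'
#' Expected columns: `gssp_id`, `locus`, `exon`, `start`, `end`, `selector`
#' (coordinates 0-based half-open in the locus alignment). All rows are
#' validated against the loaded reference; duplicate identifiers and
#' regions or selectors that do not fit the alignment are rejected with the
#' offending `gssp_id` named.
#'
#' @param table path to the TSV file, or its content as a string.
#' @param ref a [ReferenceSet-class].
#' @return data.frame of validated definitions.
#' @export
importGssps <- function(table, ref) {
  if (length(table) == 1L && !grepl("\n", table) && file.exists(table))
    table <- paste0(readLines(table, warn = FALSE), collapse = "\n")
  df <- utils::read.delim(text = table, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("gssp_id", "locus", "exon", "start", "end", "selector")
  if (!all(need %in% names(df)))
    .err("parseError", "GSSP table needs columns %s",
         paste(need, collapse = ", "))
  df <- df[need]
  df$exon <- as.integer(df$exon)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$selector <- toupper(df$selector)
  dup <- df$gssp_id[duplicated(df$gssp_id)]
  if (length(dup))
    .err("duplicateGsspError", "duplicate gssp_id: %s",
         paste(unique(dup), collapse = ", "))
  for (k in seq_len(nrow(df))) {
    if (!df$locus[k] %in% loci(ref))
      .err("gsspRowError", "GSSP %s: locus %s absent from reference",
           df$gssp_id[k], df$locus[k])
    L <- nchar(consensusSeq(ref, df$locus[k]))
    if (df$start[k] < 0L || df$end[k] > L || df$start[k] >= df$end[k])
      .err("gsspRowError", "GSSP %s: region [%d,%d) outside alignment (%d columns)",
           df$gssp_id[k], df$start[k], df$end[k], L)
    if (nchar(df$selector[k]) != df$end[k] - df$start[k])
      .err("gsspRowError", "GSSP %s: selector length %d != region length %d",
           df$gssp_id[k], nchar(df$selector[k]), df$end[k] - df$start[k])
    .charMasks(.chars(df$selector[k]), what = sprintf("GSSP %s selector",
                                                      df$gssp_id[k]))
  }
  df
}

# Project a read's calls onto the alignment columns of a locus.
# Returns masks per column (NA = not covered) and the covered span.
.projectRead <- function(read, ref, locus, scheme) {
  cons <- consensusSeq(ref, locus)
  aln <- semiglobalAlign(calledBases(read), cons, scheme)
  m <- rep(NA_integer_, nchar(cons))
  keep <- !is.na(aln@queryToRef)
  m[aln@queryToRef[keep] + 1L] <- unname(.CODE2MASK[read@bases[keep]])
  list(masks = m, span = c(aln@refStart, aln@refEnd), score = aln@score)
}

#' Identify which GSSP a read belongs to
#'
#' Aligns the read to each candidate locus consensus and returns the
#' definition whose region overlaps the aligned span the most among those
#' whose selector is consistent with the read (no region column where the
#' read's code and the selector's code are disjoint). Ties break by larger
#' overlap, then `gssp_id`.
#'
#' @param read a [CalledSequence-class] from a GSSP chromatogram.
#' @param gssps definitions from [importGssps()].
#' @param ref a [ReferenceSet-class].
#' @param scheme a [scoringScheme()].
#' @return The matching definition as a one-row data.frame.
#' @export
identifyGssp <- function(read, gssps, ref, scheme = scoringScheme()) {
  if (!nrow(gssps)) .err("validationError", "empty GSSP definition list")
  stats <- lapply(unique(gssps$locus), function(loc) {
    pr <- tryCatch(.projectRead(read, ref, loc, scheme),
                   error = function(e) NULL)
    if (is.null(pr)) return(NULL)
    d <- gssps[gssps$locus == loc, , drop = FALSE]
    lapply(seq_len(nrow(d)), function(k) {
      cols <- seq.int(d$start[k] + 1L, d$end[k])
      rm_ <- pr$masks[cols]
      sel <- .charMasks(.chars(d$selector[k]))
      cov <- which(!is.na(rm_) & !is.na(sel) & sel > 0L)
      bad <- sum(bitwAnd(rm_[cov], sel[cov]) == 0L)
      list(id = d$gssp_id[k], row = d[k, , drop = FALSE],
           overlap = length(cov), inconsistent = bad)
    })
  })
  stats <- do.call(c, stats)
  if (is.null(stats) || !length(stats))
    .err("gsspIdentificationError", "read aligns to no GSSP locus")
  ok <- Filter(function(s) s$overlap > 0L && s$inconsistent == 0L, stats)
  if (!length(ok)) {
    near <- stats[order(vapply(stats, function(s) s$inconsistent, 0),
                        -vapply(stats, function(s) s$overlap, 0L))]
    near <- utils::head(near, 3L)
    .err("gsspIdentificationError",
         "no GSSP consistent with the read; nearest: %s",
         paste(vapply(near, function(s)
           sprintf("%s (overlap %d, %d inconsistent)", s$id, s$overlap,
                   s$inconsistent), ""), collapse = "; "))
  }
  ord <- order(-vapply(ok, function(s) s$overlap, 0L),
               vapply(ok, function(s) s$id, ""))
  ok[[ord[1]]]$row
}

#' Filter ambiguous candidates with a GSSP read
#'
#' A GSSP read derives from a single allele, so over its region it should
#' be non-degenerate and equal to one allele of the true pair. A candidate
#' pair survives iff at least one of its alleles (a) matches the GSSP
#' selector over the region (is amplifiable) and (b) equals the read
#' positionwise over the region columns the read covers. Heterozygous read
#' positions beyond `maxHetFrac` trigger a non-specific-amplification
#' warning; degenerate positions are ignored either way. Ranking order is
#' preserved among survivors, and the filter is idempotent for a fixed read.
#'
#' @param candidates candidate data.frame from [enumeratePairs()].
#' @param gsspRead a [CalledSequence-class] of the GSSP trace.
#' @param gssp a one-row definition (from [importGssps()] /
#'   [identifyGssp()]).
#' @param ref a [ReferenceSet-class].
#' @param scheme a [scoringScheme()].
#' @param maxHetFrac warning threshold on the fraction of heterozygous
#'   positions in the read's covered region (default 0.2).
#' @return The surviving candidates, same columns and order.
#' @export
filterWithGssp <- function(candidates, gsspRead, gssp, ref,
                           scheme = scoringScheme(), maxHetFrac = 0.2) {
  if (!nrow(candidates)) return(candidates)
  locus <- gssp$locus[1]
  pr <- .projectRead(gsspRead, ref, locus, scheme)
  cols <- seq.int(gssp$start[1] + 1L, gssp$end[1])
  rm_ <- pr$masks[cols]
  sel <- .charMasks(.chars(gssp$selector[1]))
  covered <- which(!is.na(rm_))
  if (length(covered)) {
    hetFrac <- mean(.BITCOUNT[rm_[covered] + 1L] > 1L)
    if (hetFrac > maxHetFrac)
      .warn("gsspHeterozygousWarning",
            paste0("%.0f%% of GSSP read positions are heterozygous; ",
                   "possible non-specific amplification"), 100 * hetFrac)
  }
  usable <- covered[.BITCOUNT[rm_[covered] + 1L] == 1L]

  alleleOK <- function(name) {
    am <- .seqMasks(alleleSeq(ref, name))[cols]
    selCols <- which(!is.na(am) & am > 0L & !is.na(sel) & sel > 0L)
    if (any(bitwAnd(am[selCols], sel[selCols]) == 0L)) return(FALSE)
    if (length(usable) && any(am[usable] != rm_[usable], na.rm = TRUE))
      return(FALSE)
    TRUE
  }
  nms <- unique(c(candidates$allele1, candidates$allele2))
  okMap <- stats::setNames(vapply(nms, alleleOK, logical(1)), nms)
  keep <- okMap[candidates$allele1] | okMap[candidates$allele2]
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
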