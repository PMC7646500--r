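# Shared fixtures and independent oracles, all built in code.

# Render a degenerate truth string as Gaussian peaks, independently of the
# package simulator (so basecaller tests do not lean on simulateSample).
renderTrace <- function(truth, spacing = 12L, sigma = 2.5, amp = 1000,
                        ratio = 1.0, quals = 50L) {
  ch <- strsplit(toupper(truth), "")[[1]]
  n <- length(ch)
  pos <- spacing * seq_len(n)
  len <- spacing * (n + 1L) + 1L
  sig <- matrix(0, len, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  gauss <- function(center, h) h * exp(-((0:(len - 1)) - center)^2 / (2 * sigma^2))
  for (i in seq_len(n)) {
    dec <- iupacDecode(ch[i])
    sig[, dec[1]] <- sig[, dec[1]] + gauss(pos[i], amp)
    for (b in dec[-1]) sig[, b] <- sig[, b] + gauss(pos[i], ratio * amp)
  }
  Chromatogram(round(sig), pos, ch, rep(quals, n))
}

# Three homozygous A peaks with a controllable secondary C peak under the
# middle base: apex at pos2 + offset, height ratio * amp.
traceWithSecondary <- function(ratio, offset, spacing = 12L, sigma = 2.5,
                               amp = 1000) {
  pos <- spacing * (1:3)
  len <- spacing * 4L + 1L
  sig <- matrix(0, len, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  gauss <- function(center, h) h * exp(-((0:(len - 1)) - center)^2 / (2 * sigma^2))
  for (p in pos) sig[, "A"] <- sig[, "A"] + gauss(p, amp)
  sig[, "C"] <- sig[, "C"] + gauss(pos[2] + offset, ratio * amp)
  Chromatogram(round(sig), pos, c("A", "A", "A"), c(50L, 50L, 50L))
}

# CalledSequence from a plain base string (evidence filled from the codes).
mkCS <- function(bases, quals = 50L, source = "forward") {
  ch <- strsplit(toupper(bases), "")[[1]]
  dec <- lapply(ch, iupacDecode)
  two <- lengths(dec) == 2L
  SangerHLA::CalledSequence(
    bases = ch,
    primaryBase = vapply(dec, `[`, "", 1L),
    secondaryBase = ifelse(two, vapply(dec, function(d) d[min(2L, length(d))], ""),
                           NA_character_),
    primaryHeight = rep(1000, length(ch)),
    secondaryHeight = ifelse(two, 1000, NA_real_),
    qualities = rep_len(quals, length(ch)),
    positions = 12L * seq_along(ch), source = source)
}

mkSampleConsensus <- function(bases, locus = "SYN", sampleID = "s",
                              quals = 50L) {
  ch <- strsplit(toupper(bases), "")[[1]]
  ch[ch == "?"] <- NA_character_
  known <- !is.na(ch)
  new("SampleConsensus", sampleID = sampleID, locus = locus, bases = ch,
      support = ifelse(known, "forward", "none"),
      conflict = rep(FALSE, length(ch)),
      qualities = ifelse(known, rep_len(quals, length(ch)), 0L))
}

# Tiny hand-built reference: locus TOY, one exon, three alleles.
toyRef <- function() {
  tsv <- paste(
    "allele_name\texon\tsequence",
    "TOY*01:01\t2\tAAAAAA",
    "TOY*02:01\t2\tAAGAAA",
    "TOY*03:01\t2\tAATAAC",
    sep = "\n")
  parseReference(tsv, dialect = "simple-tsv", version = "toy")
}

# --- independent alignment oracle ------------------------------------------
# Per-column score computed by explicit exhaustive pairing of the two
# diploid allele pairs (no bitmask arithmetic).
oracleColScore <- function(a, b, match2 = 2L, match1 = 1L, mismatch = 0L) {
  da <- iupacDecode(a); db <- iupacDecode(b)
  if (length(da) > 2L || length(db) > 2L)
    return(if (length(intersect(da, db))) match1 else mismatch)
  pa <- if (length(da) == 1L) c(da, da) else da
  pb <- if (length(db) == 1L) c(db, db) else db
  best <- max(sum(pa == pb), sum(pa == rev(pb)))
  c(mismatch, match1, match2)[best + 1L]
}

# Maximum over all free-end-gap alignments, by the recursive definition
# "best suffix alignment starting at (i, j), allowed to stop anywhere",
# memoised, maximised over all start cells.
oracleAlignScore <- function(q, r, indel = -1L) {
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  n <- length(qc); m <- length(rc)
  memo <- array(NA_integer_, dim = c(n + 1L, m + 1L))
  e <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- 0L
    if (i <= n && j <= m) v <- max(v, oracleColScore(qc[i], rc[j]) + e(i + 1L, j + 1L))
    if (i <= n) v <- max(v, indel + e(i + 1L, j))
    if (j <= m) v <- max(v, indel + e(i, j + 1L))
    memo[i, j] <<- v
    v
  }
  best <- 0L
  for (i in seq_len(n + 1L)) for (j in seq_len(m + 1L))
    best <- max(best, e(i, j))
  best
}

revComp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

degenAlphabet <- c("A", "C", "G", "T", "R", "Y", "M", "K", "S", "W")

randSeq <- function(len, alphabet = degenAlphabet) {
  paste0(sample(alphabet, len, replace = TRUE), collapse = "")
}
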