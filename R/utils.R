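#' @useDynLib SangerHLA, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

.BASES <- c("A", "C", "G", "T")

# Bitmask encoding of base sets: A=1, C=2, G=4, T=8. The IUPAC code of a set
# is then a pure table lookup and the union of two codes is bitwOr().
.BASE_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L)

# Lookup tables derived from the canonical Biostrings IUPAC map.
.CODE2MASK <- vapply(Biostrings::IUPAC_CODE_MAP, function(s) {
  sum(.BASE_MASK[strsplit(s, "")[[1]]])
}, integer(1))

.MASK2CODE <- {
  v <- character(15L)
  v[.CODE2MASK] <- names(.CODE2MASK)
  v
}

.BITCOUNT <- vapply(0:15, function(m) {
  sum(bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L)
}, integer(1))

# IUPAC-aware complement table, taken from Biostrings so the degenerate codes
# map correctly (R<->Y, M<->K, B<->V, D<->H; S, W, N self-complementary).
.COMP_SRC <- paste0(c(names(Biostrings::IUPAC_CODE_MAP), ".", "-"), collapse = "")
.COMP_DST <- paste0(c(strsplit(as.character(Biostrings::complement(
  Biostrings::DNAString(paste0(names(Biostrings::IUPAC_CODE_MAP), collapse = "")))),
  "")[[1]], ".", "-"), collapse = "")

.complementChars <- function(x) chartr(.COMP_SRC, .COMP_DST, x)

#' @noRd
.err <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "sangerHLAError")))
}

.warn <- function(class, fmt, ...) {
  warning(warningCondition(sprintf(fmt, ...), class = c(class, "sangerHLAWarning")))
}

# Split a sequence string into single characters (uppercased).
.chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]

# Masks for a character vector of sequence symbols. Alignment gaps ('-', '.')
# map to 0; unknown stretches ('*') map to NA (no observation); anything that
# is not an IUPAC code is an error unless `permissive`.
.charMasks <- function(chars, permissive = FALSE, what = "sequence") {
  m <- unname(.CODE2MASK[chars])
  gap <- chars %in% c("-", ".")
  m[gap] <- 0L
  unk <- chars == "*"
  m[unk] <- NA_integer_
  bad <- is.na(m) & !unk
  if (any(bad)) {
    if (!permissive) {
      .err("invalidBaseError", "invalid %s character(s): %s", what,
           paste(unique(chars[bad]), collapse = ", "))
    }
    m[bad] <- NA_integer_
  }
  m
}

.seqMasks <- function(s, ...) .charMasks(.chars(s), ...)

# Per-column comparison score between two mask-encoded degenerate bases,
# interpreting each as an unordered diploid pair (X -> (X,X), 2-fold code ->
# its two bases). Vectorised.
.maskScore <- function(a, b, scheme = scoringScheme()) {
  stopifnot(length(a) == length(b))
  small <- .BITCOUNT[a + 1L] <= 2L & .BITCOUNT[b + 1L] <= 2L
  out <- ifelse(a == b & small, scheme$match2,
         ifelse(bitwAnd(a, b) > 0L, scheme$match1, scheme$mismatch))
  out[a == 0L | b == 0L] <- scheme$mismatch
  as.integer(out)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.isString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
.isCount <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
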