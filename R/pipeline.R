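# End-to-end typing runs, resumable sessions, and report export.
#
# A run reads chromatograms, calls bases, merges strands, enumerates and
# ranks allele pairs, and optionally applies GSSP reads — per sample, with
# per-sample error isolation. All intermediate state needed to reproduce
# the results (merged consensus, GSSP read calls, edits) is kept in a
# TypingSession that serialises to a single JSON file; reloading it
# reproduces identical TypingResults without re-reading any chromatogram.

# Minimal CalledSequence from a degenerate base string (evidence heights
# are unknown); used when reconstructing sessions.
.csFromBases <- function(bases, qualities, positions, source) {
  ch <- if (length(bases) == 1L && nchar(bases[1]) != 1L) .chars(bases) else bases
  m <- unname(.CODE2MASK[ch])
  two <- .BITCOUNT[m + 1L] == 2L
  prim <- vapply(ch, function(b) iupacDecode(b)[1], "")
  sec <- rep(NA_character_, length(ch))
  sec[two] <- vapply(ch[two], function(b) iupacDecode(b)[2], "")
  CalledSequence(bases = ch, primaryBase = unname(prim), secondaryBase = sec,
                 primaryHeight = rep(NA_real_, length(ch)),
                 secondaryHeight = ifelse(two, NA_real_, NA_real_),
                 qualities = qualities, positions = positions,
                 source = source)
}

.parseSampleFilename <- function(path) {
  base <- sub("\\.(ab1|fsa)$", "", basename(path), ignore.case = TRUE)
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  if (length(parts) < 3L) return(NULL)
  n <- length(parts)
  tag <- toupper(parts[n])
  role <- if (tag %in% c("F", "FWD", "FORWARD")) "forward"
          else if (tag %in% c("R", "REV", "REVERSE")) "reverse"
          else "gssp"
  list(sampleID = paste(parts[seq_len(n - 2L)], collapse = "_"),
       locus = parts[n - 1L], role = role,
       gsspID = if (role == "gssp") parts[n] else NA_character_,
       file = path)
}

# Normalise the accepted input forms into one record per sample x locus.
.resolveInputs <- function(inputs) {
  if (is.character(inputs) && length(inputs) == 1L && dir.exists(inputs))
    inputs <- list.files(inputs, pattern = "\\.(ab1|fsa)$", full.names = TRUE,
                         ignore.case = TRUE)
  if (is.character(inputs) && length(inputs) == 1L &&
      grepl("\\.json$", inputs, ignore.case = TRUE))
    inputs <- jsonlite::read_json(inputs)
  if (is.list(inputs) && !is.null(inputs$samples)) {
    return(lapply(inputs$samples, function(s) list(
      sampleID = s$sample_id, locus = s$locus,
      forward = s$forward, reverse = s$reverse,
      gssp = lapply(s$gssp %||% list(), function(g)
        list(file = g$file, gsspID = g$gssp_id %||% NA_character_)))))
  }
  recs <- Filter(Negate(is.null), lapply(inputs, .parseSampleFilename))
  if (!length(recs))
    .err("validationError",
         "no inputs: expected a manifest or files named <sample>_<locus>_<F|R|gsspID>.ab1")
  keys <- vapply(recs, function(r) paste(r$sampleID, r$locus, sep = "\r"), "")
  lapply(split(recs, keys), function(g) {
    out <- list(sampleID = g[[1]]$sampleID, locus = g[[1]]$locus,
                forward = NULL, reverse = NULL, gssp = list())
    for (r in g) {
      if (r$role == "forward") out$forward <- r$file
      else if (r$role == "reverse") out$reverse <- r$file
      else out$gssp <- c(out$gssp, list(list(file = r$file, gsspID = r$gsspID)))
    }
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Recompute candidates and result of one sample state from its stored
# consensus, reapplying stored GSSP evidence. The single code path used by
# fresh runs, session reloads and base edits.
.recomputeSample <- function(ref, state, params) {
  sc <- new("SampleConsensus", sampleID = state$sampleID,
            locus = state$locus, bases = state$consensusBases,
            support = state$support, conflict = state$conflict,
            qualities = state$qualities)
  cand <- enumeratePairs(sc, ref, maxMismatch = params$maxMismatch,
                         scheme = params$scheme)
  applied <- character(0)
  for (g in state$gsspReads) {
    def <- params$gsspDefs[params$gsspDefs$gssp_id == g$gsspID, , drop = FALSE]
    if (!nrow(def)) next
    cs <- .csFromBases(g$bases, g$qualities, g$positions, "gssp")
    cand <- filterWithGssp(cand, cs, def, ref, scheme = params$scheme)
    applied <- c(applied, g$gsspID)
  }
  state$result <- rankReport(cand, sampleID = state$sampleID,
                             locus = state$locus,
                             coveredColumns = sum(!is.na(state$consensusBases)),
                             gsspApplied = applied)
  state$gsspApplied <- applied
  state
}

#' Run the full typing pipeline
#'
#' For every sample: read chromatograms, call bases ([callBases()]), merge
#' strands ([mergeReads()]), enumerate and rank allele pairs
#' ([enumeratePairs()], [rankReport()]) and apply any GSSP reads
#' ([filterWithGssp()]). A failing sample is recorded with status "error"
#' and the run continues.
#'
#' @param inputs a directory of `.ab1`/`.fsa` files following the
#'   `<sample>_<locus>_<F|R|gsspID>.ab1` convention, a character vector of
#'   such files, a manifest JSON path, or an equivalent manifest list
#'   (`samples` = list of `sample_id`, `locus`, `forward`, `reverse`,
#'   optional `gssp` entries with `file` and `gssp_id`).
#' @param reference a [ReferenceSet-class] or a directory written by
#'   [writeReference()].
#' @param gssps optional GSSP definition table ([importGssps()] output, or
#'   a TSV path/content).
#' @param hetParams a [hetCallParams()] list.
#' @param scheme a [scoringScheme()].
#' @param maxMismatch candidate display window (see [enumeratePairs()]).
#' @param minScoreFrac read alignment floor (see [mergeReads()]).
#' @param strict passed to [readABIF()].
#' @return A [TypingSession-class]; per-sample results via
#'   [typingResults()].
#' @export
runTyping <- function(inputs, reference, gssps = NULL,
                      hetParams = hetCallParams(), scheme = scoringScheme(),
                      maxMismatch = 5L, minScoreFrac = 0.5, strict = TRUE) {
  ref <- if (is(reference, "ReferenceSet")) reference else
    readReference(reference)
  gsspDefs <- if (is.null(gssps)) {
    data.frame(gssp_id = character(0), locus = character(0),
               exon = integer(0), start = integer(0), end = integer(0),
               selector = character(0))
  } else if (is.data.frame(gssps)) gssps else importGssps(gssps, ref)
  params <- list(hetParams = hetParams, scheme = scheme,
                 maxMismatch = as.integer(maxMismatch),
                 minScoreFrac = minScoreFrac, gsspDefs = gsspDefs)
  recs <- .resolveInputs(inputs)
  samples <- list()
  for (rec in recs) {
    key <- paste(rec$sampleID, rec$locus, sep = ":")
    state <- tryCatch({
      cons <- consensusSeq(ref, rec$locus)
      fcs <- if (!is.null(rec$forward))
        callBases(readABIF(rec$forward, strict = strict), hetParams,
                  source = "forward")
      rcs <- if (!is.null(rec$reverse))
        callBases(reverseOrient(readABIF(rec$reverse, strict = strict)),
                  hetParams, source = "reverse")
      sc <- mergeReads(fcs, rcs, cons, scheme = scheme,
                       minScoreFrac = minScoreFrac,
                       sampleID = rec$sampleID, locus = rec$locus)
      gsspReads <- lapply(rec$gssp, function(g) {
        cs <- callBases(readABIF(g$file, strict = strict), hetParams,
                        source = "gssp")
        id <- g$gsspID
        if (is.na(id) || !id %in% gsspDefs$gssp_id)
          id <- identifyGssp(cs, gsspDefs, ref, scheme)$gssp_id[1]
        list(gsspID = id, bases = calledBases(cs),
             qualities = baseQualities(cs), positions = peakPositions(cs))
      })
      st <- list(sampleID = rec$sampleID, locus = rec$locus,
                 files = rec[c("forward", "reverse")],
                 consensusBases = sc@bases, support = sc@support,
                 conflict = sc@conflict, qualities = sc@qualities,
                 gsspReads = gsspReads, edits = list())
      .recomputeSample(ref, st, params)
    }, error = function(e) {
      list(sampleID = rec$sampleID, locus = rec$locus, files = rec,
           gsspReads = list(), edits = list(),
           result = new("TypingResult", sampleID = rec$sampleID,
                        locus = rec$locus,
                        candidates = data.frame(), minMismatch = NA_integer_,
                        ambiguous = NA, assignment = character(0),
                        coveredColumns = NA_integer_,
                        gsspApplied = character(0), status = "error",
                        message = conditionMessage(e)))
    })
    samples[[key]] <- state
  }
  now <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  new("TypingSession", reference = ref, samples = samples, params = params,
      created = now, updated = now)
}

#' Override a base call and recompute downstream results
#'
#' Stores a position -> base override on the sample's merged consensus (the
#' headless equivalent of editing a miscalled base under the trace), records
#' it in the sample's audit trail, and recomputes candidate enumeration,
#' GSSP filtering and ranking. Applying the same edit twice is idempotent.
#'
#' @param session a [TypingSession-class].
#' @param sampleID sample key as shown in the session (`"<sample>:<locus>"`
#'   or plain sample id when unambiguous).
#' @param position 0-based alignment coordinate; must lie inside the
#'   sample's coverage.
#' @param base a single IUPAC character.
#' @return The updated session.
#' @export
applyBaseEdit <- function(session, sampleID, position, base) {
  base <- toupper(base)
  if (!.isString(base) || is.na(.CODE2MASK[base]))
    .err("validationError", "'%s' is not a valid IUPAC base", base)
  key <- if (sampleID %in% names(session@samples)) sampleID else {
    hits <- grep(paste0("^", sampleID, ":"), names(session@samples), value = TRUE)
    if (length(hits) != 1L)
      .err("validationError", "sample '%s' not found (or ambiguous)", sampleID)
    hits
  }
  state <- session@samples[[key]]
  if (!.isCount(position) || position >= length(state$consensusBases) ||
      is.na(state$consensusBases[position + 1L]))
    .err("validationError",
         "position %s is outside the sample's coverage", format(position))
  state$consensusBases[position + 1L] <- base
  state$edits <- c(state$edits, list(list(position = as.integer(position),
                                          base = base)))
  session@samples[[key]] <- .recomputeSample(session@reference, state,
                                             session@params)
  session@updated <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  session
}

.resultToList <- function(r) {
  cand <- candidates(r)
  list(sample_id = r@sampleID, locus = r@locus, status = r@status,
       min_mismatch = r@minMismatch, ambiguous = r@ambiguous,
       assignment = as.list(r@assignment),
       covered_columns = r@coveredColumns,
       gssp_applied = as.list(r@gsspApplied),
       message = r@message,
       candidates = lapply(seq_len(nrow(cand)), function(i) list(
         allele1 = cand$allele1[i], allele2 = cand$allele2[i],
         mismatch_count = cand$mismatch_count[i],
         total_score = cand$total_score[i],
         mismatch_positions = as.list(cand$mismatch_positions[[i]]))))
}

#' Export typing results
#'
#' @param results a list of [TypingResult-class]s or a
#'   [TypingSession-class].
#' @param format `"json"`, `"tsv"` or `"text"`. The TSV has one row per
#'   sample x locus with the two-field alleles, mismatch count, ambiguity
#'   flag and GSSPs applied; an empty result list yields a header-only
#'   table. Reports carry no timestamps, so identical runs export
#'   byte-identical content.
#' @param file optional output path.
#' @return The report content as a single string (invisibly when `file` is
#'   given).
#' @export
exportReport <- function(results, format = c("json", "tsv", "text"),
                         file = NULL) {
  format <- match.arg(format)
  if (is(results, "TypingSession")) results <- typingResults(results)
  out <- switch(format,
    json = as.character(jsonlite::toJSON(
      lapply(results, .resultToList), auto_unbox = TRUE, digits = NA,
      pretty = TRUE, null = "null", na = "null")),
    tsv = {
      rows <- vapply(results, function(r) {
        a <- if (length(r@assignment)) r@assignment else c(NA, NA)
        paste(r@sampleID, r@locus, a[1], a[2], r@minMismatch, r@ambiguous,
              paste(r@gsspApplied, collapse = ","), r@status, sep = "\t")
      }, "")
      paste0(paste(c(paste("sample_id", "locus", "allele1", "allele2",
                           "mismatch_count", "ambiguous", "gssp_applied",
                           "status", sep = "\t"), rows), collapse = "\n"),
             "\n")
    },
    text = {
      blocks <- vapply(results, function(r) {
        hdr <- sprintf("Sample %s  locus %s  [%s]", r@sampleID, r@locus,
                       r@status)
        asg <- if (length(r@assignment))
          sprintf("  assignment: %s (mismatches: %s%s)",
                  paste(r@assignment, collapse = " / "), r@minMismatch,
                  if (isTRUE(r@ambiguous)) "; AMBIGUOUS - consider GSSP"
                  else "") else "  no typing"
        cand <- candidates(r)
        lines <- if (nrow(cand)) vapply(seq_len(min(nrow(cand), 10L)),
          function(i) sprintf("    %s + %s  mismatches=%d score=%d",
                              cand$allele1[i], cand$allele2[i],
                              cand$mismatch_count[i], cand$total_score[i]),
          "") else character(0)
        paste(c(hdr, asg, lines), collapse = "\n")
      }, "")
      paste0(paste(blocks, collapse = "\n\n"), "\n")
    })
  if (!is.null(file)) {
    writeLines(out, file, sep = "")
    return(invisible(out))
  }
  out
}

#' Save / load a typing session
#'
#' The session — reference, parameters, per-sample merged consensus, GSSP
#' read calls, edits and results — is serialised to one JSON file.
#' [loadSession()] reconstructs it and recomputes the per-sample results
#' from the stored consensus (never from the chromatograms); a save/load
#' round-trip therefore reproduces identical results.
#'
#' @param session a [TypingSession-class].
#' @param path JSON file path.
#' @return `path` invisibly; `loadSession()` returns the session.
#' @export
saveSession <- function(session, path) {
  ref <- session@reference
  ser <- list(
    format = "sangerhla-session-1",
    created = session@created, updated = session@updated,
    reference = list(version = ref@version,
                     alleles = ref@alleles[c("locus", "name", "sequence")],
                     exon_spans = ref@exonSpans),
    params = list(
      het = unclass(session@params$hetParams),
      scheme = unclass(session@params$scheme),
      max_mismatch = session@params$maxMismatch,
      min_score_frac = session@params$minScoreFrac,
      gssp_defs = session@params$gsspDefs),
    samples = lapply(session@samples, function(s) list(
      sample_id = s$sampleID, locus = s$locus,
      consensus = paste0(ifelse(is.na(s$consensusBases), "?",
                                s$consensusBases), collapse = ""),
      support = paste0(substr(s$support, 1, 1), collapse = ""),
      conflict = as.integer(which(s$conflict) - 1L),
      qualities = s$qualities,
      gssp_reads = lapply(s$gsspReads, function(g) list(
        gssp_id = g$gsspID, bases = paste0(g$bases, collapse = ""),
        qualities = g$qualities, positions = g$positions)),
      edits = s$edits)))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname saveSession
#' @export
loadSession <- function(path) {
  j <- jsonlite::read_json(path)
  ref <- ReferenceSet(
    do.call(rbind, lapply(j$reference$alleles, as.data.frame)),
    do.call(rbind, lapply(j$reference$exon_spans, as.data.frame)),
    version = j$reference$version)
  gsspDefs <- if (length(j$params$gssp_defs))
    do.call(rbind, lapply(j$params$gssp_defs, as.data.frame))
  else data.frame(gssp_id = character(0), locus = character(0),
                  exon = integer(0), start = integer(0), end = integer(0),
                  selector = character(0))
  params <- list(
    hetParams = do.call(hetCallParams, j$params$het),
    scheme = do.call(scoringScheme, j$params$scheme),
    maxMismatch = as.integer(j$params$max_mismatch),
    minScoreFrac = j$params$min_score_frac,
    gsspDefs = gsspDefs)
  supportMap <- c(n = "none", f = "forward", r = "reverse", b = "both")
  samples <- lapply(j$samples, function(s) {
    bases <- .chars(s$consensus)
    bases[bases == "?"] <- NA_character_
    L <- length(bases)
    conflict <- rep(FALSE, L)
    conflict[unlist(s$conflict) + 1L] <- TRUE
    st <- list(sampleID = s$sample_id, locus = s$locus,
               consensusBases = bases,
               support = unname(supportMap[strsplit(s$support, "")[[1]]]),
               conflict = conflict,
               qualities = as.integer(unlist(s$qualities)),
               gsspReads = lapply(s$gssp_reads, function(g) list(
                 gsspID = g$gssp_id, bases = .chars(g$bases),
                 qualities = as.integer(unlist(g$qualities)),
                 positions = as.integer(unlist(g$positions)))),
               edits = s$edits)
    .recomputeSample(ref, st, params)
  })
  names(samples) <- names(j$samples)
  new("TypingSession", reference = ref, samples = samples, params = params,
      created = j$created, updated = j$updated)
}
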