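#' @include AllClasses.R anchors.R telomere.R
NULL

#' Curation configuration
#'
#' All thresholds the curation engine applies, with the defaults the
#' toolkit was designed around: terminal overlaps of at least 50 kb are
#' merged, contigs shorter than the minimum usable long-read length
#' (10 kb) are dropped, reads with >= 80% of their length aligned to other
#' scaffolds are not recruited for local reassembly, and scaffold ends
#' are trimmed where short-read depth falls below 1.
#'
#' @param minOverlap merge threshold in bp (default 50000).
#' @param minContigLength contigs shorter than this are dropped
#'   (default 10000; a contig of exactly this length survives).
#' @param minReadLength minimum read length for reassembly recruitment
#'   (default 10000).
#' @param dropAlignedFraction reads whose union aligned fraction to
#'   non-target scaffolds is at least this are dropped (default 0.80,
#'   inclusive).
#' @param trimMinDepth terminal bases with depth below this are trimmed
#'   (default 1, i.e. zero-depth ends go).
#' @param telomere a [telomereParams()] list.
#' @param k anchor k-mer size (default 21).
#' @param mitoCoverFraction contig flagged mitochondrial when at least
#'   this fraction of its length is covered by anchor chains to a
#'   mitochondrial reference (default 0.5).
#' @param terminalSearch see [detectTerminalOverlap()] (default 200000).
#' @param maxGap anchor chaining gap tolerance in bp (default 10000).
#' @param minAnchors minimum anchors per correspondence chain
#'   (default 50).
#' @param minSpan minimum span for split evidence in bp (default 50000).
#' @return a validated list of class `CurationConfig`.
#' @export
curationConfig <- function(minOverlap = 50000L, minContigLength = 10000L,
                           minReadLength = 10000L,
                           dropAlignedFraction = 0.80, trimMinDepth = 1L,
                           telomere = telomereParams(), k = 21L,
                           mitoCoverFraction = 0.5,
                           terminalSearch = 200000L, maxGap = 10000L,
                           minAnchors = 50L, minSpan = 50000L) {
  stopifnot(minOverlap > 0, minContigLength > 0, minReadLength > 0,
            dropAlignedFraction > 0, dropAlignedFraction <= 1,
            trimMinDepth > 0, mitoCoverFraction > 0)
  structure(list(minOverlap = minOverlap,
                 minContigLength = minContigLength,
                 minReadLength = minReadLength,
                 dropAlignedFraction = dropAlignedFraction,
                 trimMinDepth = trimMinDepth, telomere = telomere,
                 k = as.integer(k),
                 mitoCoverFraction = mitoCoverFraction,
                 terminalSearch = terminalSearch, maxGap = maxGap,
                 minAnchors = minAnchors, minSpan = minSpan),
            class = "CurationConfig")
}

emptyActions <- function() {
  data.frame(ordinal = integer(), action = character(),
             subjects = character(), parameters = character(),
             result = character(), stringsAsFactors = FALSE)
}

addAction <- function(log, action, subjects, parameters = "",
                      result = "") {
  rbind(log, data.frame(ordinal = nrow(log) + 1L, action = action,
                        subjects = subjects, parameters = parameters,
                        result = result, stringsAsFactors = FALSE))
}

encodeParams <- function(...) {
  kv <- list(...)
  paste(names(kv), unlist(kv), sep = "=", collapse = ";")
}

decodeParams <- function(s) {
  if (!nzchar(s)) return(list())
  kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
  out <- lapply(kv, `[[`, 2L)
  names(out) <- vapply(kv, `[[`, "", 1L)
  out
}

#' Summarise a candidate assembly for baseline ranking
#'
#' @param x an [Assembly-class].
#' @param params [telomereParams()] used for the T2T count.
#' @return one-row data.frame: `assembler`, `n_contigs`,
#'   `n_contigs_ge_100kb`, `n50`, `l50`, `t2t_count`.
#' @export
summarizeCandidate <- function(x, params = telomereParams()) {
  st <- assemblyStats(x)
  tel <- scanTelomeres(x, params)
  data.frame(assembler = x@name, n_contigs = length(x),
             n_contigs_ge_100kb = sum(scaffoldLengths(x) >= 100000L),
             n50 = st@n50, l50 = st@l50, t2t_count = sum(tel$t2t))
}

#' Select the baseline assembly among draft candidates
#'
#' Ranks candidates by telomere-to-telomere contig count (descending),
#' then contig count (ascending), then N50 (descending); deterministic
#' (remaining ties resolved by input order).
#'
#' @param candidates data.frame of candidate summaries (one per
#'   assembler), as from [summarizeCandidate()].
#' @return list with `best` (the winning row) and `ranking` (the full
#'   data.frame ordered best-first, with a `rank` column).
#' @export
selectBaseline <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop("empty candidate list")
  ord <- order(-candidates$t2t_count, candidates$n_contigs,
               -candidates$n50)
  ranking <- candidates[ord, , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  list(best = ranking[1L, , drop = FALSE], ranking = ranking)
}

#' Drop contigs shorter than the minimum usable length
#'
#' @param x an [Assembly-class].
#' @param minContigLength drop threshold in bp; a contig is kept iff its
#'   length is at least this (default 10000).
#' @param log an existing action log to append to.
#' @return list with `assembly` (contigs removed) and `actions`.
#' @export
dropShortContigs <- function(x, minContigLength = 10000L,
                             log = emptyActions()) {
  lens <- scaffoldLengths(x)
  short <- names(lens)[lens < minContigLength]
  for (id in short)
    log <- addAction(log, "drop_short", id,
                     encodeParams(length = lens[[id]],
                                  threshold = minContigLength))
  keep <- setdiff(names(lens), short)
  list(assembly = x[keep], actions = log)
}

#' Flag mitochondrial contigs by anchor coverage against references
#'
#' A contig is flagged when the fraction of its length covered by unique
#' k-mer anchor chains to any mitochondrial reference reaches
#' `mitoCoverFraction`. Flagged contigs are quarantined by [curate()],
#' never deleted.
#'
#' @param x an [Assembly-class].
#' @param mitoRefs an [Assembly-class] of reference mitochondrial
#'   genomes, or `NULL` (no flags, a warning is logged).
#' @param config a [curationConfig()].
#' @return character vector of flagged contig ids (named with the covered
#'   fraction).
#' @export
flagMitochondrial <- function(x, mitoRefs, config = curationConfig()) {
  if (is.null(mitoRefs) || length(mitoRefs) == 0L) {
    warning("no mitochondrial references supplied; nothing flagged")
    return(character())
  }
  anc <- anchorMatches(x, mitoRefs, k = config$k)
  if (nrow(anc) == 0L) return(character())
  chains <- chainAnchors(anc, k = config$k, maxGap = config$maxGap)
  chains <- chains[chains$n_anchors >= 10L, , drop = FALSE]
  flagged <- character()
  lens <- scaffoldLengths(x)
  for (id in unique(chains$a_scaffold)) {
    ch <- chains[chains$a_scaffold == id, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(start = ch$a_start,
                                           end = ch$a_end + config$k - 1))
    frac <- sum(IRanges::width(ir)) / lens[[id]]
    if (frac >= config$mitoCoverFraction)
      flagged[id] <- frac
  }
  names(flagged)
}

#' Merge two contigs across a detected terminal overlap
#'
#' Concatenates two contigs that share a terminal overlap of at least the
#' merge threshold, keeping the overlap bases from contig `a`. The second
#' contig is reverse-complemented when the overlap chain is in reverse
#' orientation. Errors on a non-candidate report or mismatched termini.
#'
#' @param a,b contig sequences (character strings).
#' @param report an `OverlapReport` from [detectTerminalOverlap()] with
#'   `is_merge_candidate = TRUE`.
#' @return merged sequence (character). The merged length equals
#'   `nchar(a) + nchar(b) - overlap_length`.
#' @export
mergeByOverlap <- function(a, b, report) {
  if (!isTRUE(report$is_merge_candidate))
    stop("overlap report is not a merge candidate")
  o <- report$overlap_length
  if (o > nchar(a) || o > nchar(b))
    stop("overlap longer than a contig")
  bT <- report$b_terminus
  if (identical(report$orientation, "reverse")) {
    b <- revComp(b)
    bT <- if (bT == "start") "end" else "start"
  }
  if (report$a_terminus == "end" && bT == "start") {
    paste0(a, substr(b, o + 1L, nchar(b)))
  } else if (report$a_terminus == "start" && bT == "end") {
    paste0(substr(b, 1L, nchar(b) - o), a)
  } else {
    stop("termini mismatch: cannot merge ", report$a_terminus, " with ",
         bT)
  }
}

#' Split a chimeric scaffold at a breakpoint
#'
#' @param x scaffold sequence (character).
#' @param breakpoint split position in bp; the first part is bases
#'   `1..breakpoint`, the second `breakpoint+1..length`.
#' @param evidence supporting evidence (correspondence split support
#'   and/or multiple centromere calls); refused when missing unless
#'   `force = TRUE`.
#' @param force split without evidence.
#' @return list with `left` and `right` sequences; lengths sum to the
#'   original length.
#' @export
splitAtBreakpoint <- function(x, breakpoint, evidence = NULL,
                              force = FALSE) {
  n <- nchar(x)
  if (breakpoint <= 0 || breakpoint >= n)
    stop("breakpoint must lie strictly inside the scaffold")
  if (is.null(evidence) && !force)
    stop("refusing to split without evidence (use force = TRUE)")
  list(left = substr(x, 1L, breakpoint),
       right = substr(x, breakpoint + 1L, n))
}

#' Trim scaffold ends lacking read support
#'
#' Removes the maximal terminal runs whose depth is below `trimMinDepth`
#' at both ends; internal unsupported runs are untouched. Idempotent.
#'
#' @param x scaffold sequence (character).
#' @param covTrack [CoverageTrack-class] of the same length.
#' @param trimMinDepth minimum supporting depth (default 1).
#' @return list with `sequence`, `depth` (trimmed track vector),
#'   `left` and `right` (bp removed per end).
#' @export
trimUnsupportedEnds <- function(x, covTrack, trimMinDepth = 1L) {
  depth <- if (is(covTrack, "CoverageTrack")) covTrack@depth else covTrack
  n <- nchar(x)
  if (length(depth) != n)
    stop("coverage length must equal scaffold length")
  supported <- which(depth >= trimMinDepth)
  if (length(supported) == 0L)
    stop("whole scaffold unsupported; refusing to emit empty scaffold")
  left <- supported[1L] - 1L
  right <- n - supported[length(supported)]
  list(sequence = substr(x, left + 1L, n - right),
       depth = depth[(left + 1L):(n - right)],
       left = left, right = right)
}

#' Recruit reads for local reassembly
#'
#' A read is kept iff it is at least `minReadLength` long and the union of
#' its aligned intervals to scaffolds outside `excludedScaffolds` covers
#' less than `dropAlignedFraction` of its length (reads aligning >= 80%
#' elsewhere are dropped, inclusive).
#'
#' @param alignments data.frame as from [readPaf()].
#' @param excludedScaffolds scaffolds being rebuilt; alignments to them do
#'   not count against a read.
#' @param config a [curationConfig()].
#' @return character vector of kept read ids.
#' @export
partitionUnassignedReads <- function(alignments, excludedScaffolds,
                                     config = curationConfig()) {
  if (nrow(alignments) == 0L) return(character())
  lens <- tapply(alignments$query_length, alignments$query_id,
                 function(v) v[1L])
  others <- setdiff(unique(alignments$target_id), excludedScaffolds)
  frac <- alignedFraction(alignments, targets = others)
  reads <- names(lens)
  keep <- lens[reads] >= config$minReadLength &
    frac[reads] < config$dropAlignedFraction
  sort(reads[keep])
}

# Refine an approximate chimera breakpoint using interior telomere arrays:
# a misjoin of two complete chromosomes leaves the left chromosome's
# terminal (TTAGGG)n array and/or the right chromosome's initial (CCCTAA)n
# array at the junction, which locate it exactly. When neither array is
# found nearby, the anchor-chain midpoint stands (accuracy bounded by k
# plus the chaining gap).
refineBreakpoint <- function(seq, bp, telomere, window = 5000L) {
  n <- nchar(seq)
  lo <- max(1L, as.integer(bp) - window)
  hi <- min(n, as.integer(bp) + window)
  region <- substr(seq, lo, hi)
  eRun <- longestTandemRun(region, telomere$endMotif,
                           telomere$maxInterruption, tieBreak = "start")
  if (eRun$copies >= telomere$minCopies) {
    cand <- lo + eRun$span[2L] - 1L
    if (cand > 0L && cand < n) return(cand)
  }
  sRun <- longestTandemRun(region, telomere$startMotif,
                           telomere$maxInterruption, tieBreak = "end")
  if (sRun$copies >= telomere$minCopies) {
    cand <- lo + sRun$span[1L] - 2L
    if (cand > 0L && cand < n) return(cand)
  }
  bp
}

# ---- full pipeline -------------------------------------------------------

# coverage helpers used by merge/split to keep tracks in step with edits
coverageVector <- function(coverage, id) {
  tr <- coverage[[id]]
  if (is.null(tr)) NULL else if (is(tr, "CoverageTrack")) tr@depth else tr
}

#' Run the full curation pipeline
#'
#' Applies, in order: short-contig dropping, mitochondrial quarantining,
#' terminal-overlap merging, chimera splitting (evidence from alternate
#' assemblies), unsupported-end trimming, and renaming to
#' `scaffold_1 ... scaffold_n` in decreasing length order. Every decision
#' is logged with its measured evidence; [replayActions()] re-applies the
#' log to the baseline and reproduces the output byte-identically.
#'
#' @param baseline the baseline [Assembly-class] (e.g. the winner of
#'   [selectBaseline()]).
#' @param alternates list of alternate [Assembly-class] objects providing
#'   split evidence.
#' @param coverage named list of [CoverageTrack-class] (or plain integer
#'   vectors), one per baseline contig, used for end trimming; `NULL`
#'   skips trimming.
#' @param mitoRefs [Assembly-class] of mitochondrial references, or
#'   `NULL`.
#' @param config a [curationConfig()].
#' @return a [CurationResult-class].
#' @export
curate <- function(baseline, alternates = list(), coverage = NULL,
                   mitoRefs = NULL, config = curationConfig()) {
  stopifnot(is(baseline, "Assembly"), length(baseline) > 0L)
  log <- emptyActions()
  seqs <- stats::setNames(as.list(as.character(baseline@seqs)),
                          scaffoldNames(baseline))
  cov <- if (is.null(coverage)) list()
         else stats::setNames(lapply(names(coverage), function(id)
           coverageVector(coverage, id)), names(coverage))

  # 1. drop short contigs
  lens <- vapply(seqs, nchar, 0)
  short <- names(lens)[lens < config$minContigLength]
  for (id in short) {
    log <- addAction(log, "drop_short", id,
                     encodeParams(length = lens[[id]],
                                  threshold = config$minContigLength))
    seqs[[id]] <- NULL
    cov[[id]] <- NULL
  }

  # 2. quarantine mitochondrial contigs
  quarantine <- list()
  if (!is.null(mitoRefs) && length(mitoRefs) > 0L) {
    flagged <- flagMitochondrial(
      assembly(unlist(seqs), name = baseline@name), mitoRefs, config)
    for (id in flagged) {
      log <- addAction(log, "flag_mito", id,
                       encodeParams(cover_fraction_min =
                                      config$mitoCoverFraction))
      quarantine[[id]] <- seqs[[id]]
      seqs[[id]] <- NULL
      cov[[id]] <- NULL
    }
  }

  # 3. merge terminal-overlap candidates (greedy, largest overlap first)
  repeat {
    ids <- names(seqs)
    bestRep <- NULL
    if (length(ids) >= 2L) {
      for (i in seq_len(length(ids) - 1L)) {
        for (j in (i + 1L):length(ids)) {
          # keep the longer contig as 'a' so overlap bases come from it
          aId <- ids[i]; bId <- ids[j]
          if (nchar(seqs[[bId]]) > nchar(seqs[[aId]])) {
            tmp <- aId; aId <- bId; bId <- tmp
          }
          rep <- detectTerminalOverlap(
            stats::setNames(seqs[[aId]], aId)[[1L]],
            stats::setNames(seqs[[bId]], bId)[[1L]],
            k = config$k, minOverlap = config$minOverlap,
            terminalSearch = config$terminalSearch,
            maxGap = config$maxGap)
          rep$a_scaffold <- aId
          rep$b_scaffold <- bId
          if (isTRUE(rep$is_merge_candidate) &&
              (is.null(bestRep) ||
               rep$overlap_length > bestRep$overlap_length))
            bestRep <- rep
        }
      }
    }
    if (is.null(bestRep)) break
    aId <- bestRep$a_scaffold
    bId <- bestRep$b_scaffold
    merged <- mergeByOverlap(seqs[[aId]], seqs[[bId]], bestRep)
    newId <- paste(aId, bId, sep = "+")
    o <- bestRep$overlap_length
    # propagate coverage through the same arithmetic as the sequence
    if (!is.null(cov[[aId]]) && !is.null(cov[[bId]])) {
      cb <- cov[[bId]]
      if (identical(bestRep$orientation, "reverse")) cb <- rev(cb)
      bT <- bestRep$b_terminus
      if (identical(bestRep$orientation, "reverse"))
        bT <- if (bT == "start") "end" else "start"
      tailB <- if (o < length(cb)) cb[(o + 1L):length(cb)] else integer()
      cov[[newId]] <- if (bestRep$a_terminus == "end")
        c(cov[[aId]], tailB)
      else
        c(cb[seq_len(length(cb) - o)], cov[[aId]])
    }
    log <- addAction(log, "merge", paste(aId, bId, sep = ","),
                     encodeParams(overlap = o,
                                  orientation = bestRep$orientation,
                                  a_terminus = bestRep$a_terminus,
                                  b_terminus = bestRep$b_terminus),
                     result = newId)
    # rebuild the list preserving order: merged replaces 'a'
    pos <- match(aId, names(seqs))
    seqs[[aId]] <- NULL
    seqs[[bId]] <- NULL
    seqs <- append(seqs, stats::setNames(list(merged), newId),
                   after = pos - 1L)
    cov[[aId]] <- NULL
    cov[[bId]] <- NULL
  }

  # 4. split chimeras using correspondence evidence from alternates
  corrByAlt <- lapply(alternates, function(alt) {
    anc <- anchorMatches(assembly(unlist(seqs), name = baseline@name),
                         alt, k = config$k)
    contigCorrespondence(anc, minAnchors = config$minAnchors,
                         minSpan = config$minSpan, k = config$k,
                         maxGap = config$maxGap)
  })
  for (id in names(seqs)) {
    bps <- numeric()
    for (ai in seq_along(alternates)) {
      entry <- corrByAlt[[ai]][[id]]
      if (!is.null(entry) && isTRUE(entry$split)) {
        bps <- entry$breakpoints
        evidenceAlt <- alternates[[ai]]@name
        break
      }
    }
    if (length(bps) == 0L) next
    bps <- vapply(bps, function(bp)
      refineBreakpoint(seqs[[id]], bp, config$telomere), numeric(1L))
    pieces <- list()
    rest <- seqs[[id]]
    offset <- 0
    for (bp in sort(bps)) {
      sp <- splitAtBreakpoint(rest, bp - offset,
                              evidence = "correspondence")
      pieces[[length(pieces) + 1L]] <- sp$left
      rest <- sp$right
      offset <- bp
    }
    pieces[[length(pieces) + 1L]] <- rest
    newIds <- paste0(id, ".", seq_along(pieces))
    log <- addAction(log, "split", id,
                     encodeParams(breakpoints = paste(sort(bps),
                                                      collapse = ","),
                                  evidence = evidenceAlt),
                     result = paste(newIds, collapse = ","))
    pos <- match(id, names(seqs))
    seqs[[id]] <- NULL
    seqs <- append(seqs, stats::setNames(pieces, newIds),
                   after = pos - 1L)
    if (!is.null(cov[[id]])) {
      cuts <- c(0, sort(bps), length(cov[[id]]))
      for (m in seq_along(newIds))
        cov[[newIds[m]]] <- cov[[id]][(cuts[m] + 1L):cuts[m + 1L]]
      cov[[id]] <- NULL
    }
  }

  # 5. trim unsupported ends
  for (id in names(seqs)) {
    if (is.null(cov[[id]])) next
    tr <- trimUnsupportedEnds(seqs[[id]], cov[[id]], config$trimMinDepth)
    if (tr$left > 0L || tr$right > 0L) {
      log <- addAction(log, "trim", id,
                       encodeParams(left = tr$left, right = tr$right),
                       result = id)
      seqs[[id]] <- tr$sequence
      cov[[id]] <- tr$depth
    }
  }

  # 6. rename in decreasing length order
  lens <- vapply(seqs, nchar, 0)
  ord <- order(-lens, names(seqs))
  newNames <- paste0("scaffold_", seq_along(ord))
  mapStr <- paste(names(seqs)[ord], newNames, sep = ">", collapse = ",")
  log <- addAction(log, "rename", paste(names(seqs)[ord], collapse = ","),
                   encodeParams(map = mapStr),
                   result = paste(newNames, collapse = ","))
  finalSeqs <- stats::setNames(unlist(seqs[ord]), newNames)
  finalCov <- stats::setNames(cov[names(seqs)[ord]], newNames)
  finalCov <- finalCov[!vapply(finalCov, is.null, TRUE)]
  finalAsm <- assembly(finalSeqs, name = paste0(baseline@name, "_curated"))
  quarantineAsm <- assembly(
    if (length(quarantine)) unlist(quarantine) else character(),
    name = paste0(baseline@name, "_quarantined"))
  new("CurationResult", assembly = finalAsm, quarantined = quarantineAsm,
      actions = log, telomeres = scanTelomeres(finalAsm, config$telomere),
      stats = assemblyStats(finalAsm),
      coverage = lapply(finalCov, function(d)
        new("CoverageTrack", scaffold = "x", depth = as.integer(d))))
}

#' Replay a curation action log against the baseline
#'
#' Re-applies the logged actions (drops, quarantines, merges with their
#' recorded overlap/orientation, splits at recorded breakpoints, trims by
#' recorded amounts, final renaming) to the baseline assembly. The result
#' must be byte-identical to the assembly the original [curate()] run
#' produced; this is the audit guarantee of the log.
#'
#' @param baseline the baseline [Assembly-class] given to [curate()].
#' @param actions the action log data.frame from a
#'   [CurationResult-class].
#' @return the reconstructed final [Assembly-class].
#' @export
replayActions <- function(baseline, actions) {
  seqs <- stats::setNames(as.list(as.character(baseline@seqs)),
                          scaffoldNames(baseline))
  for (i in seq_len(nrow(actions))) {
    act <- actions[i, ]
    p <- decodeParams(act$parameters)
    subjects <- strsplit(act$subjects, ",", fixed = TRUE)[[1L]]
    if (act$action %in% c("drop_short", "flag_mito")) {
      for (id in subjects) seqs[[id]] <- NULL
    } else if (act$action == "merge") {
      rep <- list(a_terminus = p$a_terminus, b_terminus = p$b_terminus,
                  orientation = p$orientation,
                  overlap_length = as.numeric(p$overlap),
                  is_merge_candidate = TRUE)
      merged <- mergeByOverlap(seqs[[subjects[1L]]], seqs[[subjects[2L]]],
                               rep)
      pos <- match(subjects[1L], names(seqs))
      seqs[[subjects[1L]]] <- NULL
      seqs[[subjects[2L]]] <- NULL
      seqs <- append(seqs, stats::setNames(list(merged), act$result),
                     after = pos - 1L)
    } else if (act$action == "split") {
      bps <- as.numeric(strsplit(p$breakpoints, ",", fixed = TRUE)[[1L]])
      newIds <- strsplit(act$result, ",", fixed = TRUE)[[1L]]
      pieces <- list()
      rest <- seqs[[subjects[1L]]]
      offset <- 0
      for (bp in sort(bps)) {
        sp <- splitAtBreakpoint(rest, bp - offset, force = TRUE)
        pieces[[length(pieces) + 1L]] <- sp$left
        rest <- sp$right
        offset <- bp
      }
      pieces[[length(pieces) + 1L]] <- rest
      pos <- match(subjects[1L], names(seqs))
      seqs[[subjects[1L]]] <- NULL
      seqs <- append(seqs, stats::setNames(pieces, newIds),
                     after = pos - 1L)
    } else if (act$action == "trim") {
      id <- subjects[1L]
      n <- nchar(seqs[[id]])
      seqs[[id]] <- substr(seqs[[id]], as.integer(p$left) + 1L,
                           n - as.integer(p$right))
    } else if (act$action == "rename") {
      pairs <- strsplit(strsplit(p$map, ",", fixed = TRUE)[[1L]], ">",
                        fixed = TRUE)
      old <- vapply(pairs, `[[`, "", 1L)
      newN <- vapply(pairs, `[[`, "", 2L)
      seqs <- stats::setNames(seqs[old], newN)
    }
  }
  assembly(unlist(seqs), name = paste0(baseline@name, "_replayed"))
}
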