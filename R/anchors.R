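#' @include AllClasses.R
NULL

revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Unique k-mer anchor matches between two assemblies
#'
#' Dotplot-grade whole-assembly comparison: a position pair is an anchor
#' when its canonical k-mer (lexicographic minimum of the k-mer and its
#' reverse complement) occurs exactly once in each assembly. Windows
#' containing N are skipped. Anchors give deterministic, desk-scale
#' evidence for contig correspondence, terminal overlaps and chimera
#' breakpoints without base-level alignment.
#'
#' @param a,b [Assembly-class] objects (or single named character vectors
#'   accepted by [assembly()]).
#' @param k odd k-mer size in `[11, 31]` (default 21).
#' @return data.frame sorted by (`a_scaffold`, `a_pos`): `a_scaffold`,
#'   `a_pos`, `b_scaffold`, `b_pos` (1-based k-mer start positions) and
#'   `orientation` (`"forward"`/`"reverse"`).
#' @export
anchorMatches <- function(a, b, k = 21L) {
  if (!is(a, "Assembly")) a <- assembly(a, name = "a")
  if (!is(b, "Assembly")) b <- assembly(b, name = "b")
  df <- .kmerAnchors(as.character(a@seqs), as.character(b@seqs),
                    as.integer(k))
  ord <- order(df$a_seq, df$a_pos)
  out <- data.frame(
    a_scaffold = scaffoldNames(a)[df$a_seq[ord]],
    a_pos = df$a_pos[ord],
    b_scaffold = scaffoldNames(b)[df$b_seq[ord]],
    b_pos = df$b_pos[ord],
    orientation = c("reverse", "forward")[df$forward[ord] + 1L])
  rownames(out) <- NULL
  out
}

# Elementary collinear chaining: within (a_scaffold, b_scaffold,
# orientation), anchors sorted by a_pos join a chain when the a-gap is
# <= maxGap, the b step has the right direction, and the two coordinate
# deltas agree within maxGap.
chainAnchors <- function(anchors, k = 21L, maxGap = 10000L) {
  empty <- data.frame(a_scaffold = character(), b_scaffold = character(),
                      orientation = character(), a_start = numeric(),
                      a_end = numeric(), b_start = numeric(),
                      b_end = numeric(), n_anchors = integer())
  if (nrow(anchors) == 0L) return(empty)
  key <- paste(anchors$a_scaffold, anchors$b_scaffold, anchors$orientation,
               sep = "\r")
  chunks <- split(anchors, key)
  res <- lapply(chunks, function(d) {
    d <- d[order(d$a_pos), , drop = FALSE]
    fwd <- d$orientation[1L] == "forward"
    if (nrow(d) > 1L) {
      da <- diff(d$a_pos)
      db <- diff(d$b_pos)
      ok <- da <= maxGap &
        (if (fwd) db > 0 & abs(db - da) <= maxGap
         else db < 0 & abs(-db - da) <= maxGap)
      cid <- cumsum(c(1L, as.integer(!ok)))
    } else cid <- 1L
    f <- factor(cid, levels = unique(cid))
    data.frame(a_scaffold = d$a_scaffold[1L], b_scaffold = d$b_scaffold[1L],
               orientation = d$orientation[1L],
               a_start = as.vector(tapply(d$a_pos, f, min)),
               a_end = as.vector(tapply(d$a_pos, f, max)),
               b_start = as.vector(tapply(d$b_pos, f, min)),
               b_end = as.vector(tapply(d$b_pos, f, max)),
               n_anchors = as.vector(tapply(d$a_pos, f, length)))
  })
  chains <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  mergeChains(chains, maxGap)
}

# Second-level merge: consecutive chains of the same pair/orientation that
# sit on the same dotplot diagonal (coordinate gaps agree within maxGap)
# are fused, whatever the gap length. This heals chains broken by an
# isolated spurious anchor or by an anchor desert (tandem repeats such as
# an rRNA array carry no assembly-unique k-mers), while chains from truly
# different placements differ in diagonal offset and stay separate.
mergeChains <- function(chains, maxGap) {
  if (nrow(chains) < 2L) return(chains)
  key <- paste(chains$a_scaffold, chains$b_scaffold, chains$orientation,
               sep = "\r")
  parts <- split(chains, key)
  res <- lapply(parts, function(d) {
    d <- d[order(d$a_start), , drop = FALSE]
    if (nrow(d) == 1L) return(d)
    fwd <- d$orientation[1L] == "forward"
    out <- d[1L, , drop = FALSE]
    for (i in 2L:nrow(d)) {
      j <- nrow(out)
      aGap <- d$a_start[i] - out$a_end[j]
      bGap <- if (fwd) d$b_start[i] - out$b_end[j]
              else out$b_start[j] - d$b_end[i]
      if (aGap >= 0 && bGap > 0 && abs(bGap - aGap) <= maxGap) {
        out$a_end[j] <- d$a_end[i]
        out$b_start[j] <- min(out$b_start[j], d$b_start[i])
        out$b_end[j] <- max(out$b_end[j], d$b_end[i])
        out$n_anchors[j] <- out$n_anchors[j] + d$n_anchors[i]
      } else {
        out <- rbind(out, d[i, , drop = FALSE])
      }
    }
    out
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Contig correspondence between two assemblies
#'
#' Groups unique k-mer anchors into maximal collinear chains and reports,
#' per scaffold of assembly A, its partner scaffolds in assembly B. A
#' scaffold with two or more partners covering disjoint spans of at least
#' `minSpan` bp is flagged as chimera/split evidence, with the breakpoint
#' placed at the midpoint between adjacent chains.
#'
#' @param anchors data.frame from [anchorMatches()].
#' @param minAnchors minimum anchors per reported partner chain
#'   (default 50).
#' @param minSpan minimum a-side span (bp) for a partner to count as split
#'   evidence (default 50000).
#' @param k k-mer size used for the anchors (affects span ends).
#' @param maxGap chaining gap tolerance in bp (default 10000).
#' @return list with one entry per a-scaffold present in `anchors`:
#'   `a_scaffold`, `partners` (data.frame: `b_scaffold`, `a_start`,
#'   `a_end`, `b_start`, `b_end`, `anchor_count`, `orientation`, spans in
#'   bases), `split` (logical) and `breakpoints` (numeric, possibly
#'   empty).
#' @export
contigCorrespondence <- function(anchors, minAnchors = 50L,
                                 minSpan = 50000L, k = 21L,
                                 maxGap = 10000L) {
  chains <- chainAnchors(anchors, k = k, maxGap = maxGap)
  chains <- chains[chains$n_anchors >= minAnchors, , drop = FALSE]
  ids <- unique(anchors$a_scaffold)
  out <- lapply(ids, function(id) {
    ch <- chains[chains$a_scaffold == id, , drop = FALSE]
    if (nrow(ch) == 0L) {
      return(list(a_scaffold = id,
                  partners = data.frame(b_scaffold = character(),
                                        a_start = numeric(),
                                        a_end = numeric(),
                                        b_start = numeric(),
                                        b_end = numeric(),
                                        anchor_count = integer(),
                                        orientation = character()),
                  split = FALSE, breakpoints = numeric()))
    }
    partners <- data.frame(b_scaffold = ch$b_scaffold,
                           a_start = ch$a_start,
                           a_end = ch$a_end + k - 1,
                           b_start = ch$b_start,
                           b_end = ch$b_end + k - 1,
                           anchor_count = ch$n_anchors,
                           orientation = ch$orientation)
    partners <- partners[order(partners$a_start), , drop = FALSE]
    big <- partners[partners$a_end - partners$a_start + 1 >= minSpan, ,
                    drop = FALSE]
    breakpoints <- numeric()
    split <- FALSE
    if (nrow(big) >= 2L) {
      # disjoint spans: successive big chains that do not overlap on a
      disjoint <- big$a_start[-1L] > big$a_end[-nrow(big)]
      if (any(disjoint)) {
        split <- TRUE
        idx <- which(disjoint)
        breakpoints <- floor((big$a_end[idx] + big$a_start[idx + 1L]) / 2)
      }
    }
    list(a_scaffold = id, partners = partners, split = split,
         breakpoints = breakpoints)
  })
  names(out) <- ids
  out
}

#' Detect a terminal overlap between two contigs
#'
#' Estimates, from the maximal collinear anchor chain that links a
#' terminus of contig `a` to a terminus of contig `b`, the length of a
#' shared terminal overlap. The contig pair is a merge candidate when the
#' estimated overlap reaches `minOverlap` (the >50 kb concatenation rule)
#' and the chain reaches within `terminalSearch` of both termini.
#'
#' @param a,b contig sequences (character) or single-scaffold
#'   [Assembly-class] objects.
#' @param k k-mer size (default 21).
#' @param minOverlap merge threshold in bp (default 50000).
#' @param terminalSearch how far from a terminus the chain may start
#'   (default 200000 bp).
#' @param maxGap chaining gap tolerance (default 10000).
#' @return list of class `OverlapReport`: `a_scaffold`, `b_scaffold`,
#'   `a_terminus`, `b_terminus` (`"start"`/`"end"` or `NA`),
#'   `overlap_length`, `orientation`, `is_merge_candidate`.
#' @export
detectTerminalOverlap <- function(a, b, k = 21L, minOverlap = 50000L,
                                  terminalSearch = 200000L,
                                  maxGap = 10000L) {
  if (!is(a, "Assembly")) a <- assembly(c(a = a))
  if (!is(b, "Assembly")) b <- assembly(c(b = b))
  stopifnot(length(a) == 1L, length(b) == 1L)
  lenA <- unname(scaffoldLengths(a)[1L])
  lenB <- unname(scaffoldLengths(b)[1L])
  anc <- anchorMatches(a, b, k = k)
  report <- list(a_scaffold = scaffoldNames(a)[1L],
                 b_scaffold = scaffoldNames(b)[1L],
                 a_terminus = NA_character_, b_terminus = NA_character_,
                 overlap_length = 0, orientation = NA_character_,
                 is_merge_candidate = FALSE)
  class(report) <- "OverlapReport"
  if (nrow(anc) == 0L) return(report)
  chains <- chainAnchors(anc, k = k, maxGap = maxGap)
  chains <- chains[chains$n_anchors >= 10L, , drop = FALSE]
  best <- NULL
  bestSlack <- Inf
  for (i in seq_len(nrow(chains))) {
    ch <- chains[i, ]
    aEndBase <- ch$a_end + k - 1
    bEndBase <- ch$b_end + k - 1
    fwd <- ch$orientation == "forward"
    # terminus configurations consistent with the chain orientation
    configs <- if (fwd) list(c("end", "start"), c("start", "end"))
               else list(c("end", "end"), c("start", "start"))
    for (cfg in configs) {
      aT <- cfg[1L]; bT <- cfg[2L]
      distA <- if (aT == "end") lenA - aEndBase else ch$a_start - 1
      distB <- if (bT == "end") lenB - bEndBase else ch$b_start - 1
      if (distA > terminalSearch || distB > terminalSearch) next
      oA <- if (aT == "end") lenA - ch$a_start + 1 else aEndBase
      oB <- if (bT == "end") lenB - ch$b_start + 1 else bEndBase
      o <- max(oA, oB)
      # the overlap chain must run into both termini: prefer the
      # configuration (and chain) with the least terminal slack
      slack <- distA + distB
      if (slack < bestSlack ||
          (slack == bestSlack && !is.null(best) &&
           o > best$overlap_length)) {
        bestSlack <- slack
        best <- list(a_terminus = aT, b_terminus = bT, overlap_length = o,
                     orientation = ch$orientation)
      }
    }
  }
  if (is.null(best)) return(report)
  report$a_terminus <- best$a_terminus
  report$b_terminus <- best$b_terminus
  report$overlap_length <- best$overlap_length
  report$orientation <- best$orientation
  report$is_merge_candidate <- best$overlap_length >= minOverlap
  report
}

#' @export
print.OverlapReport <- function(x, ...) {
  cat("OverlapReport: ", x$a_scaffold, " (", x$a_terminus, ") ~ ",
      x$b_scaffold, " (", x$b_terminus, "), ",
      format(x$overlap_length, big.mark = ","), " bp, ",
      x$orientation, "; merge candidate: ", x$is_merge_candidate, "\n",
      sep = "")
  invisible(x)
}
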