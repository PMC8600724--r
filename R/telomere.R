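#' @include AllClasses.R
NULL

#' Telomere scan parameters
#'
#' In ascomycete fungi the telomere is a tandem array of the 6-mer
#' TTAGGG; on the sequence start (5' terminus) the motif appears as its
#' reverse complement CCCTAA. Both motifs, the terminal window examined,
#' the interruption tolerance and the minimum copy number for a presence
#' call are configurable.
#'
#' @param startMotif motif expected at the scaffold start (default
#'   `"CCCTAA"`).
#' @param endMotif motif expected at the scaffold end (default `"TTAGGG"`).
#' @param terminalWindow bp examined at each terminus (default 1000).
#' @param maxInterruption largest gap (bp) across which consecutive tandem
#'   runs are chained into one array (default 6, one motif length).
#' @param minCopies tandem copies required for a presence call (default 3).
#' @return a validated list of class `TelomereParams`.
#' @export
telomereParams <- function(startMotif = "CCCTAA", endMotif = "TTAGGG",
                           terminalWindow = 1000L, maxInterruption = 6L,
                           minCopies = 3L) {
  stopifnot(nzchar(startMotif), nzchar(endMotif),
            terminalWindow >= nchar(startMotif),
            terminalWindow >= nchar(endMotif),
            maxInterruption >= 0L, minCopies >= 1L)
  structure(list(startMotif = toupper(startMotif),
                 endMotif = toupper(endMotif),
                 terminalWindow = as.integer(terminalWindow),
                 maxInterruption = as.integer(maxInterruption),
                 minCopies = as.integer(minCopies)),
            class = "TelomereParams")
}

# All start positions (1-based) of exact motif occurrences, overlaps allowed.
motifStarts <- function(sequence, motif) {
  if (nchar(sequence) < nchar(motif)) return(integer())
  hits <- gregexpr(motif, sequence, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer())
  as.integer(hits)
}

#' Longest chained tandem run of a motif
#'
#' Finds the maximal chain of exact tandem motif copies, where consecutive
#' copies are either perfectly adjacent or separated by a gap of at most
#' `maxInterruption` bp. Returns the chain with the most copies; ties are
#' broken toward the terminus given by `tieBreak`.
#'
#' @param sequence nucleotide string.
#' @param motif motif string (length >= 2).
#' @param maxInterruption largest chained gap in bp (default 6).
#' @param tieBreak `"start"` or `"end"`: when two chains have the same copy
#'   count, prefer the one closest to that terminus.
#' @return list with `copies` (count of exact motif copies in the chain)
#'   and `span` (c(start, end), 1-based inclusive; `c(0, 0)` when the motif
#'   is absent).
#' @export
longestTandemRun <- function(sequence, motif, maxInterruption = 6L,
                             tieBreak = c("start", "end")) {
  tieBreak <- match.arg(tieBreak)
  if (!nzchar(sequence)) stop("empty sequence")
  if (nchar(motif) < 2L) stop("motif length must be >= 2")
  starts <- motifStarts(sequence, motif)
  if (length(starts) == 0L)
    return(list(copies = 0L, span = c(0L, 0L)))
  L <- nchar(motif)
  # Collapse overlapping occurrences into non-overlapping tandem runs:
  # greedy left-to-right, a copy must begin at or after the end of the
  # previous accepted copy.
  runs <- list()   # each: c(first_start, n_copies)
  cur_start <- starts[1L]
  cur_n <- 1L
  next_ok <- cur_start + L
  for (s in starts[-1L]) {
    if (s == next_ok) {            # perfect tandem continuation
      cur_n <- cur_n + 1L
      next_ok <- s + L
    } else if (s < next_ok) {      # overlapping occurrence, skip
      next
    } else {                       # gap: close the run
      runs[[length(runs) + 1L]] <- c(cur_start, cur_n)
      cur_start <- s
      cur_n <- 1L
      next_ok <- s + L
    }
  }
  runs[[length(runs) + 1L]] <- c(cur_start, cur_n)
  rs <- vapply(runs, `[[`, 0, 1L)         # run first-copy start
  rn <- vapply(runs, `[[`, 0, 2L)         # copies per run
  re <- rs + rn * L - 1L                  # run last base
  # Chain runs across gaps <= maxInterruption.
  nruns <- length(rs)
  chain_id <- integer(nruns)
  cid <- 1L
  chain_id[1L] <- 1L
  if (nruns > 1L) {
    for (i in 2L:nruns) {
      gap <- rs[i] - re[i - 1L] - 1L
      if (gap > maxInterruption) cid <- cid + 1L
      chain_id[i] <- cid
    }
  }
  f <- factor(chain_id, levels = unique(chain_id))
  copies <- as.vector(tapply(rn, f, sum))
  first <- as.vector(tapply(rs, f, min))
  last <- as.vector(tapply(re, f, max))
  best <- which(copies == max(copies))
  if (length(best) > 1L) {
    best <- if (tieBreak == "start") best[which.min(first[best])]
            else best[which.max(last[best])]
  }
  list(copies = as.integer(copies[[best]]),
       span = c(as.integer(first[[best]]), as.integer(last[[best]])))
}

#' Scan an assembly for terminal telomere arrays
#'
#' For each scaffold, counts tandem copies of the start motif within the
#' first `terminalWindow` bases and of the end motif within the last
#' `terminalWindow` bases, flags presence at `minCopies`, and classifies a
#' scaffold as telomere-to-telomere (T2T) when both termini carry an array.
#' Scaffolds shorter than the terminal window are scanned whole, with a
#' warning.
#'
#' @param x an [Assembly-class].
#' @param params a [telomereParams()] list.
#' @return data.frame with one row per scaffold in assembly order:
#'   `scaffold`, `start_copies`, `end_copies`, `start_present`,
#'   `end_present`, `t2t`.
#' @export
scanTelomeres <- function(x, params = telomereParams()) {
  stopifnot(is(x, "Assembly"))
  if (length(x) == 0L) stop("empty assembly")
  rows <- lapply(scaffoldNames(x), function(id) {
    seq <- x[[id]]
    n <- nchar(seq)
    w <- params$terminalWindow
    if (n < w) {
      warning("scaffold ", id, " shorter than terminal window; ",
              "scanning whole scaffold")
      w <- n
    }
    head_seq <- substr(seq, 1L, w)
    tail_seq <- substr(seq, n - w + 1L, n)
    s <- longestTandemRun(head_seq, params$startMotif,
                          params$maxInterruption, tieBreak = "start")
    e <- longestTandemRun(tail_seq, params$endMotif,
                          params$maxInterruption, tieBreak = "end")
    data.frame(scaffold = id,
               start_copies = s$copies, end_copies = e$copies,
               start_present = s$copies >= params$minCopies,
               end_present = e$copies >= params$minCopies)
  })
  df <- do.call(rbind, rows)
  df$t2t <- df$start_present & df$end_present
  df
}
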