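#' @include AllClasses.R AllGenerics.R
NULL

# rolling mean with shrinking windows at the edges (always averages the
# values actually available within half-width on each side)
rollMean <- function(x, width) {
  n <- length(x)
  half <- floor(width / 2)
  cs <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  cn <- cumsum(c(0, !is.na(x)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  num <- cs[hi + 1L] - cs[lo]
  den <- cn[hi + 1L] - cn[lo]
  ifelse(den > 0, num / den, NA_real_)
}

windowBounds <- function(len, windowSize) {
  nWin <- ceiling(len / windowSize)
  start <- (seq_len(nWin) - 1L) * windowSize + 1L
  end <- pmin(start + windowSize - 1L, len)
  list(n = nWin, start = start, end = end)
}

#' @describeIn windowTrack per-window GC percent of a scaffold sequence
#'   (`100 * (G + C) / non-N bases`); windows of only N are `NA`.
#' @param scaffold scaffold id to record on the track.
#' @export
setMethod("windowTrack", "character", function(x, windowSize,
                                               scaffold = "scaffold") {
  stopifnot(windowSize >= 100L)
  len <- nchar(x)
  wb <- windowBounds(len, windowSize)
  v <- Biostrings::Views(Biostrings::DNAString(x), start = wb$start,
                         end = wb$end)
  freq <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
  gc <- freq[, "C"] + freq[, "G"]
  nonN <- rowSums(freq)
  vals <- ifelse(nonN > 0, 100 * gc / nonN, NA_real_)
  new("WindowTrack", scaffold = scaffold, windowSize = as.integer(windowSize),
      values = as.numeric(vals), statKind = "gc_percent",
      scaffoldLength = as.numeric(len))
})

#' @describeIn windowTrack per-window `log2(mean depth + 1)` of a
#'   [CoverageTrack-class]; the partial last window is normalised by its
#'   actual length. The `+ 1` keeps zero-coverage windows finite.
#' @export
setMethod("windowTrack", "CoverageTrack", function(x, windowSize) {
  stopifnot(windowSize >= 100L)
  len <- length(x@depth)
  wb <- windowBounds(len, windowSize)
  cs <- cumsum(c(0, as.numeric(x@depth)))
  means <- (cs[wb$end + 1L] - cs[wb$start]) / (wb$end - wb$start + 1L)
  new("WindowTrack", scaffold = x@scaffold,
      windowSize = as.integer(windowSize),
      values = log2(means + 1), statKind = "log2_coverage",
      scaffoldLength = as.numeric(len))
})

#' @describeIn windowTrack per-window gene counts from a `GRanges`; a gene
#'   belongs to the window containing its start coordinate.
#' @param scaffoldLength length (bp) of the scaffold being windowed.
#' @export
setMethod("windowTrack", "GRanges", function(x, windowSize, scaffold,
                                             scaffoldLength) {
  stopifnot(windowSize >= 100L)
  x <- x[as.character(GenomicRanges::seqnames(x)) == scaffold]
  wb <- windowBounds(scaffoldLength, windowSize)
  idx <- (GenomicRanges::start(x) - 1L) %/% windowSize + 1L
  counts <- tabulate(idx, nbins = wb$n)
  new("WindowTrack", scaffold = scaffold,
      windowSize = as.integer(windowSize),
      values = as.numeric(counts), statKind = "gene_count",
      scaffoldLength = as.numeric(scaffoldLength))
})

#' Locate the centromere of a scaffold from GC and gene-density troughs
#'
#' Fungal centromeres in this toolkit's target genomes are AT-rich and
#' gene-scarce. The detector standardises a GC track and a gene-count
#' track (same scaffold, same window size), sums the two z-scores, smooths
#' the combined score with a moving average, and calls the centromere at
#' the minimising window, excluding a terminal fraction of windows
#' (telomeric regions are themselves AT-rich). Arms are measured from the
#' call; the scaffold is classified metacentric when the long/short arm
#' ratio is at most `armRatioMax`, submetacentric otherwise.
#'
#' @param gcTrack [WindowTrack-class] of kind `gc_percent`.
#' @param geneTrack [WindowTrack-class] of kind `gene_count`, same scaffold
#'   and window size.
#' @param exclusionFraction fraction of windows excluded at each terminus
#'   (default 0.05).
#' @param smoothWindows moving-average width in windows (default 25).
#' @param armRatioMax metacentric/submetacentric boundary for the
#'   long/short arm ratio (default 1.7, the standard cytogenetic
#'   convention).
#' @param confidenceScore calls whose smoothed combined z-score trough is
#'   above this value are flagged low-confidence (default -1).
#' @return list of class `CentromereCall`: `scaffold`, `window`,
#'   `position` (bp, window midpoint), `arm_short`, `arm_long`,
#'   `arm_ratio`, `classification`, `score`, `low_confidence`.
#' @export
detectCentromere <- function(gcTrack, geneTrack, exclusionFraction = 0.05,
                             smoothWindows = 25L, armRatioMax = 1.7,
                             confidenceScore = -1) {
  stopifnot(is(gcTrack, "WindowTrack"), is(geneTrack, "WindowTrack"),
            gcTrack@statKind == "gc_percent",
            geneTrack@statKind == "gene_count",
            gcTrack@scaffold == geneTrack@scaffold,
            gcTrack@windowSize == geneTrack@windowSize,
            length(gcTrack@values) == length(geneTrack@values))
  n <- length(gcTrack@values)
  if (n < 100L) stop("track too short (< 100 windows)")
  zscore <- function(v) {
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v, na.rm = TRUE)) / s
  }
  combined <- zscore(gcTrack@values) + zscore(geneTrack@values)
  smoothed <- rollMean(combined, smoothWindows)
  excl <- ceiling(exclusionFraction * n)
  allowed <- setdiff(seq_len(n), c(seq_len(excl), n - excl + seq_len(excl)))
  wMin <- allowed[which.min(smoothed[allowed])]
  # centre the call on the trough basin rather than the noisy argmin: a
  # centromere is a plateau of low windows, so take the midpoint of the
  # contiguous run of windows close to the minimum
  ref <- stats::median(smoothed[allowed], na.rm = TRUE)
  cut <- smoothed[wMin] + 0.25 * (ref - smoothed[wMin])
  lo <- wMin
  while (lo - 1L >= min(allowed) && !is.na(smoothed[lo - 1L]) &&
         smoothed[lo - 1L] <= cut) lo <- lo - 1L
  hi <- wMin
  while (hi + 1L <= max(allowed) && !is.na(smoothed[hi + 1L]) &&
         smoothed[hi + 1L] <= cut) hi <- hi + 1L
  w <- as.integer(round((lo + hi) / 2))
  ws <- gcTrack@windowSize
  len <- gcTrack@scaffoldLength
  pos <- min((w - 1) * ws + floor(ws / 2), len)
  arms <- sort(c(pos, len - pos))
  ratio <- if (arms[1L] > 0) arms[2L] / arms[1L] else Inf
  out <- list(scaffold = gcTrack@scaffold, window = w, position = pos,
              arm_short = arms[1L], arm_long = arms[2L], arm_ratio = ratio,
              classification = if (ratio <= armRatioMax) "metacentric"
                               else "submetacentric",
              score = smoothed[w],
              low_confidence = !(smoothed[w] <= confidenceScore))
  class(out) <- "CentromereCall"
  out
}

#' @export
print.CentromereCall <- function(x, ...) {
  cat("CentromereCall ", x$scaffold, ": position ",
      format(x$position, big.mark = ","), " (", x$classification,
      ", arm ratio ", round(x$arm_ratio, 2), ")",
      if (x$low_confidence) " [low confidence]", "\n", sep = "")
  invisible(x)
}

#' Count tandem copies of a labelled feature-cluster unit
#'
#' Counts the maximal uninterrupted repetition of an ordered unit of
#' subunit labels (default the rRNA cistron 18S, 5.8S, 26S) among features
#' sorted by position on one scaffold. Matches must be strand-consistent:
#' a minus-strand cluster presents the unit in reversed label order.
#' Consecutive members more than `maxMemberGap` bp apart break the chain.
#'
#' @param features `GRanges` with a `subunit` metadata column (see
#'   [readFeatures()]).
#' @param unit ordered character vector of subunit labels (default
#'   `c("18S", "5.8S", "26S")`). ITS spacers are not part of the unit.
#' @param maxMemberGap largest allowed gap between consecutive members in
#'   bp (default 50000).
#' @return list of class `TandemClusterCall`: `scaffold`, `unit`,
#'   `copies`, `span` (c(start, end) in bp, `c(0, 0)` when absent),
#'   `members` (indices into `features` of the matched members).
#' @export
detectTandemCluster <- function(features, unit = c("18S", "5.8S", "26S"),
                                maxMemberGap = 50000L) {
  sub <- features[!is.na(S4Vectors::mcols(features)$subunit)]
  emptyCall <- function(scaf) {
    out <- list(scaffold = scaf, unit = unit, copies = 0L,
                span = c(0, 0), members = integer())
    class(out) <- "TandemClusterCall"
    out
  }
  if (length(sub) == 0L) return(emptyCall(NA_character_))
  scaf <- names(sort(table(as.character(GenomicRanges::seqnames(sub))),
                     decreasing = TRUE))[1L]
  onScaf <- which(as.character(GenomicRanges::seqnames(sub)) == scaf)
  sub <- sub[onScaf]
  ord <- order(GenomicRanges::start(sub))
  sub <- sub[ord]
  labels <- S4Vectors::mcols(sub)$subunit
  strands <- as.character(GenomicRanges::strand(sub))
  starts <- GenomicRanges::start(sub)
  ends <- GenomicRanges::end(sub)
  u <- length(unit)
  n <- length(labels)
  best <- list(copies = 0L, at = integer())
  for (pattern in list(list(lab = unit, str = "+"),
                       list(lab = rev(unit), str = "-"))) {
    i <- 1L
    while (i + u - 1L <= n) {
      # count consecutive repetitions of the pattern starting at i
      copies <- 0L
      j <- i
      while (j + u - 1L <= n &&
             identical(labels[j:(j + u - 1L)], pattern$lab) &&
             all(strands[j:(j + u - 1L)] %in% c(pattern$str, "*")) &&
             (j == i || starts[j] - ends[j - 1L] <= maxMemberGap) &&
             all(diff(starts[j:(j + u - 1L)]) > 0) &&
             all(starts[j:(j + u - 1L)][-1L] -
                 ends[j:(j + u - 1L)][-u] <= maxMemberGap)) {
        copies <- copies + 1L
        j <- j + u
      }
      if (copies > best$copies)
        best <- list(copies = copies, at = i:(i + copies * u - 1L))
      i <- if (copies > 0L) j else i + 1L
    }
  }
  if (best$copies == 0L) return(emptyCall(scaf))
  span <- c(min(starts[best$at]), max(ends[best$at]))
  out <- list(scaffold = scaf, unit = unit, copies = best$copies,
              span = span, members = onScaf[ord][best$at])
  class(out) <- "TandemClusterCall"
  out
}

#' @export
print.TandemClusterCall <- function(x, ...) {
  cat("TandemClusterCall ", x$scaffold, ": ", x$copies, " copies of [",
      paste(x$unit, collapse = "-"), "]", sep = "")
  if (x$copies > 0L)
    cat(" spanning ", format(x$span[1L], big.mark = ","), "-",
        format(x$span[2L], big.mark = ","), sep = "")
  cat("\n")
  invisible(x)
}

#' High-coverage peak regions of a coverage track
#'
#' Maximal runs of bases whose depth is at least `foldOverMedian` times
#' the track median, merged across gaps of at most `mergeGap` bp. Picks
#' out repeat-driven coverage pile-ups such as tandem rRNA arrays. When
#' the median is zero the threshold falls back to `foldOverMedian` times
#' the mean depth.
#'
#' @param covTrack a [CoverageTrack-class].
#' @param foldOverMedian peak threshold as a multiple of the median depth
#'   (default 10).
#' @param mergeGap merge peaks separated by at most this many bases
#'   (default 1000).
#' @return data.frame with columns `start`, `end` (1-based inclusive),
#'   zero rows when no peak exists.
#' @export
peakRegions <- function(covTrack, foldOverMedian = 10, mergeGap = 1000L) {
  depth <- covTrack@depth
  none <- data.frame(start = integer(), end = integer())
  if (length(depth) == 0L || all(depth == 0L)) return(none)
  med <- stats::median(depth)
  threshold <- foldOverMedian * (if (med > 0) med else mean(depth))
  hit <- depth >= threshold
  if (!any(hit)) return(none)
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge across small gaps
  keep <- iv[1L, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    j <- nrow(keep)
    if (iv$start[i] - keep$end[j] - 1L <= mergeGap)
      keep$end[j] <- iv$end[i]
    else
      keep <- rbind(keep, iv[i, ])
  }
  rownames(keep) <- NULL
  keep
}
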