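# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately use different algorithms from the package
# implementations they check.

randomDna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutateSeq <- function(seq, rate) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (p in hit)
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste(chars, collapse = "")
}

revCompStr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# N50/L50 by explicit scan over descending lengths
oracleN50 <- function(lens) {
  sorted <- sort(lens, decreasing = TRUE)
  tot <- sum(lens)
  cum <- 0
  for (i in seq_along(sorted)) {
    cum <- cum + sorted[i]
    if (cum >= tot / 2) return(list(n50 = sorted[i], l50 = i))
  }
}

# covered length of a union of [start, end) intervals by sweep line
oracleUnionLength <- function(starts, ends) {
  ev <- rbind(data.frame(x = starts, d = 1L), data.frame(x = ends, d = -1L))
  ev <- ev[order(ev$x, -ev$d), ]
  depth <- 0L
  covered <- 0
  lastX <- NA
  for (i in seq_len(nrow(ev))) {
    if (depth > 0L) covered <- covered + ev$x[i] - lastX
    depth <- depth + ev$d[i]
    lastX <- ev$x[i]
  }
  covered
}

# maximal chained tandem copies by memoised DP over motif occurrences:
# a chain steps from one exact copy to a later copy whose start lies in
# [copy end + 1, copy end + 1 + maxInt]
oracleTandemCopies <- function(seq, motif, maxInt) {
  hits <- gregexpr(motif, seq, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(0L)
  starts <- as.integer(hits)
  L <- nchar(motif)
  n <- length(starts)
  best <- rep(NA_integer_, n)
  solve <- function(i) {
    if (!is.na(best[i])) return(best[i])
    b <- 1L
    nxt <- which(starts - (starts[i] + L) >= 0 &
                 starts - (starts[i] + L) <= maxInt)
    for (j in nxt) b <- max(b, 1L + solve(j))
    best[i] <<- b
    b
  }
  max(vapply(seq_len(n), solve, integer(1L)))
}

# per-window GC by direct substring counting
oracleGcTrack <- function(seq, windowSize) {
  n <- nchar(seq)
  nWin <- ceiling(n / windowSize)
  vapply(seq_len(nWin), function(w) {
    part <- substr(seq, (w - 1) * windowSize + 1, min(w * windowSize, n))
    chars <- strsplit(part, "", fixed = TRUE)[[1L]]
    nonN <- sum(chars != "N")
    if (nonN == 0) return(NA_real_)
    100 * sum(chars %in% c("G", "C")) / nonN
  }, numeric(1L))
}

# per-window log2 mean coverage by direct looping
oracleCovTrack <- function(depth, windowSize) {
  n <- length(depth)
  nWin <- ceiling(n / windowSize)
  vapply(seq_len(nWin), function(w) {
    idx <- ((w - 1) * windowSize + 1):min(w * windowSize, n)
    log2(mean(depth[idx]) + 1)
  }, numeric(1L))
}

# prefilter keep-set by per-gene loop
oraclePrefilter <- function(counts, groups, minMedian) {
  keep <- character()
  for (g in rownames(counts)) {
    meds <- vapply(unique(groups), function(grp)
      stats::median(counts[g, groups == grp]), numeric(1L))
    if (max(meds) >= minMedian) keep <- c(keep, g)
  }
  keep
}

# terminal trim coordinates by explicit linear scans
oracleTrim <- function(depth, minDepth) {
  n <- length(depth)
  left <- 0L
  while (left < n && depth[left + 1L] < minDepth) left <- left + 1L
  right <- 0L
  while (right < n - left && depth[n - right] < minDepth)
    right <- right + 1L
  c(left = left, right = right)
}

# best tandem repetition count of `unit` in a label sequence by scoring
# every start position and both reading directions
oracleUnitCopies <- function(labels, unit) {
  best <- 0L
  u <- length(unit)
  n <- length(labels)
  for (pattern in list(unit, rev(unit))) {
    for (i in seq_len(max(n - u + 1L, 0L))) {
      c0 <- 0L
      j <- i
      while (j + u - 1L <= n &&
             identical(labels[j:(j + u - 1L)], pattern)) {
        c0 <- c0 + 1L
        j <- j + u
      }
      best <- max(best, c0)
    }
  }
  best
}

# a tiny three-chromosome benchmark kept cheap for unit tests
smallBenchmark <- function(seed) {
  syntheticBenchmark(
    seed = seed,
    spec = genomeSpec(lengths = c(300000L, 250000L, 200000L),
                      cenFraction = c(0.5, 0.3, 0.5), seed = seed))
}
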