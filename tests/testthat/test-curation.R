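test_that("baseline selection ranks by T2T count, contigs, then N50", {
  cand <- data.frame(
    assembler = c("canu", "flye", "miniasm", "shasta", "wtdbg2"),
    n_contigs = c(25L, 14L, 9L, 30L, 12L),
    n_contigs_ge_100kb = c(12L, 9L, 7L, 11L, 8L),
    n50 = c(2.1e6, 5.2e6, 6.4e6, 1.8e6, 6.4e6),
    l50 = c(6L, 3L, 3L, 7L, 3L),
    t2t_count = c(1L, 3L, 5L, 0L, 3L))
  sel <- selectBaseline(cand)
  expect_equal(sel$best$assembler, "miniasm")
  expect_equal(sel$ranking$rank, 1:5)

  single <- cand[2, ]
  expect_equal(selectBaseline(single)$best$assembler, "flye")

  tie <- data.frame(assembler = c("a", "b"), n_contigs = c(12L, 9L),
                    n_contigs_ge_100kb = c(7L, 7L), n50 = c(5e6, 5e6),
                    l50 = c(3L, 3L), t2t_count = c(5L, 5L))
  expect_equal(selectBaseline(tie)$best$assembler, "b")
  expect_error(selectBaseline(cand[0, ]), "empty")
})

test_that("candidate summaries count contigs, sizes and T2T status", {
  set.seed(51)
  t2tSeq <- paste0(strrep("CCCTAA", 12), randomDna(150000),
                   strrep("TTAGGG", 12))
  openSeq <- randomDna(120000)
  asm <- assembly(c(c1 = t2tSeq, c2 = openSeq, c3 = randomDna(50000)),
                  name = "toy")
  cs <- summarizeCandidate(asm)
  expect_equal(cs$n_contigs, 3L)
  expect_equal(cs$n_contigs_ge_100kb, 2L)
  expect_equal(cs$t2t_count, 1L)
})

test_that("short contigs are dropped at the boundary rule", {
  asm <- assembly(c(a = strrep("A", 5000), b = strrep("C", 10000),
                    c = strrep("G", 20000)))
  res <- dropShortContigs(asm, 10000)
  expect_identical(scaffoldNames(res$assembly), c("b", "c"))
  expect_equal(res$actions$action, "drop_short")
  expect_equal(res$actions$subjects, "a")

  allLong <- assembly(c(a = strrep("A", 20000)))
  res2 <- dropShortContigs(allLong, 10000)
  expect_identical(scaffoldNames(res2$assembly), "a")
  expect_equal(nrow(res2$actions), 0L)
})

test_that("mitochondrial contigs are flagged by anchor coverage fraction", {
  set.seed(53)
  mitoSeq <- randomDna(28000, gc = 0.3)
  mito <- assembly(c(mt_ref = mitoSeq), name = "mito")
  contig <- mutateSeq(mitoSeq, 0.01)
  nuclear <- paste0(randomDna(40000), substr(mitoSeq, 1, 2500),
                    randomDna(10000))
  asm <- assembly(c(m = contig, n = nuclear))
  flagged <- flagMitochondrial(asm, mito)
  expect_identical(flagged, "m")
  expect_warning(out <- flagMitochondrial(asm, NULL), "no mitochondrial")
  expect_length(out, 0L)
})

test_that("overlap merging reconstructs the source and guards thresholds", {
  set.seed(55)
  chr <- randomDna(240000)
  a <- substr(chr, 1, 150000)
  b <- substr(chr, 150000 - 60000 + 1, 240000)
  rep <- detectTerminalOverlap(a, b)
  merged <- mergeByOverlap(a, b, rep)
  expect_identical(merged, chr)
  expect_equal(nchar(merged), nchar(a) + nchar(b) - rep$overlap_length)

  # reverse orientation: second contig flipped
  bRc <- revCompStr(b)
  repR <- detectTerminalOverlap(a, bRc)
  expect_identical(mergeByOverlap(a, bRc, repR), chr)

  bad <- rep
  bad$is_merge_candidate <- FALSE
  expect_error(mergeByOverlap(a, b, bad), "not a merge candidate")
})

test_that("splitting conserves bases and enforces guards", {
  s <- strrep("ACGT", 1000)
  sp <- splitAtBreakpoint(s, 1000, evidence = "correspondence")
  expect_equal(nchar(sp$left), 1000)
  expect_equal(nchar(sp$left) + nchar(sp$right), nchar(s))
  expect_identical(paste0(sp$left, sp$right), s)
  expect_error(splitAtBreakpoint(s, 0, evidence = "x"), "breakpoint")
  expect_error(splitAtBreakpoint(s, nchar(s), evidence = "x"),
               "breakpoint")
  expect_error(splitAtBreakpoint(s, 100), "evidence")
  expect_silent(splitAtBreakpoint(s, 100, force = TRUE))
})

test_that("end trimming removes exactly the unsupported terminal runs", {
  set.seed(57)
  s <- randomDna(5000)
  depth <- c(rep(0L, 100), rep(8L, 4800), rep(0L, 100))
  tr <- trimUnsupportedEnds(s, depth)
  expect_equal(nchar(tr$sequence), 4800)
  expect_equal(tr$left, 100L)
  expect_equal(tr$right, 100L)
  # idempotent
  again <- trimUnsupportedEnds(tr$sequence, tr$depth)
  expect_identical(again$sequence, tr$sequence)
  expect_equal(again$left + again$right, 0L)
  # internal zeros untouched
  depth2 <- rep(5L, 5000)
  depth2[2000:2100] <- 0L
  expect_equal(nchar(trimUnsupportedEnds(s, depth2)$sequence), 5000)
  expect_error(trimUnsupportedEnds(s, rep(0L, 5000)), "unsupported")

  # property: trim coordinates equal a linear-scan oracle
  for (i in 1:100) {
    n <- sample(200:2000, 1)
    depth <- as.integer(rbinom(n, 1, 0.9) * rpois(n, 10))
    if (all(depth == 0)) depth[sample(n, 1)] <- 5L
    seq <- strrep("A", n)
    tr <- trimUnsupportedEnds(seq, depth, 1L)
    orc <- oracleTrim(depth, 1L)
    expect_equal(c(left = tr$left, right = tr$right), orc,
                 info = paste("case", i))
  }
})

test_that("read recruitment applies the length and aligned-fraction gates", {
  aln <- data.frame(
    query_id = c("r1", "r2", "r3", "r4", "r4"),
    query_length = c(10000, 10000, 9000, 20000, 20000),
    query_start = c(0, 0, 0, 0, 10000),
    query_end = c(8000, 7900, 100, 6000, 14000),
    target_id = c("s1", "s1", "s1", "sX", "s1"),
    strand = "+")
  kept <- partitionUnassignedReads(aln, excludedScaffolds = "sX")
  expect_false("r1" %in% kept)   # 8000/10000 = 0.80 >= 0.80: dropped
  expect_true("r2" %in% kept)    # 0.79 < 0.80
  expect_false("r3" %in% kept)   # shorter than 10 kb
  expect_true("r4" %in% kept)    # only 4000/20000 counted outside sX
})

test_that("the full pipeline repairs the planted baseline end to end", {
  bench <- smallBenchmark(seed = 7)
  res <- curate(bench$baseline, alternates = list(bench$alternate),
                coverage = bench$coverage, mitoRefs = bench$mito)
  fin <- finalAssembly(res)
  truthSeqs <- as.character(bench$genome$assembly@seqs)

  expect_equal(length(fin), 3L)
  expect_true(all(telomereReport(res)$t2t))
  for (i in seq_len(3))
    expect_true(fin[[i]] %in% truthSeqs)
  expect_identical(scaffoldNames(fin),
                   paste0("scaffold_", 1:3))
  expect_equal(unname(scaffoldLengths(fin)),
               unname(sort(nchar(truthSeqs), decreasing = TRUE)))
  # quarantined, not deleted
  expect_equal(length(quarantined(res)), 1L)
  # every stage appears in the log
  expect_setequal(unique(actionLog(res)$action),
                  c("drop_short", "flag_mito", "merge", "split", "trim",
                    "rename"))
})

test_that("the action log replays to a byte-identical assembly", {
  bench <- smallBenchmark(seed = 8)
  res <- curate(bench$baseline, alternates = list(bench$alternate),
                coverage = bench$coverage, mitoRefs = bench$mito)
  replayed <- replayActions(bench$baseline, actionLog(res))
  expect_identical(as.character(replayed@seqs),
                   as.character(finalAssembly(res)@seqs))
})

test_that("curation is a fixed point on an already-perfect assembly", {
  bench <- smallBenchmark(seed = 9)
  truth <- bench$genome$assembly
  cov <- simulateCoverage(truth, meanDepth = 25, seed = 99)
  res <- curate(truth, alternates = list(bench$alternate),
                coverage = cov, mitoRefs = bench$mito)
  expect_false(any(actionLog(res)$action %in%
                     c("merge", "split", "trim", "drop_short")))
  fin <- finalAssembly(res)
  expect_equal(length(fin), 3L)
  expect_setequal(unname(as.character(fin@seqs)),
                  unname(as.character(truth@seqs)))
})

test_that("rerunning with the same inputs is byte-identical", {
  bench1 <- smallBenchmark(seed = 10)
  bench2 <- smallBenchmark(seed = 10)
  expect_identical(as.character(bench1$baseline@seqs),
                   as.character(bench2$baseline@seqs))
  r1 <- curate(bench1$baseline, alternates = list(bench1$alternate),
               coverage = bench1$coverage, mitoRefs = bench1$mito)
  r2 <- curate(bench2$baseline, alternates = list(bench2$alternate),
               coverage = bench2$coverage, mitoRefs = bench2$mito)
  expect_identical(as.character(finalAssembly(r1)@seqs),
                   as.character(finalAssembly(r2)@seqs))
  expect_identical(actionLog(r1), actionLog(r2))
})

test_that("base bookkeeping balances across the pipeline", {
  bench <- smallBenchmark(seed = 11)
  res <- curate(bench$baseline, alternates = list(bench$alternate),
                coverage = bench$coverage, mitoRefs = bench$mito)
  log <- actionLog(res)
  p <- lapply(log$parameters, t2tcurate:::decodeParams)
  dropped <- sum(vapply(p[log$action == "drop_short"],
                        function(x) as.numeric(x$length), 0))
  overlap <- sum(vapply(p[log$action == "merge"],
                        function(x) as.numeric(x$overlap), 0))
  trimmed <- sum(vapply(p[log$action == "trim"], function(x)
    as.numeric(x$left) + as.numeric(x$right), 0))
  quarantinedBp <- sum(scaffoldLengths(quarantined(res)))
  expect_equal(sum(scaffoldLengths(finalAssembly(res))),
               sum(scaffoldLengths(bench$baseline)) - dropped -
                 overlap - trimmed - quarantinedBp)
})
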