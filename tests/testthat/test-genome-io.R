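test_that("readFasta parses records in order and normalises sequences", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "NNNN"), f)
  asm <- readFasta(f)
  expect_s4_class(asm, "Assembly")
  expect_identical(scaffoldNames(asm), c("a", "b"))
  expect_identical(unname(scaffoldLengths(asm)), c(4L, 4L))

  writeLines(c(">a", "acgu"), f)
  expect_identical(readFasta(f)[["a"]], "ACGT")
})

test_that("readFasta rejects malformed input", {
  f <- tempfile(fileext = ".fasta")
  expect_error(readFasta(f), "no such file")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(readFasta(f), "duplicate")
  writeLines(c(">a", "ACXT"), f)
  expect_error(readFasta(f), "illegal symbol")
  writeLines(c(">a", "ACGT", ">b"), f)
  expect_error(readFasta(f))
})

test_that("FASTA write/read round trip is byte-identical at 60 columns", {
  set.seed(42)
  seqs <- setNames(vapply(1:10, function(i)
    randomDna(sample(50:500, 1)), ""), paste0("s", 1:10))
  asm <- assembly(seqs, name = "fixture")
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  writeFasta(asm, f1)
  back <- readFasta(f1)
  expect_identical(as.character(back@seqs), as.character(asm@seqs))
  writeFasta(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("assembly statistics match hand-computed and oracle values", {
  asm <- assembly(setNames(
    vapply(c(40, 30, 20, 10), function(n) strrep("A", n), ""),
    paste0("s", 1:4)))
  st <- assemblyStats(asm)
  expect_equal(st@totalLength, 100)
  expect_equal(st@n50, 30)
  expect_equal(st@l50, 2L)

  # property: N50/L50 equal the sort-and-scan oracle on random multisets
  set.seed(1)
  for (i in 1:200) {
    lens <- sample(1:5000, sample(1:60, 1), replace = TRUE)
    asm <- assembly(setNames(strrep("A", lens),
                             paste0("s", seq_along(lens))))
    st <- assemblyStats(asm)
    orc <- oracleN50(lens)
    expect_equal(st@n50, orc$n50)
    expect_equal(st@l50, orc$l50)
  }
})

test_that("GC percent is invariant under reordering and reverse complement", {
  set.seed(7)
  seqs <- setNames(vapply(1:5, function(i) randomDna(500, gc = 0.4), ""),
                   paste0("s", 1:5))
  gc0 <- assemblyStats(assembly(seqs))@gcPercent
  gcShuffled <- assemblyStats(assembly(seqs[c(3, 1, 5, 2, 4)]))@gcPercent
  gcRc <- assemblyStats(assembly(vapply(seqs, revCompStr, "")))@gcPercent
  expect_equal(gcShuffled, gc0)
  expect_equal(gcRc, gc0)
})

test_that("per-base coverage reader enforces consecutive positions", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("s1\t1\t5", "s1\t2\t0", "s1\t3\t7"), f)
  tracks <- readPerBaseCoverage(f)
  expect_identical(tracks$s1@depth, c(5L, 0L, 7L))

  writeLines(c("s1\t1\t5", "s1\t3\t7"), f)
  expect_error(readPerBaseCoverage(f), "non-consecutive")
  writeLines(c("s1\t1\t-2"), f)
  expect_error(readPerBaseCoverage(f), "negative depth")
})

test_that("coverage write/read round trips simulated tracks", {
  asm <- assembly(c(c1 = randomDna(2000), c2 = randomDna(1500)))
  cov <- simulateCoverage(asm, meanDepth = 12, seed = 7)
  f <- tempfile(fileext = ".tsv")
  writePerBaseCoverage(cov, f)
  back <- readPerBaseCoverage(f)
  expect_identical(back$c1@depth, cov$c1@depth)
  expect_identical(back$c2@depth, cov$c2@depth)
})

test_that("bedGraph input expands to the same per-base track", {
  f <- tempfile(fileext = ".bedgraph")
  writeLines(c("s1\t0\t3\t5", "s1\t3\t5\t0", "s1\t5\t6\t9"), f)
  tracks <- readBedGraph(f)
  expect_identical(tracks$s1@depth, c(5L, 5L, 5L, 0L, 0L, 9L))
  writeLines(c("s1\t0\t3\t5", "s1\t4\t6\t2"), f)
  expect_error(readBedGraph(f), "tile")
})

test_that("PAF reader keeps 0-based half-open coordinates and validates", {
  f <- tempfile(fileext = ".paf")
  writeLines(paste(c("r1", 10000, 0, 8000, "+", "t1", 99, 0, 1, 1, 1, 60),
                   collapse = "\t"), f)
  aln <- readPaf(f)
  expect_equal(unname(alignedFraction(aln)[["r1"]]), 0.80)

  writeLines(c(paste(c("r1", 10000, 0, 6000, "+", "t1"), collapse = "\t"),
               paste(c("r1", 10000, 4000, 9000, "+", "t2"),
                     collapse = "\t")), f)
  aln <- readPaf(f)
  expect_equal(unname(alignedFraction(aln)[["r1"]]) * 10000, 9000)

  writeLines(paste(c("r1", 10000, 8000, 8000, "+", "t1"), collapse = "\t"),
             f)
  expect_error(readPaf(f), "qend <= qstart")
  writeLines(paste(c("r1", 10000, 0, 10001, "+", "t1"), collapse = "\t"),
             f)
  expect_error(readPaf(f), "qend > qlen")
})

test_that("union aligned fractions match a sweep-line oracle", {
  set.seed(11)
  for (i in 1:50) {
    qlen <- sample(5000:20000, 1)
    nInt <- sample(1:6, 1)
    starts <- sort(sample(0:(qlen - 100), nInt))
    ends <- pmin(starts + sample(50:5000, nInt, replace = TRUE), qlen)
    aln <- data.frame(query_id = "r", query_length = qlen,
                      query_start = starts, query_end = ends,
                      target_id = "t", strand = "+")
    expect_equal(unname(alignedFraction(aln)[["r"]]),
                 oracleUnionLength(starts, ends) / qlen)
  }
})

test_that("GFF3 features round trip with subunit labels preserved", {
  gr <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(start = c(1, 500), end = c(10, 2000)),
    strand = c("+", "-"), type = c("rRNA", "gene"),
    product = c("18S ribosomal RNA", "hypothetical protein"))
  f <- tempfile(fileext = ".gff3")
  writeFeatures(gr, f)
  back <- readFeatures(f)
  expect_equal(GenomicRanges::start(back), c(1, 500))
  expect_equal(GenomicRanges::end(back), c(10, 2000))
  expect_equal(S4Vectors::mcols(back)$subunit[1], "18S")
  expect_true(is.na(S4Vectors::mcols(back)$subunit[2]))
})

test_that("subunit labels are extracted from product descriptions", {
  expect_equal(extractSubunit(c("18S ribosomal RNA", "5.8S rRNA",
                                "26S ribosomal RNA", "polymerase")),
               c("18S", "5.8S", "26S", NA))
})
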