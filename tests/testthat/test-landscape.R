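test_that("GC windows saturate, flag all-N windows, and match the oracle", {
  tr <- windowTrack(strrep("G", 1000), 1000, scaffold = "s")
  expect_equal(tr@values, 100)

  trN <- windowTrack(paste0(strrep("N", 1000), strrep("GC", 500)), 1000,
                     scaffold = "s")
  expect_true(is.na(trN@values[1]))
  expect_equal(trN@values[2], 100)

  set.seed(31)
  s <- randomDna(100000, gc = 0.45)
  tr <- windowTrack(s, 1000, scaffold = "s")
  expect_equal(tr@values, oracleGcTrack(s, 1000))
  # partial last window
  s2 <- randomDna(2500)
  expect_equal(windowTrack(s2, 1000, scaffold = "s")@values,
               oracleGcTrack(s2, 1000))
})

test_that("coverage windows use log2(mean + 1) and match the oracle", {
  cov <- new("CoverageTrack", scaffold = "s", depth = rep(4L, 3000))
  tr <- windowTrack(cov, 1000)
  expect_equal(tr@values, rep(log2(5), 3), tolerance = 1e-12)

  set.seed(33)
  depth <- as.integer(rpois(10500, 20))
  cov <- new("CoverageTrack", scaffold = "s", depth = depth)
  expect_equal(windowTrack(cov, 1000)@values, oracleCovTrack(depth, 1000))
})

test_that("gene counts bin by start coordinate and sum to the total", {
  gr <- GenomicRanges::GRanges(
    "s", IRanges::IRanges(start = c(1, 999, 1000, 150000),
                          end = c(500, 1400, 1600, 151000)))
  tr <- windowTrack(gr, 1000, scaffold = "s", scaffoldLength = 200000)
  expect_equal(tr@values[1], 3)       # starts 1, 999, 1000 (window 1 ends at 1000)
  expect_equal(tr@values[2], 0)
  expect_equal(tr@values[150], 1)     # start 150000 is the last base of window 150
  expect_equal(sum(tr@values), length(gr))
})

test_that("GC mass is conserved across windows", {
  set.seed(35)
  s <- paste0(randomDna(5500, gc = 0.6), strrep("N", 700), randomDna(1800))
  tr <- windowTrack(s, 1000, scaffold = "s")
  wb <- t2tcurate:::windowBounds(nchar(s), 1000)
  nonN <- vapply(seq_len(wb$n), function(w) {
    part <- substr(s, wb$start[w], wb$end[w])
    nchar(gsub("N", "", part))
  }, numeric(1))
  mass <- sum(tr@values * nonN / 100, na.rm = TRUE)
  chars <- strsplit(s, "")[[1]]
  expect_equal(mass, sum(chars %in% c("G", "C")))
})

test_that("planted centromeres are localised and classified", {
  spec <- genomeSpec(lengths = c(300000L, 300000L),
                     cenFraction = c(0.5, 0.25), rrnaChromosome = 0L,
                     mitoLength = 0L, seed = 41)
  g <- generateGenome(spec)
  for (i in 1:2) {
    chrom <- paste0("chr", i)
    s <- g$assembly[[chrom]]
    gc <- windowTrack(s, 1000, scaffold = chrom)
    genes <- windowTrack(g$features, 1000, scaffold = chrom,
                         scaffoldLength = nchar(s))
    call <- detectCentromere(gc, genes)
    truthMid <- mean(g$truth[[chrom]]$centromere)
    expect_lt(abs(call$position - truthMid) / 1000, 2.5,
              label = paste(chrom, "within 2 windows of the plant"))
    expect_false(call$low_confidence)
    expect_equal(call$arm_short + call$arm_long, nchar(s))
  }
  # metacentric at midpoint, submetacentric at the 25% plant
  sMeta <- g$assembly[["chr1"]]
  gcM <- windowTrack(sMeta, 1000, scaffold = "chr1")
  gnM <- windowTrack(g$features, 1000, scaffold = "chr1",
                     scaffoldLength = nchar(sMeta))
  expect_equal(detectCentromere(gcM, gnM)$classification, "metacentric")
  sSub <- g$assembly[["chr2"]]
  gcS <- windowTrack(sSub, 1000, scaffold = "chr2")
  gnS <- windowTrack(g$features, 1000, scaffold = "chr2",
                     scaffoldLength = nchar(sSub))
  callS <- detectCentromere(gcS, gnS)
  expect_equal(callS$classification, "submetacentric")
  expect_gt(callS$arm_ratio, 2.5)
})

test_that("uniform tracks still return a call but flagged low-confidence", {
  gc <- new("WindowTrack", scaffold = "s", windowSize = 1000L,
            values = rep(48, 200), statKind = "gc_percent",
            scaffoldLength = 2e5)
  genes <- new("WindowTrack", scaffold = "s", windowSize = 1000L,
               values = rep(3, 200), statKind = "gene_count",
               scaffoldLength = 2e5)
  call <- detectCentromere(gc, genes)
  expect_true(call$low_confidence)
  expect_error(detectCentromere(
    new("WindowTrack", scaffold = "s", windowSize = 1000L,
        values = rep(48, 50), statKind = "gc_percent",
        scaffoldLength = 5e4),
    new("WindowTrack", scaffold = "s", windowSize = 1000L,
        values = rep(1, 50), statKind = "gene_count",
        scaffoldLength = 5e4)), "too short")
})

test_that("centromere recovery holds across seeded genomes", {
  hits <- 0L
  n <- 40L
  for (seed in seq_len(n)) {
    spec <- genomeSpec(lengths = 250000L, cenFraction = 0.4,
                       rrnaChromosome = 0L, mitoLength = 0L,
                       seed = seed + 300)
    g <- generateGenome(spec)
    s <- g$assembly[["chr1"]]
    gc <- windowTrack(s, 1000, scaffold = "chr1")
    genes <- windowTrack(g$features, 1000, scaffold = "chr1",
                         scaffoldLength = nchar(s))
    call <- detectCentromere(gc, genes)
    truthMid <- mean(g$truth[["chr1"]]$centromere)
    if (abs(call$position - truthMid) <= 2.5 * 1000) hits <- hits + 1L
  }
  expect_gte(hits / n, 0.95)
})

test_that("tandem cluster counting matches plants and the scoring oracle", {
  mkFeat <- function(labels, starts, strand = "+") {
    GenomicRanges::GRanges("s", IRanges::IRanges(start = starts,
                                                 end = starts + 999),
                           strand = strand, subunit = labels)
  }
  one <- mkFeat(c("18S", "5.8S", "26S"), c(1000, 2100, 3200))
  expect_equal(detectTandemCluster(one)$copies, 1L)

  set.seed(43)
  labs <- rep(c("18S", "5.8S", "26S"), 4)
  starts <- cumsum(c(1000, rep(1100, 11))) +
    cumsum(c(0, sample(0:4000, 11, replace = TRUE)))
  four <- mkFeat(labs, starts)
  call <- detectTandemCluster(four)
  expect_equal(call$copies, 4L)
  expect_equal(length(call$members), 12L)

  # minus-strand cluster appears in reversed label order
  minus <- mkFeat(rep(c("26S", "5.8S", "18S"), 3),
                  cumsum(c(1000, rep(1500, 8))), strand = "-")
  expect_equal(detectTandemCluster(minus)$copies, 3L)

  none <- mkFeat(c("18S", "18S", "26S"), c(1000, 2100, 3200))
  expect_equal(detectTandemCluster(none)$copies, 0L)
  expect_equal(detectTandemCluster(none)$span, c(0, 0))

  # random label sequences against the exhaustive scoring oracle
  set.seed(45)
  for (i in 1:60) {
    labs <- sample(c("18S", "5.8S", "26S"), sample(3:15, 1),
                   replace = TRUE)
    starts <- cumsum(rep(1500, length(labs)))
    gr <- mkFeat(labs, starts, strand = "*")
    expect_equal(detectTandemCluster(gr)$copies,
                 oracleUnitCopies(labs, c("18S", "5.8S", "26S")),
                 info = paste("case", i))
  }
})

test_that("coverage peaks require signal, merge over small gaps", {
  flat <- new("CoverageTrack", scaffold = "s", depth = rep(30L, 50000))
  expect_equal(nrow(peakRegions(flat)), 0L)

  set.seed(47)
  depth <- as.integer(rnbinom(100000, mu = 30, size = 50))
  depth[40001:60000] <- as.integer(rnbinom(20000, mu = 1500, size = 50))
  tr <- new("CoverageTrack", scaffold = "s", depth = depth)
  pk <- peakRegions(tr)
  expect_equal(nrow(pk), 1L)
  ov <- min(pk$end[1], 60000) - max(pk$start[1], 40001) + 1
  expect_gte(ov / 20000, 0.95)

  gap <- rep(30L, 10000)
  gap[2001:3000] <- 900L
  gap[3501:4500] <- 900L
  trG <- new("CoverageTrack", scaffold = "s", depth = gap)
  expect_equal(nrow(peakRegions(trG)), 1L)

  zero <- new("CoverageTrack", scaffold = "s", depth = rep(0L, 1000))
  expect_equal(nrow(peakRegions(zero)), 0L)
})
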