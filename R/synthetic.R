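#' @include AllClasses.R telomere.R
NULL

randSeq <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Deterministically mutate away any exact telomere-motif occurrence inside
# the terminal stretches of a chromosome body, so that planted terminal
# arrays are the only chained motif copies a scanner can find there.
scrubMotifs <- function(seq, motifs, margin = 1500L) {
  n <- nchar(seq)
  regions <- list(c(1L, min(margin, n)),
                  c(max(1L, n - margin + 1L), n))
  for (motif in motifs) {
    repeat {
      found <- FALSE
      for (rg in regions) {
        part <- substr(seq, rg[1L], rg[2L])
        hit <- regexpr(motif, part, fixed = TRUE)
        if (hit > 0) {
          pos <- rg[1L] + hit - 1L + 2L   # third base of the occurrence
          ch <- substr(seq, pos, pos)
          substr(seq, pos, pos) <- if (ch == "C") "G" else "C"
          found <- TRUE
        }
      }
      if (!found) break
    }
  }
  seq
}

#' Specification for a planted-truth synthetic genome
#'
#' Describes the genome the generator emulates: chromosomes bounded by
#' exact telomere tandem arrays (copy numbers in the 12-17 range observed
#' in complete fungal T2T assemblies), an AT-rich gene-free centromere per
#' chromosome, one tandem rRNA cistron array (default 7 copies of
#' 18S-5.8S-26S), genome-wide GC around 0.48, and an optional ~28 kb
#' mitochondrial genome.
#'
#' @param lengths chromosome lengths in bp (default 800, 600 and 500 kb,
#'   desk-scale stand-ins for Mb-scale chromosomes).
#' @param startCopies,endCopies telomere copy numbers per terminus;
#'   `NULL` draws each uniformly from 12-17 under the spec seed.
#' @param cenFraction centromere midpoint as a fraction of each length
#'   (default 0.5, 0.3, 0.5: two metacentric, one submetacentric).
#' @param cenWidth centromere width in bp (default 30000).
#' @param atBoost how much the centromere GC fraction is lowered
#'   (default 0.25).
#' @param rrnaChromosome,rrnaCopies which chromosome carries the tandem
#'   rRNA array and how many unit copies (defaults 2 and 7).
#' @param mitoLength mitochondrial genome length (default 28000; 0
#'   disables it).
#' @param baseGC genome background GC fraction (default 0.48).
#' @param geneEvery mean spacing of planted genes in bp (default 4000).
#' @param seed integer fixing all randomness.
#' @return a list of class `GenomeSpec`.
#' @export
genomeSpec <- function(lengths = c(800000L, 600000L, 500000L),
                       startCopies = NULL, endCopies = NULL,
                       cenFraction = c(0.5, 0.3, 0.5),
                       cenWidth = 30000L, atBoost = 0.25,
                       rrnaChromosome = 2L, rrnaCopies = 7L,
                       mitoLength = 28000L, baseGC = 0.48,
                       geneEvery = 4000L, seed = 1L) {
  nChr <- length(lengths)
  stopifnot(all(lengths >= 100000L), length(cenFraction) == nChr,
            all(cenFraction > 0 & cenFraction < 1),
            cenWidth < min(lengths), baseGC > 0, baseGC < 1,
            atBoost < baseGC)
  structure(list(lengths = as.integer(lengths),
                 startCopies = startCopies, endCopies = endCopies,
                 cenFraction = cenFraction,
                 cenWidth = as.integer(cenWidth), atBoost = atBoost,
                 rrnaChromosome = as.integer(rrnaChromosome),
                 rrnaCopies = as.integer(rrnaCopies),
                 mitoLength = as.integer(mitoLength), baseGC = baseGC,
                 geneEvery = as.integer(geneEvery),
                 seed = as.integer(seed)),
            class = "GenomeSpec")
}

#' Generate a planted-truth genome
#'
#' Each chromosome is built as `(CCCTAA) x n_start + body + (TTAGGG) x
#' n_end`: i.i.d. background sequence at the base GC, an AT-boosted
#' gene-free centromere window, one tandem rRNA cluster (identical unit
#' copies with short internal spacers, each copy annotated with 18S,
#' 5.8S and 26S rRNA features), and gene features scattered outside the
#' centromere. Every planted quantity is recorded in the returned truth
#' object. Deterministic per spec seed.
#'
#' @param spec a [genomeSpec()].
#' @return list with `assembly` ([Assembly-class], scaffolds
#'   `chr1 ... chrN`), `features` (`GRanges` with `type`, `product`,
#'   `subunit` columns), `mito` (single-scaffold [Assembly-class] or
#'   `NULL`), and `truth` (per-chromosome planted telomere copies,
#'   centromere interval, rRNA interval and copies, gene counts).
#' @export
generateGenome <- function(spec) {
  stopifnot(inherits(spec, "GenomeSpec"))
  set.seed(spec$seed)
  nChr <- length(spec$lengths)
  startCopies <- spec$startCopies
  endCopies <- spec$endCopies
  if (is.null(startCopies)) startCopies <- sample(12:17, nChr, TRUE)
  if (is.null(endCopies)) endCopies <- sample(12:17, nChr, TRUE)
  seqs <- character(nChr)
  truth <- list()
  featRows <- list()
  unitLengths <- c(`18S` = 1800L, `5.8S` = 160L, `26S` = 3400L)
  its <- c(250L, 200L)        # ITS1/ITS2 spacers inside the unit
  interUnit <- 400L           # spacer between tandem unit copies
  for (i in seq_len(nChr)) {
    L <- spec$lengths[i]
    chrom <- paste0("chr", i)
    telS <- strrep("CCCTAA", startCopies[i])
    telE <- strrep("TTAGGG", endCopies[i])
    bodyLen <- L - nchar(telS) - nchar(telE)
    body <- randSeq(bodyLen, spec$baseGC)
    bodyOff <- nchar(telS)  # chromosome coord of body base b = bodyOff + b

    # centromere: AT-boosted, gene-free
    cenMid <- round(spec$cenFraction[i] * L)
    cenStart <- max(bodyOff + 1L, cenMid - spec$cenWidth %/% 2L)
    cenEnd <- min(bodyOff + bodyLen, cenStart + spec$cenWidth - 1L)
    substr(body, cenStart - bodyOff, cenEnd - bodyOff) <-
      randSeq(cenEnd - cenStart + 1L, spec$baseGC - spec$atBoost)

    # tandem rRNA cluster
    rrna <- NULL
    if (i == spec$rrnaChromosome && spec$rrnaCopies > 0L) {
      sub18 <- randSeq(unitLengths[[1L]], 0.5)
      sub58 <- randSeq(unitLengths[[2L]], 0.5)
      sub26 <- randSeq(unitLengths[[3L]], 0.5)
      unitSeq <- paste0(sub18, randSeq(its[1L], spec$baseGC), sub58,
                        randSeq(its[2L], spec$baseGC), sub26,
                        randSeq(interUnit, spec$baseGC))
      cluster <- strrep(unitSeq, spec$rrnaCopies)
      clStart <- round(0.75 * L)   # chromosome coord, clear of centromere
      stopifnot(clStart > cenEnd + 1000L,
                clStart + nchar(cluster) < bodyOff + bodyLen - 2000L)
      substr(body, clStart - bodyOff, clStart - bodyOff +
               nchar(cluster) - 1L) <- cluster
      unitLen <- nchar(unitSeq)
      for (cp in seq_len(spec$rrnaCopies)) {
        off <- clStart + (cp - 1L) * unitLen
        offs <- c(0L,
                  unitLengths[[1L]] + its[1L],
                  unitLengths[[1L]] + its[1L] + unitLengths[[2L]] + its[2L])
        for (s in 1:3) {
          featRows[[length(featRows) + 1L]] <- data.frame(
            scaffold = chrom, start = off + offs[s],
            end = off + offs[s] + unitLengths[[s]] - 1L, strand = "+",
            type = "rRNA",
            product = paste(names(unitLengths)[s], "ribosomal RNA"))
        }
      }
      rrna <- list(start = clStart,
                   end = clStart + nchar(cluster) - 1L,
                   copies = spec$rrnaCopies)
    }

    body <- scrubMotifs(body, c("CCCTAA", "TTAGGG"))
    seqs[i] <- paste0(telS, body, telE)
    names(seqs)[i] <- chrom

    # scatter genes outside the centromere (and the rRNA cluster)
    pos <- bodyOff + 500L
    nGenes <- 0L
    geneLen <- 1500L
    while (pos + geneLen < bodyOff + bodyLen - 500L) {
      inCen <- pos <= cenEnd + 500L && pos + geneLen >= cenStart - 500L
      inRrna <- !is.null(rrna) && pos <= rrna$end + 500L &&
        pos + geneLen >= rrna$start - 500L
      if (!inCen && !inRrna) {
        featRows[[length(featRows) + 1L]] <- data.frame(
          scaffold = chrom, start = pos, end = pos + geneLen - 1L,
          strand = sample(c("+", "-"), 1L), type = "gene",
          product = "hypothetical protein")
        nGenes <- nGenes + 1L
      }
      pos <- pos + geneLen +
        sample(seq(500L, 2L * spec$geneEvery - geneLen), 1L)
    }

    truth[[chrom]] <- list(length = L,
                           start_copies = startCopies[i],
                           end_copies = endCopies[i],
                           centromere = c(cenStart, cenEnd),
                           rrna = rrna, n_genes = nGenes)
  }
  featDf <- do.call(rbind, featRows)
  gr <- GenomicRanges::GRanges(
    seqnames = featDf$scaffold,
    ranges = IRanges::IRanges(start = featDf$start, end = featDf$end),
    strand = featDf$strand, type = featDf$type, product = featDf$product)
  S4Vectors::mcols(gr)$subunit <- extractSubunit(featDf$product)
  mito <- NULL
  if (spec$mitoLength > 0L)
    mito <- assembly(c(mito_ref = randSeq(spec$mitoLength, 0.3)),
                     name = "mito_ref")
  list(assembly = assembly(seqs, name = "truth"), features = gr,
       mito = mito, truth = truth)
}

applyNoise <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Derive candidate draft assemblies from a truth genome
#'
#' Materialises the contigs described by `plan`: each contig is a
#' concatenation of recorded truth-genome segments (chromosome, start,
#' end, strand), optionally with substitution noise and random junk
#' prepended/appended; extra junk-only contigs and a mitochondrial copy
#' can be added. Provenance is recorded base-exactly in the returned
#' truth.
#'
#' @param genome the output of [generateGenome()].
#' @param plan list with one entry per candidate; each entry has `name`
#'   and `contigs`, a named list where each contig is a list of:
#'   `segments` (list of `list(chrom, start, end, strand)`), optional
#'   `junkStart`/`junkEnd` (bp of random sequence to add), optional
#'   `noise` (substitution rate), or `random` (bp: a pure junk contig),
#'   or `mito = TRUE` (copy of the mitochondrial genome).
#' @param seed seed for noise and junk sequence.
#' @return list with `assemblies` (named list of [Assembly-class]) and
#'   `truth` (the plan, with junk lengths echoed).
#' @export
deriveCandidateAssemblies <- function(genome, plan, seed = 1L) {
  set.seed(seed)
  assemblies <- list()
  for (cand in plan) {
    seqs <- character()
    for (ctgId in names(cand$contigs)) {
      ctg <- cand$contigs[[ctgId]]
      if (!is.null(ctg$random)) {
        seqs[ctgId] <- randSeq(ctg$random, 0.48)
        next
      }
      if (isTRUE(ctg$mito)) {
        s <- genome$mito[[1L]]
        if (!is.null(ctg$noise)) s <- applyNoise(s, ctg$noise)
        seqs[ctgId] <- s
        next
      }
      parts <- vapply(ctg$segments, function(sg) {
        s <- substr(genome$assembly[[sg$chrom]], sg$start, sg$end)
        if (identical(sg$strand, "-")) s <- revComp(s)
        s
      }, "")
      s <- paste(parts, collapse = "")
      if (!is.null(ctg$noise) && ctg$noise > 0) s <- applyNoise(s, ctg$noise)
      if (!is.null(ctg$junkStart) && ctg$junkStart > 0)
        s <- paste0(randSeq(ctg$junkStart, 0.48), s)
      if (!is.null(ctg$junkEnd) && ctg$junkEnd > 0)
        s <- paste0(s, randSeq(ctg$junkEnd, 0.48))
      seqs[ctgId] <- s
    }
    assemblies[[cand$name]] <- assembly(seqs, name = cand$name)
  }
  list(assemblies = assemblies, truth = plan)
}

#' Simulate per-base coverage tracks
#'
#' Negative-binomial per-base depths around a constant mean, with
#' optional forced-zero terminal stretches (emulating unsupported contig
#' ends) and an optional boosted interval (emulating a tandem-repeat
#' coverage pile-up).
#'
#' @param x an [Assembly-class].
#' @param meanDepth mean depth (0 gives all-zero tracks).
#' @param zeroEnds bp forced to zero at each scaffold terminus: a single
#'   number for all scaffolds, or a named list of `c(start_bp, end_bp)`
#'   per scaffold.
#' @param boost optional `list(scaffold, start, end, multiplier)`.
#' @param dispersion negative-binomial size parameter (default 50).
#' @param seed RNG seed.
#' @return named list of [CoverageTrack-class], one per scaffold.
#' @export
simulateCoverage <- function(x, meanDepth = 30, zeroEnds = 0,
                             boost = NULL, dispersion = 50, seed = 1L) {
  stopifnot(meanDepth >= 0)
  set.seed(seed)
  out <- list()
  for (id in scaffoldNames(x)) {
    n <- unname(scaffoldLengths(x)[id])
    depth <- if (meanDepth == 0) integer(n)
             else stats::rnbinom(n, mu = meanDepth, size = dispersion)
    if (!is.null(boost) && identical(boost$scaffold, id)) {
      if (boost$start < 1 || boost$end > n)
        stop("boost interval outside scaffold")
      idx <- boost$start:boost$end
      depth[idx] <- stats::rnbinom(length(idx),
                                   mu = meanDepth * boost$multiplier,
                                   size = dispersion)
    }
    ze <- if (is.list(zeroEnds)) {
      if (is.null(zeroEnds[[id]])) c(0L, 0L) else zeroEnds[[id]]
    } else c(zeroEnds, zeroEnds)
    if (ze[1L] > 0) depth[seq_len(min(ze[1L], n))] <- 0L
    if (ze[2L] > 0) depth[n - seq_len(min(ze[2L], n)) + 1L] <- 0L
    out[[id]] <- new("CoverageTrack", scaffold = id,
                     depth = as.integer(depth))
  }
  out
}

#' Simulate an expression count matrix with planted fold changes
#'
#' Negative-binomial counts for two groups (default 2 + 2 samples, the
#' replicate layout of the emulated experiment), with planted log2 fold
#' changes for a subset of genes. The accompanying results table is a
#' documented stand-in for an external differential-expression model: the
#' estimated log2FC is the log-ratio of pseudocount-shrunken group means,
#' the p-value a Welch t-test on log2 counts, and the adjusted p-value
#' Benjamini-Hochberg step-up.
#'
#' @param nGenes number of genes.
#' @param plantedEffects named numeric vector of log2 fold changes (names
#'   = gene indices or ids `gene_...`); unnamed genes are null.
#' @param groupSizes samples per group (default `c(2, 2)`).
#' @param nbMean negative-binomial mean count (default 200).
#' @param nbDispersion negative-binomial dispersion alpha; the size
#'   parameter is `1/alpha` (default 0.02).
#' @param seed RNG seed.
#' @return list with `counts` (integer matrix genes x samples),
#'   `results` (data.frame `gene_id`, `log2_fold_change`, `p_value`,
#'   `adjusted_p_value`), `groups` (factor) and `truth` (planted log2FC
#'   per gene, 0 for null genes).
#' @export
simulateExpression <- function(nGenes = 1000L, plantedEffects = NULL,
                               groupSizes = c(2L, 2L), nbMean = 200,
                               nbDispersion = 0.02, seed = 1L) {
  stopifnot(nbMean > 0, all(groupSizes >= 1L))
  set.seed(seed)
  ids <- sprintf("gene_%04d", seq_len(nGenes))
  lfc <- stats::setNames(numeric(nGenes), ids)
  if (!is.null(plantedEffects)) {
    nm <- names(plantedEffects)
    idx <- if (is.null(nm)) seq_along(plantedEffects)
           else ifelse(grepl("^gene_", nm), match(nm, ids),
                       as.integer(nm))
    lfc[idx] <- plantedEffects
  }
  size <- 1 / nbDispersion
  groups <- factor(rep(c("control", "rich"), groupSizes),
                   levels = c("control", "rich"))
  counts <- matrix(0L, nrow = nGenes, ncol = sum(groupSizes),
                   dimnames = list(ids, paste0(groups, "_",
                                               unlist(lapply(groupSizes,
                                                             seq_len)))))
  for (j in seq_len(ncol(counts))) {
    mu <- if (groups[j] == "rich") nbMean * 2^lfc else rep(nbMean, nGenes)
    counts[, j] <- stats::rnbinom(nGenes, mu = mu, size = size)
  }
  m1 <- rowMeans(counts[, groups == "control", drop = FALSE])
  m2 <- rowMeans(counts[, groups == "rich", drop = FALSE])
  est <- log2((m2 + 1) / (m1 + 1))
  lc <- log2(counts + 1)
  p <- vapply(seq_len(nGenes), function(g) {
    a <- lc[g, groups == "control"]
    b <- lc[g, groups == "rich"]
    if (stats::sd(c(a, b)) == 0) return(1)
    tryCatch(stats::t.test(b, a)$p.value, error = function(e) 1)
  }, numeric(1L))
  adj <- stats::p.adjust(p, method = "BH")
  list(counts = counts,
       results = data.frame(gene_id = ids, log2_fold_change = est,
                            p_value = p, adjusted_p_value = adj),
       groups = groups, truth = lfc)
}

#' Build the standard curation benchmark
#'
#' Generates a truth genome and the baseline assembly the curation engine
#' must repair: one chromosome presented as two contigs sharing an exact
#' terminal overlap, two chromosomes fused into a chimera, a short junk
#' contig below the minimum usable read length, a noisy mitochondrial
#' copy, and unsupported random junk at the free contig ends (zero
#' simulated coverage). An identity alternate assembly provides split
#' evidence.
#'
#' @param seed integer seed driving the genome, the derived contigs and
#'   the coverage simulation.
#' @param spec optional [genomeSpec()] (its seed is overridden by
#'   `seed`).
#' @param overlap terminal overlap length planted between the two contig
#'   fragments (default 60000).
#' @param endJunk bp of unsupported junk at free contig ends
#'   (default 100).
#' @param meanDepth simulated mean coverage depth (default 30).
#' @return list: `genome` (from [generateGenome()]), `baseline` and
#'   `alternate` ([Assembly-class]), `coverage` (tracks for the baseline
#'   contigs), `mito` (reference [Assembly-class]), and `truth`
#'   (overlap length, chimera junction, junk/mito contig ids, planted
#'   per-chromosome records).
#' @export
syntheticBenchmark <- function(seed = 1L, spec = NULL, overlap = 60000L,
                               endJunk = 100L, meanDepth = 30) {
  if (is.null(spec)) spec <- genomeSpec(seed = seed)
  spec$seed <- as.integer(seed)
  genome <- generateGenome(spec)
  L <- scaffoldLengths(genome$assembly)
  p <- floor(0.6 * L[["chr1"]])
  plan <- list(
    list(name = "baseline", contigs = list(
      ctgB = list(segments = list(
        list(chrom = "chr2", start = 1L, end = L[["chr2"]], strand = "+"),
        list(chrom = "chr3", start = 1L, end = L[["chr3"]], strand = "+")),
        junkStart = endJunk, junkEnd = endJunk),
      ctgA1 = list(segments = list(
        list(chrom = "chr1", start = 1L, end = p, strand = "+")),
        junkStart = endJunk),
      ctgA2 = list(segments = list(
        list(chrom = "chr1", start = p - overlap + 1L, end = L[["chr1"]],
             strand = "+")),
        junkEnd = endJunk),
      ctgJ = list(random = 5000L),
      ctgM = list(mito = TRUE, noise = 0.005))),
    list(name = "alternate", contigs = list(
      altB = list(segments = list(
        list(chrom = "chr2", start = 1L, end = L[["chr2"]],
             strand = "+"))),
      altC = list(segments = list(
        list(chrom = "chr3", start = 1L, end = L[["chr3"]],
             strand = "+"))),
      altA = list(segments = list(
        list(chrom = "chr1", start = 1L, end = L[["chr1"]],
             strand = "+"))))))
  cand <- deriveCandidateAssemblies(genome, plan, seed = seed + 1L)
  baseline <- cand$assemblies$baseline
  coverage <- simulateCoverage(
    baseline, meanDepth = meanDepth,
    zeroEnds = list(ctgB = c(endJunk, endJunk),
                    ctgA1 = c(endJunk, 0L), ctgA2 = c(0L, endJunk),
                    ctgJ = c(0L, 0L), ctgM = c(0L, 0L)),
    seed = seed + 2L)
  list(genome = genome, baseline = baseline,
       alternate = cand$assemblies$alternate, coverage = coverage,
       mito = genome$mito,
       truth = list(overlap = overlap, junction = L[["chr2"]],
                    junk_contig = "ctgJ", mito_contig = "ctgM",
                    end_junk = endJunk,
                    chromosomes = genome$truth))
}

#' Write a synthetic fixture set to disk
#'
#' Serialises a [syntheticBenchmark()] bundle as plain-text files: truth
#' genome and baseline FASTA, features GFF3, per-base coverage TSV, and
#' the truth record as JSON.
#'
#' @param bench output of [syntheticBenchmark()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticFixtures <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFasta(bench$genome$assembly, file.path(dir, "truth_genome.fasta"))
  writeFasta(bench$baseline, file.path(dir, "baseline.fasta"))
  writeFasta(bench$alternate, file.path(dir, "alternate.fasta"))
  if (!is.null(bench$mito))
    writeFasta(bench$mito, file.path(dir, "mito_ref.fasta"))
  writeFeatures(bench$genome$features, file.path(dir, "features.gff3"))
  writePerBaseCoverage(bench$coverage, file.path(dir, "coverage.tsv"))
  jsonlite::write_json(bench$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
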