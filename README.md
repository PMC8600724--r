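# t2tcurate

Automated curation of long-read fungal genome assemblies toward gapless
telomere-to-telomere (T2T) chromosome reconstructions, for genome
projects that have several draft assemblies of the same small eukaryotic
genome and want the final chromosome set — with every merge, split, drop
and trim decision measured, logged and replayable — instead of a manual
dotplot-and-scissors session.

## What it does

* **Telomere scanning.** Chromosome ends of most fungi carry tandem
  arrays of the 6-mer telomere motif: `(TTAGGG)n` at the 3' end and its
  reverse complement `(CCCTAA)n` at the 5' end. `scanTelomeres()` counts
  exact motif copies in the maximal tandem chain within each terminal
  window (chaining across interruptions of at most one motif length) and
  classifies a scaffold T2T when both termini carry an array.
* **Assembly statistics.** `assemblyStats()` computes N50 (the smallest
  length among the largest scaffolds whose cumulative length reaches half
  the assembly), L50 (the size of that set), GC% over non-N bases, and
  length summaries.
* **Cross-assembly comparison.** `anchorMatches()` finds unique k-mer
  anchors (canonical k-mers occurring exactly once in each assembly,
  k = 21 by default); collinear chains of anchors give contig
  correspondence (`contigCorrespondence()`), chimera breakpoints, and
  terminal-overlap estimates (`detectTerminalOverlap()`, with the
  >= 50 kb merge rule).
* **Curation engine.** `curate()` runs drop-short (< 10 kb) →
  quarantine-mitochondrial → merge-overlaps → split-chimeras →
  trim-unsupported-ends → rename-by-length, emits the final assembly
  plus an audit log, and `replayActions()` reproduces the output
  byte-identically from the log.
* **Genome landscape.** Windowed GC / log2-coverage / gene-count tracks
  (`windowTrack()`), AT-rich gene-poor centromere localisation with
  metacentric/submetacentric arm classification (`detectCentromere()`),
  tandem rRNA-cistron (18S–5.8S–26S) copy counting
  (`detectTandemCluster()`), and coverage peak detection
  (`peakRegions()`).
* **Gene tables.** Pfam-domain asparaginase family classification
  (`classifyAsparaginase()`: class I = PF01112, class II =
  PF00710 + PF17763, class III = PF06089, homology-only by product
  description), count prefiltering by group medians
  (`prefilterCounts()`), and differential-expression calling with the
  4-fold and adjusted-p ≤ 0.05 filters exposed separately (`callDeg()`).
* **Planted-truth simulator.** `generateGenome()` /
  `syntheticBenchmark()` build seeded genomes with known telomere copy
  numbers, centromeres, rRNA arrays, fragmented/overlapping/chimeric
  candidate assemblies, coverage tracks and expression tables, so every
  detector is testable against its plant.

## Worked example

Repair a planted baseline (one 60 kb terminal-overlap pair, one chimera
of two chromosomes, a 5 kb junk contig, a mitochondrial contig, 100 bp
unsupported contig ends):

```r
library(t2tcurate)
bench <- syntheticBenchmark(seed = 1)
res <- curate(bench$baseline, alternates = list(bench$alternate),
              coverage = bench$coverage, mitoRefs = bench$mito)
res
#> CurationResult: 3 final scaffold(s), 1 quarantined, 8 logged action(s)
#>   T2T scaffolds: 3/3
actionLog(res)[, c("ordinal", "action", "subjects", "result")]
#>   ordinal     action                  subjects                           result
#> 1       1 drop_short                      ctgJ
#> 2       2  flag_mito                      ctgM
#> 3       3      merge               ctgA1,ctgA2                      ctgA1+ctgA2
#> 4       4      split                      ctgB                    ctgB.1,ctgB.2
#> 5       5       trim                    ctgB.1                           ctgB.1
#> 6       6       trim                    ctgB.2                           ctgB.2
#> 7       7       trim               ctgA1+ctgA2                      ctgA1+ctgA2
#> 8       8     rename ctgA1+ctgA2,ctgB.1,ctgB.2 scaffold_1,scaffold_2,scaffold_3
telomereReport(res)
#>     scaffold start_copies end_copies start_present end_present  t2t
#> 1 scaffold_1           12         13          TRUE        TRUE TRUE
#> 2 scaffold_2           15         16          TRUE        TRUE TRUE
#> 3 scaffold_3           12         14          TRUE        TRUE TRUE
```

The three final scaffolds are byte-identical to the three planted truth
chromosomes, the junk contig was dropped, the mitochondrial contig was
quarantined (not deleted), and the telomere copy numbers are exactly the
planted ones.

Classifying the bundled seven-gene asparaginase table and applying the
DEG rules:

```r
calls <- classifyAsparaginase(asparaginaseExample())
table(calls$class)
#>       class_I      class_II     class_III homology_only
#>             4             1             1             1
deg <- callDeg(asparaginaseExample())
sum(deg$significant & deg$direction == "up")    # 3
sum(deg$significant & deg$direction == "down")  # 1
```

Seven putative asparaginase genes in total: four class I, one class II,
one class III, one homology-only candidate; three are significantly
up-regulated under asparaginase-rich conditions and one down-regulated.

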