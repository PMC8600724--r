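---
title: "Curating telomere-to-telomere fungal assemblies with t2tcurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating telomere-to-telomere fungal assemblies with t2tcurate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2tcurate)
```

## The problem

Long-read assemblers routinely bring small fungal genomes (30-45 Mb, a
handful of chromosomes) to near-chromosome contiguity, but the last mile
to a gapless telomere-to-telomere (T2T) reconstruction is usually manual:
inspecting dotplots between assemblers, concatenating contigs that share
a long terminal overlap, splitting contigs that other assemblers resolve
as two chromosomes, discarding junk and mitochondrial contigs, and
trimming scaffold ends that no short read supports. `t2tcurate` automates
that curation loop and makes every decision auditable and replayable,
with a planted-truth simulator so the whole pipeline can be validated
end to end without any external data.

## Telomere scanning

Fungal chromosome ends carry tandem arrays of the 6-mer TTAGGG; at the
sequence start the motif appears as its reverse complement CCCTAA. For a
terminal window (default 1000 bp, set much larger than any observed
array) `longestTandemRun()` counts exact motif copies in the maximal
chain of tandem runs, chaining runs separated by at most
`maxInterruption` bp (default 6, one motif length — complete assemblies
show near-perfect arrays, and classical tandem-repeat finders tolerate
small interruptions the same way). When two chains tie, the one nearer
the terminus is reported. A terminus is called present at `minCopies`
(default 3) and a scaffold is T2T when both termini carry an array.
Counting is checked in the test suite against an exhaustive
dynamic-programming enumeration of all chains, and scanning the reverse
complement provably swaps the two counts.

```{r telomere}
seqs <- c(done = paste0(strrep("CCCTAA", 13),
                        paste(sample(c("A","C","G","T"), 3000,
                                     replace = TRUE), collapse = ""),
                        strrep("TTAGGG", 15)))
scanTelomeres(assembly(seqs))
```

## Anchors instead of alignment

All cross-assembly comparison rests on unique k-mer anchors
(`anchorMatches()`): a position pair is an anchor when its canonical
k-mer (default k = 21) occurs exactly once in each assembly. This is
dotplot-grade evidence — deterministic, fast at desk scale, and
sufficient for merge/split decisions — without base-level alignment.
Anchors are chained when consecutive coordinate deltas agree within
10 kb and share an orientation; chains on the same dotplot diagonal are
then fused across gaps of any length, because tandem repeats (an rRNA
array, telomere arrays) carry no assembly-unique k-mers and would
otherwise punch holes in a single true correspondence. Chains from
genuinely different placements differ in diagonal offset and never fuse.

Three consumers sit on top:

* `contigCorrespondence()` reports, per contig, its partner chains in
  another assembly. Two or more partners covering disjoint spans of at
  least 50 kb constitute chimera evidence; the breakpoint is the
  midpoint between adjacent chains, so its accuracy is bounded by k plus
  the chaining gap.
* `detectTerminalOverlap()` estimates a shared terminal overlap from the
  chain that runs into a terminus of both contigs (the configuration
  with the least terminal slack wins), and applies the >= 50 kb merge
  rule.
* `flagMitochondrial()` flags a contig when anchor chains to a
  mitochondrial reference cover at least half of its length.

## The curation engine

`curate()` applies the stages in a fixed order — drop short contigs,
quarantine mitochondrial contigs, merge terminal overlaps (largest
first, overlap bases taken from the longer contig), split chimeras,
trim unsupported ends, rename by decreasing length — mirroring the
narrative order in which such curation is done by hand. Thresholds live
in `curationConfig()`: contigs shorter than the minimum usable read
length (10 kb) are dropped (a contig of exactly 10 kb survives); reads
whose union aligned fraction elsewhere is at least 0.80 are not
recruited for local reassembly (`partitionUnassignedReads()`, boundary
inclusive); terminal bases with depth below 1 are trimmed.

Two refinements matter in practice. First, an approximate chimera
breakpoint is snapped to an interior telomere-array boundary when one
exists within 5 kb — a misjoin of two complete chromosomes leaves the
left chromosome's terminal (TTAGGG)n array at the junction, which
locates it exactly; without such an array the chain midpoint stands.
Second, overlap merging takes the overlap bases verbatim from the first
contig rather than computing a consensus, since merged scaffolds are
re-polished downstream in any real workflow (polishing is out of scope
here). Mitochondrial contigs are quarantined, never deleted, so no
genome data is silently discarded.

Every stage appends to an action log carrying its measured evidence
(lengths, overlap sizes, orientations, breakpoints, trim amounts, the
final renaming map). `replayActions()` re-applies the log to the
baseline and must reproduce the final assembly byte-identically — the
tests enforce this, and it is the audit guarantee for manual review.

Local reassembly itself (running an assembler on recruited reads) is
deliberately not performed; the engine emits the recruited read ids and
expects the caller to run their assembler of choice.

## Genome landscape

`windowTrack()` computes the circular-map rings: GC percent per 1 kb
window over non-N bases, `log2(mean depth + 1)` per 1 kb window (the +1
keeps zero-coverage windows finite; published maps plot log2 of average
coverage without stating zero handling, so the transform is named
explicitly wherever plotted), and gene counts per 100 kb window, a gene
belonging to the window containing its start.

`detectCentromere()` operationalises the visual call "AT-rich and
gene-scarce": it sums the z-scores of the GC and gene-density tracks,
smooths with a 25-window moving average, excludes 5% of windows at each
terminus (telomeric regions are themselves AT-rich), and centres the
call on the trough basin — the contiguous run of windows within a
quarter of the way back from the minimum toward the track median —
rather than the noisy argmin, since a centromere is a plateau of low
windows. Arms are measured from the call; long/short arm ratio at most
1.7 (the standard cytogenetic convention) classifies the chromosome
metacentric, otherwise submetacentric. Uniform tracks still return the
minimising window but flagged low-confidence. On real data these calls
are advisory: no quantitative criterion exists for visually identified
centromeres, and this detector is this package's operationalisation.

`detectTandemCluster()` counts uninterrupted repetitions of the rRNA
cistron unit (18S, 5.8S, 26S in order; ITS spacers are not features of
the unit) among position-sorted rRNA features, strand-consistently and
with a 50 kb cap on the gap between consecutive members so a chain can
never span a chromosome arm. `peakRegions()` picks coverage pile-ups at
a 10x-over-median threshold, merging across gaps up to 1 kb — the
signature of a tandem rRNA array under whole-genome sequencing.

## Gene tables

`classifyAsparaginase()` encodes the domain-architecture classes of
fungal L-asparaginases: class I = Pfam PF01112; class II = PF00710 and
PF17763 together; class III = PF06089; proteins with none of these but
"asparaginase" in their product line are homology-only candidates.
Precedence II > III > I is arbitrary but documented; no real protein in
the worked example carries domains of two classes. `prefilterCounts()`
keeps a gene when the larger of its within-group median counts reaches
10, and `callDeg()` exposes the two published filters separately —
`deg4` (|log2FC| >= 2, boundary inclusive) and `significant` (adjusted
p <= 0.05, inclusive; a missing adjusted p is never significant) —
because "significantly up-regulated" in the motivating study means the
significance filter alone, not the 4-fold rule. The linear fold change
is reported as `2^log2FC`; note that where a source text rounds
("approximately 128-fold"), `2^7.61` is about 195, and the package
reports the computed value.

## The synthetic generator

`generateGenome()` builds chromosomes as
`(CCCTAA)×n + body + (TTAGGG)×n` with i.i.d. background sequence at
GC 0.48 (the composition of the Trichoderma-like genomes this targets),
telomere copy numbers drawn from 12-17 (the range observed in complete
fungal T2T assemblies), a 30 kb centromere window whose GC is lowered
by 0.25 and which carries no genes, one tandem rRNA cluster of 7
identical 18S-ITS1-5.8S-ITS2-26S units, genes scattered roughly every
4 kb outside the centromere, and an optional 28 kb AT-rich
mitochondrial genome. Any stray telomere-motif occurrence within the
terminal 1.5 kb of a body is deterministically mutated away so the
planted arrays are the only chained copies a scanner can find there.
Default chromosome lengths are 800/600/500 kb — desk-scale stand-ins
for Mb-scale chromosomes, chosen so a 20-seed end-to-end benchmark runs
in minutes on one CPU; the structures, not the absolute sizes, are what
the detectors consume. At these sizes 21-mer uniqueness of random
background is near-certain, which the anchor tests verify rather than
assume.

`deriveCandidateAssemblies()` materialises contigs from base-exact
provenance records (segments, strand, substitution noise, junk ends),
and `syntheticBenchmark()` wires the standard scenario: one chromosome
split into two contigs sharing an exact 60 kb terminal overlap, two
chromosomes fused into a chimera, a 5 kb junk contig, a noisy
mitochondrial copy, and 100 bp of unsupported junk at the free contig
ends, with negative-binomial coverage (mean 30, size 50) zeroed over
the junk. Substitution noise only is modelled by default; an indel
option exists but chain tolerances are documented for substitutions.

`simulateExpression()` produces negative-binomial counts (2 + 2
replicates, mean 200, dispersion 0.02) with planted log2 fold changes,
and a results table that is a documented stand-in for an external
differential-expression model: log-ratio of pseudocount-shrunken group
means, Welch t-test on log2 counts, Benjamini-Hochberg step-up
adjustment. With two replicates per group its p-values are weak, which
is faithful to the design it emulates; the tests therefore calibrate
the estimator (null median |log2FC| < 0.2) and the 4-fold flag's power
(>= 80% on planted 8-fold effects), not the t-test.

What the simulator does not emulate: sequencing error models and reads,
repeat families beyond the rRNA array and telomeres, GC-coverage bias,
indel-dominated assembler error, or the count overdispersion structure
of real RNA-seq. Passing the plant-recover suite therefore shows the
decision logic is correct under clean planted evidence; it does not
certify behaviour on pathological real assemblies, where the audit log
and the quarantine-not-delete policy are the safety net.

## Numerical and degenerate-input choices

1-based closed coordinates are used everywhere internally, matching the
Bioconductor containers (`IRanges`, `GRanges`, `Biostrings`) the
package is built on; PAF stays 0-based half-open at its reader boundary
only, and GFF3 is 1-based by definition. N bases are excluded from
every GC denominator, and an all-N window yields `NA`. A coverage track
whose median is zero falls back to a mean-based peak threshold; an
all-zero track has no peaks and refuses end-trimming (an empty scaffold
is never emitted). Ties in N50 resolve by the descending sorted scan;
baseline selection ranks by T2T count, then contig count, then N50,
with input order as the final deterministic tie-break.

## A worked run

```{r benchmark}
bench <- syntheticBenchmark(seed = 1)
res <- curate(bench$baseline, alternates = list(bench$alternate),
              coverage = bench$coverage, mitoRefs = bench$mito)
res
actionLog(res)[, c("ordinal", "action", "subjects")]
telomereReport(res)
identical(as.character(replayActions(bench$baseline,
                                     actionLog(res))@seqs),
          as.character(finalAssembly(res)@seqs))
```

## Limitations

The anchor machinery assumes substitution-dominated divergence between
candidate assemblies; heavy indel noise shortens chains and widens
breakpoint uncertainty beyond the documented k-plus-gap bound. Overlap
merging produces no consensus at the junction, so merged scaffolds
should be re-polished. Centromere calls on real data are advisory. The
differential-expression stand-in is for fixture generation only and is
no substitute for a negative-binomial GLM on real counts.
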