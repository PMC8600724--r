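#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib t2tcurate, .registration = TRUE
NULL

#' Assembly: an ordered set of named scaffolds
#'
#' Thin wrapper around a [Biostrings::DNAStringSet] that enforces the
#' conventions the curation toolkit relies on: uppercase sequences over
#' `{A,C,G,T,N}`, non-empty unique scaffold ids, and preserved record order.
#'
#' @slot name single string naming the assembly (e.g. the assembler that
#'   produced it).
#' @slot seqs a `DNAStringSet`, one entry per scaffold, names = scaffold ids.
#'
#' @seealso [assembly()], [readFasta()], [assemblyStats()]
#' @export
setClass("Assembly", representation(name = "character",
                                    seqs = "DNAStringSet"))

setValidity("Assembly", function(object) {
  ids <- names(object@seqs)
  if (length(object@name) != 1L || is.na(object@name))
    return("'name' must be a single string")
  if (length(object@seqs) &&
      (is.null(ids) || any(!nzchar(ids)) || anyNA(ids)))
    return("all scaffolds must have non-empty ids")
  if (anyDuplicated(ids))
    return("scaffold ids must be unique")
  if (length(object@seqs) && any(Biostrings::width(object@seqs) < 1L))
    return("scaffold sequences must have length >= 1")
  af <- Biostrings::alphabetFrequency(object@seqs, baseOnly = FALSE,
                                      collapse = TRUE)
  bad <- sum(af[setdiff(names(af), c("A", "C", "G", "T", "N"))])
  if (bad > 0)
    return("sequences restricted to the alphabet {A,C,G,T,N}")
  TRUE
})

#' Construct an Assembly from sequences
#'
#' @param seqs named character vector or `DNAStringSet` of scaffold
#'   sequences. Characters are uppercased and `U` is mapped to `T`; any
#'   symbol outside `{A,C,G,T,N}` is an error.
#' @param name assembly name.
#' @return an [Assembly-class] object.
#' @examples
#' asm <- assembly(c(chr1 = "ACGTACGT", chr2 = "NNACGT"))
#' scaffoldLengths(asm)
#' @export
assembly <- function(seqs, name = "assembly") {
  if (is(seqs, "XStringSet")) {
    ids <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- ids
  }
  if (!is.character(seqs))
    stop("'seqs' must be a character vector or DNAStringSet")
  norm <- chartr("u", "t", toupper(seqs))
  norm <- chartr("U", "T", norm)
  bad <- grepl("[^ACGTN]", norm)
  if (any(bad))
    stop("illegal symbol in scaffold(s): ",
         paste(utils::head(names(norm)[bad], 3L), collapse = ", "))
  dss <- Biostrings::DNAStringSet(norm)
  new("Assembly", name = name, seqs = dss)
}

#' Assembly summary statistics
#'
#' Container for the contiguity and composition summary of an assembly:
#' scaffold count, total length, N50/L50, GC percent over non-N bases and
#' N-base count.
#'
#' @slot nScaffolds integer scaffold count.
#' @slot totalLength integer total bp.
#' @slot n50,l50 contiguity statistics (see [assemblyStats()]).
#' @slot gcPercent GC percent of non-N bases.
#' @slot nBases count of N bases.
#' @slot lengths integer vector of scaffold lengths in record order.
#' @export
setClass("AssemblyStats", representation(nScaffolds = "integer",
                                         totalLength = "numeric",
                                         n50 = "numeric",
                                         l50 = "integer",
                                         gcPercent = "numeric",
                                         nBases = "numeric",
                                         lengths = "numeric"))

setValidity("AssemblyStats", function(object) {
  if (object@nScaffolds >= 1L && !(object@n50 %in% object@lengths))
    return("n50 must be one of the scaffold lengths")
  if (object@nScaffolds >= 1L && object@l50 < 1L)
    return("l50 must be >= 1 for a non-empty assembly")
  if (object@gcPercent < 0 || object@gcPercent > 100)
    return("gcPercent must lie in [0, 100]")
  if (!isTRUE(all.equal(object@totalLength, sum(object@lengths))))
    return("totalLength must equal sum(lengths)")
  TRUE
})

#' Per-base coverage track
#'
#' Per-base read depth for one scaffold, as produced by
#' `genomeCoverageBed -d`. Index i of `depth` is the depth at base i
#' (1-based) of the scaffold.
#'
#' @slot scaffold scaffold id.
#' @slot depth non-negative integer vector, one entry per base.
#' @export
setClass("CoverageTrack", representation(scaffold = "character",
                                         depth = "integer"))

setValidity("CoverageTrack", function(object) {
  if (length(object@scaffold) != 1L || !nzchar(object@scaffold))
    return("'scaffold' must be a single non-empty id")
  if (length(object@depth) && min(object@depth) < 0L)
    return("depths must be >= 0")
  TRUE
})

#' Fixed-window summary track
#'
#' One value per fixed-size window along a scaffold (the last window may be
#' partial). `statKind` records which statistic the values carry:
#' `gc_percent`, `log2_coverage` or `gene_count`.
#'
#' @slot scaffold scaffold id.
#' @slot windowSize window size in bp.
#' @slot values numeric vector, one per window; `NA` marks windows with no
#'   informative bases (e.g. all-N windows for GC).
#' @slot statKind one of `"gc_percent"`, `"log2_coverage"`, `"gene_count"`.
#' @slot scaffoldLength scaffold length in bp.
#' @export
setClass("WindowTrack", representation(scaffold = "character",
                                       windowSize = "integer",
                                       values = "numeric",
                                       statKind = "character",
                                       scaffoldLength = "numeric"))

setValidity("WindowTrack", function(object) {
  if (!object@statKind %in% c("gc_percent", "log2_coverage", "gene_count"))
    return("unknown statKind")
  expected <- as.integer(ceiling(object@scaffoldLength / object@windowSize))
  if (length(object@values) != expected)
    return("number of windows must equal ceiling(length / windowSize)")
  v <- object@values[!is.na(object@values)]
  if (object@statKind == "gc_percent" && length(v) &&
      (min(v) < 0 || max(v) > 100))
    return("gc values must lie in [0, 100]")
  if (object@statKind == "gene_count" && length(v) && min(v) < 0)
    return("gene counts must be >= 0")
  TRUE
})

#' Result of a full curation run
#'
#' Bundles the final assembly, the quarantined (e.g. mitochondrial)
#' scaffolds, the replayable action log, and final telomere / summary
#' reports.
#'
#' @slot assembly the curated [Assembly-class].
#' @slot quarantined an [Assembly-class] of scaffolds set aside (not
#'   deleted), e.g. mitochondrial contigs.
#' @slot actions the audit log, a data.frame understood by
#'   [replayActions()].
#' @slot telomeres final telomere report (see [scanTelomeres()]).
#' @slot stats final [AssemblyStats-class].
#' @slot coverage named list of final per-scaffold [CoverageTrack-class]
#'   objects (propagated through merges/splits/trims), possibly empty.
#' @export
setClass("CurationResult", representation(assembly = "Assembly",
                                          quarantined = "Assembly",
                                          actions = "data.frame",
                                          telomeres = "data.frame",
                                          stats = "AssemblyStats",
                                          coverage = "list"))
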