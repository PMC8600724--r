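#' @include AllClasses.R
NULL

#' Scaffold ids of an assembly
#' @param x an [Assembly-class].
#' @return character vector of scaffold ids, in record order.
#' @export
setGeneric("scaffoldNames", function(x) standardGeneric("scaffoldNames"))

#' Scaffold lengths of an assembly
#' @param x an [Assembly-class].
#' @return named integer vector of scaffold lengths, in record order.
#' @export
setGeneric("scaffoldLengths", function(x) standardGeneric("scaffoldLengths"))

#' Assembly summary statistics
#'
#' @param x an [Assembly-class] (or object coercible to one).
#' @return an [AssemblyStats-class] object.
#' @export
setGeneric("assemblyStats", function(x) standardGeneric("assemblyStats"))

#' Fixed-window summary track
#'
#' Computes one of the circular-map rings: per-window GC percent from a
#' scaffold sequence, per-window `log2(mean depth + 1)` from a
#' [CoverageTrack-class], or per-window gene counts from a
#' `GRanges` of features.
#'
#' @param x a `DNAString`/character scaffold sequence, a
#'   [CoverageTrack-class], or a `GRanges` of gene features.
#' @param windowSize window size in bp (>= 100). GC and coverage rings are
#'   conventionally 1 kb; the gene ring 100 kb.
#' @param ... further arguments passed to methods (`scaffold`,
#'   `scaffoldLength` for the `GRanges` method).
#' @return a [WindowTrack-class].
#' @export
setGeneric("windowTrack",
           function(x, windowSize, ...) standardGeneric("windowTrack"))

#' @rdname Assembly-class
#' @param object an [Assembly-class].
#' @export
setMethod("show", "Assembly", function(object) {
  w <- Biostrings::width(object@seqs)
  cat("Assembly '", object@name, "': ", length(w), " scaffold(s), ",
      format(sum(w), big.mark = ","), " bp\n", sep = "")
  if (length(w)) {
    n <- utils::head(seq_along(w), 8L)
    for (i in n)
      cat("  ", names(object@seqs)[i], ": ",
          format(w[i], big.mark = ","), " bp\n", sep = "")
    if (length(w) > 8L) cat("  ...\n")
  }
})

#' @describeIn Assembly-class number of scaffolds.
#' @param x an [Assembly-class].
#' @export
setMethod("length", "Assembly", function(x) length(x@seqs))

#' @describeIn Assembly-class scaffold ids.
#' @export
setMethod("names", "Assembly", function(x) names(x@seqs))

setMethod("scaffoldNames", "Assembly", function(x) names(x@seqs))

setMethod("scaffoldLengths", "Assembly", function(x) {
  stats::setNames(Biostrings::width(x@seqs), names(x@seqs))
})

#' Extract scaffold sequences
#' @param x an [Assembly-class].
#' @param i scaffold id or index.
#' @return `[[` returns a single scaffold as a character string; `[`
#'   returns a sub-[Assembly-class].
#' @rdname Assembly-extract
#' @export
setMethod("[[", "Assembly", function(x, i) as.character(x@seqs[[i]]))

#' @rdname Assembly-extract
#' @param j,drop,... ignored.
#' @export
setMethod("[", "Assembly", function(x, i, j, ..., drop = TRUE) {
  new("Assembly", name = x@name, seqs = x@seqs[i])
})

#' @describeIn AssemblyStats-class pretty-print the summary table.
#' @param object an [AssemblyStats-class].
#' @export
setMethod("show", "AssemblyStats", function(object) {
  df <- as.data.frame(object)
  cat("Assembly statistics\n")
  for (nm in names(df))
    cat(sprintf("  %-13s %s\n", nm,
                format(df[[nm]], big.mark = ",", scientific = FALSE)))
})

#' Flatten AssemblyStats to a one-row data.frame
#' @param x an [AssemblyStats-class].
#' @param row.names,optional,... ignored (standard signature).
#' @return one-row data.frame with columns n_scaffolds, total_length, n50,
#'   l50, gc_percent, n_bases.
#' @export
as.data.frame.AssemblyStats <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(n_scaffolds = x@nScaffolds, total_length = x@totalLength,
             n50 = x@n50, l50 = x@l50,
             gc_percent = round(x@gcPercent, 2), n_bases = x@nBases)
}

#' @describeIn CoverageTrack-class track length and mean depth.
#' @param object a [CoverageTrack-class].
#' @export
setMethod("show", "CoverageTrack", function(object) {
  cat("CoverageTrack ", object@scaffold, ": ",
      format(length(object@depth), big.mark = ","), " bp, mean depth ",
      round(mean(object@depth), 2), "\n", sep = "")
})

#' @describeIn WindowTrack-class window count and statistic.
#' @param object a [WindowTrack-class].
#' @export
setMethod("show", "WindowTrack", function(object) {
  cat("WindowTrack [", object@statKind, "] ", object@scaffold, ": ",
      length(object@values), " windows of ", object@windowSize, " bp\n",
      sep = "")
})

#' @describeIn CurationResult-class curation outcome overview.
#' @param object a [CurationResult-class].
#' @export
setMethod("show", "CurationResult", function(object) {
  cat("CurationResult: ", length(object@assembly), " final scaffold(s), ",
      length(object@quarantined), " quarantined, ",
      nrow(object@actions), " logged action(s)\n", sep = "")
  cat("  T2T scaffolds: ", sum(object@telomeres$t2t), "/",
      nrow(object@telomeres), "\n", sep = "")
})

#' Accessors for CurationResult
#'
#' @param x a [CurationResult-class].
#' @return `finalAssembly()` the curated [Assembly-class];
#'   `quarantined()` the set-aside scaffolds; `actionLog()` the audit
#'   data.frame; `telomereReport()` the final telomere table.
#' @rdname CurationResult-accessors
#' @export
finalAssembly <- function(x) x@assembly

#' @rdname CurationResult-accessors
#' @export
quarantined <- function(x) x@quarantined

#' @rdname CurationResult-accessors
#' @export
actionLog <- function(x) x@actions

#' @rdname CurationResult-accessors
#' @export
telomereReport <- function(x) x@telomeres
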