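#' @include AllClasses.R
NULL

#' Read a FASTA assembly
#'
#' Records are kept in file order; sequences are uppercased and `U` mapped
#' to `T`. Any other symbol outside `{A,C,G,T,N}`, a duplicate id, or an
#' empty record is an error rather than a silent coercion.
#'
#' @param path path to a FASTA file.
#' @param name assembly name; defaults to the file name without extension.
#' @return an [Assembly-class].
#' @export
readFasta <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) stop("duplicate scaffold id in ", path)
  if (any(Biostrings::width(raw) == 0L)) stop("empty record in ", path)
  seqs <- as.character(raw)
  names(seqs) <- ids
  assembly(seqs, name = name)
}

#' Write an assembly as FASTA
#'
#' Sequences are wrapped at 60 columns so that a read/write round trip is
#' byte-identical.
#'
#' @param x an [Assembly-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  stopifnot(is(x, "Assembly"))
  Biostrings::writeXStringSet(x@seqs, path, width = 60L)
  invisible(path)
}

#' Compute N50/L50, GC percent and length summary
#'
#' N50 is the smallest length among the largest scaffolds whose cumulative
#' length reaches half the total (lengths sorted descending); L50 is the
#' number of scaffolds in that cumulative set. GC percent is computed over
#' non-N bases only.
#'
#' @rdname assemblyStats
#' @export
setMethod("assemblyStats", "Assembly", function(x) {
  if (length(x) == 0L) stop("empty assembly")
  w <- as.numeric(Biostrings::width(x@seqs))
  total <- sum(w)
  sorted <- sort(w, decreasing = TRUE)
  cum <- cumsum(sorted)
  l50 <- which(cum >= total / 2)[1L]
  af <- Biostrings::alphabetFrequency(x@seqs, baseOnly = TRUE,
                                      collapse = TRUE)
  gc <- af[["C"]] + af[["G"]]
  nonN <- af[["A"]] + af[["C"]] + af[["G"]] + af[["T"]]
  nN <- total - nonN
  new("AssemblyStats", nScaffolds = length(x), totalLength = total,
      n50 = sorted[l50], l50 = as.integer(l50),
      gcPercent = if (nonN > 0) 100 * gc / nonN else NA_real_,
      nBases = nN, lengths = w)
})

#' Read per-base coverage (genomeCoverageBed -d layout)
#'
#' Expects a 3-column TSV (scaffold, 1-based position, depth) with
#' consecutive positions per scaffold starting at 1, the layout produced by
#' `genomeCoverageBed -d`. Position p is stored at index p of the track.
#'
#' @param path path to the TSV.
#' @return named list of [CoverageTrack-class] objects, one per scaffold in
#'   file order.
#' @export
readPerBaseCoverage <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("scaffold", "pos", "depth"),
                          colClasses = c("character", "integer", "integer"))
  if (nrow(df) == 0L) stop("empty coverage file")
  if (anyNA(df$pos) || anyNA(df$depth)) stop("malformed coverage line")
  if (any(df$depth < 0L)) stop("negative depth")
  ids <- unique(df$scaffold)
  out <- lapply(ids, function(id) {
    sub <- df[df$scaffold == id, , drop = FALSE]
    if (!identical(sub$pos, seq_len(nrow(sub))))
      stop("non-consecutive positions for scaffold ", id)
    new("CoverageTrack", scaffold = id, depth = sub$depth)
  })
  names(out) <- ids
  out
}

#' Read bedGraph coverage and expand to per-base tracks
#'
#' Accepts the 4-column bedGraph layout (scaffold, 0-based half-open start,
#' end, depth); intervals must tile each scaffold without gaps starting
#' at 0.
#'
#' @param path path to the bedGraph file.
#' @return named list of [CoverageTrack-class] objects.
#' @export
readBedGraph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("scaffold", "start", "end", "depth"),
                          colClasses = c("character", "integer", "integer",
                                         "integer"))
  if (any(df$end <= df$start)) stop("bedGraph interval with end <= start")
  if (any(df$depth < 0L)) stop("negative depth")
  ids <- unique(df$scaffold)
  out <- lapply(ids, function(id) {
    sub <- df[df$scaffold == id, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (sub$start[1L] != 0L ||
        any(sub$start[-1L] != sub$end[-nrow(sub)]))
      stop("bedGraph intervals must tile scaffold ", id, " without gaps")
    new("CoverageTrack", scaffold = id,
        depth = rep(sub$depth, sub$end - sub$start))
  })
  names(out) <- ids
  out
}

#' Write per-base coverage tracks in genomeCoverageBed -d layout
#' @param tracks named list of [CoverageTrack-class] objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writePerBaseCoverage <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tr in tracks) {
    df <- data.frame(tr@scaffold, seq_along(tr@depth), tr@depth)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read alignment records from PAF
#'
#' Only the first six PAF columns are interpreted (query name, length,
#' 0-based half-open start/end, strand, target name); anything after them
#' is ignored. Records failing `0 <= qstart < qend <= qlen` are errors.
#'
#' @param path path to a PAF file.
#' @return data.frame with columns `query_id`, `query_length`,
#'   `query_start`, `query_end` (0-based half-open, as in the format),
#'   `target_id`, `strand`.
#' @export
readPaf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(query_id = character(), query_length = numeric(),
                      query_start = numeric(), query_end = numeric(),
                      target_id = character(), strand = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 6L)) stop("PAF line with fewer than 6 columns")
  df <- data.frame(
    query_id = vapply(fields, `[[`, "", 1L),
    query_length = as.numeric(vapply(fields, `[[`, "", 2L)),
    query_start = as.numeric(vapply(fields, `[[`, "", 3L)),
    query_end = as.numeric(vapply(fields, `[[`, "", 4L)),
    strand = vapply(fields, `[[`, "", 5L),
    target_id = vapply(fields, `[[`, "", 6L))
  if (anyNA(df$query_length) || anyNA(df$query_start) || anyNA(df$query_end))
    stop("malformed PAF coordinates")
  if (any(df$query_end <= df$query_start))
    stop("PAF record with qend <= qstart")
  if (any(df$query_end > df$query_length))
    stop("PAF record with qend > qlen")
  if (any(df$query_start < 0)) stop("PAF record with negative qstart")
  if (!all(df$strand %in% c("+", "-"))) stop("unknown strand symbol in PAF")
  df[c("query_id", "query_length", "query_start", "query_end",
       "target_id", "strand")]
}

#' Union aligned fraction per read
#'
#' For each read, the fraction of its length covered by the union of its
#' aligned query intervals (optionally restricted to a subset of targets).
#' Multi-record reads are handled by interval union, so overlapping
#' alignments are not double counted.
#'
#' @param alignments data.frame as returned by [readPaf()].
#' @param targets optional character vector; only alignments to these
#'   targets are counted. Default: all targets.
#' @return named numeric vector, fraction in `[0, 1]` per read id (reads
#'   with no counted alignment get 0 only if present in `alignments`).
#' @export
alignedFraction <- function(alignments, targets = NULL) {
  reads <- unique(alignments$query_id)
  sub <- alignments
  if (!is.null(targets))
    sub <- sub[sub$target_id %in% targets, , drop = FALSE]
  out <- stats::setNames(numeric(length(reads)), reads)
  if (nrow(sub)) {
    sp <- split(sub, sub$query_id)
    cov <- vapply(sp, function(d) {
      ir <- IRanges::reduce(IRanges::IRanges(start = d$query_start + 1,
                                             end = d$query_end))
      sum(IRanges::width(ir)) / d$query_length[1L]
    }, numeric(1L))
    out[names(cov)] <- cov
  }
  out
}

#' Read gene features from GFF3
#'
#' Parsed via `rtracklayer`; the result is a `GRanges` (1-based closed
#' coordinates, the Bioconductor convention) with the column-9 attributes
#' as metadata columns. rRNA features with a recognisable subunit in their
#' `product` attribute gain a `subunit` column (e.g. `"18S"`).
#'
#' @param path path to a GFF3 file.
#' @return a `GRanges` of features.
#' @export
readFeatures <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (!all(as.character(GenomicRanges::strand(gr)) %in% c("+", "-", "*")))
    stop("unknown strand symbol")
  prod <- S4Vectors::mcols(gr)$product
  if (!is.null(prod)) {
    S4Vectors::mcols(gr)$subunit <- extractSubunit(prod)
  }
  gr
}

#' Extract the rRNA subunit label from a product string
#' @param product character vector of product descriptions.
#' @return character vector with values like `"18S"`, `"5.8S"`, `"26S"`, or
#'   `NA` when no subunit is recognisable.
#' @export
extractSubunit <- function(product) {
  m <- regmatches(product,
                  regexpr("\\b(5\\.8S|[0-9]{1,2}S)\\b", product))
  out <- rep(NA_character_, length(product))
  hit <- regexpr("\\b(5\\.8S|[0-9]{1,2}S)\\b", product) > 0
  hit[is.na(hit)] <- FALSE
  out[hit] <- m
  out
}

#' Write gene features as GFF3
#' @param gr a `GRanges` of features (as from [readFeatures()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeatures <- function(gr, path) {
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
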