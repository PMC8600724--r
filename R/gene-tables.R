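#' @include AllClasses.R
NULL

#' Classify putative asparaginase genes by Pfam domain architecture
#'
#' Applies the domain-architecture rules for L-asparaginase gene families:
#' class I carries the asparaginase domain PF01112; class II carries both
#' PF00710 (asparaginase, N-terminal) and PF17763
#' (glutaminase/asparaginase C-terminal); class III carries PF06089
#' (L-asparaginase II). A protein with none of the class domains whose
#' product description mentions "asparaginase" (case-insensitive) is
#' classed `homology_only`; anything else is `none`. When domains from
#' several classes co-occur the precedence is II > III > I.
#'
#' @param annotations data.frame with columns `protein_id`, `pfam`
#'   (accessions `PFxxxxx`, several separated by `;` or `,`), and
#'   `product`.
#' @return data.frame with one row per protein, in input order:
#'   `protein_id`, `class` (`class_I`, `class_II`, `class_III`,
#'   `homology_only`, `none`) and `evidence` (matched accessions or
#'   product substring).
#' @export
classifyAsparaginase <- function(annotations) {
  stopifnot(all(c("protein_id", "pfam", "product") %in%
                  names(annotations)))
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    acc <- annotations$pfam[i]
    accs <- if (is.na(acc) || !nzchar(acc)) character()
            else trimws(strsplit(acc, "[;,]")[[1L]])
    accs <- accs[nzchar(accs)]
    if (length(accs) && any(!grepl("^PF[0-9]{5}$", accs)))
      stop("malformed Pfam accession for ", annotations$protein_id[i],
           ": ", paste(accs[!grepl("^PF[0-9]{5}$", accs)], collapse = ","))
    product <- annotations$product[i]
    cls <- "none"
    evidence <- ""
    if (all(c("PF00710", "PF17763") %in% accs)) {
      cls <- "class_II"; evidence <- "PF00710+PF17763"
    } else if ("PF06089" %in% accs) {
      cls <- "class_III"; evidence <- "PF06089"
    } else if ("PF01112" %in% accs) {
      cls <- "class_I"; evidence <- "PF01112"
    } else if (!is.na(product) && grepl("asparaginase", product,
                                        ignore.case = TRUE)) {
      cls <- "homology_only"
      evidence <- regmatches(product, regexpr("(?i)[a-z-]*asparaginase",
                                              product, perl = TRUE))
    }
    data.frame(protein_id = annotations$protein_id[i], class = cls,
               evidence = evidence)
  })
  do.call(rbind, rows)
}

#' Prefilter a count matrix on per-group median expression
#'
#' A gene is kept iff the maximum over groups of its within-group median
#' count reaches `minMedian` (default 10, inclusive) — the low-expression
#' removal rule applied before differential testing.
#'
#' @param counts numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns.
#' @param groups factor/character of length `ncol(counts)` assigning each
#'   sample to a group; every group must have at least one sample.
#' @param minMedian keep threshold (default 10).
#' @return character vector of kept gene ids, in matrix order.
#' @export
prefilterCounts <- function(counts, groups, minMedian = 10) {
  groups <- as.factor(groups)
  if (length(groups) != ncol(counts))
    stop("'groups' must label every column of 'counts'")
  if (any(table(groups) == 0L)) stop("group with zero samples")
  medians <- vapply(levels(groups), function(g) {
    apply(counts[, groups == g, drop = FALSE], 1L, stats::median)
  }, numeric(nrow(counts)))
  if (is.null(dim(medians)))
    medians <- matrix(medians, nrow = nrow(counts))
  keep <- apply(medians, 1L, max) >= minMedian
  rownames(counts)[keep]
}

#' Call differential expression from a results table
#'
#' Evaluates, per gene, the two published filters separately: `deg4`
#' (absolute expression change of 4-fold or greater, i.e.
#' `|log2FC| >= log2(foldThreshold)`, boundary inclusive) and
#' `significant` (adjusted p-value at most `alpha`, boundary inclusive; a
#' missing adjusted p is never significant). Direction is `up`/`down` for
#' significant genes by the sign of the fold change, `none` otherwise.
#'
#' @param records data.frame with columns `gene_id`, `log2_fold_change`
#'   (asparaginase-rich over non-rich), `p_value`,
#'   `adjusted_p_value` (`NA` allowed).
#' @param foldThreshold linear fold-change threshold (default 4).
#' @param alpha adjusted-p significance level (default 0.05).
#' @return data.frame: `gene_id`, `significant`, `deg4`, `direction`,
#'   `linear_fold` (`2^log2FC`).
#' @export
callDeg <- function(records, foldThreshold = 4, alpha = 0.05) {
  stopifnot(all(c("gene_id", "log2_fold_change", "adjusted_p_value") %in%
                  names(records)))
  lfc <- records$log2_fold_change
  if (any(!is.finite(lfc))) stop("non-finite log2 fold change")
  adjp <- records$adjusted_p_value
  significant <- !is.na(adjp) & adjp <= alpha
  deg4 <- abs(lfc) >= log2(foldThreshold)
  direction <- ifelse(!significant, "none",
                      ifelse(lfc > 0, "up", "down"))
  data.frame(gene_id = records$gene_id, significant = significant,
             deg4 = deg4, direction = direction, linear_fold = 2^lfc)
}

#' COG category shares of a gene set
#'
#' Simple category proportions of an input COG-assignment table,
#' restricted to a gene set (e.g. a DEG list).
#'
#' @param cogTable data.frame with columns `gene_id` and `category`.
#' @param geneIds genes to tally.
#' @return data.frame: `category`, `count`, `share` (fraction of the
#'   tallied genes).
#' @export
cogShares <- function(cogTable, geneIds) {
  sub <- cogTable[cogTable$gene_id %in% geneIds, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(data.frame(category = character(), count = integer(),
                      share = numeric()))
  tab <- sort(table(sub$category), decreasing = TRUE)
  data.frame(category = names(tab), count = as.integer(tab),
             share = as.numeric(tab) / nrow(sub))
}

#' The putative asparaginase gene table bundled with the package
#'
#' Loads the packaged seven-gene asparaginase annotation/expression table
#' (protein id, length, log2 fold change, p-values, product, Pfam
#' accessions) used in the worked examples.
#'
#' @return data.frame with columns `protein_id`, `gene_id`, `amino_acids`,
#'   `log2_fold_change`, `p_value`, `adjusted_p_value`, `product`,
#'   `pfam`.
#' @export
asparaginaseExample <- function() {
  path <- system.file("extdata", "asparaginase_genes.tsv",
                      package = "t2tcurate", mustWork = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          na.strings = "NA", quote = "",
                          stringsAsFactors = FALSE)
  df$gene_id <- sub("-T[0-9]+$", "", df$protein_id)
  df
}
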