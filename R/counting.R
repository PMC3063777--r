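#' Construct a count matrix container
#'
#' @param counts Integer matrix, genes x samples, with dimnames.
#' @param samples Data.frame with `sample_id`, `strain` (`B6`/`D2`) and
#'   optionally `lane`, `flowcell`; one row per column of `counts`.
#' @param N Per-sample total unique mapped reads (named, defaults to column
#'   sums).
#' @return A `CountMatrix` object.
#' @export
count_matrix <- function(counts, samples, N = colSums(counts)) {
  stopifnot(is.matrix(counts), ncol(counts) == nrow(samples),
            all(colnames(counts) == samples$sample_id))
  if (is.null(names(N))) names(N) <- colnames(counts)
  stopifnot(all(N >= colSums(counts)))
  obj <- list(counts = counts, samples = samples, N = N)
  class(obj) <- "CountMatrix"
  obj
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples;",
      "median library size", stats::median(x$N), "\n")
  invisible(x)
}

#' Count unique read starts into union exons
#'
#' A unique alignment increments gene g in its sample iff its leftmost
#' genomic base (`pos`, 0-based, regardless of strand) lies in a union exon
#' of g.  Multi-mapped and unmapped reads are never counted.  Per-sample
#' totals `N_j` are the numbers of unique alignments, whether or not they
#' start in an exon.  Alignments on chromosomes absent from the models are
#' tallied (`n_off_model`), not errors.
#'
#' @param alignments Data.frame from [seed_align()] with an added
#'   `sample_id` column, or a list of such per sample.
#' @param models A `GeneModelSet` that has passed
#'   [remove_intergene_overlaps()] (so gene assignment is unambiguous).
#' @param samples Sample metadata data.frame (`sample_id`, `strain`, ...).
#' @return A `CountMatrix`; attribute `n_off_model` counts unique alignments
#'   on chromosomes not present in the models.
#' @export
count_reads <- function(alignments, models, samples) {
  if (is.list(alignments) && !is.data.frame(alignments)) {
    alignments <- do.call(rbind, alignments)
  }
  stopifnot("sample_id" %in% names(alignments))
  gene_ids <- models$genes$gene_id
  uq <- alignments[alignments$status == "unique", , drop = FALSE]
  N <- vapply(samples$sample_id, function(s) sum(uq$sample_id == s), numeric(1))
  counts <- matrix(0L, length(gene_ids), nrow(samples),
                   dimnames = list(gene_ids, samples$sample_id))
  n_off <- 0L
  if (nrow(uq) > 0) {
    known <- uq$chrom %in% as.character(unique(GenomicRanges::seqnames(models$exons)))
    n_off <- sum(!known)
    uq <- uq[known, , drop = FALSE]
    if (nrow(uq) > 0) {
      starts <- GenomicRanges::GRanges(uq$chrom,
                                       IRanges::IRanges(uq$pos + 1L, width = 1L))
      hits <- GenomicRanges::findOverlaps(starts, models$exons, ignore.strand = TRUE)
      gi <- models$exons$gene_id[S4Vectors::subjectHits(hits)]
      si <- uq$sample_id[S4Vectors::queryHits(hits)]
      tab <- table(factor(gi, levels = gene_ids),
                   factor(si, levels = samples$sample_id))
      counts <- counts + unclass(tab)
    }
  }
  storage.mode(counts) <- "integer"
  out <- count_matrix(counts, samples, N)
  attr(out, "n_off_model") <- n_off
  out
}

#' Apply the zero-count gene filters
#'
#' Removes (a) genes with zero counts in every sample, then (b) genes with a
#' zero count in at least one B6 sample AND at least one D2 sample.  A gene
#' qualifying for both is reported under (a).
#'
#' @param counts A `CountMatrix`.
#' @return The filtered `CountMatrix`, with attribute `removal_report`: a
#'   data.frame of removed genes and the rule that removed them
#'   (`all_zero` or `zero_in_both_strains`).
#' @export
filter_genes <- function(counts) {
  samples <- counts$samples
  for (st in c("B6", "D2")) {
    if (!any(samples$strain == st)) stop("no samples for strain ", st)
  }
  y <- counts$counts
  b6 <- samples$strain == "B6"
  d2 <- samples$strain == "D2"
  all_zero <- rowSums(y) == 0
  zero_both <- !all_zero &
    rowSums(y[, b6, drop = FALSE] == 0) >= 1 &
    rowSums(y[, d2, drop = FALSE] == 0) >= 1
  report <- rbind(
    data.frame(gene_id = rownames(y)[all_zero],
               reason = rep("all_zero", sum(all_zero))),
    data.frame(gene_id = rownames(y)[zero_both],
               reason = rep("zero_in_both_strains", sum(zero_both)))
  )
  keep <- !(all_zero | zero_both)
  out <- count_matrix(y[keep, , drop = FALSE], samples, counts$N)
  attr(out, "removal_report") <- report
  out
}

#' Write a count matrix and its sample table as TSV
#'
#' @param counts A `CountMatrix`.
#' @param path Counts TSV (first column `gene_id`, then one column per
#'   sample).
#' @param samples_path Optional TSV for per-sample metadata and `N_j`.
#' @return Invisibly, `path`.
#' @export
write_counts_tsv <- function(counts, path, samples_path = NULL) {
  df <- data.frame(gene_id = rownames(counts$counts), counts$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(samples_path)) {
    sdf <- counts$samples
    sdf$N <- counts$N[sdf$sample_id]
    utils::write.table(sdf, samples_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a count matrix written by [write_counts_tsv()]
#'
#' @param path Counts TSV.
#' @param samples_path Samples TSV with `sample_id`, `strain` and `N`.
#' @return A `CountMatrix`.
#' @export
read_counts_tsv <- function(path, samples_path) {
  df <- utils::read.delim(path, check.names = FALSE)
  samples <- utils::read.delim(samples_path)
  y <- as.matrix(df[, -1, drop = FALSE])
  rownames(y) <- df$gene_id
  storage.mode(y) <- "integer"
  N <- samples$N
  names(N) <- samples$sample_id
  count_matrix(y[, samples$sample_id, drop = FALSE], samples, N)
}
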