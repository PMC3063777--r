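#' Read an exon annotation table
#'
#' Reads transcript-level exon annotations either from a GTF/GFF file (fields
#' seqname, start, end, strand plus `gene_id`/`transcript_id` attributes; only
#' rows with feature type `exon` are used) or from a 6-column TSV
#' (`gene_id`, `transcript_id`, `chrom`, `start`, `end`, `strand`).
#' Coordinates are 1-based inclusive in both formats and are preserved.
#'
#' Malformed rows (missing `gene_id`/`transcript_id`, or `start > end`) are
#' rejected record-by-record and reported, with line numbers, in the
#' `rejected` attribute of the result; well-formed rows are unaffected.
#'
#' @param path Path to a GTF/GFF file (extension `.gtf`, `.gff`, `.gff3`) or
#'   a tab-separated exon table.
#' @param format `"auto"` (default, by extension), `"gtf"` or `"tsv"`.
#' @return A data.frame of exon records with columns `gene_id`,
#'   `transcript_id`, `chrom`, `start`, `end`, `strand`, one row per exon,
#'   with a `rejected` attribute (data.frame of line numbers and reasons).
#' @export
read_exon_annotation <- function(path, format = c("auto", "gtf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.g[tf]f3?$", path, ignore.case = TRUE)) "gtf" else "tsv"
  }
  if (format == "gtf") .read_exons_gtf(path) else .read_exons_tsv(path)
}

.attr_field <- function(attr, key) {
  m <- regmatches(attr, regexpr(paste0(key, "[ =]+\"?[^\";]+\"?"), attr))
  out <- rep(NA_character_, length(attr))
  hit <- lengths(regmatches(attr, gregexpr(paste0(key, "[ =]"), attr))) > 0
  val <- sub(paste0("^", key, "[ =]+\"?"), "", m)
  val <- sub("\"?;?$", "", val)
  out[hit] <- val
  out
}

.read_exons_gtf <- function(path) {
  lines <- readLines(path)
  ln <- seq_along(lines)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lines <- lines[keep]; ln <- ln[keep]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad_cols <- nf < 9
  rejected <- data.frame(line = integer(), reason = character())
  if (any(bad_cols)) {
    rejected <- rbind(rejected, data.frame(line = ln[bad_cols], reason = "fewer than 9 fields"))
    fields <- fields[!bad_cols]; ln <- ln[!bad_cols]
  }
  if (length(fields) == 0) {
    out <- .empty_exon_frame()
    attr(out, "rejected") <- rejected
    return(out)
  }
  mat <- do.call(rbind, lapply(fields, `[`, 1:9))
  is_exon <- mat[, 3] == "exon"
  mat <- mat[is_exon, , drop = FALSE]; ln <- ln[is_exon]
  gene_id <- .attr_field(mat[, 9], "gene_id")
  transcript_id <- .attr_field(mat[, 9], "transcript_id")
  start <- suppressWarnings(as.integer(mat[, 4]))
  end <- suppressWarnings(as.integer(mat[, 5]))
  bad <- is.na(gene_id) | is.na(transcript_id)
  if (any(bad)) {
    rejected <- rbind(rejected, data.frame(line = ln[bad], reason = "missing gene_id or transcript_id"))
  }
  bad2 <- !bad & (is.na(start) | is.na(end) | start > end)
  if (any(bad2)) {
    rejected <- rbind(rejected, data.frame(line = ln[bad2], reason = "start > end or non-numeric coordinates"))
  }
  ok <- !bad & !bad2
  out <- data.frame(
    gene_id = gene_id[ok], transcript_id = transcript_id[ok],
    chrom = mat[ok, 1], start = start[ok], end = end[ok],
    strand = mat[ok, 7], stringsAsFactors = FALSE
  )
  attr(out, "rejected") <- rejected
  out
}

.read_exons_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df))) {
    # headerless 6-column variant
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 6) stop("exon TSV must have 6 columns: ", paste(need, collapse = ", "))
    names(df)[1:6] <- need
  }
  ln <- seq_len(nrow(df)) + 1L
  for (col in c("gene_id", "transcript_id", "chrom", "strand")) {
    df[[col]] <- as.character(df[[col]])
  }
  df$start <- suppressWarnings(as.integer(df$start))
  df$end <- suppressWarnings(as.integer(df$end))
  bad <- is.na(df$gene_id) | is.na(df$transcript_id) | df$gene_id == "" | df$transcript_id == ""
  bad2 <- !bad & (is.na(df$start) | is.na(df$end) | df$start > df$end)
  rejected <- rbind(
    data.frame(line = ln[bad], reason = rep("missing gene_id or transcript_id", sum(bad))),
    data.frame(line = ln[bad2], reason = rep("start > end or non-numeric coordinates", sum(bad2)))
  )
  out <- df[!bad & !bad2, need]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

.empty_exon_frame <- function() {
  data.frame(gene_id = character(), transcript_id = character(),
             chrom = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Build per-gene union-exon models
#'
#' For each gene, merges the exon intervals of all its transcripts into a set
#' of disjoint, sorted "union exons": overlapping or book-ended exons coalesce
#' into a single interval spanning the earliest start to the latest end.
#' Strand is carried along but plays no role in merging (the counting scheme
#' is unstranded).
#'
#' @param annotations Exon records as returned by [read_exon_annotation()].
#' @return A `GeneModelSet`: a list with elements
#'   \describe{
#'     \item{genes}{data.frame with `gene_id`, `chrom`, `strand`,
#'       `union_exon_length` (bases).}
#'     \item{exons}{[GenomicRanges::GRanges] of union exons with a `gene_id`
#'       metadata column, sorted by (chrom, start).}
#'     \item{removed}{`GRanges` of intervals excised for inter-gene overlap
#'       (empty until [remove_intergene_overlaps()]).}
#'   }
#' @export
build_union_exons <- function(annotations) {
  if (nrow(annotations) == 0) stop("no exon annotations supplied")
  chrom_per_gene <- tapply(annotations$chrom, annotations$gene_id,
                           function(x) length(unique(x)))
  multi <- names(chrom_per_gene)[chrom_per_gene > 1]
  if (length(multi) > 0) {
    stop("gene(s) with exons on multiple chromosomes: ", paste(multi, collapse = ", "))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$chrom,
    ranges = IRanges::IRanges(annotations$start, annotations$end),
    gene_id = annotations$gene_id
  )
  by_gene <- S4Vectors::split(gr, gr$gene_id)
  merged <- GenomicRanges::reduce(by_gene)   # merges overlapping + book-ended
  flat <- unlist(merged, use.names = TRUE)
  flat$gene_id <- names(flat)
  names(flat) <- NULL
  strand_per_gene <- vapply(split(annotations$strand, annotations$gene_id),
                            function(x) x[1], character(1))
  gene_ids <- names(merged)
  genes <- data.frame(
    gene_id = gene_ids,
    chrom = vapply(split(annotations$chrom, annotations$gene_id), function(x) x[1], character(1))[gene_ids],
    strand = strand_per_gene[gene_ids],
    union_exon_length = vapply(gene_ids, function(g) sum(IRanges::width(merged[[g]])), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(genes) <- NULL
  models <- list(
    genes = genes,
    exons = sort(flat, ignore.strand = TRUE),
    removed = GenomicRanges::GRanges()
  )
  class(models) <- "GeneModelSet"
  models
}

#' Remove intervals shared between genes
#'
#' Every base covered by the union exons of two or more genes is excised from
#' all genes that share it, so that read counting is gene-unambiguous.  The
#' excised intervals are recorded (each shared region once).  Genes reduced
#' to zero length are retained with an empty model, not dropped.  The
#' operation is idempotent.
#'
#' @param models A `GeneModelSet` from [build_union_exons()].
#' @return A `GeneModelSet` with disjoint inter-gene models; `removed` holds
#'   the excised intervals and gene lengths are recomputed from the final
#'   model.
#' @export
remove_intergene_overlaps <- function(models) {
  stopifnot(inherits(models, "GeneModelSet"))
  ex <- models$exons
  cov <- GenomicRanges::coverage(ex)
  shared <- GenomicRanges::GRanges(IRanges::slice(cov, lower = 2, rangesOnly = TRUE))
  if (length(shared) == 0) {
    out <- models
    out$removed <- GenomicRanges::GRanges()
    return(out)
  }
  keep <- GenomicRanges::setdiff(ex, shared, ignore.strand = TRUE)
  # re-attribute the surviving pieces to genes by overlap with the originals
  hits <- GenomicRanges::findOverlaps(keep, ex, ignore.strand = TRUE)
  pieces <- GenomicRanges::pintersect(
    keep[S4Vectors::queryHits(hits)], ex[S4Vectors::subjectHits(hits)]
  )
  pieces$gene_id <- ex$gene_id[S4Vectors::subjectHits(hits)]
  pieces$hit <- NULL
  pieces <- sort(pieces, ignore.strand = TRUE)
  genes <- models$genes
  w <- tapply(IRanges::width(pieces), pieces$gene_id, sum)
  genes$union_exon_length <- ifelse(genes$gene_id %in% names(w),
                                    as.numeric(w[genes$gene_id]), 0)
  out <- list(genes = genes, exons = pieces, removed = sort(shared))
  class(out) <- "GeneModelSet"
  out
}

#' @export
print.GeneModelSet <- function(x, ...) {
  cat("GeneModelSet:", nrow(x$genes), "genes,", length(x$exons),
      "union exons,", length(x$removed), "removed inter-gene intervals\n")
  invisible(x)
}

#' Write union-exon models as BED-like TSVs
#'
#' Writes the union exons (and, optionally, the removed inter-gene intervals)
#' as BED-like tab-separated files with 0-based half-open coordinates, sorted
#' by (chrom, start).
#'
#' @param models A `GeneModelSet`.
#' @param path Output path for the union-exon BED (columns chrom, start0,
#'   end0, gene_id).
#' @param removed_path Optional path for the removed-intervals BED.
#' @return Invisibly, `path`.
#' @export
write_union_exons_bed <- function(models, path, removed_path = NULL) {
  ex <- models$exons
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start0 = GenomicRanges::start(ex) - 1L,
    end0 = GenomicRanges::end(ex),
    gene_id = ex$gene_id
  )
  df <- df[order(df$chrom, df$start0), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(removed_path)) {
    rm_ <- models$removed
    rdf <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(rm_)),
      start0 = GenomicRanges::start(rm_) - 1L,
      end0 = GenomicRanges::end(rm_)
    )
    rdf <- rdf[order(rdf$chrom, rdf$start0), ]
    utils::write.table(rdf, removed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
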