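# Allele-specific mapping bias: SNP-substituted strain genome, per-gene SNP
# density, and classification of DE status changes between the
# reference-aligned and substituted-genome-aligned analyses.

#' Read a strain SNP list
#'
#' Accepts a VCF (CHROM/POS/REF/ALT columns; only biallelic single-nucleotide
#' records are kept, others are skipped and tallied) or a headerless
#' 4-column TSV (`chrom`, `pos`, `ref_allele`, `alt_allele`).
#'
#' @param path VCF (`.vcf`) or TSV file.
#' @return Data.frame with `chrom`, `pos` (1-based), `ref_allele`,
#'   `alt_allele`; attribute `n_skipped` counts non-SNV records.
#' @export
read_snps <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    out <- data.frame(chrom = character(), pos = integer(),
                      ref_allele = character(), alt_allele = character())
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  is_vcf <- grepl("\\.vcf$", path, ignore.case = TRUE) ||
    all(lengths(fields) >= 8)
  if (is_vcf) {
    chrom <- vapply(fields, `[`, "", 1)
    pos <- as.integer(vapply(fields, `[`, "", 2))
    ref <- toupper(vapply(fields, `[`, "", 4))
    alt <- toupper(vapply(fields, `[`, "", 5))
  } else {
    chrom <- vapply(fields, `[`, "", 1)
    pos <- as.integer(vapply(fields, `[`, "", 2))
    ref <- toupper(vapply(fields, `[`, "", 3))
    alt <- toupper(vapply(fields, `[`, "", 4))
  }
  snv <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  out <- data.frame(chrom = chrom[snv], pos = pos[snv],
                    ref_allele = ref[snv], alt_allele = alt[snv],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!snv)
  out
}

#' Write SNPs as a minimal VCF
#'
#' @param snps SNP data.frame (`chrom`, `pos`, `ref_allele`, `alt_allele`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_snps_vcf <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snps) > 0) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", snps$chrom, snps$pos,
                       snps$ref_allele, snps$alt_allele), con)
  }
  invisible(path)
}

#' Build the SNP-substituted strain genome
#'
#' Writes the alternate (D2) allele into the reference sequence at every SNP
#' position, except that positions where the reference carries `N`
#' (repeat-masked) are left as `N`, and positions where the reference base
#' contradicts the stated `ref_allele` are skipped with a warning.  Genome
#' length is preserved.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param snps SNP data.frame from [read_snps()].
#' @return The substituted genome, with attribute `substitution_report`
#'   (list: `substituted`, `skipped_n`, `skipped_mismatch`).
#' @export
build_snp_substituted_genome <- function(genome, snps) {
  report <- list(substituted = 0L, skipped_n = 0L, skipped_mismatch = 0L)
  out <- genome
  for (ch in unique(snps$chrom)) {
    if (!ch %in% names(genome)) stop("SNP on unknown chromosome: ", ch)
    s <- snps[snps$chrom == ch, ]
    L <- nchar(genome[[ch]])
    if (any(s$pos < 1 | s$pos > L)) {
      bad <- which(s$pos < 1 | s$pos > L)[1]
      stop("SNP position out of bounds: ", ch, ":", s$pos[bad])
    }
    v <- strsplit(out[[ch]], "", fixed = TRUE)[[1]]
    ref_base <- toupper(v[s$pos])
    is_n <- ref_base == "N"
    mismatch <- !is_n & ref_base != s$ref_allele
    do_sub <- !is_n & !mismatch
    v[s$pos[do_sub]] <- s$alt_allele[do_sub]
    out[[ch]] <- paste(v, collapse = "")
    report$substituted <- report$substituted + sum(do_sub)
    report$skipped_n <- report$skipped_n + sum(is_n)
    report$skipped_mismatch <- report$skipped_mismatch + sum(mismatch)
    if (any(mismatch)) {
      warning(sum(mismatch), " SNP(s) on ", ch,
              " skipped: stated ref allele does not match the genome")
    }
  }
  attr(out, "substitution_report") <- report
  out
}

#' SNPs per kilobase of union exons
#'
#' Counts SNPs whose position falls inside each gene's final union-exon
#' model and divides by the model length in kilobases.  Zero-length genes
#' are excluded (density undefined) and listed in the `excluded` attribute.
#'
#' @param models A `GeneModelSet` after [remove_intergene_overlaps()].
#' @param snps SNP data.frame.
#' @return Data.frame with `gene_id`, `n_snps`, `union_exon_length`,
#'   `snps_per_kb`; attribute `excluded` lists zero-length genes.
#' @export
snps_per_kb <- function(models, snps) {
  genes <- models$genes
  n_snp <- stats::setNames(rep(0L, nrow(genes)), genes$gene_id)
  if (nrow(snps) > 0 && length(models$exons) > 0) {
    sg <- GenomicRanges::GRanges(snps$chrom,
                                 IRanges::IRanges(snps$pos, width = 1L))
    hits <- GenomicRanges::findOverlaps(sg, models$exons, ignore.strand = TRUE)
    tab <- table(models$exons$gene_id[S4Vectors::subjectHits(hits)])
    n_snp[names(tab)] <- as.integer(tab)
  }
  keep <- genes$union_exon_length > 0
  out <- data.frame(
    gene_id = genes$gene_id[keep],
    n_snps = as.integer(n_snp[genes$gene_id[keep]]),
    union_exon_length = genes$union_exon_length[keep],
    snps_per_kb = n_snp[genes$gene_id[keep]] /
      (genes$union_exon_length[keep] / 1000)
  )
  rownames(out) <- NULL
  attr(out, "excluded") <- genes$gene_id[!keep]
  out
}

#' Classify per-gene DE status changes between two analysis runs
#'
#' Compares each gene's (DE, direction) state before (all samples aligned to
#' the reference) and after (D2 samples realigned to the SNP-substituted
#' genome).  Categories: `retained_*` (DE with the same direction in both
#' runs), `lost_*` (DE before, non-DE after; putative false positives when
#' the direction was B6>D2), `gained_*` (non-DE before, DE after; putative
#' false negatives when the new direction is D2>B6), `stable_nonDE`, and
#' `direction_flip` for genes DE in both runs with opposite directions.
#'
#' @param de_before,de_after `DEResult` data.frames over the same gene
#'   universe; genes present in only one are reported, not classified.
#' @param q_threshold DE threshold (default 0.01).
#' @return A `BiasAssessment`: list with `per_gene` (data.frame `gene_id`,
#'   `status`, plus before/after direction), `category_counts` (named
#'   vector) and `unmatched_genes`.
#' @export
classify_status_changes <- function(de_before, de_after, q_threshold = 0.01) {
  common <- intersect(de_before$gene_id, de_after$gene_id)
  unmatched <- union(setdiff(de_before$gene_id, common),
                     setdiff(de_after$gene_id, common))
  b <- de_before[match(common, de_before$gene_id), ]
  a <- de_after[match(common, de_after$gene_id), ]
  de_b <- b$q_value < q_threshold
  de_a <- a$q_value < q_threshold
  dir_b <- ifelse(de_b, ifelse(b$log2_fold_change > 0, "B6>D2", "D2>B6"), "none")
  dir_a <- ifelse(de_a, ifelse(a$log2_fold_change > 0, "B6>D2", "D2>B6"), "none")
  status <- character(length(common))
  status[!de_b & !de_a] <- "stable_nonDE"
  status[de_b & !de_a & dir_b == "B6>D2"] <- "lost_B6gtD2"
  status[de_b & !de_a & dir_b == "D2>B6"] <- "lost_D2gtB6"
  status[!de_b & de_a & dir_a == "B6>D2"] <- "gained_B6gtD2"
  status[!de_b & de_a & dir_a == "D2>B6"] <- "gained_D2gtB6"
  status[de_b & de_a & dir_b == dir_a & dir_b == "B6>D2"] <- "retained_B6gtD2"
  status[de_b & de_a & dir_b == dir_a & dir_b == "D2>B6"] <- "retained_D2gtB6"
  status[de_b & de_a & dir_b != dir_a] <- "direction_flip"
  levels_ <- c("retained_B6gtD2", "retained_D2gtB6", "lost_B6gtD2",
               "lost_D2gtB6", "gained_B6gtD2", "gained_D2gtB6",
               "direction_flip", "stable_nonDE")
  per_gene <- data.frame(gene_id = common, status = status,
                         direction_before = dir_b, direction_after = dir_a,
                         q_before = b$q_value, q_after = a$q_value,
                         stringsAsFactors = FALSE)
  out <- list(
    per_gene = per_gene,
    category_counts = table(factor(status, levels = levels_)),
    unmatched_genes = unmatched
  )
  class(out) <- "BiasAssessment"
  out
}

#' @export
print.BiasAssessment <- function(x, ...) {
  cat("BiasAssessment over", nrow(x$per_gene), "genes:\n")
  print(x$category_counts)
  invisible(x)
}

#' Run the two-pass allele-bias pipeline
#'
#' Pipeline A aligns every sample's reads to the reference genome, counts
#' into the union-exon models, filters genes, and runs the exact-test DE
#' analysis.  Pipeline B reuses the B6 alignments, realigns only the D2
#' samples' reads to the SNP-substituted genome (coordinates are preserved
#' because substitution keeps genome length), restricts counting to pipeline
#' A's post-filter gene universe, and repeats the DE analysis (dispersion
#' re-estimated).  Per-gene DE status changes are then classified.
#'
#' @param genome Named character vector (reference, B6).
#' @param snps SNP data.frame (D2 alleles).
#' @param reads_by_sample Named list (by `sample_id`) of read data.frames
#'   (`read_id`, `sequence`), untrimmed or trimmed.
#' @param models A `GeneModelSet` after [remove_intergene_overlaps()].
#' @param samples Sample metadata (`sample_id`, `strain`).
#' @param q_threshold DE threshold (default 0.01).
#' @return List with `assessment` (a `BiasAssessment`), `de_before`,
#'   `de_after`, `counts_before`, `counts_after`, `alignment_stats`
#'   (per-sample unique/multi/unmapped for both passes) and
#'   `substitution_report`.
#' @export
run_allele_bias_pipeline <- function(genome, snps, reads_by_sample, models,
                                     samples, q_threshold = 0.01) {
  stopifnot(all(samples$sample_id %in% names(reads_by_sample)))
  idx_ref <- build_genome_index(genome)
  align_one <- function(reads, index, sid) {
    tr <- trim_reads(reads)
    al <- seed_align(tr$trimmed, index)
    al$sample_id <- sid
    al
  }
  aln_a <- lapply(samples$sample_id, function(s)
    align_one(reads_by_sample[[s]], idx_ref, s))
  names(aln_a) <- samples$sample_id
  counts_a <- filter_genes(count_reads(aln_a, models, samples))
  de_a <- de_analysis(counts_a, method = "exact", q_threshold = q_threshold)

  sub_genome <- build_snp_substituted_genome(genome, snps)
  d2 <- samples$sample_id[samples$strain == "D2"]
  aln_b <- aln_a
  if (nrow(snps) > 0) {
    idx_sub <- build_genome_index(sub_genome)
    for (s in d2) aln_b[[s]] <- align_one(reads_by_sample[[s]], idx_sub, s)
  }
  counts_b_full <- count_reads(aln_b, models, samples)
  keep <- rownames(counts_b_full$counts) %in% rownames(counts_a$counts)
  counts_b <- count_matrix(counts_b_full$counts[keep, , drop = FALSE],
                           samples, counts_b_full$N)
  de_b <- de_analysis(counts_b, method = "exact", q_threshold = q_threshold)

  stat_tab <- function(alns) do.call(rbind, lapply(names(alns), function(s) {
    a <- alns[[s]]
    data.frame(sample_id = s,
               unique = sum(a$status == "unique"),
               multi = sum(a$status == "multi"),
               unmapped = sum(a$status == "unmapped"))
  }))
  sa <- stat_tab(aln_a); sb <- stat_tab(aln_b)
  stats_ <- merge(sa, sb, by = "sample_id", suffixes = c("_ref", "_sub"))
  stats_$unique_delta <- stats_$unique_sub - stats_$unique_ref

  list(
    assessment = classify_status_changes(de_a, de_b, q_threshold),
    de_before = de_a, de_after = de_b,
    counts_before = counts_a, counts_after = counts_b,
    alignment_stats = stats_,
    substitution_report = attr(sub_genome, "substitution_report")
  )
}
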