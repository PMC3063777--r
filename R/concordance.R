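# Microarray probe/probeset filtering, best-probe selection, and
# three-platform detection / differential-expression concordance.
#
# Probe-level processing (RMA/MAS5/VST/RSN, probe-genome alignment, the
# detection p-values) happens upstream; this module consumes probe result
# tables carrying mapping flags, SNP-overlap flags, per-sample detection
# calls, p/q-values and linear-scale fold changes.

.detection_failed <- function(calls, strains) {
  # absent in >= 1 sample of each strain
  absent <- calls == "absent"
  any(absent & strains == "B6") && any(absent & strains == "D2")
}

#' Filter Affymetrix probesets
#'
#' Applies, in order: (1) drop probesets without a unique-exon Ensembl gene
#' mapping; (2) drop probesets left with fewer than 4 of their probes after
#' SNP/non-unique probe masking; (3) drop probesets with an `absent`
#' detection call in at least one B6 and at least one D2 sample.  The first
#' failing rule claims the removal in the tally; the surviving set is
#' independent of rule order.
#'
#' @param probes Data.frame with columns `probeset_id`, `gene_id` (`NA` if
#'   unmapped), `maps_unique`, `n_probes_total`, `n_probes_after_mask`,
#'   `p_value`, `q_value`, `fold_change`, and per-sample detection-call
#'   columns named `detection_<sample_id>` with values
#'   `present`/`marginal`/`absent`.
#' @param samples Sample metadata (`sample_id`, `strain`).
#' @return The surviving rows, with attribute `removal_tally` (named vector
#'   over rules `no_gene_mapping`, `probes_after_mask_lt4`,
#'   `absent_in_both_strains`).
#' @export
filter_affy <- function(probes, samples) {
  det <- .detection_matrix(probes, samples)
  r1 <- is.na(probes$gene_id) | probes$gene_id == "" | !probes$maps_unique
  r2 <- !r1 & probes$n_probes_after_mask < 4
  r3 <- !r1 & !r2 & apply(det, 1, .detection_failed,
                          strains = samples$strain)
  keep <- !(r1 | r2 | r3)
  out <- probes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removal_tally") <- c(
    no_gene_mapping = sum(r1),
    probes_after_mask_lt4 = sum(r2),
    absent_in_both_strains = sum(r3)
  )
  out
}

#' Filter Illumina probes
#'
#' Applies, in order: (1) drop probes without a perfect unique genomic
#' mapping; (2) drop probes without an Ensembl gene ID; (3) drop probes
#' spanning one or more SNPs; (4) drop probes failing detection (an
#' `absent` call — detection p >= 0.05 — in at least one sample of each
#' strain, mirroring the Affymetrix exclusion pattern).  First failing rule
#' claims the tally; survivors are order-independent.
#'
#' @param probes Data.frame with `probe_id`, `gene_id`, `maps_unique`,
#'   `spans_snp`, `p_value`, `q_value`, `fold_change`, and
#'   `detection_<sample_id>` columns.
#' @param samples Sample metadata.
#' @return Surviving rows with attribute `removal_tally` (rules
#'   `non_unique_mapping`, `no_gene_mapping`, `spans_snp`,
#'   `absent_in_both_strains`).
#' @export
filter_illumina <- function(probes, samples) {
  det <- .detection_matrix(probes, samples)
  r1 <- !probes$maps_unique
  r2 <- !r1 & (is.na(probes$gene_id) | probes$gene_id == "")
  r3 <- !r1 & !r2 & probes$spans_snp
  r4 <- !r1 & !r2 & !r3 & apply(det, 1, .detection_failed,
                                strains = samples$strain)
  keep <- !(r1 | r2 | r3 | r4)
  out <- probes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removal_tally") <- c(
    non_unique_mapping = sum(r1),
    no_gene_mapping = sum(r2),
    spans_snp = sum(r3),
    absent_in_both_strains = sum(r4)
  )
  out
}

.detection_matrix <- function(probes, samples) {
  cols <- paste0("detection_", samples$sample_id)
  missing <- setdiff(cols, names(probes))
  if (length(missing) > 0) stop("missing detection columns: ",
                                paste(missing, collapse = ", "))
  as.matrix(probes[, cols, drop = FALSE])
}

#' Select the best probe/probeset per gene
#'
#' Per gene, keeps the surviving record with the smallest q-value; ties are
#' broken by the smallest p-value, then lexicographic probe identifier.
#'
#' @param surviving Filtered probe data.frame (from [filter_affy()] or
#'   [filter_illumina()]).
#' @param id_col Identifier column (`"probeset_id"` or `"probe_id"`;
#'   auto-detected by default).
#' @return One row per gene.
#' @export
best_probe_per_gene <- function(surviving, id_col = NULL) {
  if (is.null(id_col)) {
    id_col <- if ("probeset_id" %in% names(surviving)) "probeset_id" else "probe_id"
  }
  o <- order(surviving$gene_id, surviving$q_value, surviving$p_value,
             surviving[[id_col]])
  s <- surviving[o, , drop = FALSE]
  out <- s[!duplicated(s$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Three-set detection Venn counts
#'
#' @param rnaseq_genes,affy_genes,illumina_genes Character vectors of
#'   detected gene identifiers.
#' @return Named vector of the 7 region counts (`rnaseq_only`, `affy_only`,
#'   `illumina_only`, `rnaseq_affy`, `rnaseq_illumina`, `affy_illumina`,
#'   `all_three`).
#' @export
detection_venn <- function(rnaseq_genes, affy_genes, illumina_genes) {
  r <- unique(rnaseq_genes); a <- unique(affy_genes); i <- unique(illumina_genes)
  u <- union(union(r, a), i)
  in_r <- u %in% r; in_a <- u %in% a; in_i <- u %in% i
  c(
    rnaseq_only = sum(in_r & !in_a & !in_i),
    affy_only = sum(!in_r & in_a & !in_i),
    illumina_only = sum(!in_r & !in_a & in_i),
    rnaseq_affy = sum(in_r & in_a & !in_i),
    rnaseq_illumina = sum(in_r & !in_a & in_i),
    affy_illumina = sum(!in_r & in_a & in_i),
    all_three = sum(in_r & in_a & in_i)
  )
}

#' DE concordance of RNA-Seq against two microarray platforms
#'
#' Classifies every RNA-Seq DE gene by where it is detected (best-probe
#' tables define platform detection) and where it is also DE at the same
#' q-threshold: `de_all_three`, `de_with_affy_only` / `de_with_illumina_only`
#' (DE shared with exactly one platform), `de_rnaseq_only_detected_both`
#' (detected everywhere, DE only by RNA-Seq), `de_rnaseq_only_detected_one`,
#' and `rnaseq_only_detected` (not detected on either array).  Within each
#' shared-DE category, fold-change direction agreement (sign of the RNA-Seq
#' log2 fold change vs sign of log2 of the array fold change) is counted.
#' Also reports a two-sided t-test comparing average log2 abundance of
#' RNA-Seq-only-DE genes (detected on both arrays) against genes whose DE is
#' corroborated by at least one array.
#'
#' @param rnaseq A `DEResult` data.frame.
#' @param affy_best,illumina_best Best-probe tables (one row per gene) that
#'   passed all filters.
#' @param q_threshold DE threshold (default 0.01).
#' @return A `ConcordanceSummary`: list with `per_gene` (classification of
#'   each RNA-Seq DE gene), `category_counts`, `direction` (per category:
#'   agree/conflict counts), `venn` (detection Venn over all tested genes),
#'   `abundance_test` (t-test results) and `anomalies`.
#' @export
de_concordance <- function(rnaseq, affy_best, illumina_best,
                           q_threshold = 0.01) {
  venn <- detection_venn(rnaseq$gene_id, affy_best$gene_id,
                         illumina_best$gene_id)
  de <- rnaseq[rnaseq$q_value < q_threshold, , drop = FALSE]
  af <- affy_best[match(de$gene_id, affy_best$gene_id), ]
  il <- illumina_best[match(de$gene_id, illumina_best$gene_id), ]
  det_a <- !is.na(af$gene_id)
  det_i <- !is.na(il$gene_id)
  de_a <- det_a & af$q_value < q_threshold
  de_i <- det_i & il$q_value < q_threshold
  anomalies <- de$gene_id[(de_a & (is.na(af$fold_change) | af$fold_change <= 0)) |
                          (de_i & (is.na(il$fold_change) | il$fold_change <= 0))]
  category <- ifelse(!det_a & !det_i, "rnaseq_only_detected",
              ifelse(de_a & de_i, "de_all_three",
              ifelse(de_a & !de_i, "de_with_affy_only",
              ifelse(de_i & !de_a, "de_with_illumina_only",
              ifelse(det_a & det_i, "de_rnaseq_only_detected_both",
                     "de_rnaseq_only_detected_one")))))
  sign_r <- sign(de$log2_fold_change)
  agree_a <- de_a & sign(log2(af$fold_change)) == sign_r
  agree_i <- de_i & sign(log2(il$fold_change)) == sign_r
  direction <- list()
  for (cat_ in c("de_all_three", "de_with_affy_only", "de_with_illumina_only")) {
    i <- which(category == cat_)
    agr <- switch(cat_,
      de_all_three = agree_a[i] & agree_i[i],
      de_with_affy_only = agree_a[i],
      de_with_illumina_only = agree_i[i])
    direction[[cat_]] <- c(agree = sum(agr, na.rm = TRUE),
                           conflict = sum(!agr, na.rm = TRUE))
  }
  lvls <- c("de_all_three", "de_with_affy_only", "de_with_illumina_only",
            "de_rnaseq_only_detected_both", "de_rnaseq_only_detected_one",
            "rnaseq_only_detected")
  g_only <- category == "de_rnaseq_only_detected_both"
  g_agree <- category %in% c("de_all_three", "de_with_affy_only",
                             "de_with_illumina_only")
  abundance_test <- NULL
  if (sum(g_only) >= 2 && sum(g_agree) >= 2) {
    tt <- stats::t.test(de$avg_log_abundance[g_only],
                        de$avg_log_abundance[g_agree])
    abundance_test <- list(p_value = tt$p.value,
                           mean_rnaseq_only = unname(tt$estimate[1]),
                           mean_agreed = unname(tt$estimate[2]))
  }
  out <- list(
    per_gene = data.frame(gene_id = de$gene_id, category = category,
                          stringsAsFactors = FALSE),
    category_counts = table(factor(category, levels = lvls)),
    direction = direction,
    venn = venn,
    abundance_test = abundance_test,
    anomalies = anomalies
  )
  class(out) <- "ConcordanceSummary"
  out
}

#' @export
print.ConcordanceSummary <- function(x, ...) {
  cat("ConcordanceSummary over", nrow(x$per_gene), "RNA-Seq DE genes\n")
  print(x$category_counts)
  invisible(x)
}
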