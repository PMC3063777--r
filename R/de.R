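# Assembly of per-gene differential-expression results: fold changes,
# average abundance, q-values, low-count flagging, direction calls, and the
# gene-length bias diagnostic.

#' Assemble per-gene differential-expression results
#'
#' Computes, for each gene, the log2 fold change B6 over D2 of normalized
#' mean proportions (zero-guarded with the pseudo-fraction `c = 0.5 / M*`),
#' the average log2 abundance (log2 of the mean across samples of
#' `y_gj / M_j`), q-values from the supplied p-values, the low-count flag
#' (average log2 abundance below -20, about one read per million), and a
#' direction call (`B6>D2` / `D2>B6`) for genes with `q` below the
#' threshold, `none` otherwise.
#'
#' @param counts A `CountMatrix`.
#' @param factors `NormalizationFactors`.
#' @param p Named vector of per-gene p-values (same genes as `counts`).
#' @param common_libsize `M*` used for the zero-guard (defaults to the
#'   geometric mean of the effective library sizes).
#' @param q_threshold DE threshold on the q-value (default 0.01).
#' @return A `DEResult` data.frame with columns `gene_id`,
#'   `log2_fold_change`, `avg_log_abundance`, `p_value`, `q_value`,
#'   `low_count_flag`, `direction`; attributes `pi0`, `q_threshold` and
#'   `zero_guard`.
#' @export
call_de <- function(counts, factors, p, common_libsize = NULL,
                    q_threshold = 0.01) {
  y <- counts$counts
  stopifnot(all(rownames(y) %in% names(p)))
  p <- p[rownames(y)]
  M <- factors$eff_libsize[match(colnames(y), factors$sample_id)]
  if (is.null(common_libsize)) common_libsize <- exp(mean(log(M)))
  prop <- sweep(y, 2, M, "/")
  b6 <- counts$samples$strain == "B6"
  cguard <- 0.5 / common_libsize
  mean_b6 <- rowMeans(prop[, b6, drop = FALSE])
  mean_d2 <- rowMeans(prop[, !b6, drop = FALSE])
  log2fc <- log2((mean_b6 + cguard) / (mean_d2 + cguard))
  avg_log <- log2(rowMeans(prop))
  q <- storey_qvalues(p)
  de <- q < q_threshold
  direction <- rep("none", nrow(y))
  direction[de & log2fc > 0] <- "B6>D2"
  direction[de & log2fc < 0] <- "D2>B6"
  out <- data.frame(
    gene_id = rownames(y),
    log2_fold_change = log2fc,
    avg_log_abundance = avg_log,
    p_value = as.numeric(p),
    q_value = as.numeric(q),
    low_count_flag = avg_log < -20,
    direction = direction,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "pi0") <- attr(q, "pi0")
  attr(out, "q_threshold") <- q_threshold
  attr(out, "zero_guard") <- cguard
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Recompute the low-read-count flag
#'
#' Sets `low_count_flag` to `TRUE` where the average log2 abundance (log2 of
#' the mean normalized proportion) is below -20.
#'
#' @param results A `DEResult` data.frame.
#' @return The results with the flag recomputed.
#' @export
flag_low_count <- function(results) {
  results$low_count_flag <- results$avg_log_abundance < -20
  results
}

#' Run the full differential-expression analysis on a count matrix
#'
#' Convenience wrapper: upper-quartile factors, common-dispersion estimation
#' on pseudocounts, the NB exact test (or the Poisson LRT comparator),
#' Storey q-values and direction calls.
#'
#' @param counts A filtered `CountMatrix` with both strains present.
#' @param method `"exact"` (NB exact test, default) or `"poisson"` (LRT).
#' @param q_threshold DE threshold (default 0.01).
#' @return A `DEResult` data.frame; attributes include `phi` (for the exact
#'   route) and `factors`.
#' @export
de_analysis <- function(counts, method = c("exact", "poisson"),
                        q_threshold = 0.01) {
  method <- match.arg(method)
  factors <- upper_quartile_factors(counts)
  groups <- factor(counts$samples$strain, levels = c("B6", "D2"))
  if (method == "exact") {
    disp <- estimate_common_dispersion(counts, factors, groups)
    p <- exact_test_matrix(disp$pseudo, groups, disp$phi)
    res <- call_de(counts, factors, p, common_libsize = disp$common_libsize,
                   q_threshold = q_threshold)
    attr(res, "phi") <- disp$phi
  } else {
    p <- poisson_lrt_matrix(counts, factors, groups)
    res <- call_de(counts, factors, p, q_threshold = q_threshold)
  }
  attr(res, "factors") <- factors
  attr(res, "method") <- method
  res
}

#' Gene-length bias diagnostic
#'
#' Splits tested genes into quartiles of union-exon length and reports the
#' number of DE genes and the median q-value per quartile, plus a chi-square
#' goodness-of-fit p-value against DE calls landing uniformly across
#' quartiles (a length-unbiased test statistic should not concentrate DE in
#' long genes).
#'
#' @param results A `DEResult` data.frame.
#' @param models A `GeneModelSet` providing `union_exon_length`.
#' @param q_threshold DE threshold (default 0.01).
#' @return List with `table` (per-quartile data.frame: `quartile`,
#'   `n_genes`, `n_de`, `median_q`, length range) and `chisq_p`.
#' @export
length_bias_summary <- function(results, models, q_threshold = 0.01) {
  len <- models$genes$union_exon_length[match(results$gene_id,
                                              models$genes$gene_id)]
  if (any(is.na(len))) stop("union_exon_length missing for some tested genes")
  if (nrow(results) < 4) stop("need at least 4 genes for quartiles")
  br <- stats::quantile(len, probs = seq(0, 1, 0.25))
  quart <- cut(len, breaks = unique(br), include.lowest = TRUE, labels = FALSE)
  de <- results$q_value < q_threshold
  tab <- do.call(rbind, lapply(sort(unique(quart)), function(qt) {
    i <- quart == qt
    data.frame(quartile = qt, n_genes = sum(i), n_de = sum(de[i]),
               median_q = stats::median(results$q_value[i]),
               min_length = min(len[i]), max_length = max(len[i]))
  }))
  n_de <- tab$n_de
  chisq_p <- if (sum(n_de) == 0) 1 else
    suppressWarnings(stats::chisq.test(n_de,
                                       p = tab$n_genes / sum(tab$n_genes))$p.value)
  list(table = tab, chisq_p = chisq_p)
}

#' Write DE results as TSV
#'
#' @param results A `DEResult` data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_de_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
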