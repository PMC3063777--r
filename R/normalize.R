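#' Scale counts by total unique reads (diagnostic)
#'
#' Divides each count by the sample's total unique read count expressed in
#' megabases of reads: `y / (N / 1e6)`.  Used for diagnostic distribution
#' plots only, not for testing.
#'
#' @param counts A `CountMatrix`.
#' @return Numeric matrix of scaled values (same shape as the counts).
#' @export
total_count_scale <- function(counts) {
  N <- counts$N[colnames(counts$counts)]
  if (any(N == 0)) stop("sample(s) with zero total reads: ",
                        paste(names(N)[N == 0], collapse = ", "))
  sweep(counts$counts, 2, N / 1e6, "/")
}

#' Upper-quartile normalization factors
#'
#' For each sample j, `u_j` is the 75th percentile (linear interpolation) of
#' the counts of genes with nonzero count in that sample; the raw factor
#' `u_j / N_j` is rescaled so the factors have geometric mean 1, and the
#' effective library size is `M_j = f_j * N_j`.
#'
#' @param counts A `CountMatrix`.
#' @return A `NormalizationFactors` data.frame with columns `sample_id`,
#'   `N`, `upper_quartile`, `factor`, `eff_libsize`.
#' @export
upper_quartile_factors <- function(counts) {
  y <- counts$counts
  N <- counts$N[colnames(y)]
  u <- vapply(seq_len(ncol(y)), function(j) {
    v <- y[, j]
    v <- v[v > 0]
    if (length(v) == 0) stop("sample with all-zero counts: ", colnames(y)[j])
    stats::quantile(v, 0.75, names = FALSE)
  }, numeric(1))
  raw <- u / N
  f <- raw / exp(mean(log(raw)))
  out <- data.frame(sample_id = colnames(y), N = as.numeric(N),
                    upper_quartile = u, factor = f, eff_libsize = f * N)
  rownames(out) <- NULL
  class(out) <- c("NormalizationFactors", "data.frame")
  out
}
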