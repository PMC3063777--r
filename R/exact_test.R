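# Exact negative-binomial test conditional on the two-group sum, and the
# single-factor Poisson likelihood-ratio comparator.

#' Exact NB test for one gene
#'
#' Conditional on the total `S = s_A + s_B` of the (rounded) pseudocount
#' group sums, the probability of observing a split `(s, S - s)` is
#' proportional to `NB(s; n_A mu, n_A/phi) * NB(S - s; n_B mu, n_B/phi)`
#' with `mu = S / (n_A + n_B)`.  The two-sided p-value sums the conditional
#' probabilities of all outcomes no more probable than the observed one
#' (ties included, with a small relative tolerance so analytically equal
#' probabilities computed by different routes still count as ties).
#' `phi = 0` reduces to the exact conditional binomial test.
#'
#' @param s_a,s_b Group sums (non-negative; real values are rounded half to
#'   even).
#' @param n_a,n_b Group sizes.
#' @param phi Common dispersion (>= 0).
#' @return Two-sided p-value in \[0, 1\]; `S = 0` returns 1.
#' @export
nb_exact_test <- function(s_a, s_b, n_a, n_b, phi) {
  s_a <- round(s_a); s_b <- round(s_b)
  S <- s_a + s_b
  if (S == 0) return(1)
  mu <- S / (n_a + n_b)
  s <- 0:S
  lp <- .dnb(s, mu = n_a * mu, phi = if (phi > 0) phi / n_a else 0, log = TRUE) +
    .dnb(S - s, mu = n_b * mu, phi = if (phi > 0) phi / n_b else 0, log = TRUE)
  # normalize on the log scale
  m <- max(lp)
  w <- exp(lp - m)
  w <- w / sum(w)
  obs <- w[s_a + 1]
  min(sum(w[w <= obs * (1 + 1e-8)]), 1)
}

#' Exact NB tests for a pseudocount matrix
#'
#' Applies [nb_exact_test()] gene by gene to group sums of pseudocounts.
#'
#' @param pseudo Matrix of pseudocounts (genes x samples).
#' @param groups Factor with exactly two levels.
#' @param phi Common dispersion.
#' @return Named numeric vector of p-values.
#' @export
exact_test_matrix <- function(pseudo, groups, phi) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2)
  a <- groups == levels(groups)[1]
  s_a <- round(rowSums(pseudo[, a, drop = FALSE]))
  s_b <- round(rowSums(pseudo[, !a, drop = FALSE]))
  n_a <- sum(a); n_b <- sum(!a)
  p <- vapply(seq_along(s_a), function(g)
    nb_exact_test(s_a[g], s_b[g], n_a, n_b, phi), numeric(1))
  names(p) <- rownames(pseudo)
  p
}

#' Single-factor Poisson likelihood-ratio test for one gene
#'
#' Null: `y_j ~ Poisson(M_j lambda)`; alternative: a separate rate per
#' group.  MLEs are closed-form (`lambda = sum(y) / sum(M)` per stratum);
#' the p-value is the upper chi-square(1) tail of twice the log-likelihood
#' ratio.  An all-zero gene returns p = 1.
#'
#' @param y Counts for one gene across samples.
#' @param groups Factor with two levels.
#' @param M Effective library sizes (offsets).
#' @return p-value.
#' @export
poisson_lrt <- function(y, groups, M) {
  stopifnot(length(y) == length(M), all(M > 0))
  if (sum(y) == 0) return(1)
  groups <- factor(groups)
  ll <- function(yy, mm) {
    lam <- sum(yy) / sum(mm)
    if (lam == 0) return(0)
    sum(yy * log(mm * lam) - mm * lam)
  }
  ll_null <- ll(y, M)
  ll_alt <- sum(vapply(levels(groups), function(k) {
    i <- groups == k
    ll(y[i], M[i])
  }, numeric(1)))
  stat <- max(2 * (ll_alt - ll_null), 0)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Poisson LRT for a count matrix
#'
#' @param counts A `CountMatrix`.
#' @param factors `NormalizationFactors` (effective library sizes used as
#'   offsets).
#' @param groups Factor per sample (defaults to strain).
#' @return Named vector of p-values.
#' @export
poisson_lrt_matrix <- function(counts, factors,
                               groups = factor(counts$samples$strain)) {
  y <- counts$counts
  M <- factors$eff_libsize[match(colnames(y), factors$sample_id)]
  p <- vapply(seq_len(nrow(y)), function(g) poisson_lrt(y[g, ], groups, M),
              numeric(1))
  names(p) <- rownames(y)
  p
}
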