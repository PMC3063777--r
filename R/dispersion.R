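# Quantile adjustment to a common library size and conditional
# maximum-likelihood estimation of the common negative-binomial dispersion.
#
# The exact test conditions on per-group sums, which is only valid when all
# samples share one library size; observed counts are therefore mapped to
# "pseudocounts" at the geometric-mean effective library size by matching
# NB cumulative probabilities (mid-probability transform, linearly
# interpolated between integer support points so that equal library sizes
# return the counts unchanged).

.pnb <- function(q, mu, phi) {
  if (phi <= 0) stats::ppois(q, mu) else stats::pnbinom(q, mu = mu, size = 1 / phi)
}
.qnb <- function(p, mu, phi) {
  if (phi <= 0) stats::qpois(p, mu) else stats::qnbinom(p, mu = mu, size = 1 / phi)
}
.dnb <- function(x, mu, phi, log = FALSE) {
  if (phi <= 0) stats::dpois(x, mu, log = log)
  else stats::dnbinom(x, mu = mu, size = 1 / phi, log = log)
}

.mid_cdf <- function(y, mu, phi) {
  (.pnb(y - 1, mu, phi) + .pnb(y, mu, phi)) / 2
}

# inverse of the interpolated mid-probability CDF
.mid_quantile <- function(u, mu, phi) {
  k0 <- .qnb(pmin(u, 1 - 1e-12), mu, phi)
  m0 <- .mid_cdf(k0, mu, phi)
  k <- ifelse(m0 >= u, k0, k0 + 1)
  lower <- .mid_cdf(k - 1, mu, phi)
  upper <- .mid_cdf(k, mu, phi)
  z <- ifelse(upper > lower, k - 1 + (u - lower) / (upper - lower), k)
  pmax(z, 0)
}

#' Quantile-adjust counts to a common effective library size
#'
#' Maps each observed count to the (real-valued) pseudocount whose NB
#' cumulative probability at the common library size `M* = geomean(M_j)`
#' matches the observed count's cumulative probability at its own `M_j`,
#' under a gene- and group-specific mean and the supplied common dispersion.
#' With equal effective library sizes the counts are returned unchanged;
#' with `phi = 0` the matching is Poisson.
#'
#' @param counts A `CountMatrix`.
#' @param factors `NormalizationFactors` from [upper_quartile_factors()].
#' @param phi Common NB dispersion (>= 0).
#' @param groups Factor of group labels per sample (defaults to strain).
#' @return List with `pseudo` (matrix of pseudocounts), `common_libsize`
#'   (`M*`) and `groups`.
#' @export
quantile_adjust <- function(counts, factors, phi,
                            groups = factor(counts$samples$strain)) {
  y <- counts$counts
  M <- factors$eff_libsize[match(colnames(y), factors$sample_id)]
  stopifnot(all(M > 0), length(groups) == ncol(y))
  Mstar <- exp(mean(log(M)))
  pseudo <- y * 0
  for (k in levels(factor(groups))) {
    idx <- which(groups == k)
    lam <- rowSums(y[, idx, drop = FALSE]) / sum(M[idx])
    pos <- lam > 0
    for (j in idx) {
      u <- .mid_cdf(y[pos, j], lam[pos] * M[j], phi)
      pseudo[pos, j] <- .mid_quantile(u, lam[pos] * Mstar, phi)
    }
  }
  list(pseudo = pseudo, common_libsize = Mstar, groups = groups)
}

# Dirichlet-multinomial (NB conditional on the sum) log-likelihood of one
# group's pseudocounts at dispersion phi, summed over genes.  z: G x n.
.dm_loglik_group <- function(z, phi) {
  n <- ncol(z)
  r <- 1 / phi
  zs <- rowSums(z)
  lgamma(zs + 1) - rowSums(lgamma(z + 1)) +
    rowSums(lgamma(z + r)) - n * lgamma(r) +
    lgamma(n * r) - lgamma(zs + n * r)
}

.common_disp_loglik <- function(pseudo, groups, phi) {
  ll <- 0
  for (k in levels(groups)) {
    z <- pseudo[, groups == k, drop = FALSE]
    ll <- ll + sum(.dm_loglik_group(z, phi))
  }
  ll
}

#' Estimate the common NB dispersion by conditional maximum likelihood
#'
#' Maximizes the summed Dirichlet-multinomial (NB-conditional-on-sum)
#' log-likelihood of the quantile-adjusted pseudocounts over the dispersion,
#' parameterized as `delta = phi / (1 + phi)` on `[0.001, 0.95]` (coarse grid
#' then golden-section refinement).  Adjustment and estimation are iterated
#' twice, then the pseudocounts are recomputed at the final estimate.
#'
#' @param counts A `CountMatrix`.
#' @param factors `NormalizationFactors`.
#' @param groups Factor of group labels (defaults to strain); every group
#'   must have at least 2 samples.
#' @param n_iter Number of adjust/estimate iterations (default 2).
#' @return A `DispersionEstimate`: list with `phi`, `delta`, `profile`
#'   (data.frame of the grid `delta` and `loglik`), `pseudo` (final
#'   pseudocounts), `common_libsize` and `groups`.
#' @export
estimate_common_dispersion <- function(counts, factors,
                                       groups = factor(counts$samples$strain),
                                       n_iter = 2) {
  groups <- factor(groups)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("group(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  grid <- seq(0.001, 0.95, length.out = 25)
  phi <- 0
  profile <- NULL
  for (it in seq_len(n_iter)) {
    adj <- quantile_adjust(counts, factors, phi, groups)
    ll <- vapply(grid, function(d)
      .common_disp_loglik(adj$pseudo, groups, d / (1 - d)), numeric(1))
    profile <- data.frame(delta = grid, loglik = ll)
    i <- which.max(ll)
    lo <- grid[max(i - 1, 1)]
    hi <- grid[min(i + 1, length(grid))]
    opt <- stats::optimize(function(d)
      .common_disp_loglik(adj$pseudo, groups, d / (1 - d)),
      interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
    delta <- opt$maximum
    # keep the grid edge if refinement did not beat it
    if (opt$objective < ll[i]) delta <- grid[i]
    phi <- delta / (1 - delta)
  }
  adj <- quantile_adjust(counts, factors, phi, groups)
  out <- list(phi = phi, delta = phi / (1 + phi), profile = profile,
              pseudo = adj$pseudo, common_libsize = adj$common_libsize,
              groups = groups)
  class(out) <- "DispersionEstimate"
  out
}

#' @export
print.DispersionEstimate <- function(x, ...) {
  cat("Common NB dispersion: phi =", signif(x$phi, 4),
      "(delta =", signif(x$delta, 4), ")\n")
  invisible(x)
}
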