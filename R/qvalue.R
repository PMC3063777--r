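#' Storey q-values
#'
#' Estimates the proportion of true nulls `pi0` from the tail behaviour of
#' the p-value distribution on the grid `lambda = 0.05, 0.10, ..., 0.95`
#' (`pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))`), extrapolates to
#' `lambda = 1` with a cubic smoothing spline (3 effective degrees of
#' freedom), clamps to `(0, 1]`, and falls back to `pi0 = 1` if the fit
#' exceeds 1 or fewer than 4 grid points are usable.  q-values are the step-up `min_{j >= i} pi0 m p_(j) / j`;
#' tied p-values share a q-value and q is monotone nondecreasing in p.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of q-values in the input order, with attribute `pi0`.
#' @export
storey_qvalues <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
  usable <- is.finite(pi0_l)
  pi0 <- 1
  if (sum(usable) >= 4) {
    fit <- stats::smooth.spline(lambda[usable], pi0_l[usable], df = 3)
    pred <- stats::predict(fit, x = 1)$y
    pi0 <- if (is.finite(pred) && pred <= 1) max(pred, .Machine$double.eps) else 1
  }
  o <- order(p)
  ro <- order(o)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- q_sorted[ro]
  # ties share q (cummin already guarantees it, enforce exactly)
  q <- stats::ave(q, p, FUN = min)
  attr(q, "pi0") <- pi0
  q
}
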