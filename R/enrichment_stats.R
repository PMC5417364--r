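# Exact and approximate statistical primitives. These are authored here
# (log-space hypergeometric tail, exact enumeration rank tests with a
# configurable crossover to the normal approximation) so that tests can
# check them against independent oracles rather than routing both sides of
# the comparison through one library call.

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing `n` genes from a
#' universe of `N` of which `K` carry the annotation, the probability of
#' seeing `k` or more carriers. Computed by summing log-binomial terms with
#' a log-sum-exp reduction, so small tails are stable.
#'
#' @param k observed overlap.
#' @param K annotated genes in the universe.
#' @param n size of the drawn set.
#' @param N universe size.
#' @return probability in (0, 1].
#' @examples
#' hypergeom_upper_tail(5, 5, 5, 10)  # 1/252
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (length(k) != 1L) stop_is("scalar arguments expected")
  if (K > N || n > N || k < 0 || k > min(K, n))
    stop_is("invalid hypergeometric parameters: k=%s K=%s n=%s N=%s", k, K, n, N)
  kk <- seq.int(k, min(K, n))
  lp <- lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)
  m <- max(lp)
  p <- exp(m + log(sum(exp(lp - m))))
  min(p, 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: q_(i) = min_{j >= i} ( p_(j) * m / j ), capped
#' at 1, returned in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of adjusted values.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop_is("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / seq.int(m, 1)))[ro]
}

# Exact two-sample rank-sum p by enumerating all C(n_x + n_y, n_x) group
# assignments of the pooled mid-ranks. W is the rank sum of x.
#' @noRd
.rank_sum_exact <- function(r_x, r_all, alternative) {
  n <- length(r_all); nx <- length(r_x)
  W <- sum(r_x)
  combs <- utils::combn(n, nx)
  Ws <- colSums(matrix(r_all[combs], nrow = nx))
  eps <- 1e-9
  p_less <- mean(Ws <= W + eps)     # P(W* <= W): evidence for x < y is small W
  p_greater <- mean(Ws >= W - eps)
  switch(alternative,
         less = p_less,
         greater = p_greater,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Mid-ranks for ties. Exact p by full enumeration of group assignments
#' when `n_x + n_y <= exact_max` (default 12), otherwise a normal
#' approximation with tie correction and continuity correction.
#' `alternative = "less"` means x tends to be smaller than y.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @param exact_max total-n crossover between exact enumeration and the
#'   normal approximation.
#' @return list with `statistic` (rank sum of `x`), `p.value` and `exact`.
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "less", "greater"),
                          exact_max = 12) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop_is("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))          # mid-ranks
  W <- sum(r[seq_len(nx)])
  if (n <= exact_max) {
    p <- .rank_sum_exact(r[seq_len(nx)], r, alternative)
    return(list(statistic = W, p.value = p, exact = TRUE))
  }
  mu <- nx * (n + 1) / 2
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = W, p.value = 1, exact = FALSE))
  sd <- sqrt(sigma2)
  z_less <- (W - mu + 0.5) / sd
  z_greater <- (W - mu - 0.5) / sd
  p <- switch(alternative,
              less = pnorm(z_less),
              greater = pnorm(z_greater, lower.tail = FALSE),
              two.sided = min(1, 2 * min(pnorm(z_less),
                                         pnorm(z_greater, lower.tail = FALSE))))
  list(statistic = W, p.value = p, exact = FALSE)
}

#' Wilcoxon signed-rank test against zero
#'
#' For paired/per-gene deltas. Zeros are dropped (Wilcoxon convention);
#' exact p by enumeration of all 2^n sign assignments when
#' `n <= exact_max`, else normal approximation with tie and continuity
#' correction.
#'
#' @param d numeric vector of differences.
#' @inheritParams rank_sum_test
#' @return list with `statistic` (positive-rank sum `V`), `p.value`,
#'   `exact`.
#' @export
signed_rank_test <- function(d, alternative = c("two.sided", "less", "greater"),
                             exact_max = 12) {
  alternative <- match.arg(alternative)
  d <- d[d != 0]
  n <- length(d)
  if (!n) return(list(statistic = 0, p.value = 1, exact = TRUE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- as.vector(signs %*% r)
    eps <- 1e-9
    p_less <- mean(Vs <= V + eps)
    p_greater <- mean(Vs >= V - eps)
    p <- switch(alternative, less = p_less, greater = p_greater,
                two.sided = min(1, 2 * min(p_less, p_greater)))
    return(list(statistic = V, p.value = p, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  sd <- sqrt(sigma2)
  p <- switch(alternative,
              less = pnorm((V - mu + 0.5) / sd),
              greater = pnorm((V - mu - 0.5) / sd, lower.tail = FALSE),
              two.sided = min(1, 2 * min(pnorm((V - mu + 0.5) / sd),
                                         pnorm((V - mu - 0.5) / sd,
                                               lower.tail = FALSE))))
  list(statistic = V, p.value = p, exact = FALSE)
}
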