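# Exact distribution of the Wilcoxon signed-rank statistic with tied
# (average) ranks: ranks are doubled to integers and the distribution of
# the positive-rank sum over all 2^n sign assignments is built by
# convolution. Returns probabilities over sums 0..sum(ranks2).
signed_rank_distribution <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (r in ranks2) {
    g <- f / 2
    g[(r + 1):(total + 1)] <- g[(r + 1):(total + 1)] + f[1:(total + 1 - r)] / 2
    f <- g
  }
  f
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test for paired samples, the standard comparison
#' for non-normal paired measurements (before/during/after firing rates,
#' waveform features). Zero differences are dropped and reported. For
#' `n <= exact_limit` non-zero pairs the p-value is exact, computed from
#' the full distribution of the positive-rank sum over all sign
#' assignments (valid under ties, where the classical exact tables are
#' not); above the limit a normal approximation with tie correction is
#' used.
#'
#' @param x,y Paired samples (equal length, at least 3 pairs).
#' @param exact_limit Largest n for the exact enumeration (default 25).
#' @return One-row tibble with `statistic` (positive-rank sum V),
#'   `p_value`, `n`, `n_zero_dropped`, `method`.
#' @export
#' @examples
#' paired_wilcoxon(c(1, 2, 3), c(2, 3, 4)) # exact two-sided p = 0.25
paired_wilcoxon <- function(x, y, exact_limit = 25) {
  if (length(x) != length(y)) abort("x and y must be paired (equal length).")
  if (length(x) < 3) abort("need at least 3 pairs.")
  d <- x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort("degenerate: all differences are zero.")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  total <- n * (n + 1) / 2
  if (n <= exact_limit) {
    ranks2 <- as.integer(round(2 * r))
    f <- signed_rank_distribution(ranks2)
    sums <- seq_along(f) - 1
    v2 <- round(2 * v)
    center <- sum(ranks2) / 2
    p <- sum(f[abs(sums - center) >= abs(v2 - center) - 1e-9])
    method <- "exact"
  } else {
    mu <- total / 2
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal_approx"
  }
  tibble(
    statistic = v, p_value = min(p, 1), n = n,
    n_zero_dropped = n_zero, method = method
  )
}

#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples (the standard AFM
#' group comparison). For combined sizes `m + n <= exact_limit` the
#' p-value is exact: the permutation distribution of U is enumerated over
#' all assignments of the pooled (average) ranks to the two groups, so
#' ties are handled exactly. Larger samples use the normal approximation
#' with tie correction.
#'
#' @param x,y Independent samples (non-empty).
#' @param exact_limit Largest pooled size for exact enumeration (default 12).
#' @return One-row tibble with `statistic` (U of the first sample),
#'   `p_value`, `n_x`, `n_y`, `method`.
#' @export
#' @examples
#' mannwhitney_u(c(1, 2), c(3, 4)) # U = 0, exact two-sided p = 1/3
mannwhitney_u <- function(x, y, exact_limit = 12) {
  m <- length(x)
  n <- length(y)
  if (m == 0 || n == 0) abort("both groups must be non-empty.")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  center <- m * n / 2
  if (m + n <= exact_limit) {
    combos <- utils::combn(m + n, m)
    us <- apply(combos, 2, function(idx) sum(r[idx])) - m * (m + 1) / 2
    p <- mean(abs(us - center) >= abs(u - center) - 1e-9)
    method <- "exact"
  } else {
    tie_tab <- table(r)
    nn <- m + n
    sigma2 <- m * n / 12 * ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    z <- (u - center) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal_approx"
  }
  tibble(
    statistic = u, p_value = min(p, 1), n_x = m, n_y = n, method = method
  )
}

#' Pearson correlation with t-distribution p-value
#'
#' Product-moment correlation between two samples with the two-sided
#' p-value from the t distribution on `n - 2` degrees of freedom (wraps
#' [stats::cor.test()]). Used for stiffness versus firing-rate
#' correlations.
#'
#' @param x,y Samples of equal length (n >= 3, both with nonzero variance).
#' @return One-row tibble with `r`, `p_value`, `n`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("need paired samples with at least 3 observations.")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("zero variance in one of the samples.")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Chi-squared test of response proportions across conditions
#'
#' Pearson chi-squared test (no continuity correction) on a 2 x k table
#' of responded / not-responded counts per condition, as used to compare
#' responder fractions across indentation speeds or treatments.
#'
#' @param counts A 2 x k matrix: row 1 responded, row 2 not responded.
#' @return One-row tibble with `chisq`, `df`, `p_value`.
#' @export
#' @examples
#' chisq_proportions(matrix(c(10, 0, 0, 10), nrow = 2)) # chi-squared 20
chisq_proportions <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2) abort("`counts` must have 2 rows (responded / not).")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("zero marginal count; expected counts must be positive.")
  }
  ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
  if (any(ht$expected <= 0)) abort("expected counts must be positive.")
  tibble(
    chisq = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value
  )
}
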