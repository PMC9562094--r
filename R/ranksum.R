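#' Wilcoxon rank-sum test with exact tied-rank enumeration
#'
#' Two-sample rank-sum test used throughout the package (tree acceptance in
#' the prioritization, comparison of gene lists in the validation stage).
#' Layer and combined scores are small discrete values, so ties are the norm
#' rather than the exception; the usual exact algorithms that assume
#' tie-free data do not apply. When both samples have at most `exact_limit`
#' observations the full permutation distribution of the midrank sum is
#' computed by dynamic programming over doubled midranks (integers), which
#' is exact under arbitrary ties. Larger samples use the normal
#' approximation with tie-corrected variance and continuity correction,
#' matching [stats::wilcox.test()].
#'
#' @param x numeric vector, first sample.
#' @param y numeric vector, second sample.
#' @param alternative `"greater"` (x tends larger), `"less"`, or
#'   `"two.sided"`.
#' @param exact_limit both samples at or below this size use exact
#'   enumeration (default 12).
#' @return list with `statistic` (Mann-Whitney U of `x`), `p_value`,
#'   `method` (`"exact"` or `"normal"`), `n1`, `n2`.
#' @examples
#' rank_sum_test(c(4, 5, 6), c(1, 2, 3), alternative = "greater")$p_value
#' @export
rank_sum_test <- function(x, y, alternative = c("greater", "less", "two.sided"),
                          exact_limit = 12L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("rank_sum_test: both samples must be non-empty")
  if (anyNA(x) || anyNA(y))
    stop("rank_sum_test: NA values not allowed")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])                 # rank sum of x
  u <- w - n1 * (n1 + 1) / 2               # Mann-Whitney U

  if (n1 <= exact_limit && n2 <= exact_limit) {
    p <- ranksum_exact_p(r, n1, w, alternative)
    method <- "exact"
  } else {
    p <- ranksum_normal_p(r, n1, n2, u, alternative)
    method <- "normal"
  }
  list(statistic = u, p_value = p, method = method, n1 = n1, n2 = n2)
}

# Exact tail probability of the midrank sum under the permutation null.
# DP over doubled midranks (always integers): f[j+1, s+1] = number of
# subsets of size j with doubled rank sum s.
ranksum_exact_p <- function(r, n1, w_obs, alternative) {
  d <- as.integer(round(2 * r))            # doubled midranks
  n <- length(d)
  smax <- sum(sort(d, decreasing = TRUE)[seq_len(n1)])
  # f is (n1+1) x (smax+1); counts can exceed .Machine$integer.max for
  # n up to 24 (C(24,12) ~ 2.7e6, fine), use double for safety
  f <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  f[1L, 1L] <- 1
  for (i in seq_len(n)) {
    di <- d[i]
    jmax <- min(i, n1)
    for (j in seq(jmax, 1L)) {
      cols <- seq_len(smax + 1L - di)
      f[j + 1L, cols + di] <- f[j + 1L, cols + di] + f[j, cols]
    }
  }
  counts <- f[n1 + 1L, ]
  total <- sum(counts)
  sums <- (seq_along(counts) - 1L)          # doubled sums
  w2 <- round(2 * w_obs)
  p_ge <- sum(counts[sums >= w2]) / total
  p_le <- sum(counts[sums <= w2]) / total
  switch(alternative,
         greater   = p_ge,
         less      = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Tie-corrected normal approximation with continuity correction
# (same form as stats::wilcox.test).
ranksum_normal_p <- function(r, n1, n2, u, alternative) {
  n <- n1 + n2
  ties <- rle(sort(r))$lengths
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {                        # all observations identical
    return(switch(alternative, greater = 1, less = 1, two.sided = 1))
  }
  sd <- sqrt(sigma2)
  z_g <- (u - mu - 0.5) / sd
  z_l <- (u - mu + 0.5) / sd
  switch(alternative,
         greater   = stats::pnorm(z_g, lower.tail = FALSE),
         less      = stats::pnorm(z_l),
         two.sided = {
           z <- (u - mu - sign(u - mu) * 0.5) / sd
           min(1, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
         })
}
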