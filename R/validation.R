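#' Compare prioritized genes with the remaining genes
#'
#' One-sided Wilcoxon rank-sum test of the prioritized genes'
#' differential-expression p-values against the remaining genes in the
#' expression table (alternative: prioritized genes have smaller
#' p-values). Genes absent from the table are dropped and counted.
#'
#' @param ctgenes character vector of prioritized gene ids.
#' @param expr named numeric vector of DE p-values
#'   (see [read_expression()]).
#' @return list of class `comparison_result` with `test_name`,
#'   `statistic`, `p_value`, `n1`, `n2`, `direction`
#'   (`"ctgenes_better"` / `"other_better"` / `"none"`), `n_missing`.
#' @export
compare_vs_remaining <- function(ctgenes, expr) {
  ct <- intersect(ctgenes, names(expr))
  n_missing <- length(ctgenes) - length(ct)
  if (length(ct) < 2L)
    stop("coverage error: fewer than two prioritized genes found in the ",
         "expression table")
  x <- expr[ct]
  y <- expr[setdiff(names(expr), ct)]
  res <- rank_sum_test(x, y, alternative = "less")
  direction <- if (res$p_value < 0.05) "ctgenes_better"
  else if (rank_sum_test(x, y, alternative = "greater")$p_value < 0.05)
    "other_better" else "none"
  structure(list(test_name = "ctgenes_vs_remaining",
                 statistic = res$statistic, p_value = res$p_value,
                 n1 = res$n1, n2 = res$n2, direction = direction,
                 n_missing = n_missing),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: U = %.1f, p = %.3g (n1 = %d, n2 = %d), direction: %s\n",
              x$test_name, x$statistic, x$p_value, x$n1, x$n2, x$direction))
  invisible(x)
}

#' Empirical p-value against random gene sets
#'
#' Draws B gene sets of the same size as the prioritized list, without
#' replacement from a pool (by default the test-gene pool), and counts how
#' often a random set outperforms the prioritized genes. "Outperforms"
#' defaults to a strictly larger median `-log10 p` of DE p-values (robust
#' and invariant to monotone transforms); the mean is available as an
#' alternative summary. The empirical p-value is the outperforming
#' fraction; a zero count is reported as the bound `< 1/B`.
#'
#' @param ctgenes prioritized gene ids.
#' @param pool gene universe to sample from (must contain more genes than
#'   the prioritized set; genes absent from `expr` are ignored in
#'   summaries).
#' @param expr named numeric vector of DE p-values.
#' @param B number of random sets (default 10000).
#' @param summary per-set summary statistic, `"median"` or `"mean"`.
#' @return list with `p_empirical`, `bound` (`TRUE` when the count was 0
#'   and the value is the upper bound 1/B), `label` (printable form, e.g.
#'   `"< 1e-04"`), `n_outperforming`, `B`, `ct_summary`, and
#'   `random_summaries` (the B per-set summaries).
#' @export
empirical_pvalue_random_sets <- function(ctgenes, pool, expr, B = 10000L,
                                         summary = c("median", "mean")) {
  summary <- match.arg(summary)
  size <- length(ctgenes)
  pool <- unique(pool)
  if (length(pool) <= size)
    stop("sampling error: pool must be larger than the prioritized set")
  sfun <- if (summary == "median") stats::median else mean
  ct_vals <- -log10(expr[intersect(ctgenes, names(expr))])
  if (length(ct_vals) == 0L)
    stop("coverage error: no prioritized gene found in the expression table")
  ct_sum <- sfun(ct_vals)

  lp <- -log10(expr)
  sums <- numeric(B)
  for (b in seq_len(B)) {
    set <- pool[sample.int(length(pool), size)]
    v <- lp[intersect(set, names(expr))]
    sums[b] <- if (length(v)) sfun(v) else -Inf
  }
  n_out <- sum(sums > ct_sum)
  p <- n_out / B
  bound <- n_out == 0L
  label <- if (bound) sprintf("< %.1e", 1 / B) else format(p)
  list(p_empirical = if (bound) 1 / B else p, bound = bound, label = label,
       n_outperforming = n_out, B = B, ct_summary = ct_sum,
       random_summaries = sums)
}

#' Compare prioritized genes with a competitor gene list
#'
#' Reports both one-sided Wilcoxon rank-sum tests on the two sets' DE
#' p-values (prioritized-smaller and competitor-smaller) plus the
#' upper-tail hypergeometric probability of their overlap given a gene
#' universe.
#'
#' @param ctgenes prioritized gene ids.
#' @param competitor competitor gene ids.
#' @param expr named numeric vector of DE p-values.
#' @param universe gene universe for the overlap test (must contain the
#'   union of both sets).
#' @return list with `wilcoxon_ct_better`, `wilcoxon_competitor_better`
#'   (both `comparison_result`), `overlap` (count), and `overlap_p`
#'   (hypergeometric `P(X >= overlap)`).
#' @export
compare_vs_competitor <- function(ctgenes, competitor, expr, universe) {
  stopifnot(length(ctgenes) > 0, length(competitor) > 0)
  if (!all(c(ctgenes, competitor) %in% universe))
    stop("universe error: universe must contain both gene sets")
  x <- expr[intersect(ctgenes, names(expr))]
  y <- expr[intersect(competitor, names(expr))]
  if (length(x) == 0L || length(y) == 0L)
    stop("coverage error: a gene set has no overlap with the expression table")
  mk <- function(name, alt) {
    res <- rank_sum_test(x, y, alternative = alt)
    structure(list(test_name = name, statistic = res$statistic,
                   p_value = res$p_value, n1 = res$n1, n2 = res$n2,
                   direction = if (res$p_value < 0.05)
                     (if (alt == "less") "ctgenes_better" else "other_better")
                   else "none"),
              class = "comparison_result")
  }
  k <- length(intersect(ctgenes, competitor))
  N <- length(unique(universe))
  K <- length(unique(competitor))
  n <- length(unique(ctgenes))
  overlap_p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(wilcoxon_ct_better = mk("ctgenes_vs_competitor", "less"),
       wilcoxon_competitor_better = mk("competitor_vs_ctgenes", "greater"),
       overlap = k, overlap_p = overlap_p)
}
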