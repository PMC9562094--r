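#' Configuration for the bootstrap/permutation prioritization
#'
#' @param r number of accepted decision trees to collect (default 10000).
#' @param q number of permutation samples for the null pool
#'   (default 10000).
#' @param h top-set size (the chosen cut-off's gene count).
#' @param alpha one-sided significance level for tree acceptance
#'   (default 0.05).
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @param max_rejected_trees guard against non-convergence
#'   (default `10 * r`).
#' @param perm_mode `"layers"` shuffles each layer's scores independently
#'   across genes and recomputes the combined score, breaking the
#'   within-gene correlation between layers (the null the acceptance test
#'   needs); `"combined"` shuffles the combined score vector itself, which
#'   conserves its multiset exactly.
#' @param perm_pooling `"pooled"` runs one rank-sum test of the bootstrap
#'   top scores against all q top-sets pooled; `"per_set"` runs q tests
#'   and accepts on a strict majority.
#' @return list of validated settings.
#' @export
nprf_config <- function(r = 10000L, q = 10000L, h, alpha = 0.05, seed,
                        max_rejected_trees = 10L * r,
                        perm_mode = c("layers", "combined"),
                        perm_pooling = c("pooled", "per_set")) {
  perm_mode <- match.arg(perm_mode)
  perm_pooling <- match.arg(perm_pooling)
  stopifnot(r >= 1, q >= 1, h >= 1, alpha > 0, alpha < 1,
            !missing(seed), is.numeric(seed))
  list(r = as.integer(r), q = as.integer(q), h = as.integer(h),
       alpha = alpha, seed = as.integer(seed),
       max_rejected_trees = as.integer(max_rejected_trees),
       perm_mode = perm_mode, perm_pooling = perm_pooling)
}

#' Draw one bootstrap sample of gene indices
#'
#' Uniform with replacement, sample size equal to the training-set size.
#'
#' @param D a `gene_score_matrix`.
#' @return integer vector of gene indices of length `n`.
#' @export
draw_bootstrap <- function(D) {
  n <- length(D$genes)
  sample.int(n, n, replace = TRUE)
}

#' Draw one permutation of the training set
#'
#' The null model breaks the structure of the training set by shuffling
#' scores across gene labels. In `"layers"` mode each layer column is
#' permuted independently and the combined score recomputed (destroying
#' the within-gene agreement between layers that the signal genes carry);
#' in `"combined"` mode the combined score vector is permuted as a whole,
#' conserving its multiset.
#'
#' @param D a `gene_score_matrix`.
#' @param mode `"layers"` or `"combined"`.
#' @return numeric vector of permuted combined scores (one per gene).
#' @export
draw_permutation <- function(D, mode = c("layers", "combined")) {
  mode <- match.arg(mode)
  n <- length(D$genes)
  if (mode == "combined") {
    return(D$combined[sample.int(n)])
  }
  Sp <- D$S
  for (l in seq_len(ncol(Sp))) Sp[, l] <- Sp[sample.int(n), l]
  D$W * rowSums(Sp)
}

# Priority order of gene indices: combined desc, then layer-score sum desc,
# then gene_id ascending (deterministic tie-breaking for top-h selection).
.gene_priority_order <- function(D) {
  order(-D$combined, -rowSums(D$S), D$genes)
}

#' Top-h distinct genes of a (bootstrap) sample
#'
#' Duplicated draws collapse to one entry per gene; the h highest by
#' combined score are returned, ties broken by higher layer-score sum then
#' lexicographic gene id.
#'
#' @param D a `gene_score_matrix`.
#' @param idx integer gene indices of the sample (duplicates allowed);
#'   `NULL` means the full training set.
#' @param h top-set size.
#' @return integer vector of h gene indices in priority order, or `NULL`
#'   when the sample holds fewer than h distinct genes (the caller counts
#'   the tree as rejected).
#' @export
top_h <- function(D, idx = NULL, h) {
  ord <- attr(D, "priority_order")
  if (is.null(ord)) ord <- .gene_priority_order(D)
  if (is.null(idx)) {
    if (h > length(D$genes)) stop("h exceeds the number of genes")
    return(ord[seq_len(h)])
  }
  present <- logical(length(D$genes))
  present[idx] <- TRUE
  cand <- ord[present[ord]]
  if (length(cand) < h) return(NULL)
  cand[seq_len(h)]
}

#' Tree acceptance test
#'
#' One-sided Wilcoxon rank-sum test of the bootstrap top scores against
#' the permutation-null top scores; the tree is accepted only when the
#' bootstrap scores are significantly distributed higher (`p < alpha`).
#' With every score identical the p-value is 1 and the tree is rejected.
#'
#' @param boot_top_scores combined scores of the bootstrap top set.
#' @param perm_top_scores pooled combined scores of the permutation top
#'   sets.
#' @param alpha significance level.
#' @return list with `accept` (logical) and `p_value`.
#' @export
tree_acceptance_test <- function(boot_top_scores, perm_top_scores,
                                 alpha = 0.05) {
  res <- rank_sum_test(boot_top_scores, perm_top_scores,
                       alternative = "greater")
  list(accept = res$p_value < alpha, p_value = res$p_value)
}

#' Run the bootstrap/permutation prioritization
#'
#' The "decision tree" of this forest is an accepted bootstrap top set:
#' (1) draw a bootstrap sample of the test genes and take its top h by
#' combined score; (2) build a permutation null pool once from q shuffled
#' copies of the training set, taking each copy's top h; (3) accept the
#' tree only if its scores are significantly higher than the null pool by
#' a one-sided rank-sum test, otherwise discard and redraw; (4) repeat
#' until r trees are accepted and tally one vote per gene per tree.
#'
#' @param D a `gene_score_matrix` (the test genes).
#' @param cfg configuration from [nprf_config()].
#' @return object of class `nprf_result`: list with `tally` (named vote
#'   counts, all genes), `trees_accepted`, `trees_rejected`,
#'   `probabilities` (data frame `gene_id count probability combined`,
#'   zero-count genes removed, sorted), `drop_index`, `acceptance_rate`,
#'   `config`.
#' @export
run_nprf <- function(D, cfg) {
  stopifnot(inherits(D, "gene_score_matrix"))
  n <- length(D$genes)
  if (cfg$h > n) stop("h exceeds the training-set size")
  set.seed(cfg$seed)
  attr(D, "priority_order") <- .gene_priority_order(D)

  # permutation null pool, built once: q top-h score sets
  perm_sets <- matrix(0, nrow = cfg$q, ncol = cfg$h)
  for (t in seq_len(cfg$q)) {
    pc <- draw_permutation(D, mode = cfg$perm_mode)
    perm_sets[t, ] <- sort(pc, decreasing = TRUE)[seq_len(cfg$h)]
  }
  perm_pool <- as.vector(t(perm_sets))

  counts <- integer(n)
  accepted <- 0L
  rejected <- 0L
  while (accepted < cfg$r) {
    if (rejected > cfg$max_rejected_trees)
      stop("convergence error: ", rejected, " trees rejected before ",
           accepted, " of ", cfg$r, " were accepted (acceptance rate ",
           signif(accepted / (accepted + rejected), 3), ")")
    idx <- draw_bootstrap(D)
    top <- top_h(D, idx, cfg$h)
    if (is.null(top)) { rejected <- rejected + 1L; next }
    ok <- if (cfg$perm_pooling == "pooled") {
      tree_acceptance_test(D$combined[top], perm_pool, cfg$alpha)$accept
    } else {
      sig <- vapply(seq_len(cfg$q), function(t)
        ranksum_normal_p(rank(c(D$combined[top], perm_sets[t, ])),
                         cfg$h, cfg$h,
                         sum(rank(c(D$combined[top], perm_sets[t, ]))[seq_len(cfg$h)]) -
                           cfg$h * (cfg$h + 1) / 2,
                         "greater") < cfg$alpha, logical(1))
      mean(sig) > 0.5
    }
    if (!ok) { rejected <- rejected + 1L; next }
    counts[top] <- counts[top] + 1L
    accepted <- accepted + 1L
  }

  tally <- stats::setNames(counts, D$genes)
  nz <- which(counts > 0L)
  ordp <- nz[order(-counts[nz], -D$combined[nz], D$genes[nz])]
  probs <- data.frame(gene_id = D$genes[ordp],
                      count = counts[ordp],
                      probability = counts[ordp] / cfg$r,
                      combined = unname(D$combined[ordp]),
                      stringsAsFactors = FALSE)
  drop_idx <- if (nrow(probs) >= 2L)
    detect_probability_drop(probs$probability) else NA_integer_
  structure(list(tally = tally, trees_accepted = accepted,
                 trees_rejected = rejected, probabilities = probs,
                 drop_index = drop_idx,
                 acceptance_rate = accepted / (accepted + rejected),
                 config = cfg),
            class = "nprf_result")
}

#' @export
print.nprf_result <- function(x, ...) {
  cat(sprintf("prioritization over %d accepted trees (%d rejected, acceptance rate %.3f)\n",
              x$trees_accepted, x$trees_rejected, x$acceptance_rate))
  cat(sprintf("%d genes with nonzero votes; probability drop after rank %s\n",
              nrow(x$probabilities), x$drop_index))
  invisible(x)
}

#' Position of the largest consecutive drop in gene probabilities
#'
#' On the descending probability list, returns the rank k maximizing
#' `p[k] - p[k+1]` (the first such k on ties) — the natural boundary of
#' the prioritized set.
#'
#' @param probs numeric vector of gene probabilities sorted descending.
#' @return integer rank after which the largest drop occurs.
#' @export
detect_probability_drop <- function(probs) {
  if (length(probs) < 2L)
    stop("undefined-drop error: need at least two probabilities")
  drops <- probs[-length(probs)] - probs[-1L]
  # first index on ties, robust to floating-point noise
  which(drops >= max(drops) - 1e-9)[1L]
}

#' Final prioritized gene list
#'
#' The top h genes by vote count, ties broken by higher combined score
#' then lexicographic gene id. A consistency flag reports whether h
#' coincides with the largest probability drop.
#'
#' @param result an `nprf_result`.
#' @param h number of genes to select (defaults to the run's h).
#' @return data frame `rank gene_id count probability combined` with
#'   attribute `drop_consistent`.
#' @export
finalize_ctgenes <- function(result, h = result$config$h) {
  stopifnot(inherits(result, "nprf_result"))
  probs <- result$probabilities
  if (nrow(probs) < h)
    stop("shortfall error: only ", nrow(probs),
         " genes with nonzero counts, need ", h)
  out <- probs[seq_len(h), , drop = FALSE]
  out <- cbind(rank = seq_len(h), out)
  rownames(out) <- NULL
  attr(out, "drop_consistent") <-
    !is.na(result$drop_index) && result$drop_index == h
  out
}
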