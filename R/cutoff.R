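#' Core-gene selection criteria
#'
#' Core genes are the small curated set of high-confidence cold-tolerance
#' genes used only to locate the cut-off score. A test gene qualifies under
#' any of three scenarios: (1) curated flag `most_significant`; (2) the
#' frequency/rank/score predicate — reported on strictly more than
#' `min_layers_reported` layers, combined score within the top
#' `top_rank_fraction` of the test genes, and scoring strictly above
#' `min_layer_score` on every reported layer excluding homologs; (3)
#' curated flag `qpcr_validated` (transcriptome measurement confirmed by
#' q-PCR at p below `qpcr_p_threshold` — the threshold is recorded here,
#' the judgement itself is curation input).
#'
#' @param top_rank_fraction top fraction of test genes by combined score
#'   (default 0.005).
#' @param min_layers_reported strict lower bound on reported layers
#'   (default 3).
#' @param min_layer_score strict lower bound per non-homolog layer
#'   (default 3).
#' @param qpcr_p_threshold q-PCR significance threshold (default 1e-4).
#' @return list of criteria.
#' @export
core_gene_criteria <- function(top_rank_fraction = 0.005,
                               min_layers_reported = 3L,
                               min_layer_score = 3,
                               qpcr_p_threshold = 1e-4) {
  stopifnot(top_rank_fraction > 0, top_rank_fraction < 1,
            min_layers_reported > 0, min_layer_score > 0,
            qpcr_p_threshold > 0)
  list(top_rank_fraction = top_rank_fraction,
       min_layers_reported = as.integer(min_layers_reported),
       min_layer_score = min_layer_score,
       qpcr_p_threshold = qpcr_p_threshold)
}

#' Select core genes from a score matrix
#'
#' @param matrix a `gene_score_matrix` (see [build_score_matrix()]).
#' @param flags optional data frame with columns `gene_id`,
#'   `most_significant`, `qpcr_validated` (logical curated flags).
#' @param criteria from [core_gene_criteria()].
#' @return character vector of core gene ids (deterministic order).
#' @export
select_core_genes <- function(matrix, flags = NULL,
                              criteria = core_gene_criteria()) {
  stopifnot(inherits(matrix, "gene_score_matrix"))
  genes <- matrix$genes
  sel <- rep(FALSE, length(genes))
  names(sel) <- genes

  if (!is.null(flags)) {
    f1 <- flags$gene_id[isTRUE_vec(flags$most_significant)]
    f3 <- flags$gene_id[isTRUE_vec(flags$qpcr_validated)]
    sel[genes %in% c(f1, f3)] <- TRUE
  }

  # scenario 2: > min_layers layers, top fraction by combined score,
  # > min_layer_score on each reported non-homolog layer
  n_layers <- rowSums(matrix$S > 0)
  k_top <- max(1L, ceiling(criteria$top_rank_fraction * length(genes)))
  rank_cut <- sort(matrix$combined, decreasing = TRUE)[k_top]
  non_hom <- matrix$S[, setdiff(matrix$layers, "homologs"), drop = FALSE]
  layer_ok <- apply(non_hom, 1L, function(s) {
    rep_l <- s[s > 0]
    length(rep_l) > 0 && all(rep_l > criteria$min_layer_score)
  })
  s2 <- n_layers > criteria$min_layers_reported &
    matrix$combined >= rank_cut & layer_ok
  sel[s2] <- TRUE

  out <- genes[sel]
  if (length(out) == 0L)
    stop("no-core-genes error: no gene satisfies any core scenario")
  sort(out)
}

isTRUE_vec <- function(x) if (is.null(x)) logical(0) else !is.na(x) & x

#' Locate the cut-off bin between core and test score distributions
#'
#' Candidate integer cut-offs c are those where at least `tau_core` of the
#' core genes score at or above c while at most `tau_test` of the test
#' genes do — the region where the left-skewed core distribution has
#' separated from the right-skewed test distribution. The candidates form
#' the cut-off bin (lower bound, middle point, upper bound); the upper
#' bound is the chosen threshold and `h` counts the test genes with
#' combined score at or above it (closed tail).
#'
#' @param core_scores combined scores of the core genes.
#' @param test_scores combined scores of all test genes.
#' @param tau_core minimum core fraction retained at the cut-off
#'   (default 0.9).
#' @param tau_test maximum test fraction retained (default 0.01).
#' @return object of class `cutoff_bin`: list with `lower`, `middle`,
#'   `upper`, `chosen`, `h`, `candidates`.
#' @export
determine_cutoff <- function(core_scores, test_scores,
                             tau_core = 0.9, tau_test = 0.01) {
  stopifnot(length(core_scores) > 0, length(test_scores) > 0)
  cmax <- ceiling(max(core_scores, test_scores))
  cand <- integer(0)
  for (c in 0:cmax) {
    f_core <- mean(core_scores >= c)
    f_test <- mean(test_scores >= c)
    if (f_core >= tau_core && f_test <= tau_test) cand <- c(cand, c)
  }
  if (length(cand) == 0L)
    stop("separation-failure error: no integer cut-off separates the ",
         "core and test distributions (core median ",
         stats::median(core_scores), ", test median ",
         stats::median(test_scores), ")")
  lower <- min(cand)
  upper <- max(cand)
  middle <- cand[ceiling(length(cand) / 2)]
  h <- sum(test_scores >= upper)
  if (h < 1)
    stop("separation-failure error: chosen cut-off ", upper,
         " retains no test gene (h = 0)")
  structure(list(lower = lower, middle = middle, upper = upper,
                 chosen = upper, h = h, candidates = cand),
            class = "cutoff_bin")
}

#' @export
print.cutoff_bin <- function(x, ...) {
  cat(sprintf("cut-off bin [%d, %d, %d], chosen = %d, h = %d\n",
              x$lower, x$middle, x$upper, x$chosen, x$h))
  invisible(x)
}

#' Sensitivity of the gene count and enrichment yield to the cut-off
#'
#' For each of the bin's lower / middle / upper cut-offs, reports the
#' number of test genes retained and, when an enrichment function is
#' given, the number of significantly enriched pathways found for that
#' gene set.
#'
#' @param matrix a `gene_score_matrix`.
#' @param bin a `cutoff_bin`.
#' @param enrich_fn optional `function(genes) -> integer` returning the
#'   enriched-pathway count for a gene set.
#' @return data frame with columns `cutoff`, `h`, `n_enriched_pathways`
#'   (NA when `enrich_fn` is absent).
#' @export
compare_threshold_sensitivity <- function(matrix, bin, enrich_fn = NULL) {
  stopifnot(inherits(matrix, "gene_score_matrix"), inherits(bin, "cutoff_bin"))
  cuts <- c(bin$lower, bin$middle, bin$upper)
  h <- vapply(cuts, function(c) sum(matrix$combined >= c), integer(1))
  n_enr <- rep(NA_integer_, 3L)
  if (!is.null(enrich_fn)) {
    for (i in seq_along(cuts)) {
      genes <- matrix$genes[matrix$combined >= cuts[i]]
      n_enr[i] <- enrich_fn(genes)
    }
  }
  data.frame(cutoff = cuts, h = h, n_enriched_pathways = n_enr)
}
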