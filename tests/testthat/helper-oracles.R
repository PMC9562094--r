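# Independent brute-force oracles and small fixture builders.
# Oracles are deliberately naive and share no code with the implementation.

# Exact one-sided rank-sum p by full enumeration of n1-subsets (midranks).
brute_ranksum_greater <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(i) sum(r[i]))
  mean(w_all >= w_obs - 1e-12)
}

# Upper-tail hypergeometric by direct mass summation with choose().
brute_hyper_upper <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Dual-tail cut-off rule re-derived with an exhaustive scan (independent
# of determine_cutoff's loop structure).
brute_cutoff_candidates <- function(core, test, tau_core, tau_test) {
  Filter(function(c) {
    sum(core >= c) / length(core) >= tau_core &&
      sum(test >= c) / length(test) <= tau_test
  }, 0:ceiling(max(c(core, test))))
}

# Node degrees from a pairwise-intersection scan over gene sets.
brute_crosstalk_degrees <- function(sets, min_shared = 1L) {
  m <- length(sets)
  deg <- stats::setNames(integer(m), names(sets))
  if (m < 2) return(deg)
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    if (length(intersect(sets[[i]], sets[[j]])) >= min_shared) {
      deg[i] <- deg[i] + 1L
      deg[j] <- deg[j] + 1L
    }
  }
  deg
}

# Brute-force windowed marker-to-gene scan.
brute_map_marker <- function(chrom, start, end, ann, window) {
  hits <- character(0)
  for (i in seq_len(nrow(ann))) {
    if (ann$chrom[i] != chrom) next
    if (max(start, ann$start[i] - window) <= min(end, ann$end[i] + window))
      hits <- c(hits, ann$gene_id[i])
  }
  sort(hits)
}

# Small gene-score-matrix fixture. combined defaults to W * rowSums(S).
make_gsm <- function(S, W = rep(1, nrow(S)), duration_class = "short") {
  if (is.null(rownames(S))) rownames(S) <- sprintf("g%03d", seq_len(nrow(S)))
  if (is.null(colnames(S)))
    colnames(S) <- evidence_layers()[seq_len(ncol(S))]
  onoprio:::new_gene_score_matrix(duration_class, S, W, W * rowSums(S))
}

# Matrix with n_signal genes strong on 4 layers and the rest weak.
planted_gsm <- function(n_genes, n_signal, signal = 2.25, noise = 0.25,
                        seed = 1) {
  set.seed(seed)
  S <- matrix(0, n_genes, 5,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              evidence_layers()))
  S[seq_len(n_signal), 1:4] <- pmin(pmax(
    stats::rnorm(n_signal * 4, signal, 0.05), 0), 10)
  for (i in (n_signal + 1):n_genes) {
    l <- sample.int(4, 1)
    S[i, l] <- pmin(stats::rgamma(1, 2, scale = noise), 10)
  }
  make_gsm(S)
}

# Random additive (unrooted) tree plus its exact path-length matrix.
random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 2)
  list(tree = tr, D = cophenetic(tr))
}
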