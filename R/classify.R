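#' Remove uninformative markers from a genotype panel
#'
#' Markers where every genotyped sample carries the same dosage are
#' monomorphic and carry no classification signal; they are removed, and
#' genes left without any marker are dropped from the marker-to-gene map.
#'
#' @param G genotype list as returned by [read_genotypes()] (`dosage`
#'   markers x samples, `marker_gene`), or a bare dosage matrix.
#' @return genotype list with informative markers only plus attributes
#'   `n_markers_removed` and `n_genes_retained`.
#' @export
filter_informative_snps <- function(G) {
  if (is.matrix(G)) G <- list(dosage = G, marker_gene = stats::setNames(
    rep(NA_character_, nrow(G)), rownames(G)))
  dos <- G$dosage
  poly <- apply(dos, 1L, function(g) {
    g <- g[!is.na(g)]
    length(unique(g)) > 1L
  })
  if (!any(poly))
    stop("uninformative-panel error: no polymorphic marker survives")
  out <- list(dosage = dos[poly, , drop = FALSE],
              marker_gene = G$marker_gene[poly])
  genes <- unique(out$marker_gene[!is.na(out$marker_gene)])
  attr(out, "n_markers_removed") <- sum(!poly)
  attr(out, "n_genes_retained") <- length(genes)
  out
}

#' Identity-by-state dissimilarity between samples
#'
#' Allele-sharing distance on 0/1/2 dosages: per locus the similarity is
#' `1 - |g_i - g_j| / 2`; the dissimilarity of a sample pair is one minus
#' the mean similarity over their pairwise non-missing loci. Values lie in
#' `[0, 1]` with a zero diagonal.
#'
#' @param G genotype list (see [read_genotypes()]) or a markers x samples
#'   dosage matrix.
#' @return symmetric samples x samples numeric matrix.
#' @export
ibs_distance <- function(G) {
  dos <- if (is.list(G)) G$dosage else G
  ns <- ncol(dos)
  if (ns < 2L) stop("need at least two samples")
  ids <- colnames(dos)
  D <- matrix(0, ns, ns, dimnames = list(ids, ids))
  for (i in seq_len(ns - 1L)) for (j in seq((i + 1L), ns)) {
    gi <- dos[, i]; gj <- dos[, j]
    ok <- !is.na(gi) & !is.na(gj)
    if (!any(ok))
      stop("missingness error: samples '", ids[i], "' and '", ids[j],
           "' share no genotyped locus")
    d <- mean(abs(gi[ok] - gj[ok]) / 2)
    D[i, j] <- d; D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomeration minimizing
#' `Q(i,j) = (m - 2) d(i,j) - R_i - R_j` (R = row sums over active
#' nodes), with branch lengths from the usual split formula. Ties on Q are
#' broken by the lexicographically smallest node-label pair, so the result
#' is deterministic and invariant to input order. A negative branch length
#' is clamped to zero with the deficit moved to its sister branch (the
#' pair's total length is conserved) and the tree flagged via attribute
#' `negative_branches`.
#'
#' @param D symmetric distance matrix with sample ids as dimnames
#'   (at least 3 samples, non-negative, zero diagonal).
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || !isSymmetric(unname(D)))
    stop("matrix error: distances must be a symmetric matrix")
  if (any(D < 0)) stop("matrix error: negative distances")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 samples")
  tips <- rownames(D)
  if (is.null(tips)) tips <- paste0("t", seq_len(n))

  # active nodes carry (phylo id, label for tie-breaking)
  ids <- seq_len(n)                 # phylo node numbers
  labels <- tips
  d <- D
  n_internal <- n - 2L
  next_internal <- n + 2L           # n+1 reserved for the root (final join)
  edges <- matrix(0L, 0L, 2L); lens <- numeric(0)
  neg_flag <- FALSE
  m <- n

  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    lens <<- c(lens, len)
  }

  while (m > 3L) {
    R <- rowSums(d)
    Qbest <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(m - 1L)) for (j in seq((i + 1L), m)) {
      Q <- (m - 2) * d[i, j] - R[i] - R[j]
      if (Q < Qbest - 1e-12) { Qbest <- Q; bi <- i; bj <- j }
      else if (abs(Q - Qbest) <= 1e-12) {
        # lexicographic pair tie-break on sorted label pairs
        cur <- sort(c(labels[i], labels[j]))
        best <- sort(c(labels[bi], labels[bj]))
        if (cur[1] < best[1] || (cur[1] == best[1] && cur[2] < best[2])) {
          bi <- i; bj <- j
        }
      }
    }
    li <- d[bi, bj] / 2 + (R[bi] - R[bj]) / (2 * (m - 2))
    lj <- d[bi, bj] - li
    if (li < 0) { lj <- d[bi, bj]; li <- 0; neg_flag <- TRUE }
    if (lj < 0) { li <- d[bi, bj]; lj <- 0; neg_flag <- TRUE }
    u <- next_internal; next_internal <- next_internal + 1L
    add_edge(u, ids[bi], li)
    add_edge(u, ids[bj], lj)
    du <- (d[bi, ] + d[bj, ] - d[bi, bj]) / 2
    keep <- setdiff(seq_len(m), c(bi, bj))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    ids <- c(ids[keep], u)
    labels <- c(labels[keep], paste0("(", paste(sort(c(labels[bi], labels[bj])),
                                                collapse = ","), ")"))
    dimnames(d) <- NULL
    m <- m - 1L
  }

  # final three nodes join at the root (node n+1)
  root <- n + 1L
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  for (v in list(c(1, la), c(2, lb), c(3, lc))) {
    len <- v[2]
    if (len < 0) { len <- 0; neg_flag <- TRUE }
    add_edge(root, ids[v[1]], len)
  }

  tr <- structure(list(edge = edges, edge.length = lens,
                       tip.label = tips, Nnode = n_internal),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "negative_branches") <- neg_flag
  tr
}

#' Best label-separating bipartition of a tree
#'
#' Every edge of an unrooted tree splits the samples into two blocks; this
#' scans all edges and returns the split most concordant with a two-class
#' phenotype labelling. Concordance is the agreement fraction maximized
#' over the two block-to-class assignments; samples labelled `"unknown"`
#' or `NA` are excluded from scoring.
#'
#' @param tree an `ape::phylo` with tip labels matching the sample ids.
#' @param labels named character vector sample -> class (exactly two
#'   distinct known classes required).
#' @return list with `concordance` (fraction), `edge` (index into
#'   `tree$edge`), `block1`, `block2` (tip-id character vectors), and
#'   `n_scored`.
#' @export
bipartition_concordance <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"))
  lab <- labels[tree$tip.label]
  names(lab) <- tree$tip.label
  known <- !is.na(lab) & lab != "unknown"
  classes <- unique(lab[known])
  if (length(classes) < 2L)
    stop("degenerate-label error: need two distinct known classes")
  if (length(classes) > 2L)
    stop("degenerate-label error: more than two classes supplied")
  ntips <- length(tree$tip.label)

  # tips below each node, via one postorder pass
  below <- vector("list", ntips + tree$Nnode)
  for (i in seq_len(ntips)) below[[i]] <- i
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }

  best <- list(concordance = -1)
  n_scored <- sum(known)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    in_block <- seq_len(ntips) %in% below[[ch]]
    a <- lab[in_block & known]; b <- lab[!in_block & known]
    agree1 <- (sum(a == classes[1]) + sum(b == classes[2])) / n_scored
    agree2 <- (sum(a == classes[2]) + sum(b == classes[1])) / n_scored
    conc <- max(agree1, agree2)
    if (conc > best$concordance) {
      best <- list(concordance = conc, edge = e,
                   block1 = tree$tip.label[in_block],
                   block2 = tree$tip.label[!in_block],
                   n_scored = n_scored)
    }
  }
  best
}

#' Genotype-based sample classification in one call
#'
#' Filters uninformative markers, computes the identity-by-state distance
#' matrix, builds the neighbor-joining tree, and scores the best
#' bipartition against phenotype labels.
#'
#' @param G genotype list (see [read_genotypes()]).
#' @param labels named character vector sample -> class.
#' @return list with `genotypes` (filtered), `distance`, `tree`,
#'   `concordance` (from [bipartition_concordance()]).
#' @export
classify_samples <- function(G, labels) {
  Gf <- filter_informative_snps(G)
  D <- ibs_distance(Gf)
  tree <- neighbor_joining(D)
  conc <- bipartition_concordance(tree, labels)
  list(genotypes = Gf, distance = D, tree = tree, concordance = conc)
}
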