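#' Hypergeometric gene-set enrichment with Bonferroni correction
#'
#' Terms outside the `[min_size, max_size]` gene-count window are excluded
#' before testing (to avoid overly limited or overly broad pathways); for
#' each surviving term the upper-tail hypergeometric probability of the
#' observed query overlap is computed and Bonferroni-adjusted over the
#' number of tested terms.
#'
#' @param query gene set of interest (must be contained in `universe`).
#' @param terms named list of term gene sets (see [read_gmt()]).
#' @param universe background gene set.
#' @param min_size,max_size term-size filter (defaults 5 and 2500),
#'   applied to the annotation's raw term sizes; overlap counts are then
#'   computed on the universe restriction.
#' @param alpha significance level on the adjusted p-value
#'   (default 0.05).
#' @return data frame of class `enrichment_result`, sorted by adjusted
#'   p-value: `term_id term_name k K n N p p_adj significant`, with the
#'   query-overlap gene sets in attribute `overlap_genes`.
#' @export
enrich <- function(query, terms, universe, min_size = 5L, max_size = 2500L,
                   alpha = 0.05) {
  query <- unique(query); universe <- unique(universe)
  if (length(universe) == 0L || length(query) == 0L)
    stop("input error: query and universe must be non-empty")
  if (!all(query %in% universe))
    stop("input error: query must be a subset of the universe")
  # size filter on the annotation as provided; K on the universe restriction
  sizes <- lengths(lapply(terms, unique))
  keep <- sizes >= min_size & sizes <= max_size
  term_genes <- lapply(terms[keep], function(g) intersect(unique(g), universe))
  T_tested <- length(term_genes)
  N <- length(universe); n <- length(query)
  if (T_tested == 0L) {
    out <- data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), p_adj = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
    attr(out, "overlap_genes") <- list()
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  overlaps <- lapply(term_genes, intersect, query)
  k <- lengths(overlaps)
  K <- lengths(term_genes)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_adj <- pmin(1, p * T_tested)
  nm <- vapply(names(term_genes), function(id) {
    tn <- attr(terms[[id]], "term_name")
    if (is.null(tn)) id else tn
  }, character(1))
  out <- data.frame(term_id = names(term_genes), term_name = unname(nm),
                    k = unname(k), K = unname(K), n = n, N = N,
                    p = unname(p), p_adj = unname(p_adj),
                    significant = unname(p_adj < alpha),
                    stringsAsFactors = FALSE)
  ord <- order(out$p_adj, out$p, out$term_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "overlap_genes") <- overlaps[out$term_id]
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Build the pathway-crosstalk network from enriched terms
#'
#' Nodes are the significantly enriched pathways (node size
#' `-log10 p_adj`, annotated with their duration class); an undirected
#' edge joins two pathways sharing at least `min_shared` query genes,
#' weighted by the shared-gene count. Edge overlap is counted among the
#' query genes by default (the prioritized genes driving the enrichment);
#' `overlap = "term"` counts term-wide shared genes instead. Degree means
#' and medians are summarized per duration class on the merged network.
#'
#' @param results an `enrichment_result` (or a named list of them, one per
#'   duration class; names are used as the classes).
#' @param classes optional named character vector term_id -> duration
#'   class (ignored when `results` is a named list).
#' @param min_shared minimum shared genes for an edge (default 1).
#' @param overlap `"query"` or `"term"`.
#' @return list of class `crosstalk_network`: `graph` (igraph, undirected,
#'   vertex attributes `duration_class`, `node_size`; edge attribute
#'   `weight`), `nodes`, `edges` (data frames), `degree_summary` (per
#'   class: n, mean, median).
#' @export
build_crosstalk <- function(results, classes = NULL, min_shared = 1L,
                            overlap = c("query", "term")) {
  overlap <- match.arg(overlap)
  if (inherits(results, "enrichment_result")) {
    results <- list(all = results)
  }
  nodes <- list(); gene_sets <- list()
  for (cls in names(results)) {
    res <- results[[cls]]
    sig <- res[res$significant, , drop = FALSE]
    if (nrow(sig) == 0L) next
    ov <- attr(res, "overlap_genes")
    for (i in seq_len(nrow(sig))) {
      id <- sig$term_id[i]
      node_cls <- if (!is.null(classes)) unname(classes[id]) else cls
      key <- paste(id, node_cls, sep = "|")
      nodes[[key]] <- data.frame(term_id = id, duration_class = node_cls,
                                 node_size = -log10(max(sig$p_adj[i], 1e-300)),
                                 stringsAsFactors = FALSE)
      gene_sets[[key]] <- ov[[id]]
    }
  }
  if (length(nodes) == 0L)
    stop("input error: no significant term to build a network from")
  node_df <- do.call(rbind, nodes)
  node_df <- node_df[order(node_df$term_id, node_df$duration_class), , drop = FALSE]
  rownames(node_df) <- NULL
  keys <- paste(node_df$term_id, node_df$duration_class, sep = "|")
  sets <- gene_sets[keys]

  m <- length(keys)
  ea <- character(0); eb <- character(0); ew <- integer(0)
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) for (j in seq((i + 1L), m)) {
      w <- length(intersect(sets[[i]], sets[[j]]))
      if (w >= min_shared) {
        ea <- c(ea, keys[i]); eb <- c(eb, keys[j]); ew <- c(ew, w)
      }
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, m, name = keys,
                            term_id = node_df$term_id,
                            duration_class = node_df$duration_class,
                            node_size = node_df$node_size)
  if (length(ea))
    g <- igraph::add_edges(g, rbind(ea, eb), weight = ew)
  deg <- igraph::degree(g)
  degree_summary <- do.call(rbind, lapply(split(deg, node_df$duration_class),
    function(d) data.frame(n = length(d), mean_degree = mean(d),
                           median_degree = stats::median(d))))
  degree_summary <- cbind(duration_class = rownames(degree_summary),
                          degree_summary)
  rownames(degree_summary) <- NULL
  edges <- data.frame(term_a = ea, term_b = eb, weight = ew,
                      stringsAsFactors = FALSE)
  structure(list(graph = g, nodes = cbind(node_df, degree = unname(deg)),
                 edges = edges, degree_summary = degree_summary),
            class = "crosstalk_network")
}

#' @export
print.crosstalk_network <- function(x, ...) {
  cat(sprintf("pathway crosstalk network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  print(x$degree_summary)
  invisible(x)
}

#' Write a crosstalk network to GraphML and an edge-list TSV
#'
#' @param net a `crosstalk_network`.
#' @param graphml_path,edges_path output paths (either may be `NULL` to
#'   skip).
#' @export
write_crosstalk <- function(net, graphml_path = NULL, edges_path = NULL) {
  stopifnot(inherits(net, "crosstalk_network"))
  if (!is.null(graphml_path))
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  if (!is.null(edges_path))
    utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(net)
}
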