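#' Default pipeline configuration
#'
#' Central place for every stage's tunable parameters. Either a
#' `synthetic` block (arguments to [synthetic_config()]) or an `inputs`
#' block of file paths (`evidence`, optional `annotations`, `expression`,
#' `genotypes`, `phenotypes`, `gmt`, optional `core_flags`) must be
#' supplied to [run_pipeline()].
#'
#' @param seed integer seed used for every stochastic stage.
#' @param out_dir output directory.
#' @return nested list of defaults, override fields as needed.
#' @export
pipeline_config <- function(seed, out_dir = "onoprio_run") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    synthetic = NULL,
    inputs = NULL,
    scoring = list(weights = c(short = 1, mid = 1, long = 1),
                   window_bp = 20000, aggregate = "max"),
    cutoff = list(tau_core = 0.9, tau_test = 0.01),
    nprf = list(r = 1000L, q = 1000L, alpha = 0.05, h = NULL,
                perm_mode = "layers", perm_pooling = "pooled"),
    validation = list(B = 1000L, summary = "median"),
    enrichment = list(min_size = 5L, max_size = 2500L, alpha = 0.05),
    crosstalk = list(min_shared = 1L),
    classify = list(enabled = TRUE)
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline aborted at stage '", name, "': ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes scoring, cut-off determination, bootstrap/permutation
#' prioritization, expression-based validation, enrichment, crosstalk and
#' genotype classification in order, writing each stage's outputs to
#' `cfg$out_dir` before the next stage starts, and returns (and writes) a
#' machine-readable run report. Reruns with an identical configuration
#' are byte-identical.
#'
#' @param cfg configuration list from [pipeline_config()], with either
#'   `cfg$synthetic` (a [synthetic_config()]) or `cfg$inputs` (file
#'   paths) populated.
#' @return the run report (invisible), also written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = cfg[setdiff(names(cfg), "synthetic")],
                 seed = cfg$seed)

  truth <- NULL
  if (!is.null(cfg$synthetic)) {
    syn <- cfg$synthetic
    ev <- gen_evidence(syn)
    records <- ev$records; truth <- ev$truth
    expr <- gen_expression(syn, truth)
    gt <- gen_genotypes(syn, truth)
    genotypes <- gt$genotypes; phenotypes <- gt$labels
    terms <- gen_annotations(syn, truth)
    annotations <- NULL; flags <- NULL
    report$synthetic <- list(n_genes = syn$n_genes, n_signal = syn$n_signal,
                             seed = syn$seed)
  } else if (!is.null(cfg$inputs)) {
    inp <- cfg$inputs
    records <- read_evidence(inp$evidence)
    annotations <- if (!is.null(inp$annotations)) read_annotations(inp$annotations)
    expr <- if (!is.null(inp$expression)) read_expression(inp$expression)
    genotypes <- if (!is.null(inp$genotypes)) read_genotypes(inp$genotypes)
    phenotypes <- if (!is.null(inp$phenotypes)) read_phenotypes(inp$phenotypes)
    terms <- if (!is.null(inp$gmt)) read_gmt(inp$gmt)
    flags <- if (!is.null(inp$core_flags))
      utils::read.delim(inp$core_flags, stringsAsFactors = FALSE)
  } else stop("input error: provide cfg$synthetic or cfg$inputs")

  # -- scoring ---------------------------------------------------------
  matrices <- .stage("scoring", {
    rec <- filter_evidence(records)
    rec <- score_evidence(rec)
    ms <- build_score_matrix(rec, annotations = annotations,
                             weights = cfg$scoring$weights,
                             window_bp = cfg$scoring$window_bp,
                             aggregate = cfg$scoring$aggregate)
    for (dc in names(ms))
      write_score_matrix(ms[[dc]], file.path(cfg$out_dir,
                                             paste0("scores_", dc, ".tsv")))
    ms
  })

  results <- list()
  enr_by_class <- list()
  for (dc in names(matrices)) {
    M <- matrices[[dc]]
    res <- list(n_test_genes = length(M$genes))

    bin <- .stage(paste0("cutoff[", dc, "]"), {
      core <- select_core_genes(M, flags = flags)
      determine_cutoff(M$combined[core], M$combined,
                       tau_core = cfg$cutoff$tau_core,
                       tau_test = cfg$cutoff$tau_test)
    })
    res$cutoff <- list(lower = bin$lower, middle = bin$middle,
                       upper = bin$upper, chosen = bin$chosen, h = bin$h)

    h <- if (!is.null(cfg$nprf$h)) cfg$nprf$h else bin$h
    nprf_res <- .stage(paste0("prioritize[", dc, "]"), {
      ncfg <- nprf_config(r = cfg$nprf$r, q = cfg$nprf$q, h = h,
                          alpha = cfg$nprf$alpha,
                          seed = cfg$seed + match(dc, c("short", "mid", "long")),
                          perm_mode = cfg$nprf$perm_mode,
                          perm_pooling = cfg$nprf$perm_pooling)
      run_nprf(M, ncfg)
    })
    ct <- finalize_ctgenes(nprf_res)
    utils::write.table(ct, file.path(cfg$out_dir, paste0("ctgenes_", dc, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$nprf <- list(h = h, acceptance_rate = nprf_res$acceptance_rate,
                     drop_index = nprf_res$drop_index,
                     drop_consistent = attr(ct, "drop_consistent"),
                     ctgenes = ct$gene_id)
    if (!is.null(truth))
      res$planted_recovery <- setequal(ct$gene_id, truth)

    if (!is.null(expr)) {
      res$validation <- .stage(paste0("validate[", dc, "]"), {
        set.seed(cfg$seed + 100L + match(dc, c("short", "mid", "long")))
        vr <- compare_vs_remaining(ct$gene_id, expr)
        emp <- empirical_pvalue_random_sets(ct$gene_id, M$genes, expr,
                                            B = cfg$validation$B,
                                            summary = cfg$validation$summary)
        list(vs_remaining_p = vr$p_value, direction = vr$direction,
             empirical_p = emp$p_empirical, empirical_label = emp$label)
      })
    }

    if (!is.null(terms)) {
      enr <- .stage(paste0("enrich[", dc, "]"), {
        e <- enrich(ct$gene_id, terms, universe = M$genes,
                    min_size = cfg$enrichment$min_size,
                    max_size = cfg$enrichment$max_size,
                    alpha = cfg$enrichment$alpha)
        utils::write.table(as.data.frame(e),
                           file.path(cfg$out_dir, paste0("enrichment_", dc, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        e
      })
      res$enrichment <- list(n_tested = nrow(enr),
                             n_significant = sum(enr$significant),
                             top_term = if (nrow(enr)) enr$term_id[1] else NA)
      enr_by_class[[dc]] <- enr
    }
    results[[dc]] <- res
  }
  report$classes <- results

  # -- crosstalk over all classes' significant terms -------------------
  enr_list <- Filter(function(e) any(e$significant), enr_by_class)
  if (length(enr_list)) {
    net <- .stage("crosstalk", {
      n <- build_crosstalk(enr_list, min_shared = cfg$crosstalk$min_shared)
      write_crosstalk(n, graphml_path = file.path(cfg$out_dir, "crosstalk.graphml"),
                      edges_path = file.path(cfg$out_dir, "crosstalk_edges.tsv"))
      n
    })
    report$crosstalk <- list(n_nodes = nrow(net$nodes),
                             n_edges = nrow(net$edges),
                             degree_summary = net$degree_summary)
  }

  # -- genotype classification ----------------------------------------
  if (isTRUE(cfg$classify$enabled) && !is.null(genotypes) &&
      !is.null(phenotypes)) {
    cl <- .stage("classify", {
      out <- classify_samples(genotypes, phenotypes)
      ape::write.tree(out$tree, file.path(cfg$out_dir, "nj_tree.nwk"))
      utils::write.table(out$distance,
                         file.path(cfg$out_dir, "ibs_distance.tsv"),
                         sep = "\t", quote = FALSE)
      out
    })
    report$classification <- list(
      n_markers = nrow(cl$genotypes$dosage),
      n_genes = attr(cl$genotypes, "n_genes_retained"),
      concordance = cl$concordance$concordance,
      n_scored = cl$concordance$n_scored)
  }

  # strip per-class ctgene vectors are kept; write the report
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(report)
}
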