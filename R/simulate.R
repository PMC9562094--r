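#' Configuration for the synthetic-data generators
#'
#' Defines a planted-truth benchmark emulating the study conditions: a
#' pool of test genes of which `n_signal` carry strong concordant evidence
#' in at least four layers, an expression-significance table where the
#' signal genes are differentially expressed, a two-cluster genotype panel
#' (cold-resistant vs cold-susceptible samples), and gene-set annotations
#' with one planted term. Every generator is a pure function of this
#' configuration, including its seed.
#'
#' @param n_genes total test-gene pool size (default 2000).
#' @param n_signal number of planted signal genes (default 10).
#' @param signal_mean,signal_sd per-layer score distribution of signal
#'   genes on the four omics layers (defaults 4.2 and 0.05: comfortably
#'   above the core-gene per-layer threshold of 3, tightly concordant
#'   across layers as curated high-confidence genes are, and placing the
#'   combined score ~19.8 well clear of an integer cut-off boundary).
#' @param noise_mean mean per-record score of noise genes (default 0.75;
#'   0 produces genes with no evidence at all, which drop out of the
#'   score matrix).
#' @param expr_signal_beta Beta(a, b) parameters of the signal genes'
#'   DE p-values (default c(0.1, 10), mass near 0); null genes are
#'   Uniform(0, 1).
#' @param n_samples named sample counts per phenotype cluster
#'   (default 28 resistant + 28 susceptible, the study's design).
#' @param n_snps_per_gene markers per signal gene (default 2).
#' @param cluster_divergence allele-frequency gap between the two
#'   clusters at signal-gene markers (default 0.9; 0 removes all
#'   cluster signal).
#' @param missing_rate genotype missingness (default 0.02).
#' @param n_decoy_terms random gene-set annotations beside the planted
#'   term (default 30).
#' @param seed integer RNG seed (mandatory).
#' @return list of settings.
#' @export
synthetic_config <- function(n_genes = 2000L, n_signal = 10L,
                             signal_mean = 4.2, signal_sd = 0.05,
                             noise_mean = 0.75,
                             expr_signal_beta = c(0.1, 10),
                             n_samples = c(resistant = 28L, susceptible = 28L),
                             n_snps_per_gene = 2L,
                             cluster_divergence = 0.9,
                             missing_rate = 0.02,
                             n_decoy_terms = 30L,
                             seed) {
  stopifnot(!missing(seed), is.numeric(seed), n_signal <= n_genes,
            cluster_divergence >= 0, cluster_divergence <= 1,
            missing_rate >= 0, missing_rate < 1)
  list(n_genes = as.integer(n_genes), n_signal = as.integer(n_signal),
       signal_mean = signal_mean, signal_sd = signal_sd,
       noise_mean = noise_mean, expr_signal_beta = expr_signal_beta,
       n_samples = n_samples, n_snps_per_gene = as.integer(n_snps_per_gene),
       cluster_divergence = cluster_divergence,
       missing_rate = missing_rate, n_decoy_terms = as.integer(n_decoy_terms),
       seed = as.integer(seed))
}

.syn_gene_ids <- function(cfg) sprintf("G%05d", seq_len(cfg$n_genes))

.syn_durations <- list(short = c(3, 6), mid = c(24, 48), long = c(72, 96))

#' Generate a synthetic evidence table with planted signal genes
#'
#' Signal genes receive one high-scoring record on each of the four omics
#' layers (DNA p-value, RNA fold change, protein p-value, function preset
#' score) in every duration class, plus a duration-agnostic homolog
#' record (reference count 4); raw values are placed in each transform's
#' domain so that the scored evidence lands near `signal_mean` per layer.
#' Noise genes receive one or two sparse low-scoring records.
#'
#' @param cfg from [synthetic_config()].
#' @return list with `records` (evidence data frame) and `truth`
#'   (character vector of planted gene ids).
#' @export
gen_evidence <- function(cfg) {
  set.seed(cfg$seed + 1L)
  genes <- .syn_gene_ids(cfg)
  signal <- genes[seq_len(cfg$n_signal)]
  rows <- list()
  omics <- data.frame(
    layer = c("DNA", "RNA", "protein", "function"),
    feature_type = c("QTL", "mRNA", "protein_pair", "metabolite_pathway"),
    value_kind = c("pvalue", "fold_change", "pvalue", "preset_score"),
    stringsAsFactors = FALSE)

  raw_for <- function(kind, s) switch(kind,
    pvalue = 10^-pmin(s, 10),
    fold_change = 2^s,
    preset_score = s,
    lod = s)

  for (g in signal) {
    for (cls in names(.syn_durations)) {
      dur <- sample(.syn_durations[[cls]], 1L)
      s <- pmax(0, stats::rnorm(4, cfg$signal_mean, cfg$signal_sd))
      for (i in 1:4) {
        rows[[length(rows) + 1L]] <- data.frame(
          marker_id = g, layer = omics$layer[i],
          feature_type = omics$feature_type[i],
          value_kind = omics$value_kind[i],
          value = raw_for(omics$value_kind[i], s[i]),
          is_log = FALSE, temperature_C = 4, duration_hours = dur,
          qtl_interval_cM = if (omics$feature_type[i] == "QTL") 2 else NA_real_,
          source_id = sprintf("study_%s_%s", cls, omics$layer[i]),
          stringsAsFactors = FALSE)
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      marker_id = g, layer = "homologs", feature_type = "homolog",
      value_kind = "ref_count", value = 4, is_log = FALSE,
      temperature_C = NA_real_, duration_hours = NA_real_,
      qtl_interval_cM = NA_real_, source_id = "homolog_curation",
      stringsAsFactors = FALSE)
  }

  noise <- setdiff(genes, signal)
  if (cfg$noise_mean > 0) {
    n_rec <- 2L + stats::rpois(length(noise), 1)
    for (i in seq_along(noise)) {
      for (k in seq_len(n_rec[i])) {
        li <- sample.int(4, 1L)
        s <- stats::rgamma(1, shape = 2, scale = cfg$noise_mean / 2)
        dur <- if (stats::runif(1) < 0.1) NA_real_
        else sample(unlist(.syn_durations), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          marker_id = noise[i], layer = omics$layer[li],
          feature_type = omics$feature_type[li],
          value_kind = omics$value_kind[li],
          value = raw_for(omics$value_kind[li], s),
          is_log = FALSE, temperature_C = 4, duration_hours = dur,
          qtl_interval_cM = if (omics$feature_type[li] == "QTL") 2 else NA_real_,
          source_id = sprintf("study_noise_%02d", sample.int(20, 1L)),
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  list(records = records, truth = signal)
}

#' Generate a synthetic expression-significance table
#'
#' Signal genes draw DE p-values from `Beta(a, b)` (mass near zero), all
#' other genes from `Uniform(0, 1)`.
#'
#' @param cfg from [synthetic_config()].
#' @param truth planted gene ids from [gen_evidence()].
#' @return named numeric vector of p-values over all genes.
#' @export
gen_expression <- function(cfg, truth) {
  set.seed(cfg$seed + 2L)
  genes <- .syn_gene_ids(cfg)
  p <- stats::runif(length(genes))
  is_sig <- genes %in% truth
  p[is_sig] <- stats::rbeta(sum(is_sig), cfg$expr_signal_beta[1],
                            cfg$expr_signal_beta[2])
  p <- pmin(pmax(p, 1e-300), 1)
  stats::setNames(p, genes)
}

#' Generate a synthetic two-cluster genotype panel
#'
#' Markers inside signal genes have an allele-frequency gap of
#' `cluster_divergence` between the resistant and susceptible clusters;
#' background markers (in a sample of non-signal genes) share one
#' frequency. Dosages are Binomial(2, freq) with entries masked at
#' `missing_rate`. One deliberately monomorphic marker is appended to
#' exercise the informativeness filter.
#'
#' @param cfg from [synthetic_config()].
#' @param truth planted gene ids.
#' @return list with `genotypes` (list `dosage`, `marker_gene`) and
#'   `labels` (named phenotype vector).
#' @export
gen_genotypes <- function(cfg, truth) {
  set.seed(cfg$seed + 3L)
  n_per <- cfg$n_samples
  samples <- unlist(lapply(names(n_per), function(cl)
    sprintf("%s_%02d", cl, seq_len(n_per[[cl]]))))
  cluster <- rep(names(n_per), n_per)
  gap <- cfg$cluster_divergence
  f_lo <- (1 - gap) / 2
  f_hi <- (1 + gap) / 2

  marker_gene <- character(0)
  freqs <- list()
  for (g in truth) {
    for (k in seq_len(cfg$n_snps_per_gene)) {
      marker_gene <- c(marker_gene, g)
      freqs[[length(freqs) + 1L]] <- c(resistant = f_hi, susceptible = f_lo)
    }
  }
  n_bg <- max(10L, 2L * cfg$n_signal)
  bg_genes <- sample(setdiff(.syn_gene_ids(cfg), truth), n_bg)
  for (g in bg_genes) {
    marker_gene <- c(marker_gene, g)
    f <- stats::runif(1, 0.1, 0.9)
    freqs[[length(freqs) + 1L]] <- c(resistant = f, susceptible = f)
  }
  nm <- length(marker_gene)
  dos <- matrix(NA_integer_, nm, length(samples),
                dimnames = list(sprintf("snp%04d", seq_len(nm)), samples))
  for (i in seq_len(nm)) {
    f <- freqs[[i]][cluster]
    dos[i, ] <- stats::rbinom(length(samples), 2L, f)
  }
  # planted monomorphic marker (filtered out downstream)
  dos <- rbind(dos, mono = rep(2L, length(samples)))
  marker_gene <- c(marker_gene, sample(bg_genes, 1L))
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(length(dos)) < cfg$missing_rate,
                   nrow(dos), ncol(dos))
    dos[mask] <- NA_integer_
  }
  names(marker_gene) <- rownames(dos)
  labels <- stats::setNames(cluster, samples)
  list(genotypes = list(dosage = dos, marker_gene = marker_gene),
       labels = labels)
}

#' Generate synthetic gene-set annotations
#'
#' One planted term holds at least 80% of the signal genes (padded with
#' null genes to the minimum testable size); decoy terms have random
#' composition, plus one deliberately undersized (3 genes) and one
#' deliberately oversized (2600 ids) term to exercise the size filter.
#'
#' @param cfg from [synthetic_config()].
#' @param truth planted gene ids.
#' @return named list of gene-set character vectors (GMT-shaped).
#' @export
gen_annotations <- function(cfg, truth) {
  set.seed(cfg$seed + 4L)
  genes <- .syn_gene_ids(cfg)
  n_in <- max(ceiling(0.8 * length(truth)), 1L)
  planted <- c(truth[seq_len(n_in)],
               sample(setdiff(genes, truth), max(5L - n_in, 2L)))
  terms <- list(planted_term = unique(planted))
  for (i in seq_len(cfg$n_decoy_terms)) {
    sz <- sample(5:50, 1L)
    terms[[sprintf("decoy%03d", i)]] <- sample(genes, sz)
  }
  terms[["undersized"]] <- sample(genes, 3L)
  terms[["oversized"]] <- c(genes, sprintf("FAKE%04d", seq_len(2600L - length(genes))))
  for (id in names(terms)) attr(terms[[id]], "term_name") <- id
  terms
}

#' Write every synthetic input to a directory
#'
#' Materializes the generated evidence, expression, genotype, phenotype,
#' GMT and truth files in the formats the readers consume.
#'
#' @param cfg from [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisible named vector of written paths.
#' @export
write_synthetic_inputs <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- gen_evidence(cfg)
  expr <- gen_expression(cfg, ev$truth)
  gt <- gen_genotypes(cfg, ev$truth)
  terms <- gen_annotations(cfg, ev$truth)
  paths <- c(evidence = file.path(dir, "evidence.tsv"),
             expression = file.path(dir, "expression.tsv"),
             genotypes = file.path(dir, "genotypes.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             gmt = file.path(dir, "terms.gmt"),
             truth = file.path(dir, "truth.json"))
  write_evidence(ev$records, paths["evidence"])
  utils::write.table(data.frame(gene_id = names(expr), pvalue = unname(expr)),
                     paths["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gdf <- data.frame(marker_id = rownames(gt$genotypes$dosage),
                    gene_id = unname(gt$genotypes$marker_gene),
                    gt$genotypes$dosage, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(gdf, paths["genotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(gt$labels),
                                label = unname(gt$labels)),
                     paths["phenotypes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(terms, paths["gmt"])
  jsonlite::write_json(list(signal_genes = ev$truth, seed = cfg$seed),
                       paths["truth"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
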