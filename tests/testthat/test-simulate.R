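# Generators run at reduced scale here; study-scale behavior is exercised
# in the acceptance suite.

test_that("generators are pure functions of the configuration", {
  cfg <- synthetic_config(n_genes = 150, n_signal = 5, seed = 101)
  ev1 <- gen_evidence(cfg); ev2 <- gen_evidence(cfg)
  expect_identical(ev1, ev2)
  expect_identical(gen_expression(cfg, ev1$truth),
                   gen_expression(cfg, ev1$truth))
  expect_identical(gen_genotypes(cfg, ev1$truth),
                   gen_genotypes(cfg, ev1$truth))
  expect_identical(gen_annotations(cfg, ev1$truth),
                   gen_annotations(cfg, ev1$truth))
})

test_that("planted genes dominate the combined score ranking after scoring", {
  cfg <- synthetic_config(n_genes = 300, n_signal = 8, seed = 102)
  ev <- gen_evidence(cfg)
  expect_true(all(ev$records$temperature_C < 15, na.rm = TRUE))
  ms <- build_score_matrix(score_evidence(filter_evidence(ev$records)))
  for (M in ms) {
    top <- M$genes[order(-M$combined)][1:8]
    expect_setequal(top, ev$truth)
    expect_true(all(M$S >= 0 & M$S <= 10))
  }
})

test_that("a zero-noise configuration leaves only signal genes in the matrix", {
  cfg <- synthetic_config(n_genes = 100, n_signal = 6, noise_mean = 0,
                          seed = 103)
  ev <- gen_evidence(cfg)
  ms <- build_score_matrix(score_evidence(ev$records))
  for (M in ms) expect_setequal(M$genes, ev$truth)
})

test_that("expression p-values separate signal from null as configured", {
  cfg <- synthetic_config(n_genes = 2000, n_signal = 50, seed = 104)
  truth <- sprintf("G%05d", 1:50)
  expr <- gen_expression(cfg, truth)
  expect_lt(median(expr[truth]), 0.01)                # Beta(0.1, 10) mass near 0
  expect_gt(median(expr[setdiff(names(expr), truth)]), 0.4)
  expect_true(all(expr > 0 & expr <= 1))
})

test_that("null-only expression rarely yields significant subset comparisons", {
  hits <- 0L
  for (seed in 1:100) {
    cfg <- synthetic_config(n_genes = 300, n_signal = 10, seed = 1000 + seed)
    expr <- gen_expression(cfg, character(0))          # no signal at all
    set.seed(seed)
    subset <- sample(names(expr), 20)
    p <- compare_vs_remaining(subset, expr)$p_value
    if (p < 0.05) hits <- hits + 1L
  }
  expect_lte(hits, 7)                                  # ~5% nominal rate
})

test_that("genotype panels carry the planted cluster structure and a monomorphic decoy", {
  cfg <- synthetic_config(n_genes = 200, n_signal = 6, seed = 105)
  truth <- sprintf("G%05d", 1:6)
  gt <- gen_genotypes(cfg, truth)
  expect_equal(ncol(gt$genotypes$dosage), 56)
  expect_equal(unname(table(gt$labels)["resistant"]), 28, ignore_attr = TRUE)
  expect_true("mono" %in% rownames(gt$genotypes$dosage))
  filtered <- filter_informative_snps(gt$genotypes)
  expect_false("mono" %in% rownames(filtered$dosage))
  # divergent markers actually differ in allele frequency between clusters
  snp1 <- gt$genotypes$dosage[1, ]
  f_res <- mean(snp1[gt$labels == "resistant"], na.rm = TRUE) / 2
  f_sus <- mean(snp1[gt$labels == "susceptible"], na.rm = TRUE) / 2
  expect_gt(abs(f_res - f_sus), 0.5)
})

test_that("annotations plant one enrichable term and size-filter decoys", {
  cfg <- synthetic_config(n_genes = 400, n_signal = 10, seed = 106)
  truth <- sprintf("G%05d", 1:10)
  terms <- gen_annotations(cfg, truth)
  expect_gte(length(intersect(terms$planted_term, truth)), 8)  # >= 80%
  expect_equal(length(terms$undersized), 3)
  expect_gt(length(terms$oversized), 2500)

  res <- enrich(truth, terms, universe = sprintf("G%05d", 1:400))
  expect_false("undersized" %in% res$term_id)
  expect_false("oversized" %in% res$term_id)
  expect_equal(res$term_id[1], "planted_term")         # smallest adjusted p
  expect_true(res$significant[1])
})

test_that("synthetic inputs round-trip through the file readers", {
  cfg <- synthetic_config(n_genes = 80, n_signal = 4, seed = 107)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_inputs(cfg, dir)
  ev <- read_evidence(paths["evidence"])
  expect_identical(nrow(ev), nrow(gen_evidence(cfg)$records))
  expr <- read_expression(paths["expression"])
  expect_length(expr, 80)
  G <- read_genotypes(paths["genotypes"])
  expect_equal(ncol(G$dosage), 56)
  labels <- read_phenotypes(paths["phenotypes"])
  expect_length(labels, 56)
  terms <- read_gmt(paths["gmt"])
  expect_true("planted_term" %in% names(terms))
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$signal_genes, gen_evidence(cfg)$truth)
})
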