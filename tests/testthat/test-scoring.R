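test_that("score transforms reproduce the per-kind contracts", {
  expect_equal(evidence_to_score(0.001, "pvalue"), 3)
  expect_equal(evidence_to_score(1e-15, "pvalue"), 10)       # capped
  expect_equal(evidence_to_score(4, "fold_change"), 2)
  expect_equal(evidence_to_score(0.25, "fold_change"), 2)    # |log2|
  expect_equal(evidence_to_score(-1.5, "fold_change", is_log = TRUE), 1.5)
  expect_equal(evidence_to_score(3.7, "lod"), 3)
  expect_equal(evidence_to_score(2, "ref_count"), 2)         # bins 1/2-3/>=4
  expect_equal(evidence_to_score(4, "ref_count"), 3)
  expect_equal(evidence_to_score(12, "preset_score"), 10)    # clipped
  expect_equal(evidence_to_score(-2, "preset_score"), 0)

  expect_error(evidence_to_score(0, "pvalue"), "invalid evidence")
  expect_error(evidence_to_score(1.2, "pvalue"), "invalid evidence")
  expect_error(evidence_to_score(-1, "fold_change"), "invalid evidence")
  expect_error(evidence_to_score(1, "banana"), "configuration error")
})

test_that("every emitted score lies in [0, 10] across a value grid", {
  grids <- list(pvalue = 10^seq(-20, 0, length.out = 40)[-40],
                fold_change = 2^seq(-15, 15, length.out = 30),
                lod = seq(0, 100, length.out = 25),
                degree = c(0:10, 50, 1000),
                cluster_coefficient = seq(0, 1, 0.05),
                ref_count = 1:50,
                preset_score = seq(-5, 50, 2.5))
  for (kind in names(grids)) {
    s <- evidence_to_score(grids[[kind]], kind)
    expect_true(all(s >= 0 & s <= 10), info = kind)
  }
})

test_that("duration classes split at 12 h and 48 h", {
  expect_equal(duration_class(c(3, 11.9, 12, 48, 48.1, 96, NA)),
               c("short", "short", "mid", "mid", "long", "long", NA))
})

test_that("marker mapping matches a brute-force scan and the window contract", {
  ann <- data.frame(gene_id = c("gA", "gB", "gC"),
                    chrom = c("chr1", "chr1", "chr2"),
                    start = c(110000, 130001, 50000),
                    end = c(115000, 140000, 60000))
  expect_equal(map_marker_to_genes("chr1", 100000, annotations = ann), "gA")
  expect_false("gB" %in% map_marker_to_genes("chr1", 100000, annotations = ann))
  # marker inside the gA body maps (gB is also within 20 kb of it)
  expect_setequal(map_marker_to_genes("chr1", 112000, annotations = ann),
                  c("gA", "gB"))
  expect_warning(res <- map_marker_to_genes("chrX", 1, annotations = ann),
                 "not present")
  expect_length(res, 0)

  set.seed(3)
  big <- data.frame(gene_id = sprintf("g%02d", 1:40),
                    chrom = sample(c("chr1", "chr2"), 40, TRUE),
                    start = sample.int(5e5, 40))
  big$end <- big$start + sample.int(2e4, 40)
  for (i in 1:25) {
    chrom <- sample(c("chr1", "chr2"), 1)
    a <- sample.int(5e5, 1); b <- a + sample(c(0L, sample.int(3e4, 1)), 1)
    expect_equal(map_marker_to_genes(chrom, a, b, big, window_bp = 20000),
                 brute_map_marker(chrom, a, b, big, 20000))
  }
})

test_that("evidence filtering applies temperature, QTL-interval and dedup rules", {
  rec <- data.frame(
    marker_id = c("m1", "m2", "m3", "m3", "m4"),
    layer = c("DNA", "RNA", "RNA", "RNA", "DNA"),
    feature_type = c("QTL", "mRNA", "mRNA", "mRNA", "QTL"),
    value_kind = "pvalue", value = c(0.01, 0.02, 0.03, 0.03, 0.04),
    temperature_C = c(4, 20, 4, 4, 4),
    duration_hours = 6, qtl_interval_cM = c(7, NA, NA, NA, 3),
    source_id = c("s1", "s2", "s3", "s3", "s4"))
  out <- filter_evidence(rec)
  expect_equal(out$marker_id, c("m3", "m4"))  # 7 cM dropped, 20 C dropped, dup collapsed
})

test_that("score matrix aggregation, weighting, exclusion and invariance", {
  rec <- data.frame(
    marker_id = c("gA", "gA", "gA", "gB", "gC"),
    layer = c("RNA", "RNA", "DNA", "protein", "RNA"),
    feature_type = "mRNA", value_kind = "preset_score",
    value = c(4, 7, 3, 2, 0),
    temperature_C = 4, duration_hours = c(6, 6, 6, 6, 6),
    qtl_interval_cM = NA, source_id = paste0("s", 1:5))
  rec <- score_evidence(rec)
  ms <- build_score_matrix(rec, weights = c(short = 2, mid = 1, long = 1))
  M <- ms$short
  expect_equal(unname(M$S["gA", "RNA"]), 7)        # max aggregation
  expect_equal(unname(M$combined["gA"]), 2 * (7 + 3))
  expect_false("gC" %in% M$genes)                  # zero combined excluded
  expect_true(all(M$S >= 0 & M$S <= 10))
  expect_true(all(M$combined <= M$W * 10 * length(M$layers)))

  # permutation invariance of the input record order
  set.seed(9)
  ms2 <- build_score_matrix(rec[sample.int(nrow(rec)), ],
                            weights = c(short = 2, mid = 1, long = 1))
  expect_identical(ms$short$S, ms2$short$S)
  expect_identical(ms$short$combined, ms2$short$combined)

  # sum-then-clip alternative respects the cap
  rec2 <- rec; rec2$value <- c(6, 7, 3, 2, 0); rec2 <- score_evidence(rec2)
  ms3 <- build_score_matrix(rec2, aggregate = "sum")
  expect_equal(unname(ms3$short$S["gA", "RNA"]), 10)

  expect_error(build_score_matrix(score_evidence(transform(rec, value = 0))),
               "empty-matrix")
})

test_that("duration-tagged records land in their own class; untagged in all", {
  rec <- data.frame(
    marker_id = c("gS", "gM", "gL", "gDB"),
    layer = "RNA", feature_type = "mRNA", value_kind = "preset_score",
    value = 5, temperature_C = 4,
    duration_hours = c(3, 24, 96, NA),
    qtl_interval_cM = NA, source_id = paste0("s", 1:4))
  ms <- build_score_matrix(score_evidence(rec))
  expect_setequal(ms$short$genes, c("gS", "gDB"))
  expect_setequal(ms$mid$genes, c("gM", "gDB"))
  expect_setequal(ms$long$genes, c("gL", "gDB"))
})

test_that("homolog evidence is filtered on e-value and identity", {
  ht <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   model_gene = c("AT1", "AT2", "AT3", "AT4"),
                   e_value = c(1e-12, 1e-8, 1e-20, NA),
                   identity_pct = c(40, 50, 30, 60),
                   ref_count = c(1, 2, 3, 4))
  expect_warning(out <- score_homolog_evidence(ht), "skipped")
  expect_equal(out$marker_id, "g1")     # g2 fails e-value, g3 identity, g4 NA
  expect_equal(out$layer, "homologs")
  expect_equal(evidence_to_score(out$value, "ref_count"), 1)
})

test_that("protein pairs convert to per-gene degree evidence", {
  pairs <- data.frame(gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"))
  out <- ppin_degree_evidence(pairs)
  expect_equal(out$value[match(c("a", "b", "c"), out$marker_id)], c(2, 2, 2))
  expect_true(all(out$value_kind == "degree"))
})

test_that("positional markers map through the annotation window", {
  ann <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                    start = c(110000, 400000), end = c(115000, 410000))
  rec <- data.frame(
    marker_id = c("snp1", "snp2"), layer = "DNA", feature_type = "QTL",
    value_kind = "pvalue", value = 1e-4, temperature_C = 4,
    duration_hours = 6, qtl_interval_cM = 2, source_id = c("s1", "s2"),
    chrom = "chr1", pos_start = c(100000, 200000), pos_end = NA)
  ms <- build_score_matrix(score_evidence(rec), annotations = ann)
  expect_equal(ms$short$genes, "gA")   # snp2 maps nowhere and is dropped
})
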