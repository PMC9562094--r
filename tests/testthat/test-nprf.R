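test_that("bootstrap draws have the right size, determinism and distinct fraction", {
  M <- planted_gsm(50, 10)
  set.seed(1); s1 <- draw_bootstrap(M)
  expect_length(s1, 50)
  expect_true(all(s1 %in% 1:50))
  set.seed(1); s2 <- draw_bootstrap(M)
  expect_identical(s1, s2)

  set.seed(99)
  M2 <- planted_gsm(200, 10)
  frac <- mean(replicate(2000, length(unique(draw_bootstrap(M2))) / 200))
  expect_equal(frac, 1 - exp(-1), tolerance = 0.01)
})

test_that("permutation conserves multisets and per-gene means", {
  M <- planted_gsm(40, 5)
  set.seed(2)
  pc <- draw_permutation(M, mode = "combined")
  expect_equal(sort(unname(pc)), sort(unname(M$combined)))  # multiset conserved

  one <- make_gsm(matrix(3, 1, 2))
  expect_equal(unname(draw_permutation(one, mode = "combined")),
               unname(one$combined))                   # n = 1 identity

  # layer mode conserves each layer's multiset and the global mean
  set.seed(3)
  pl <- draw_permutation(M, mode = "layers")
  expect_equal(mean(pl), mean(M$combined), tolerance = 1e-12)
  means <- rowMeans(replicate(3000, draw_permutation(M, mode = "layers")))
  se <- sd(M$combined) / sqrt(3000)
  expect_true(all(abs(means - mean(M$combined)) < 4 * se))
})

test_that("top-h selection respects ranks, ties and degenerate cases", {
  S <- matrix(0, 3, 2, dimnames = list(c("a", "b", "c"), c("DNA", "RNA")))
  S["a", 1] <- 9; S["b", 1] <- 7; S["c", 1] <- 3
  M <- make_gsm(S)
  expect_equal(M$genes[top_h(M, h = 2)], c("a", "b"))
  expect_equal(M$genes[top_h(M, c(1, 2, 3), h = 3)], c("a", "b", "c"))

  tieS <- matrix(c(5, 5), 2, 1, dimnames = list(c("b", "a"), "DNA"))
  Mt <- make_gsm(tieS)
  expect_equal(Mt$genes[top_h(Mt, h = 1)], "a")        # lexicographic tie

  expect_null(top_h(M, c(1, 1, 1), h = 2))             # too few distinct
})

test_that("prioritization recovers a planted signal with full vote conservation", {
  M <- planted_gsm(50, 10, signal = 2.25, noise = 0.25, seed = 4)
  cfg <- nprf_config(r = 300, q = 300, h = 10, seed = 21)
  res <- run_nprf(M, cfg)
  expect_equal(sum(res$tally), 300 * 10)               # conservation
  expect_true(all(res$tally <= res$trees_accepted))
  ct <- finalize_ctgenes(res)
  expect_setequal(ct$gene_id, M$genes[1:10])           # planted set recovered
  expect_true(all(res$probabilities$probability > 0 &
                  res$probabilities$probability <= 1))

  # seed determinism: identical probability lists
  res2 <- run_nprf(M, cfg)
  expect_identical(res$probabilities, res2$probabilities)

  # different seed, same recovered set
  res3 <- run_nprf(M, nprf_config(r = 300, q = 300, h = 10, seed = 22))
  expect_setequal(finalize_ctgenes(res3)$gene_id, M$genes[1:10])
})

test_that("a structureless training set never yields an accepted tree", {
  S <- matrix(2, 30, 3)
  M <- make_gsm(S)
  expect_error(run_nprf(M, nprf_config(r = 50, q = 50, h = 5, seed = 1,
                                       max_rejected_trees = 200L)),
               "convergence error")
})

test_that("raising a gene's score does not decrease its votes (paired seeds)", {
  M_lo <- planted_gsm(60, 8, signal = 2.5, noise = 0.3, seed = 6)
  S_hi <- M_lo$S
  target <- "g020"                                     # a noise gene
  S_hi[target, 1:4] <- 2.5                             # promote to signal level
  M_hi <- make_gsm(S_hi)
  cfg <- nprf_config(r = 200, q = 200, h = 9, seed = 31)
  c_lo <- run_nprf(M_lo, cfg)$tally[target]
  c_hi <- run_nprf(M_hi, cfg)$tally[target]
  expect_gte(c_hi, c_lo)
})

test_that("probability-drop detection follows the largest consecutive decline", {
  expect_equal(detect_probability_drop(c(1.0, 0.95, 0.8974, 0.0525, 0.05)), 3)
  expect_equal(detect_probability_drop(c(1.0, 0.8, 0.6, 0.4)), 1)  # first on ties
  expect_equal(detect_probability_drop(c(1.0, 1.0, 0.0)), 2)
  expect_error(detect_probability_drop(0.5), "undefined-drop")
})

test_that("final selection breaks count ties by combined score then id", {
  S <- matrix(0, 4, 1, dimnames = list(c("a", "b", "c", "d"), "DNA"))
  S[, 1] <- c(5, 6, 3, 1)
  M <- make_gsm(S)
  res <- structure(list(
    tally = c(a = 500L, b = 500L, c = 3L, d = 0L),
    trees_accepted = 500L, trees_rejected = 10L,
    probabilities = data.frame(gene_id = c("b", "a", "c"),
                               count = c(500L, 500L, 3L),
                               probability = c(1, 1, 0.006),
                               combined = c(6, 5, 3)),
    drop_index = 2L, acceptance_rate = 0.98,
    config = list(h = 2L)), class = "nprf_result")
  ct <- finalize_ctgenes(res)
  expect_equal(ct$gene_id, c("b", "a"))                # higher combined first
  expect_true(attr(ct, "drop_consistent"))
  expect_error(finalize_ctgenes(res, h = 4), "shortfall")
})
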