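test_that("monomorphic markers are removed and gene counts reported", {
  dos <- rbind(m1 = c(2L, 2L, 2L),          # monomorphic
               m2 = c(0L, 0L, 2L),
               m3 = c(1L, NA, 1L),          # monomorphic among genotyped
               m4 = c(0L, 1L, 2L),
               m5 = c(2L, 2L, 2L))
  colnames(dos) <- c("s1", "s2", "s3")
  G <- list(dosage = dos,
            marker_gene = c(m1 = "gA", m2 = "gB", m3 = "gA", m4 = "gB", m5 = "gC"))
  out <- filter_informative_snps(G)
  expect_equal(rownames(out$dosage), c("m2", "m4"))    # 3 of 5 dropped
  expect_equal(attr(out, "n_markers_removed"), 3)
  expect_equal(attr(out, "n_genes_retained"), 1)       # only gB keeps markers

  expect_error(filter_informative_snps(dos[c(1, 5), ]), "uninformative-panel")
})

test_that("identity-by-state distances follow the allele-sharing contract", {
  dos <- cbind(a = c(0L, 1L, 2L), b = c(0L, 1L, 2L), c = c(2L, 1L, 0L))
  rownames(dos) <- paste0("m", 1:3)
  D <- ibs_distance(dos)
  expect_equal(unname(D["a", "b"]), 0)                 # identical
  expect_equal(unname(D["a", "c"]), mean(c(1, 0, 1)))  # 0 vs 2 twice, 1 vs 1

  expect_equal(unname(ibs_distance(cbind(a = 0L, b = 2L))["a", "b"]), 1)
  expect_equal(unname(ibs_distance(cbind(a = 0L, b = 1L))["a", "b"]), 0.5)

  # symmetric, zero diagonal, bounded
  set.seed(15)
  dos2 <- matrix(sample(c(0:2, NA), 200, TRUE, prob = c(.3, .3, .3, .1)), 20, 10,
                 dimnames = list(NULL, paste0("s", 1:10)))
  D2 <- ibs_distance(dos2)
  expect_equal(D2, t(D2))
  expect_true(all(diag(D2) == 0) && all(D2 >= 0 & D2 <= 1))

  # triangle inequality on complete data
  dos3 <- matrix(sample(0:2, 300, TRUE), 30, 10,
                 dimnames = list(NULL, paste0("s", 1:10)))
  D3 <- ibs_distance(dos3)
  for (i in 1:10) for (j in 1:10) for (k in 1:10)
    expect_lte(D3[i, j], D3[i, k] + D3[k, j] + 1e-12)

  expect_error(ibs_distance(cbind(a = c(0L, NA), b = c(NA, 1L))),
               "missingness error")
})

test_that("neighbor joining recovers the worked additive 4-taxon case exactly", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(D)
  # AB|CD topology: the path-length matrix reproduces the input exactly
  expect_equal(cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]], D, tolerance = 1e-12)
  split <- bipartition_concordance(tr, c(A = "x", B = "x", C = "y", D = "y"))
  expect_equal(split$concordance, 1)                   # AB|CD is an edge

  # 3 taxa: forced topology, lengths solve the three equations
  D3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  tr3 <- neighbor_joining(D3)
  expect_equal(cophenetic(tr3)[letters[1:3], letters[1:3]], D3,
               tolerance = 1e-12)

  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  Dn <- D; Dn[1, 2] <- Dn[2, 1] <- -1
  expect_error(neighbor_joining(Dn), "negative")
})

test_that("neighbor joining agrees with an independent implementation", {
  for (seed in 1:5) {
    n <- sample(5:10, 1)
    fix <- random_additive_tree(n, seed)
    ours <- neighbor_joining(fix$D)
    ref <- ape::nj(as.dist(fix$D))
    expect_equal(ape::dist.topo(ape::unroot(ours), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
    expect_equal(max(abs(cophenetic(ours)[rownames(fix$D), rownames(fix$D)] -
                           fix$D)), 0, tolerance = 1e-9)
  }
})

test_that("trees round-trip through Newick without loss", {
  fix <- random_additive_tree(8, 77)
  tr <- neighbor_joining(fix$D)
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, path)
  back <- ape::read.tree(path)
  expect_equal(ape::dist.topo(tr, back), 0, ignore_attr = TRUE)
  expect_equal(cophenetic(back)[tr$tip.label, tr$tip.label],
               cophenetic(tr)[tr$tip.label, tr$tip.label], tolerance = 1e-8)
})

test_that("bipartition concordance scores known splits and mislabelings", {
  # two tight clusters in genotype space
  set.seed(16)
  dosA <- matrix(rbinom(10 * 20, 2, 0.05), 20, 10)
  dosB <- matrix(rbinom(10 * 20, 2, 0.95), 20, 10)
  dos <- cbind(dosA, dosB)
  colnames(dos) <- c(paste0("r", 1:10), paste0("s", 1:10))
  storage.mode(dos) <- "integer"
  labels <- setNames(rep(c("res", "sus"), each = 10), colnames(dos))
  out <- classify_samples(dos, labels)
  expect_equal(out$concordance$concordance, 1)

  # one mislabeled sample among 20 -> 0.95
  labels2 <- labels; labels2["r1"] <- "sus"
  conc2 <- bipartition_concordance(out$tree, labels2)
  expect_equal(conc2$concordance, 0.95)

  # unknown labels are excluded from scoring
  labels3 <- labels; labels3[c("r1", "s1")] <- "unknown"
  conc3 <- bipartition_concordance(out$tree, labels3)
  expect_equal(conc3$n_scored, 18)

  expect_error(bipartition_concordance(out$tree,
                                       setNames(rep("res", 20), colnames(dos))),
               "degenerate-label")
})
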