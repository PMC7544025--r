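test_that("p-distance handles identity, mismatches and ambiguity modes", {
  same <- as_alignment(seq_tbl(c("a", "b"), c("ACGT", "ACGT")))
  expect_equal(as.vector(p_distance(same)), 0)

  one <- as_alignment(seq_tbl(c("a", "b"), c("AAAA", "AAAT")))
  expect_equal(as.vector(p_distance(one)), 0.25)

  amb <- as_alignment(seq_tbl(c("a", "b"), c("ASAA", "ACAA")))
  expect_equal(as.vector(p_distance(amb)), 0)                      # S overlaps C
  expect_equal(as.vector(p_distance(amb, strict = TRUE)), 0.25)    # codes differ
  expect_equal(as.vector(p_distance(amb, ambiguity = "missing")), 0)  # S-column deleted

  gap <- as_alignment(seq_tbl(c("a", "b"), c("A-", "-A")))
  expect_error(p_distance(gap), "no comparable sites")
})

test_that("p-distance is symmetric with zero diagonal and detects indiscernibles", {
  fam <- gen_gene_family(seed = 2, n_high = 4L, n_low = 4L, cds_length = 60L,
                         diagnostic = tibble::tibble(
                           position = c(10L, 30L), high_allele = c("C", "A"),
                           low_allele = c("G", "G"), penetrance = c(1, 1)
                         ), background_rate = 0.02)
  D <- as.matrix(p_distance(as_alignment(fam$sequences)))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0))
})

test_that("neighbor joining recovers additive four-taxon trees exactly", {
  # tree ((a,b),(c,d)) with known branch lengths
  tr <- read_newick("((a:2,b:3):1,(c:4,d:5):2);")
  D <- ape::cophenetic.phylo(tr)
  nj <- neighbor_joining(D)
  expect_equal(ape::dist.topo(ape::unroot(tr), nj), 0, ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)], D,
               tolerance = 1e-10)
})

test_that("three taxa resolve to the closed-form star", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(lens[["a"]], (2 + 3 - 4) / 2)
  expect_equal(lens[["b"]], (2 + 4 - 3) / 2)
  expect_equal(lens[["c"]], (3 + 4 - 2) / 2)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
  d2 <- d; d2[1, 2] <- 5
  expect_error(neighbor_joining(d2), "symmetric")
})

test_that("NJ recovers random additive trees (topology and path lengths), n <= 8", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    D <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), nj), 0, ignore_attr = TRUE,
                 info = paste("seed", s))
    expect_equal(max(abs(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)] - D)), 0,
                 tolerance = 1e-8, info = paste("seed", s))
    # independent cross-check against the reference NJ implementation
    expect_equal(ape::dist.topo(ape::nj(D), nj), 0, ignore_attr = TRUE)
  }
})

test_that("leaf-order permutation yields an isomorphic tree", {
  set.seed(13)
  tr <- ape::rtree(6)
  D <- ape::cophenetic.phylo(tr)
  perm <- sample(rownames(D))
  nj1 <- neighbor_joining(D)
  nj2 <- neighbor_joining(D[perm, perm])
  expect_equal(ape::dist.topo(nj1, nj2), 0, ignore_attr = TRUE)
})

test_that("monophyly is an edge-bipartition property", {
  tr <- read_newick("((a:1,b:1):1,(c:1,d:1):1);")
  expect_true(is_group_monophyletic(tr, c("a", "b"))$monophyletic)
  expect_false(is_group_monophyletic(tr, c("a", "c"))$monophyletic)
  expect_error(is_group_monophyletic(tr, c("a", "zz")), "unknown leaf")
  # agrees with the reference implementation on random trees and subsets
  for (s in 1:10) {
    set.seed(s)
    tr <- ape::rtree(8)
    grp <- sample(tr$tip.label, 3)
    expect_equal(is_group_monophyletic(tr, grp)$monophyletic,
                 ape::is.monophyletic(tr, grp),
                 info = paste("seed", s))
  }
})

test_that("bootstrap on clearly separated groups gives near-full support", {
  # two 4-taxon groups with many diagnostic columns
  g1 <- paste(rep("A", 40), collapse = ""); g2 <- paste(rep("C", 40), collapse = "")
  jitter_seq <- function(s, i) {
    chars <- strsplit(s, "")[[1]]; chars[i] <- "T"; paste(chars, collapse = "")
  }
  aln <- as_alignment(seq_tbl(
    paste0("t", 1:8),
    c(g1, jitter_seq(g1, 1), jitter_seq(g1, 2), jitter_seq(g1, 3),
      g2, jitter_seq(g2, 4), jitter_seq(g2, 5), jitter_seq(g2, 6))
  ))
  tr <- bootstrap_support(aln, n_reps = 100, seed = 1)
  canon <- paste(sort(paste0("t", 5:8)), collapse = "|")
  expect_true(is_group_monophyletic(tr, paste0("t", 1:4))$monophyletic)
  expect_gte(attr(tr, "support")[[canon]], 95)
})

test_that("single-replicate supports are 0 or 100 and identical sequences support nothing", {
  fam <- gen_gene_family(seed = 4, n_high = 3L, n_low = 3L, cds_length = 40L,
                         diagnostic = tibble::tibble(
                           position = 5L, high_allele = "C",
                           low_allele = "G", penetrance = 1
                         ), background_rate = 0.05)
  tr <- bootstrap_support(as_alignment(fam$sequences), n_reps = 1, seed = 1)
  expect_true(all(attr(tr, "support") %in% c(0, 100)))

  ident <- as_alignment(seq_tbl(paste0("t", 1:4), rep("ACGTACGT", 4)))
  tr2 <- bootstrap_support(ident, n_reps = 10, seed = 1)
  supp <- attr(tr2, "support")
  expect_true(length(supp) == 0 || all(supp == 0) ||
                all(tr2$edge.length[tr2$edge[, 2] > 4] == 0))
  expect_error(bootstrap_support(as_alignment(seq_tbl(c("a", "b", "c"),
                                                      rep("A", 3))), 10, 1),
               "2 columns")
})

test_that("bootstrap output is bit-identical for a fixed seed", {
  fam <- gen_gene_family(seed = 8)
  aln <- as_alignment(fam$sequences)
  t1 <- bootstrap_support(aln, n_reps = 20, seed = 99)
  t2 <- bootstrap_support(aln, n_reps = 20, seed = 99)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_identical(attr(t1, "support"), attr(t2, "support"))
})
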