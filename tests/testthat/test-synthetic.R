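test_that("the default gene family round-trips through marker discovery", {
  fam <- gen_gene_family(seed = 1)
  expect_equal(nrow(fam$sequences), 38)
  expect_equal(sum(fam$sequences$group == "high"), 20)
  expect_equal(unique(nchar(fam$sequences$residues)), 792)

  m <- alignment_to_matrix(as_alignment(fam$sequences))
  mk <- find_diagnostic_snps(m, "high", theta = 0.9, require_contrast_fixed = TRUE)
  truth <- fam$truth$diagnostic
  expect_equal(mk$position, truth$position)     # recall = 1
  expect_equal(mk$allele, truth$high_allele)
  expect_equal(nrow(mk), nrow(truth))           # precision = 1
  expect_equal(mk$penetrance, truth$penetrance)
})

test_that("discovery recovers exactly the planted set at full penetrance and no leakage", {
  planted <- tibble::tibble(
    position = c(50L, 120L, 200L), high_allele = c("C", "T", "A"),
    low_allele = c("G", "A", "G"), penetrance = c(1, 1, 1)
  )
  fam <- gen_gene_family(n_high = 8L, n_low = 8L, cds_length = 300L,
                         diagnostic = planted, het_rate_high = 0.5,
                         het_rate_low = 0, background_rate = 0, seed = 7)
  m <- alignment_to_matrix(as_alignment(fam$sequences))
  for (theta in c(0.6, 0.8, 1)) {
    mk <- find_diagnostic_snps(m, "high", theta, TRUE)
    expect_equal(mk$position, planted$position, info = paste("theta", theta))
    expect_equal(mk$allele, planted$high_allele)
  }
})

test_that("low-group heterozygosity appears only when leakage is requested", {
  fam <- gen_gene_family(seed = 2)  # het_rate_low = 0
  m <- alignment_to_matrix(as_alignment(fam$sequences),
                           positions = fam$truth$diagnostic$position)
  expect_equal(attr(heterozygosity_profile(m, "low"), "total_het"), 0)

  leaky <- gen_gene_family(seed = 2, het_rate_low = 0.2)
  m2 <- alignment_to_matrix(as_alignment(leaky$sequences),
                            positions = leaky$truth$diagnostic$position)
  expect_gt(attr(heterozygosity_profile(m2, "low"), "total_het"), 0)
})

test_that("no variation is produced without planted positions or background noise", {
  fam <- gen_gene_family(n_high = 4L, n_low = 4L, cds_length = 100L,
                         diagnostic = default_diagnostic_truth()[0, ],
                         background_rate = 0, seed = 3)
  expect_equal(length(unique(fam$sequences$residues)), 1)
})

test_that("generators are pure functions of their arguments", {
  expect_identical(gen_gene_family(seed = 9), gen_gene_family(seed = 9))
  expect_false(identical(gen_gene_family(seed = 9)$sequences$residues,
                         gen_gene_family(seed = 10)$sequences$residues))
  expect_identical(gen_ct_table(seed = 4), gen_ct_table(seed = 4))
  p1 <- gen_promoters(seed = 6); p2 <- gen_promoters(seed = 6)
  expect_identical(p1, p2)
})

test_that("unreachable penetrance is rejected", {
  bad <- tibble::tibble(position = 10L, high_allele = "C",
                        low_allele = "G", penetrance = 0.05)
  expect_error(gen_gene_family(n_high = 4L, n_low = 4L, cds_length = 50L,
                               diagnostic = bad, seed = 1),
               "penetrance unreachable")
})

test_that("planted promoters are recovered with exact positions and strands", {
  prom <- gen_promoters(seed = 1)
  pats <- read_motifs(mesa_example("motifs.yaml"))
  hits <- motif_frequency_table(prom$sequences, pats)
  all_hits <- attr(hits, "hits")
  for (r in seq_len(nrow(prom$truth))) {
    t <- prom$truth[r, ]
    found <- any(all_hits$species_code == t$species_code &
                   all_hits$motif_name == t$motif &
                   all_hits$position == t$position &
                   all_hits$strand == t$strand)
    expect_true(found, info = paste(t$species_code, t$motif, t$position, t$strand))
  }
  # published-style contrast: two TATA boxes in len, one elsewhere
  expect_equal(hits[["TATA-box"]][hits$species_code == "len"], 2L)
  expect_true(all(hits[["TATA-box"]][hits$species_code != "len"] == 1L))
})

test_that("scrubbed backgrounds with nothing planted scan empty", {
  pats <- read_motifs(mesa_example("motifs.yaml"))
  species <- tibble::tibble(species_code = c("s1", "s2"), group = c("high", "low"))
  zero <- tibble::tibble(species_code = species$species_code,
                         motif = "TATA-box", count = 0L)
  prom <- gen_promoters(species = species, planted = zero, patterns = pats,
                        length = 200L, seed = 4)
  for (s in prom$sequences$residues) {
    expect_equal(nrow(scan_motifs(s, pats)), 0)
  }
  expect_equal(nrow(prom$truth), 0)
})

test_that("Ct tables encode the planted levels exactly when noiseless", {
  ct <- gen_ct_table(noise_sd = 0, seed = 1)
  rel <- delta_ct(aggregate_replicates(ct), reference_genes = c("ACT", "UBQ"))
  len <- rel[rel$species_code == "len" & rel$gene == "SAMT", ]
  ddct <- len$mean_dct[len$tissue == "leaf"] - len$mean_dct[len$tissue == "bark"]
  expect_equal(ddct, 3)  # log2(8)
  truth <- attr(ct, "truth")$levels
  for (r in seq_len(nrow(truth))) {
    got <- rel$rel_expr[rel$species_code == truth$species_code[r] &
                          rel$tissue == truth$tissue[r] &
                          rel$gene == truth$gene[r]]
    expect_equal(got, truth$level[r], tolerance = 1e-9)
  }
})

test_that("the default expression scenario ranks high-producer bark highest", {
  ct <- gen_ct_table(seed = 8)
  rel <- delta_ct(aggregate_replicates(ct), reference_genes = c("ACT", "UBQ"))
  samt <- rel[rel$gene == "SAMT", ]
  bark_high <- samt$rel_expr[samt$tissue == "bark" & samt$species_code %in% c("ale", "len")]
  rest <- samt$rel_expr[!(samt$tissue == "bark" & samt$species_code %in% c("ale", "len"))]
  expect_true(min(bark_high) > max(rest))
})
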