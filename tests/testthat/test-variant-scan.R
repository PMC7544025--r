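test_that("alignment_to_matrix extracts polymorphic columns in 1-based coordinates", {
  aln <- seq_tbl(c("x", "y"), c("AC", "AG"), group = c("high", "low"))
  m <- alignment_to_matrix(as_alignment(aln))
  expect_equal(unique(m$position), 2L)
  expect_equal(m$call, c("C", "G"))

  same <- seq_tbl(c("x", "y"), c("ACGT", "ACGT"), group = c("high", "low"))
  expect_equal(nrow(alignment_to_matrix(as_alignment(same))), 0)

  prot <- seq_tbl(c("x", "y"), c("MK", "MR"), moltype = "protein",
                  group = c("high", "low"))
  expect_error(alignment_to_matrix(as_alignment(prot)), "nucleotide")
})

test_that("sequences planted from the fixture reproduce the fixture matrix cell-by-cell", {
  fix <- fixture_matrix()
  tab <- tibble::as_tibble(fix)
  inds <- unique(tab$individual_id)
  backbone <- strsplit(paste(rep("ACGT", 100), collapse = ""), "")[[1]]  # constant background
  positions <- sort(unique(tab$position))
  residues <- vapply(inds, function(id) {
    chars <- backbone
    sub <- tab[tab$individual_id == id, ]
    chars[sub$position] <- sub$call
    paste(chars, collapse = "")
  }, "")
  meta <- dplyr::distinct(tab[c("individual_id", "species_code", "group")])
  aln <- tibble::tibble(
    id = inds, species_code = meta$species_code[match(inds, meta$individual_id)],
    group = meta$group[match(inds, meta$individual_id)],
    moltype = "dna", residues = unname(residues)
  )
  m <- alignment_to_matrix(as_alignment(aln))
  expect_equal(tibble::as_tibble(m), tab)
})

test_that("heterozygosity profile matches the published group pattern on the fixture", {
  m <- fixture_matrix()
  low <- heterozygosity_profile(m, "low")
  expect_true(all(low$n_het == 0))
  expect_equal(attr(low, "total_het"), 0)

  med <- heterozygosity_profile(m, "med")
  expect_equal(attr(med, "het_positions"), c(160L, 189L, 262L, 298L, 304L, 336L))

  # recomputed high-group profile excluding med: three positions, not four
  no_med <- allele_matrix(dplyr::filter(tibble::as_tibble(m), species_code != "med"))
  prof <- heterozygosity_profile(no_med, "high")
  expect_equal(attr(prof, "het_positions"), c(160L, 189L, 304L))

  hom_only <- allele_matrix(tibble::tibble(
    position = rep(c(1L, 2L), each = 2),
    individual_id = rep(c("a", "b"), 2),
    species_code = "", group = rep(c("high", "low"), 2),
    call = c("A", "C", "G", "T")
  ))
  expect_equal(attr(heterozygosity_profile(hom_only), "total_het"), 0)

  expect_error(heterozygosity_profile(m, "nope"), "unknown subset")
})

test_that("fixture discovery finds the six published markers with their alleles", {
  m <- fixture_matrix()
  mk <- find_diagnostic_snps(m, "high", theta = 0.9, require_contrast_fixed = TRUE)
  expect_equal(mk$position, c(160L, 189L, 262L, 298L, 304L, 336L))
  expect_equal(mk$allele, c("C", "A", "T", "G", "G", "A"))
  expect_equal(mk$carriers_contrast, rep(0L, 6))
  expect_equal(mk$penetrance, c(1, 0.95, 0.95, 0.9, 0.95, 1))
  expect_equal(mk$contrast_allele, c("G", "G", "A", "A", "T", "G"))

  g <- glance(mk)
  expect_equal(g$n_markers, 6L)
  expect_equal(g$theta, 0.9)
})

test_that("theta = 1 keeps exactly the fully penetrant positions (brute-force check)", {
  m <- fixture_matrix()
  mk <- find_diagnostic_snps(m, "high", theta = 1, require_contrast_fixed = TRUE)
  orc <- oracle_markers(m, "high", 1, TRUE)
  expect_equal(mk$position, orc$position)
  expect_equal(mk$allele, orc$allele)
  expect_equal(mk$position, c(160L, 336L))
})

test_that("no markers are reported when both groups share the fixed base", {
  m <- allele_matrix(tibble::tibble(
    position = rep(c(10L, 20L), each = 4),
    individual_id = rep(letters[1:4], 2),
    species_code = "", group = rep(c("high", "high", "low", "low"), 2),
    call = "A"
  ))
  expect_equal(nrow(find_diagnostic_snps(m, "high", 0.9, TRUE)), 0)
  expect_error(
    find_diagnostic_snps(allele_matrix(tibble::tibble(
      position = 1L, individual_id = c("a", "b"), species_code = "",
      group = "high", call = "A"
    )), "high"),
    "non-empty"
  )
})

test_that("discovery equals brute-force enumeration on random matrices", {
  for (s in 1:30) {
    m <- random_matrix(n_pos = sample(2:10, 1), n_ind = sample(4:12, 1), seed = s)
    for (theta in c(0.5, 0.8, 1)) {
      for (cf in c(TRUE, FALSE)) {
        mk <- find_diagnostic_snps(m, "high", theta, cf)
        orc <- oracle_markers(m, "high", theta, cf)
        if (is.null(orc)) {
          expect_equal(nrow(mk), 0, info = paste("seed", s, theta, cf))
        } else {
          expect_equal(mk$position, orc$position, info = paste("seed", s, theta, cf))
          expect_equal(mk$allele, orc$allele, info = paste("seed", s, theta, cf))
          expect_equal(mk$penetrance, orc$penetrance, info = paste("seed", s, theta, cf))
        }
      }
    }
  }
})

test_that("raising theta never increases the marker count", {
  thetas <- c(0.3, 0.5, 0.7, 0.9, 1)
  mats <- c(list(fixture_matrix()),
            lapply(1:20, function(s) random_matrix(6, 10, seed = s)))
  for (m in mats) {
    counts <- vapply(thetas, function(th) {
      nrow(find_diagnostic_snps(m, "high", th, FALSE))
    }, integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("marker discovery is symmetric under group relabeling at theta = 1 with fixed contrast", {
  m <- allele_matrix(tibble::tibble(
    position = rep(c(1L, 2L), each = 4),
    individual_id = rep(c("h1", "h2", "l1", "l2"), 2),
    species_code = "",
    group = rep(c("high", "high", "low", "low"), 2),
    call = c("C", "C", "G", "G",  "A", "A", "A", "A")
  ))
  up <- find_diagnostic_snps(m, "high", 1, TRUE)
  down <- find_diagnostic_snps(m, "low", 1, TRUE)
  expect_equal(up$position, down$position)
  expect_equal(up$allele, "C")
  expect_equal(down$allele, "G")
})

test_that("classification votes reproduce the published validation columns", {
  m <- fixture_matrix()
  panel <- find_diagnostic_snps(m, "high", 0.9, TRUE)

  med <- setNames(c("S", "R", "W", "R", "K", "R"),
                  c(160, 189, 262, 298, 304, 336))
  r <- classify_individual(panel, med, id = "med-like")
  expect_equal(r$votes_for_target, 6L)
  expect_equal(r$verdict, "target")

  pen <- setNames(c("G", "G", "A", "A", "T", "G"),
                  c(160, 189, 262, 298, 304, 336))
  r2 <- classify_individual(panel, pen)
  expect_equal(r2$votes_for_target, 0L)
  expect_equal(r2$verdict, "contrast")

  two <- setNames(c("S", "R"), c(160, 189))
  expect_equal(classify_individual(panel, two)$verdict, "ambiguous")
  expect_error(classify_individual(panel[0, ], med), "empty")
  expect_error(classify_individual(panel, setNames("A", "999")), "no panel position")
})

test_that("classifying the whole fixture validates all 38 individuals correctly", {
  m <- fixture_matrix()
  panel <- find_diagnostic_snps(m, "high", 0.9, TRUE)
  cls <- classify_matrix(panel, m)
  expect_equal(nrow(cls), 38)
  expect_true(all(cls$verdict[cls$group == "low"] == "contrast"))
  # high individuals vote target except genotypically intermediate ones
  high_cls <- cls[cls$group == "high", ]
  expect_true(mean(high_cls$verdict == "target") >= 0.9)
})
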