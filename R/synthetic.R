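# Synthetic-data generators with known ground truth for every pipeline
# stage. They emulate the study design: two species groups (20 high / 18
# low MeSA-producing individuals across eight birch species), a SABP2-like
# CDS with six planted group-diagnostic substitutions carried partly as
# heterozygous IUPAC consensus codes, promoters with planted cis elements,
# and RT-qPCR Ct tables with stated fold-change effects. Carrier counts
# are hit exactly (which individuals carry is a deterministic function of
# the seed), so penetrance-threshold tests are not flaky; only background
# substitutions and Ct noise are stochastic.

.BIRCH_DESIGN <- tibble::tibble(
  species_code = c("ale", "len", "bg", "med", "pen", "uti", "nan", "aln"),
  group = c(rep("high", 4), rep("low", 4)),
  n = c(6L, 6L, 4L, 4L, 6L, 4L, 4L, 4L)
)

#' Default planted diagnostic positions for the synthetic gene family
#'
#' Positions and alleles mirror the published *SABP2* marker panel
#' (positions 160/189/262/298/304/336 with high-group alleles C/A/T/G/G/A),
#' with penetrance 1, 0.95, 0.95, 0.9, 0.95, 1.
#'
#' @return tibble with `position`, `high_allele`, `low_allele`,
#'   `penetrance`.
#' @export
default_diagnostic_truth <- function() {
  tibble(
    position = c(160L, 189L, 262L, 298L, 304L, 336L),
    high_allele = c("C", "A", "T", "G", "G", "A"),
    low_allele = c("G", "G", "A", "A", "T", "G"),
    penetrance = c(1, 0.95, 0.95, 0.9, 0.95, 1)
  )
}

het_code <- function(a, b) {
  for (code in setdiff(.IUPAC_CODES, c("A", "C", "G", "T"))) {
    if (setequal(.IUPAC_EXPANSION[[code]], c(a, b))) return(code)
  }
  abort(paste0("no IUPAC code for {", a, ",", b, "}"))
}

family_individuals <- function(n_high, n_low) {
  if (n_high == 20 && n_low == 18) {
    d <- .BIRCH_DESIGN
    tibble(
      individual_id = unlist(map2(d$species_code, d$n, function(s, k) paste0(s, "_", seq_len(k)))),
      species_code = rep(d$species_code, d$n),
      group = rep(d$group, d$n)
    )
  } else {
    tibble(
      individual_id = c(paste0("hi_", seq_len(n_high)), paste0("lo_", seq_len(n_low))),
      species_code = c(rep("hi", n_high), rep("lo", n_low)),
      group = c(rep("high", n_high), rep("low", n_low))
    )
  }
}

#' Simulate a gene family with planted group-diagnostic substitutions
#'
#' One consensus sequence per individual. At each planted position,
#' carrier high-group individuals (exactly `round(penetrance * n_high)` of
#' them) receive the high allele either homozygously or, at rate
#' `het_rate_high`, as the IUPAC heterozygous code for {high, low} — the
#' way Sanger consensus data represents heterozygosity in the polyploid
#' high producers. Non-carriers and the low group are fixed for the low
#' allele, except `het_rate_low` leakage. Background substitutions are
#' sprinkled independently elsewhere at `background_rate` per site.
#'
#' @param n_high,n_low group sizes (defaults: the 20/18 study design, with
#'   the eight birch species codes).
#' @param cds_length sequence length in bp (default 792, SABP2-like).
#' @param diagnostic tibble as [default_diagnostic_truth()].
#' @param het_rate_high fraction of carriers that are heterozygous.
#' @param het_rate_low fraction of low-group individuals with heterozygous
#'   leakage at planted positions.
#' @param background_rate per-site background substitution probability.
#' @param seed RNG seed; the output is a pure function of the arguments.
#' @return list with `sequences` (sequence tibble) and `truth` (planted
#'   positions incl. carrier ids per position, plus all parameters).
#' @examples
#' fam <- gen_gene_family(seed = 42)
#' nrow(fam$sequences)
#' @export
gen_gene_family <- function(n_high = 20L, n_low = 18L, cds_length = 792L,
                            diagnostic = default_diagnostic_truth(),
                            het_rate_high = 0.5, het_rate_low = 0,
                            background_rate = 5e-4, seed = 1L) {
  stopifnot(n_high >= 1, n_low >= 1, cds_length >= 1,
            het_rate_high >= 0, het_rate_high <= 1,
            het_rate_low >= 0, het_rate_low < 1,
            background_rate >= 0, background_rate < 1)
  if (nrow(diagnostic) > 0) {
    stopifnot(all(diagnostic$position >= 1 & diagnostic$position <= cds_length),
              all(diagnostic$penetrance > 0 & diagnostic$penetrance <= 1))
    if (any(round(diagnostic$penetrance * n_high) < 1)) {
      abort("penetrance unreachable: round(penetrance * n_high) < 1 carrier")
    }
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  inds <- family_individuals(n_high, n_low)
  hi_idx <- which(inds$group == "high")
  lo_idx <- which(inds$group == "low")
  backbone <- sample(bases, cds_length, replace = TRUE)
  backbone[diagnostic$position] <- diagnostic$low_allele
  seqs <- matrix(rep(backbone, nrow(inds)), nrow = nrow(inds), byrow = TRUE)
  # background substitutions at non-diagnostic sites
  if (background_rate > 0) {
    free_sites <- setdiff(seq_len(cds_length), diagnostic$position)
    for (i in seq_len(nrow(inds))) {
      hit <- free_sites[runif(length(free_sites)) < background_rate]
      if (length(hit) > 0) {
        seqs[i, hit] <- vapply(seqs[i, hit],
                               function(b) sample(setdiff(bases, b), 1), "")
      }
    }
  }
  # deterministic assignment (only background mutations are stochastic):
  # heterozygosity is position-structured, as in real Sanger consensus
  # data from the polyploid high producers, where specific marker
  # positions are heterozygous in nearly every carrier while others are
  # homozygous throughout: round(het_rate_high * n_positions) designated
  # positions (alternating across the panel) carry the {high, low} IUPAC
  # code in every carrier. Non-carriers (penetrance leakage) rotate from
  # the last high individual downward, one position at a time, so
  # leakage never stacks up in a single individual.
  carrier_ids <- vector("list", nrow(diagnostic))
  nh <- length(hi_idx)
  nc_pointer <- 0L  # rotation slots already consumed by non-carriers
  n_pos <- nrow(diagnostic)
  het_pos_idx <- integer(0)
  if (n_pos > 0) {
    n_het_pos <- round(het_rate_high * n_pos)
    alt_order <- c(seq.int(1L, n_pos, by = 2L),
                   if (n_pos > 1) seq.int(2L, n_pos, by = 2L))
    het_pos_idx <- alt_order[seq_len(n_het_pos)]
  }
  for (k in seq_len(n_pos)) {
    pos <- diagnostic$position[k]
    hi_a <- diagnostic$high_allele[k]; lo_a <- diagnostic$low_allele[k]
    het <- het_code(hi_a, lo_a)
    n_car <- round(diagnostic$penetrance[k] * nh)
    n_nc <- nh - n_car
    non_car_local <- integer(0)
    if (n_nc > 0) {
      non_car_local <- ((nc_pointer + seq_len(n_nc) - 1L) %% nh) + 1L
      non_car_local <- nh + 1L - non_car_local  # count down from the top
      nc_pointer <- nc_pointer + n_nc
    }
    carriers_local <- setdiff(seq_len(nh), non_car_local)
    carriers <- hi_idx[carriers_local]
    seqs[carriers, pos] <- if (k %in% het_pos_idx) het else hi_a
    if (length(non_car_local) > 0) seqs[hi_idx[non_car_local], pos] <- lo_a
    seqs[lo_idx, pos] <- lo_a
    n_leak <- round(het_rate_low * length(lo_idx))
    if (n_leak > 0) {
      leak <- tail(lo_idx, n_leak)
      seqs[leak, pos] <- het
    }
    carrier_ids[[k]] <- inds$individual_id[carriers]
  }
  sequences <- tibble(
    id = inds$individual_id,
    species_code = inds$species_code,
    group = inds$group,
    moltype = "dna",
    residues = apply(seqs, 1, paste, collapse = "")
  )
  list(
    sequences = sequences,
    truth = list(
      diagnostic = mutate(diagnostic, carriers = carrier_ids),
      n_high = n_high, n_low = n_low, cds_length = cds_length,
      het_rate_high = het_rate_high, het_rate_low = het_rate_low,
      background_rate = background_rate, seed = seed
    )
  )
}

#' Simulate promoter sequences with planted cis elements
#'
#' Generates one random promoter per species, scrubbed of chance matches
#' to the motif dictionary, then plants the requested number of
#' non-overlapping motif instances at recorded positions and strands.
#' Candidate promoters are redrawn until the scanner finds exactly the
#' planted instances, so planted counts are recovered without spurious
#' junction hits.
#'
#' @param species tibble with `species_code`, `group` (default: the eight
#'   birch species).
#' @param planted tibble with `species_code`, `motif`, `count`; defaults
#'   to the published contrast pattern of two TATA boxes in the *B. lenta*
#'   promoter versus one in every other species.
#' @param patterns motif dictionary (default: the packaged
#'   `motifs.yaml`).
#' @param length promoter length in bp (default 650, within the study's
#'   603-770 bp amplicon range).
#' @param seed RNG seed.
#' @param max_tries redraw attempts per promoter before giving up.
#' @return list with `sequences` (promoter tibble, ids
#'   `<species>_promoter`) and `truth` (tibble of planted instances:
#'   species_code, motif, position, strand, instance).
#' @export
gen_promoters <- function(species = distinct(.BIRCH_DESIGN[c("species_code", "group")]),
                          planted = NULL, patterns = read_motifs(mesa_example("motifs.yaml")),
                          length = 650L, seed = 1L, max_tries = 100L) {
  patterns <- as_pattern_tbl(patterns)
  if (is.null(planted)) {
    planted <- tibble(
      species_code = species$species_code,
      motif = "TATA-box",
      count = ifelse(species$species_code == "len", 2L, 1L)
    )
  }
  stopifnot(all(planted$motif %in% patterns$name))
  pat_len <- setNames(nchar(patterns$consensus), patterns$name)
  max_len <- max(c(pat_len, 1L))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  truth_rows <- list()
  seq_rows <- list()
  for (si in seq_len(nrow(species))) {
    sp <- species$species_code[si]
    want <- planted[planted$species_code == sp, , drop = FALSE]
    want <- want[rep(seq_len(nrow(want)), want$count), c("species_code", "motif")]
    need_bp <- sum(pat_len[want$motif]) + nrow(want)  # instances + 1bp spacers
    if (need_bp > length) abort(paste0("planted motifs do not fit in ", length, " bp for ", sp))
    placed <- NULL
    for (attempt in seq_len(max_tries)) {
      chars <- scrubbed_background(length, patterns, bases)
      res <- try_plant(chars, want$motif, patterns, pat_len)
      if (is.null(res)) next
      hits <- scan_motifs(paste(res$chars, collapse = ""), patterns)
      if (nrow(res$truth) == 0) {
        if (nrow(hits) == 0) { placed <- res; break }
        next
      }
      ok <- all(vapply(seq_len(nrow(res$truth)), function(r) {
        any(hits$motif_name == res$truth$motif[r] &
              hits$position == res$truth$position[r] &
              hits$strand == res$truth$strand[r])
      }, logical(1)))
      per_motif_pos <- hits |> distinct(.data$motif_name, .data$position) |> count(.data$motif_name)
      want_n <- count(res$truth, .data$motif, name = "n_want")
      exact <- nrow(per_motif_pos) == nrow(want_n) &&
        all(per_motif_pos$n[match(want_n$motif, per_motif_pos$motif_name)] == want_n$n_want)
      if (ok && exact) { placed <- res; break }
    }
    if (is.null(placed)) abort(paste0("could not place motifs cleanly for ", sp))
    seq_rows[[si]] <- tibble(
      id = paste0(sp, "_promoter"), species_code = sp,
      group = species$group[si], moltype = "dna",
      residues = paste(placed$chars, collapse = "")
    )
    if (nrow(placed$truth) > 0) {
      placed$truth$species_code <- sp
      truth_rows[[si]] <- placed$truth
    }
  }
  truth <- bind_rows(truth_rows)
  if (nrow(truth) == 0) {
    truth <- tibble(motif = character(0), position = integer(0),
                    strand = character(0), instance = character(0),
                    species_code = character(0))
  }
  list(
    sequences = bind_rows(seq_rows),
    truth = truth[c("species_code", "motif", "position", "strand", "instance")]
  )
}

# random background with no match to any dictionary pattern on either
# strand: re-randomize matched windows until clean
scrubbed_background <- function(length, patterns, bases, max_iter = 50L) {
  chars <- sample(bases, length, replace = TRUE)
  for (it in seq_len(max_iter)) {
    hits <- scan_motifs(paste(chars, collapse = ""), patterns)
    if (nrow(hits) == 0) return(chars)
    for (r in seq_len(nrow(hits))) {
      L <- nchar(hits$match[r])
      span <- hits$position[r]:(hits$position[r] + L - 1L)
      chars[span] <- sample(bases, L, replace = TRUE)
    }
  }
  chars
}

# instantiate consensus (sample a concrete base for each ambiguous symbol)
instantiate_consensus <- function(consensus) {
  paste(vapply(strsplit(consensus, "")[[1]],
               function(s) sample(.IUPAC_EXPANSION[[s]], 1), ""), collapse = "")
}

try_plant <- function(chars, motifs, patterns, pat_len) {
  n <- length(chars)
  occupied <- rep(FALSE, n)
  rows <- list()
  for (k in seq_along(motifs)) {
    mo <- motifs[k]
    L <- pat_len[[mo]]
    # candidate starts leaving a 1bp buffer around existing plantings
    free <- which(vapply(seq_len(n - L + 1L), function(p) {
      lo <- max(1L, p - 1L); hi <- min(n, p + L)
      !any(occupied[lo:hi])
    }, logical(1)))
    if (length(free) == 0) return(NULL)
    p <- free[sample.int(length(free), 1)]
    strand <- sample(c("+", "-"), 1)
    cons <- patterns$consensus[patterns$name == mo]
    inst <- instantiate_consensus(cons)
    fwd <- if (strand == "+") inst else revcomp(inst)
    chars[p:(p + L - 1L)] <- strsplit(fwd, "")[[1]]
    occupied[p:(p + L - 1L)] <- TRUE
    rows[[k]] <- tibble(motif = mo, position = p, strand = strand, instance = inst)
  }
  list(chars = chars, truth = bind_rows(rows) %||% tibble())
}

#' Default expression ground truth for the Ct-table generator
#'
#' Emulates the study's qPCR design: SAMT strongly expressed in the bark
#' of the two high-MeSA species (8-fold over leaf in *B. lenta*) and low
#' in the low producers; SABP2 indifferent between groups; two reference
#' genes at level 1.
#'
#' @return tibble with `species_code`, `group`, `tissue`, `gene`, `level`.
#' @export
default_expression_truth <- function() {
  grid <- tidyr::crossing(
    tibble(species_code = c("ale", "len", "pen", "uti"),
           group = c("high", "high", "low", "low")) ,
    tissue = c("leaf", "bark"),
    gene = c("SAMT", "SABP2")
  )
  grid |>
    mutate(level = dplyr::case_when(
      .data$gene == "SABP2" ~ 1,
      .data$species_code == "ale" & .data$tissue == "bark" ~ 8,
      .data$species_code == "ale" ~ 4,
      .data$species_code == "len" & .data$tissue == "bark" ~ 8,
      .data$species_code == "len" ~ 1,
      TRUE ~ 0.5
    ))
}

#' Simulate an RT-qPCR Ct table with known expression levels
#'
#' Ct = `base_ct` - log2(level) + Normal(0, `noise_sd`) per technical
#' replicate; reference genes are generated at level 1.
#'
#' @param levels ground-truth tibble as [default_expression_truth()].
#' @param reference_genes names of housekeeping genes to add at level 1.
#' @param n_bio,n_tech biological and technical replicates (default 3 and
#'   3, the study design).
#' @param noise_sd technical noise in cycles (default 0.3).
#' @param base_ct reference-gene baseline Ct.
#' @param seed RNG seed.
#' @return Ct tibble (see [read_ct_table()]) with attribute `truth`.
#' @export
gen_ct_table <- function(levels = default_expression_truth(),
                         reference_genes = c("ACT", "UBQ"),
                         n_bio = 3L, n_tech = 3L, noise_sd = 0.3,
                         base_ct = 20, seed = 1L) {
  stopifnot(all(levels$level > 0), n_bio >= 1, n_tech >= 1, noise_sd >= 0)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  conditions <- distinct(levels[c("species_code", "tissue")])
  ref_levels <- tidyr::crossing(conditions, gene = reference_genes)
  ref_levels$level <- 1
  all_levels <- bind_rows(levels[c("species_code", "tissue", "gene", "level")], ref_levels)
  rows <- list()
  ri <- 1L
  for (ci in seq_len(nrow(conditions))) {
    sp <- conditions$species_code[ci]; ti <- conditions$tissue[ci]
    lv <- all_levels[all_levels$species_code == sp & all_levels$tissue == ti, ]
    for (b in seq_len(n_bio)) {
      sid <- paste(sp, ti, b, sep = "_")
      for (g in seq_len(nrow(lv))) {
        ct <- base_ct - log2(lv$level[g]) + rnorm(n_tech, 0, noise_sd)
        rows[[ri]] <- tibble(
          sample_id = sid, species_code = sp, tissue = ti,
          gene = lv$gene[g], replicate = seq_len(n_tech), ct = ct
        )
        ri <- ri + 1L
      }
    }
  }
  out <- bind_rows(rows)
  attr(out, "truth") <- list(levels = levels, reference_genes = reference_genes,
                             n_bio = n_bio, n_tech = n_tech,
                             noise_sd = noise_sd, base_ct = base_ct, seed = seed)
  out
}
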