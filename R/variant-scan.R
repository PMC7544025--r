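# Group-diagnostic SNP discovery from IUPAC consensus calls.
#
# A base a is diagnostic for the target group at a position when
#   (i)  no contrast-group individual carries a (a is outside the IUPAC
#        expansion of every non-missing contrast call),
#   (ii) the fraction of target-group individuals carrying a (within
#        heterozygous codes counts as carrying) is at least the penetrance
#        threshold theta, and
#   (iii) optionally, the contrast group is fixed for a single homozygous
#        base at that position.
# Heterozygous consensus codes are what make this work on Sanger data from
# polyploid birches: an S call in the high group is compatible with
# diagnostic allele C even though the low group is fixed for G.

#' Convert a nucleotide alignment to an allele matrix
#'
#' One matrix row is produced per polymorphic column (a column where at
#' least two distinct non-missing calls occur), or per explicitly requested
#' position. Column indices are 1-based alignment coordinates.
#'
#' @param alignment a nucleotide [as_alignment()] tibble whose records carry
#'   groups.
#' @param positions optional integer vector of 1-based columns to extract
#'   (monomorphic columns are then retained).
#' @return an [allele_matrix()]; zero-row when no column is polymorphic and
#'   `positions` is `NULL`.
#' @export
alignment_to_matrix <- function(alignment, positions = NULL) {
  alignment <- as_alignment(alignment)
  if (any(alignment$moltype != "dna")) {
    abort("alignment_to_matrix requires a nucleotide alignment")
  }
  m <- alignment_matrix(alignment)
  m[m == "-"] <- .MISSING_CALL
  len <- ncol(m)
  if (is.null(positions)) {
    keep <- vapply(seq_len(len), function(j) {
      calls <- m[, j]
      length(unique(calls[calls != .MISSING_CALL])) >= 2
    }, logical(1))
    positions <- which(keep)
  } else {
    positions <- as.integer(positions)
    if (any(positions < 1 | positions > len)) abort("requested position outside alignment")
  }
  if (length(positions) == 0) {
    out <- tibble(
      position = integer(0), individual_id = character(0),
      species_code = character(0), group = character(0), call = character(0)
    )
    class(out) <- c("allele_matrix", class(out))
    return(out)
  }
  long <- tibble(
    position = rep(positions, each = nrow(m)),
    individual_id = rep(alignment$id, times = length(positions)),
    species_code = rep(alignment$species_code, times = length(positions)),
    group = rep(alignment$group, times = length(positions)),
    call = as.vector(m[, positions])
  )
  allele_matrix(long)
}

resolve_subset <- function(matrix, subset) {
  if (is.null(subset)) return(rep(TRUE, nrow(matrix)))
  if (subset %in% .VALID_GROUPS) return(matrix$group == subset)
  if (subset %in% unique(matrix$species_code)) return(matrix$species_code == subset)
  abort(paste0("unknown subset ", sQuote(subset), ": not a group or species code"))
}

#' Per-position heterozygosity profile
#'
#' Counts heterozygous consensus calls (IUPAC codes denoting two or more
#' bases) per position within a group or species subset. The published
#' pattern this profiles: heterozygous sites concentrate in the high
#' MeSA-producing species while the low producers are homozygous
#' throughout.
#'
#' @param matrix an [allele_matrix()].
#' @param subset `NULL` (all individuals), a group name (`"high"`/`"low"`),
#'   or a species code present in the matrix.
#' @return tibble with `position`, `n_calls` (non-missing), `n_het`, and
#'   `any_het`; attribute `total_het` holds the grand total and
#'   `het_positions` the positions with at least one heterozygous call.
#' @examples
#' m <- read_allele_matrix(mesa_example("table2_sabp2.tsv"))
#' heterozygosity_profile(m, subset = "low")
#' @export
heterozygosity_profile <- function(matrix, subset = NULL) {
  stopifnot(inherits(matrix, "allele_matrix") || is.data.frame(matrix))
  keep <- resolve_subset(matrix, subset)
  sub <- as_tibble(matrix)[keep, ]
  prof <- sub |>
    group_by(.data$position) |>
    summarise(
      n_calls = sum(.data$call != .MISSING_CALL),
      n_het = sum(is_het_call(.data$call)),
      .groups = "drop"
    ) |>
    mutate(any_het = .data$n_het > 0) |>
    arrange(.data$position)
  attr(prof, "subset") <- subset %||% "all"
  attr(prof, "total_het") <- sum(prof$n_het)
  attr(prof, "het_positions") <- prof$position[prof$any_het]
  prof
}

#' Discover group-diagnostic SNP markers
#'
#' Scans every (position, allele) pair for bases diagnostic of the target
#' group under the penetrance threshold `theta`. Missing calls (`"."`) are
#' excluded from denominators; `N` calls count as carrying every base, so
#' they can defeat contrast-absence for the contrast group but never help
#' the target group discriminate (they are flagged upstream by
#' [expand_iupac()]).
#'
#' At most one marker is reported per position: the highest-penetrance
#' qualifying allele, ties broken alphabetically.
#'
#' @param matrix an [allele_matrix()] with at least one individual in each
#'   of the target and contrast groups.
#' @param target_group `"high"` or `"low"`.
#' @param theta minimum fraction of target individuals that must carry the
#'   allele, in (0, 1]. Default 0.9 — strict enough to exclude
#'   non-specific positions yet tolerant of one or two non-carrying
#'   individuals in a ~20-individual group, which formalizes "prominent"
#'   group specificity.
#' @param require_contrast_fixed if `TRUE` (default), additionally require
#'   all non-missing contrast calls to be one identical homozygous base.
#' @return tibble classed `diagnostic_markers` with columns `position`,
#'   `allele`, `target_group`, `carriers_target`, `n_target`,
#'   `carriers_contrast`, `n_contrast`, `penetrance`, `contrast_allele`
#'   (`NA` when the contrast is not fixed), sorted by position.
#' @examples
#' m <- read_allele_matrix(mesa_example("table2_sabp2.tsv"))
#' find_diagnostic_snps(m, "high", theta = 0.9)
#' @export
find_diagnostic_snps <- function(matrix, target_group = "high", theta = 0.9,
                                 require_contrast_fixed = TRUE) {
  stopifnot(theta > 0, theta <= 1)
  if (!target_group %in% c("high", "low")) abort("target_group must be 'high' or 'low'")
  contrast_group <- setdiff(c("high", "low"), target_group)
  tab <- as_tibble(matrix)
  if (sum(tab$group == target_group) == 0 || sum(tab$group == contrast_group) == 0) {
    abort(paste0("both groups must be non-empty (missing ", contrast_group,
                 " or ", target_group, " individuals)"))
  }
  positions <- sort(unique(tab$position))
  rows <- lapply(positions, function(pos) {
    at <- tab[tab$position == pos, ]
    tgt <- at$call[at$group == target_group]
    ctr <- at$call[at$group == contrast_group]
    tgt_obs <- tgt[tgt != .MISSING_CALL]
    ctr_obs <- ctr[ctr != .MISSING_CALL]
    if (length(tgt_obs) == 0 || length(ctr_obs) == 0) return(NULL)
    contrast_fixed_base <- if (length(unique(ctr_obs)) == 1 &&
                               length(iupac_alleles(ctr_obs[1])) == 1) {
      ctr_obs[1]
    } else {
      NA_character_
    }
    if (require_contrast_fixed && is.na(contrast_fixed_base)) return(NULL)
    cand <- lapply(c("A", "C", "G", "T"), function(a) {
      if (any(carries_base(ctr_obs, a))) return(NULL)
      carriers <- sum(carries_base(tgt_obs, a))
      pen <- carriers / length(tgt_obs)
      if (pen < theta) return(NULL)
      tibble(
        position = pos, allele = a, target_group = target_group,
        carriers_target = carriers, n_target = length(tgt_obs),
        carriers_contrast = 0L, n_contrast = length(ctr_obs),
        penetrance = pen, contrast_allele = contrast_fixed_base
      )
    })
    cand <- bind_rows(cand)
    if (nrow(cand) == 0) return(NULL)
    # one marker per position: highest penetrance, alphabetical tie-break
    cand[order(-cand$penetrance, cand$allele), ][1, ]
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(
      position = integer(0), allele = character(0), target_group = character(0),
      carriers_target = integer(0), n_target = integer(0),
      carriers_contrast = integer(0), n_contrast = integer(0),
      penetrance = double(0), contrast_allele = character(0)
    )
  }
  out <- arrange(out, .data$position)
  class(out) <- c("diagnostic_markers", class(out))
  attr(out, "theta") <- theta
  attr(out, "require_contrast_fixed") <- require_contrast_fixed
  out
}

#' Classify an individual against a diagnostic marker panel
#'
#' Votes at each panel position covered by the individual's calls: a vote
#' for the target group when the call carries the diagnostic allele. The
#' verdict is `target` when more than half the covered positions vote for
#' the target, `contrast` when fewer than half do, and `ambiguous` at an
#' exact tie or when fewer than 3 panel positions are covered.
#'
#' @param panel a `diagnostic_markers` tibble from [find_diagnostic_snps()].
#' @param calls named character vector (names = positions, values = IUPAC
#'   calls) or a tibble with `position` and `call` columns.
#' @param id individual label carried through to the result.
#' @return one-row tibble: `individual_id`, `votes_for_target`, `covered`,
#'   `panel_size`, `verdict`.
#' @export
classify_individual <- function(panel, calls, id = "individual") {
  if (!is.data.frame(panel) || nrow(panel) == 0) abort("empty marker panel")
  if (is.data.frame(calls)) {
    calls <- setNames(calls$call, calls$position)
  }
  pos_chr <- as.character(panel$position)
  covered_idx <- which(pos_chr %in% names(calls))
  if (length(covered_idx) == 0) abort("calls cover no panel position")
  votes <- sum(vapply(covered_idx, function(i) {
    cc <- toupper(calls[[pos_chr[i]]])
    cc != .MISSING_CALL && panel$allele[i] %in% iupac_alleles(cc)
  }, logical(1)))
  covered <- length(covered_idx)
  frac <- votes / covered
  verdict <- if (covered < 3 || frac == 0.5) {
    "ambiguous"
  } else if (frac > 0.5) "target" else "contrast"
  tibble(
    individual_id = id, votes_for_target = as.integer(votes),
    covered = as.integer(covered), panel_size = nrow(panel),
    verdict = verdict
  )
}

#' Classify every individual of an allele matrix against a panel
#'
#' @param panel a `diagnostic_markers` tibble.
#' @param matrix an [allele_matrix()].
#' @return tibble with one classification row per individual plus its
#'   species and true group (for validation summaries).
#' @export
classify_matrix <- function(panel, matrix) {
  inds <- matrix_individuals(matrix)
  tab <- as_tibble(matrix)
  res <- lapply(seq_len(nrow(inds)), function(i) {
    sub <- tab[tab$individual_id == inds$individual_id[i], ]
    classify_individual(panel, setNames(sub$call, sub$position),
                        id = inds$individual_id[i])
  })
  left_join(bind_rows(res), inds, by = "individual_id")
}

#' @export
tidy.diagnostic_markers <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @export
glance.diagnostic_markers <- function(x, ...) {
  tibble(
    n_markers = nrow(x),
    theta = attr(x, "theta"),
    require_contrast_fixed = attr(x, "require_contrast_fixed"),
    mean_penetrance = if (nrow(x)) mean(x$penetrance) else NA_real_
  )
}
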