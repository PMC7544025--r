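# Consensus-pattern scanning of promoter sequences on both strands, and
# per-species cis-element frequency tables for between-group comparison.
# Matching uses IUPAC superset semantics: a pattern symbol matches a
# sequence base when the symbol's expansion set contains that base, so
# e.g. TATAWAW matches TATATAT and TATAAAA.

#' Read a motif dictionary from YAML
#'
#' The YAML holds a `motifs` list of `{name, consensus}` entries with
#' consensus strings in IUPAC nucleotide code. A small editable dictionary
#' of published consensus strings ships with the package
#' (`mesa_example("motifs.yaml")`).
#'
#' @param path YAML file path.
#' @return tibble with columns `name`, `consensus`.
#' @export
read_motifs <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  y <- yaml::read_yaml(path)
  entries <- y$motifs %||% y
  out <- bind_rows(lapply(entries, function(e) tibble(name = e$name, consensus = toupper(e$consensus))))
  bad <- out$consensus[!vapply(strsplit(out$consensus, ""),
                               function(ch) all(ch %in% .IUPAC_CODES), logical(1))]
  if (length(bad) > 0) abort(paste0("invalid consensus: ", paste(bad, collapse = ", ")))
  out
}

as_pattern_tbl <- function(patterns) {
  if (is.data.frame(patterns)) {
    stopifnot(all(c("name", "consensus") %in% names(patterns)))
    return(as_tibble(patterns))
  }
  tibble(name = names(patterns), consensus = toupper(unname(patterns)))
}

# all 1-based start positions of an IUPAC consensus on one strand of an
# unambiguous uppercase character vector
match_consensus <- function(chars, consensus) {
  pat <- strsplit(consensus, "")[[1]]
  L <- length(pat); n <- length(chars)
  if (n < L) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (k in seq_len(L)) {
    allowed <- .IUPAC_EXPANSION[[pat[k]]]
    ok <- ok & (chars[k:(n - L + k)] %in% allowed)
    if (!any(ok)) return(integer(0))
  }
  which(ok)
}

#' Scan a promoter sequence for consensus motifs on both strands
#'
#' Scans the forward sequence and its reverse complement; minus-strand
#' hits are reported as the forward-coordinate position of the match start
#' (leftmost base of the matched region on the forward strand is
#' `position`, and the hit string is the minus-strand reading). All
#' overlapping hits are reported, sorted by position then strand.
#'
#' @param seq single ungapped DNA string.
#' @param patterns motif dictionary tibble (`name`, `consensus`) or a
#'   named character vector of consensus strings.
#' @return tibble with `motif_name`, `position` (1-based forward
#'   coordinates), `strand` (`"+"`/`"-"`), `match` (the matched substring
#'   as read on the hit strand), and `label` in the compact
#'   `"<position><strand>"` notation.
#' @examples
#' scan_motifs("GGACGTGG", c(ABRE = "ACGTG"))
#' @export
scan_motifs <- function(seq, patterns) {
  stopifnot(length(seq) == 1)
  seq <- toupper(seq)
  if (grepl("-", seq, fixed = TRUE)) abort("sequence must be ungapped")
  patterns <- as_pattern_tbl(patterns)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  rc_seq <- revcomp(seq)
  rc_chars <- strsplit(rc_seq, "")[[1]]
  rows <- pmap(patterns, function(name, consensus) {
    L <- nchar(consensus)
    fwd <- match_consensus(chars, consensus)
    rev_hits <- match_consensus(rc_chars, consensus)
    # position p on the reverse complement corresponds to forward start
    # n - p - L + 2
    out <- list()
    if (length(fwd) > 0) {
      out$f <- tibble(
        motif_name = name, position = fwd, strand = "+",
        match = substring(seq, fwd, fwd + L - 1L)
      )
    }
    if (length(rev_hits) > 0) {
      out$r <- tibble(
        motif_name = name, position = n - rev_hits - L + 2L, strand = "-",
        match = substring(rc_seq, rev_hits, rev_hits + L - 1L)
      )
    }
    bind_rows(out)
  })
  hits <- bind_rows(rows)
  if (nrow(hits) == 0) {
    hits <- tibble(motif_name = character(0), position = integer(0),
                   strand = character(0), match = character(0))
  }
  hits <- arrange(hits, .data$position, .data$strand, .data$motif_name)
  hits$position <- as.integer(hits$position)
  mutate(hits, label = paste0(.data$position, .data$strand))
}

#' Per-species cis-element frequency table
#'
#' Counts motif hits (both strands) per species promoter and summarises by
#' group, reporting also the motifs whose mean per-promoter count differs
#' between the groups.
#'
#' @param promoters sequence tibble (one promoter per species) with `id`,
#'   `species_code`, `group`, `residues` — e.g. from [read_fasta()] or
#'   [gen_promoters()].
#' @param patterns motif dictionary (see [scan_motifs()]).
#' @return tibble classed `motif_frequency`: one row per species, columns
#'   `species_code`, `group`, then one count column per motif. Attributes:
#'   `group_totals` (summed counts per group), `differences` (per-motif
#'   group means and their difference), `hits` (the full hit table).
#' @export
motif_frequency_table <- function(promoters, patterns) {
  stopifnot(nrow(promoters) >= 1)
  patterns <- as_pattern_tbl(patterns)
  hit_rows <- lapply(seq_len(nrow(promoters)), function(i) {
    h <- scan_motifs(promoters$residues[i], patterns)
    if (nrow(h) == 0) return(NULL)
    h$species_code <- promoters$species_code[i]
    h$group <- promoters$group[i]
    h$id <- promoters$id[i]
    h
  })
  hits <- bind_rows(hit_rows)
  base <- tidyr::crossing(
    species_code = promoters$species_code,
    motif_name = patterns$name
  )
  counts <- if (nrow(hits) > 0) {
    count(hits, .data$species_code, .data$motif_name, name = "count")
  } else {
    tibble(species_code = character(0), motif_name = character(0), count = integer(0))
  }
  long <- left_join(base, counts, by = c("species_code", "motif_name"))
  long$count[is.na(long$count)] <- 0L
  meta <- distinct(promoters[c("species_code", "group")])
  long <- left_join(long, meta, by = "species_code")
  wide <- pivot_wider(long, names_from = "motif_name", values_from = "count")
  wide <- wide[match(unique(promoters$species_code), wide$species_code), ]
  motif_cols <- patterns$name
  group_totals <- long |>
    group_by(.data$group, .data$motif_name) |>
    summarise(total = sum(.data$count), .groups = "drop")
  gmeans <- long |>
    filter(.data$group %in% c("high", "low")) |>
    group_by(.data$motif_name, .data$group) |>
    summarise(mean_count = mean(.data$count), .groups = "drop") |>
    pivot_wider(names_from = "group", values_from = "mean_count")
  for (g in c("high", "low")) if (!g %in% names(gmeans)) gmeans[[g]] <- NA_real_
  differences <- gmeans |>
    mutate(difference = .data$high - .data$low) |>
    filter(!is.na(.data$difference) & abs(.data$difference) > 0)
  out <- wide[c("species_code", "group", motif_cols)]
  class(out) <- c("motif_frequency", class(out))
  attr(out, "group_totals") <- group_totals
  attr(out, "differences") <- differences
  attr(out, "hits") <- hits
  out
}
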