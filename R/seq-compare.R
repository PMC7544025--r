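# Protein-level comparison: CDS translation, global alignment with affine
# gap penalties (Needleman-Wunsch/Gotoh), and verification of annotated
# functional residues (e.g. the Ser-Asp-His catalytic triad of the SABP2
# esterase) across a protein alignment.

#' Translate a coding sequence
#'
#' Standard genetic code, read from the given frame offset; a single
#' trailing stop codon is dropped. Incomplete trailing codons are ignored.
#'
#' @param cds DNA string (unambiguous A/C/G/T).
#' @param frame 0, 1 or 2: offset of the first codon.
#' @param allow_internal_stop if `TRUE`, internal stops are emitted as
#'   `"X"` instead of raising an error.
#' @return protein string.
#' @examples
#' translate_cds("ATGGCTTAA")
#' @export
translate_cds <- function(cds, frame = 0L, allow_internal_stop = FALSE) {
  stopifnot(length(cds) == 1, frame %in% 0:2)
  cds <- toupper(cds)
  chars <- strsplit(cds, "")[[1]]
  bad <- which(!(chars %in% c("A", "C", "G", "T")))
  if (length(bad) > 0) {
    abort(paste0("non-DNA character ", sQuote(chars[bad[1]]), " at offset ", bad[1]))
  }
  body <- substring(cds, frame + 1L, nchar(cds))
  n_codon <- nchar(body) %/% 3L
  if (n_codon < 1) abort("sequence shorter than one codon after frame offset")
  starts <- (seq_len(n_codon) - 1L) * 3L + 1L
  codons <- substring(body, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (aa[n_codon] == "*") aa <- aa[-n_codon]
  internal <- which(aa == "*")
  if (length(internal) > 0) {
    if (!allow_internal_stop) {
      abort(paste0("internal stop codon at codon ", internal[1]))
    }
    aa[internal] <- "X"
  }
  paste(aa, collapse = "")
}

# substitution score lookup ---------------------------------------------------

substitution_matrix <- function(name) {
  if (is.matrix(name)) return(name)
  known <- c("BLOSUM62", "BLOSUM45", "BLOSUM50", "BLOSUM80", "BLOSUM100",
             "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (!name %in% known) abort(paste0("unknown substitution matrix ", sQuote(name)))
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh dynamic programming over three states (match,
#' gap-in-a, gap-in-b) with end-to-end gap penalties. Traceback ties are
#' resolved deterministically, preferring diagonal, then a gap in the
#' second sequence.
#'
#' Percent identity is computed over alignment columns excluding terminal
#' gap columns; coverage is the fraction of query (`a`) residues inside the
#' non-terminal-gap region, following the query-relative convention of
#' BLAST-style reports.
#'
#' @param a,b protein (or other) sequences as single strings.
#' @param substitution substitution matrix name (e.g. `"BLOSUM62"`, the
#'   default) or a scoring matrix with residue dimnames.
#' @param gap_open penalty for opening a gap (negative).
#' @param gap_extend penalty per gap position (negative).
#' @return list with `score`, `aligned_a`, `aligned_b`, and a `result`
#'   tibble (`identity_pct`, `coverage_pct`, `aligned_length`, `score`).
#' @examples
#' global_align("HEAGAWGHEE", "PAWHEAE")$result
#' @export
global_align <- function(a, b, substitution = "BLOSUM62",
                         gap_open = -10, gap_extend = -0.5) {
  stopifnot(nzchar(a), nzchar(b), gap_open <= 0, gap_extend <= 0)
  S <- substitution_matrix(substitution)
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  missing_res <- setdiff(unique(c(av, bv)), rownames(S))
  if (length(missing_res) > 0) {
    abort(paste0("residue(s) absent from substitution matrix: ",
                 paste(missing_res, collapse = ", ")))
  }
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  # M: a[i] aligned to b[j]; X: gap in b (a consumed); Y: gap in a (b consumed)
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1); Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- gap_open + (i - 2) * gap_extend
  for (j in 2:(m + 1)) Y[1, j] <- gap_open + (j - 2) * gap_extend
  for (i in 2:(n + 1)) {
    srow <- S[av[i - 1], bv]
    for (j in 2:(m + 1)) {
      s <- srow[j - 1]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + gap_open, X[i - 1, j] + gap_extend,
                     Y[i - 1, j] + gap_open)
      Y[i, j] <- max(M[i, j - 1] + gap_open, Y[i, j - 1] + gap_extend,
                     X[i, j - 1] + gap_open)
    }
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  # traceback, diagonal preferred, then gap in b (vertical), then gap in a
  i <- n; j <- m
  state <- c("M", "X", "Y")[which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))]
  pa <- character(0); pb <- character(0)
  while (i > 0 || j > 0) {
    if (state == "M") {
      pa <- c(av[i], pa); pb <- c(bv[j], pb)
      here <- M[i + 1, j + 1] - S[av[i], bv[j]]
      prev <- c(M = M[i, j], X = X[i, j], Y = Y[i, j])
      state <- names(prev)[which(abs(prev - here) < 1e-9)][1]
      i <- i - 1; j <- j - 1
    } else if (state == "X") {
      pa <- c(av[i], pa); pb <- c("-", pb)
      here <- X[i + 1, j + 1]
      prev <- c(M = M[i, j + 1] + gap_open, X = X[i, j + 1] + gap_extend,
                Y = Y[i, j + 1] + gap_open)
      state <- names(prev)[which(abs(prev - here) < 1e-9)][1]
      i <- i - 1
    } else {
      pa <- c("-", pa); pb <- c(bv[j], pb)
      here <- Y[i + 1, j + 1]
      prev <- c(M = M[i + 1, j] + gap_open, Y = Y[i + 1, j] + gap_extend,
                X = X[i + 1, j] + gap_open)
      state <- names(prev)[which(abs(prev - here) < 1e-9)][1]
      j <- j - 1
    }
    if (i == 0 && j == 0) break
    if (i == 0) state <- "Y"
    if (j == 0) state <- "X"
  }
  aligned_a <- paste(pa, collapse = ""); aligned_b <- paste(pb, collapse = "")
  stats <- alignment_identity_stats(pa, pb, query_len = n)
  list(
    score = score, aligned_a = aligned_a, aligned_b = aligned_b,
    result = tibble(
      identity_pct = stats$identity_pct, coverage_pct = stats$coverage_pct,
      aligned_length = stats$aligned_length, score = score
    )
  )
}

alignment_identity_stats <- function(pa, pb, query_len) {
  gap_a <- pa == "-"; gap_b <- pb == "-"
  nongap <- which(!(gap_a | gap_b))
  L <- length(pa)
  if (length(nongap) == 0) {
    return(list(identity_pct = 0, coverage_pct = 0, aligned_length = 0L))
  }
  # columns excluding terminal gap runs: first to last column where both
  # sequences have started/not yet ended
  core_start <- max(min(which(!gap_a)), min(which(!gap_b)))
  core_end <- min(max(which(!gap_a)), max(which(!gap_b)))
  core <- core_start:core_end
  matches <- sum(pa[core] == pb[core] & !gap_a[core])
  identity <- 100 * matches / length(core)
  cov <- 100 * sum(!gap_a[core]) / query_len
  list(identity_pct = identity, coverage_pct = cov, aligned_length = length(core))
}

#' Check conserved residues across a protein alignment
#'
#' Maps annotated residue positions on an ungapped reference protein
#' through the reference row's gaps to alignment columns, then checks every
#' other sequence for the expected residue at those columns.
#'
#' @param alignment protein [as_alignment()] containing the reference.
#' @param annotation list with elements `name`, `reference` (id of the
#'   reference row), and `residues`: a data frame / list of `{pos, aa}`
#'   giving 1-based residue indices on the ungapped reference and the
#'   expected amino acid. [read_residue_annotation()] builds this from
#'   YAML.
#' @return tibble with one row per (sequence, annotated position):
#'   `id`, `ref_pos`, `column`, `expected`, `observed`, `pass`; plus a
#'   summary attribute `conserved_counts` (per-sequence number of conserved
#'   positions).
#' @export
check_residues <- function(alignment, annotation) {
  alignment <- as_alignment(alignment)
  ref_id <- annotation$reference
  if (!ref_id %in% alignment$id) {
    abort(paste0("reference ", sQuote(ref_id), " not in alignment"))
  }
  res <- as_tibble(annotation$residues)
  stopifnot(all(c("pos", "aa") %in% names(res)))
  if (any(diff(res$pos) <= 0)) abort("annotation positions must be strictly increasing")
  ref_row <- strsplit(alignment$residues[alignment$id == ref_id], "")[[1]]
  # residue index of each alignment column on the ungapped reference
  residue_index <- cumsum(ref_row != "-")
  ref_len <- residue_index[length(residue_index)]
  if (any(res$pos > ref_len)) {
    abort(paste0("annotation position ", res$pos[res$pos > ref_len][1],
                 " beyond reference length ", ref_len))
  }
  cols <- vapply(res$pos, function(p) which(residue_index == p & ref_row != "-")[1],
                 integer(1))
  rows <- lapply(seq_len(nrow(alignment)), function(i) {
    chars <- strsplit(alignment$residues[i], "")[[1]]
    tibble(
      id = alignment$id[i],
      ref_pos = res$pos,
      column = cols,
      expected = toupper(res$aa),
      observed = chars[cols],
      pass = chars[cols] == toupper(res$aa)
    )
  })
  out <- bind_rows(rows)
  counts <- out |>
    group_by(.data$id) |>
    summarise(conserved = sum(.data$pass), n_checked = n(), .groups = "drop")
  attr(out, "conserved_counts") <- counts
  attr(out, "annotation_name") <- annotation$name %||% "annotation"
  out
}

#' Read a residue annotation from YAML
#'
#' Expected YAML fields: `name`, `reference`, optional `kind`, and
#' `residues` as a list of `{pos, aa}` entries.
#'
#' @param path YAML file path.
#' @return annotation list consumable by [check_residues()].
#' @export
read_residue_annotation <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$reference), !is.null(y$residues))
  y$residues <- bind_rows(lapply(y$residues, as_tibble))
  y
}
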