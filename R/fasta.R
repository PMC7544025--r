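# Sequence records are carried as tibbles with one row per sequence:
# columns id, species_code, group, moltype, residues. Equal-length record
# sets double as alignments (see `as_alignment()`).

.VALID_GROUPS <- c("high", "low", "unassigned")

#' Default species-to-group assignment for the birch study system
#'
#' Maps the three-letter species codes of the eight *Betula* species to
#' their MeSA production group: the constitutive (high) producers
#' *B. alleghaniensis* (ale), *B. lenta* (len), *B. grossa* (bg) and
#' *B. medwediewii* (med) versus the low producers *B. pendula* (pen),
#' *B. utilis* (uti), *B. nana* (nan) and *B. alnoides* (aln).
#'
#' @return named character vector: species code -> `"high"`/`"low"`.
#' @export
betula_group_map <- function() {
  c(ale = "high", len = "high", bg = "high", med = "high",
    pen = "low", uti = "low", nan = "low", aln = "low")
}

seq_alphabet <- function(moltype) {
  if (moltype == "dna") c(.IUPAC_CODES, "-") else .PROTEIN_ALPHABET
}

validate_residues <- function(id, residues, moltype) {
  alphabet <- seq_alphabet(moltype)
  for (i in seq_along(residues)) {
    if (!nzchar(residues[[i]])) {
      abort(paste0("record ", sQuote(id[[i]]), ": empty sequence"))
    }
    chars <- strsplit(residues[[i]], "")[[1]]
    bad <- which(!(chars %in% alphabet))
    if (length(bad) > 0) {
      abort(paste0(
        "record ", sQuote(id[[i]]), ": illegal ", moltype, " character ",
        sQuote(chars[bad[1]]), " at offset ", bad[1]
      ))
    }
  }
  invisible(TRUE)
}

# derive species code from a record id of the form "<species>_<n>" (or a
# plain species prefix); returns "" when no match against the map
species_from_id <- function(id, species_map) {
  prefix <- sub("_.*$", "", id)
  ifelse(prefix %in% names(species_map), prefix, "")
}

new_seq_tbl <- function(id, residues, moltype, species_map = NULL) {
  if (anyDuplicated(id)) {
    dup <- id[duplicated(id)][1]
    abort(paste0("duplicate sequence id: ", sQuote(dup)))
  }
  residues <- unname(toupper(residues))
  validate_residues(id, residues, moltype)
  species_map <- species_map %||% character(0)
  species <- species_from_id(id, species_map)
  group <- ifelse(species == "", "unassigned", unname(species_map[species]))
  group[is.na(group)] <- "unassigned"
  tibble(
    id = id,
    species_code = species,
    group = group,
    moltype = moltype,
    residues = residues
  )
}

#' Read a FASTA file into a sequence tibble
#'
#' @param path path to a FASTA file (wrapped or unwrapped).
#' @param moltype `"dna"` or `"protein"`; residues are validated against the
#'   corresponding IUPAC alphabet.
#' @param species_map optional named character vector mapping species-code
#'   id prefixes to groups (`"high"`/`"low"`), e.g. [betula_group_map()].
#'   Records whose id prefix (up to the first underscore) is not in the map
#'   are assigned group `"unassigned"`.
#' @return tibble with columns `id`, `species_code`, `group`, `moltype`,
#'   `residues`.
#' @examples
#' tf <- tempfile(fileext = ".fna")
#' writeLines(c(">pen_1", "ACGT"), tf)
#' read_fasta(tf, "dna", betula_group_map())
#' @export
read_fasta <- function(path, moltype = c("dna", "protein"), species_map = NULL) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA ", path, ": ", conditionMessage(e)))
  )
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  new_seq_tbl(ids, as.character(set), moltype, species_map)
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs sequence tibble as returned by [read_fasta()].
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  set <- Biostrings::BStringSet(setNames(seqs$residues, seqs$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Treat a set of equal-length sequence records as an alignment
#'
#' Validates the alignment invariants (at least two records, all the same
#' length) and returns the tibble with class `mesa_alignment`.
#'
#' @param seqs sequence tibble.
#' @return the validated tibble, classed `mesa_alignment` with an
#'   `aln_length` attribute.
#' @export
as_alignment <- function(seqs) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  if (nrow(seqs) < 2) abort("an alignment needs at least 2 records")
  lens <- nchar(seqs$residues)
  if (length(unique(lens)) != 1) {
    abort("alignment records differ in length; align them first")
  }
  if (lens[1] < 1) abort("alignment has zero columns")
  out <- as_tibble(seqs)
  class(out) <- c("mesa_alignment", class(out))
  attr(out, "aln_length") <- unname(lens[1])
  out
}

alignment_length <- function(aln) {
  attr(aln, "aln_length") %||% unique(nchar(aln$residues))
}

# character matrix view (rows = records, columns = alignment columns)
alignment_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$residues, ""))
  rownames(m) <- aln$id
  m
}
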