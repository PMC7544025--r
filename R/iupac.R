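# IUPAC nucleotide ambiguity codes. Sanger sequencing of diploid/polyploid
# templates reports heterozygous sites as ambiguity codes in the consensus
# call, so these expansions are the data model for every allele-level
# computation in the package.

.IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.IUPAC_CODES <- names(.IUPAC_EXPANSION)
.MISSING_CALL <- "."

# complement map covering all ambiguity codes plus gap
.DNA_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N", "-" = "-", "." = "."
)

.PROTEIN_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "-", "*")

#' Expand IUPAC nucleotide codes into allele calls
#'
#' Each single-character IUPAC code is expanded into the set of nucleotides
#' it denotes, and classified as homozygous (one allele), heterozygous
#' (two or more alleles) or missing (`"."`). `N` expands to all four bases
#' and, while formally heterozygous, is flagged uninformative: it can never
#' provide evidence for group contrast because it is compatible with every
#' allele.
#'
#' @param code character vector of single IUPAC characters (or `"."`).
#' @return A tibble with one row per input code: `code`, `alleles`
#'   (list-column of character vectors), `n_alleles`, `zygosity`
#'   (`"homozygous"`, `"heterozygous"` or `"missing"`), and `uninformative`
#'   (`TRUE` for `N` and `"."`).
#' @examples
#' expand_iupac(c("S", "A", "N", "."))
#' @export
expand_iupac <- function(code) {
  stopifnot(is.character(code))
  bad <- setdiff(unique(code), c(.IUPAC_CODES, .MISSING_CALL))
  if (length(bad) > 0) {
    abort(paste0("not an IUPAC nucleotide code: ", paste(sQuote(bad), collapse = ", ")))
  }
  alleles <- map(code, function(cc) {
    if (cc == .MISSING_CALL) character(0) else .IUPAC_EXPANSION[[cc]]
  })
  n_alleles <- lengths(alleles)
  tibble(
    code = code,
    alleles = alleles,
    n_alleles = n_alleles,
    zygosity = dplyr::case_when(
      code == .MISSING_CALL ~ "missing",
      n_alleles == 1L ~ "homozygous",
      TRUE ~ "heterozygous"
    ),
    uninformative = code %in% c("N", .MISSING_CALL)
  )
}

# fast predicate versions used in inner loops ---------------------------------

iupac_alleles <- function(code) {
  if (code == .MISSING_CALL) return(character(0))
  .IUPAC_EXPANSION[[code]]
}

# does each call in `codes` carry `base`? missing calls carry nothing.
carries_base <- function(codes, base) {
  vapply(codes, function(cc) {
    cc != .MISSING_CALL && base %in% .IUPAC_EXPANSION[[cc]]
  }, logical(1), USE.NAMES = FALSE)
}

is_het_call <- function(codes) {
  vapply(codes, function(cc) {
    cc != .MISSING_CALL && length(.IUPAC_EXPANSION[[cc]]) >= 2L
  }, logical(1), USE.NAMES = FALSE)
}

#' Reverse complement of a DNA string with IUPAC ambiguity codes
#'
#' @param x character vector of DNA strings (may contain ambiguity codes
#'   and gaps).
#' @return character vector of reverse complements.
#' @examples
#' revcomp("ACGTR")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    chars <- strsplit(toupper(s), "")[[1]]
    bad <- setdiff(unique(chars), names(.DNA_COMPLEMENT))
    if (length(bad) > 0) {
      abort(paste0("cannot complement character(s): ", paste(sQuote(bad), collapse = ", ")))
    }
    paste(rev(unname(.DNA_COMPLEMENT[chars])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# TRUE where the set denoted by pattern code `p` contains base `b`
# (pattern-superset semantics used by the promoter scanner).
iupac_superset_match <- function(p, b) {
  b %in% .IUPAC_EXPANSION[[p]]
}

# TRUE where the expansions of two codes overlap (used by p-distance
# overlap mode).
iupac_overlap <- function(a, b) {
  length(intersect(.IUPAC_EXPANSION[[a]], .IUPAC_EXPANSION[[b]])) > 0
}
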