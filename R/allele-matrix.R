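# The allele matrix is the tabular heart of the marker analysis: one
# single-character IUPAC consensus call per individual per polymorphic
# position, with individuals labeled by species and MeSA production group.
# In memory it is a long tibble (position, individual_id, species_code,
# group, call) classed `allele_matrix`; on disk it is a wide TSV with a
# `pos` column followed by one column per individual.

#' Construct and validate an allele matrix
#'
#' @param calls long tibble with columns `position`, `individual_id`,
#'   `species_code`, `group`, `call`.
#' @return the tibble, classed `allele_matrix`, sorted by position then
#'   original individual order.
#' @export
allele_matrix <- function(calls) {
  req <- c("position", "individual_id", "species_code", "group", "call")
  missing_cols <- setdiff(req, names(calls))
  if (length(missing_cols) > 0) {
    abort(paste0("allele matrix lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  calls <- as_tibble(calls)
  calls$position <- as.integer(calls$position)
  bad <- setdiff(unique(calls$call), c(.IUPAC_CODES, .MISSING_CALL))
  if (length(bad) > 0) {
    abort(paste0("non-IUPAC call(s): ", paste(sQuote(bad), collapse = ", ")))
  }
  if (!all(calls$group %in% .VALID_GROUPS)) {
    abort("group must be one of high/low/unassigned")
  }
  ind <- unique(calls$individual_id)
  pos <- sort(unique(calls$position))
  grid_n <- length(ind) * length(pos)
  if (nrow(calls) != grid_n || anyDuplicated(calls[c("position", "individual_id")]) > 0) {
    abort("calls must form a complete position x individual grid")
  }
  calls$individual_id <- factor(calls$individual_id, levels = ind)
  calls <- arrange(calls, .data$position, .data$individual_id)
  calls$individual_id <- as.character(calls$individual_id)
  class(calls) <- c("allele_matrix", class(calls))
  calls
}

#' Read an allele matrix from a wide TSV
#'
#' The expected layout mirrors a published genotype table: a header row of
#' individual ids (first column `pos`), then one row per 1-based position
#' holding one IUPAC character (or `"."` for missing) per individual.
#' Species codes are taken from the id prefix before the first underscore
#' and mapped to groups via `species_map`.
#'
#' The packaged fixture `table2_sabp2.tsv` encodes the published *SABP2*
#' validation matrix for 38 birch individuals (20 high / 18 low MeSA
#' producers) at six polymorphic positions; see
#' `system.file("extdata", "table2_sabp2.tsv", package = "mesamarker")`.
#'
#' @param path TSV path.
#' @param species_map named character vector species code -> group;
#'   defaults to [betula_group_map()].
#' @return an [allele_matrix()] tibble.
#' @examples
#' m <- read_allele_matrix(mesa_example("table2_sabp2.tsv"))
#' dplyr::count(m, group)
#' @export
read_allele_matrix <- function(path, species_map = betula_group_map()) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) abort("allele matrix TSV needs a header and at least one position row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (header[1] != "pos") abort("first column of the allele matrix must be named 'pos'")
  ids <- header[-1]
  if (anyDuplicated(ids)) abort("duplicate individual ids in header")
  ncol_expected <- length(header)
  body <- fields[-1]
  widths <- lengths(body)
  if (any(widths != ncol_expected)) {
    abort(paste0("ragged row at line ", which(widths != ncol_expected)[1] + 1L))
  }
  positions <- suppressWarnings(as.integer(vapply(body, `[[`, "", 1L)))
  if (anyNA(positions)) abort("non-integer position value")
  if (any(diff(positions) <= 0)) abort("positions must be strictly increasing")
  call_mat <- do.call(rbind, lapply(body, function(f) toupper(f[-1])))
  species <- species_from_id(ids, species_map)
  group <- ifelse(species == "", "unassigned", unname(species_map[species]))
  group[is.na(group)] <- "unassigned"
  long <- tibble(
    position = rep(positions, each = length(ids)),
    individual_id = rep(ids, times = length(positions)),
    species_code = rep(species, times = length(positions)),
    group = rep(group, times = length(positions)),
    call = as.vector(t(call_mat))
  )
  allele_matrix(long)
}

#' Write an allele matrix to a wide TSV
#'
#' @param matrix an [allele_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allele_matrix <- function(matrix, path) {
  ind <- unique(matrix$individual_id)
  wide <- pivot_wider(
    as_tibble(matrix)[c("position", "individual_id", "call")],
    names_from = "individual_id", values_from = "call"
  )
  wide <- rename(wide, pos = "position")
  readr::write_tsv(wide[c("pos", ind)], path)
  invisible(path)
}

#' Path to a packaged example data file
#'
#' @param file file name under the package's `extdata/` directory; with no
#'   argument, lists the available files.
#' @return a file path (or a character vector of file names).
#' @export
mesa_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "mesamarker")))
  }
  path <- system.file("extdata", file, package = "mesamarker")
  if (!nzchar(path)) abort(paste0("no packaged example file ", sQuote(file)))
  path
}

matrix_individuals <- function(matrix) {
  distinct(as_tibble(matrix)[c("individual_id", "species_code", "group")])
}
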