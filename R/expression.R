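# Delta-Ct relative expression analysis of RT-qPCR data. Technical
# replicates are averaged per biological sample; the reference Ct is the
# arithmetic mean of the housekeeping genes' mean Cts (equivalent to
# geometric-mean normalization on the expression scale); relative
# expression is E^(-dCt) with amplification efficiency E = 2 by default.

#' Read a Ct table from TSV
#'
#' Columns: `sample_id`, `species_code`, `tissue` (`leaf`/`bark`), `gene`,
#' `replicate`, `ct` (quantification cycles).
#'
#' @param path TSV path.
#' @return validated Ct tibble.
#' @export
read_ct_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  validate_ct_table(tab)
}

validate_ct_table <- function(tab) {
  req <- c("sample_id", "species_code", "tissue", "gene", "replicate", "ct")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("Ct table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(tab$ct)) || any(tab$ct <= 0 | tab$ct >= 45)) {
    abort("Ct values must lie in (0, 45) cycles")
  }
  as_tibble(tab)
}

#' Average technical replicates per biological sample and gene
#'
#' @param table Ct tibble (see [read_ct_table()]).
#' @param outlier_sd technical-replicate standard deviation (cycles) above
#'   which a (sample, gene) mean is flagged; default 0.5 cycles.
#' @return tibble with `sample_id`, `species_code`, `tissue`, `gene`,
#'   `mean_ct`, `sd_ct` (0 with `single_rep = TRUE` when only one
#'   replicate), `n_reps`, `outlier`.
#' @export
aggregate_replicates <- function(table, outlier_sd = 0.5) {
  table <- validate_ct_table(table)
  out <- table |>
    group_by(.data$sample_id, .data$species_code, .data$tissue, .data$gene) |>
    summarise(
      mean_ct = mean(.data$ct),
      sd_ct = ifelse(n() > 1, sd(.data$ct), 0),
      n_reps = n(),
      .groups = "drop"
    ) |>
    mutate(
      single_rep = .data$n_reps == 1L,
      outlier = .data$sd_ct > outlier_sd
    )
  arrange(out, .data$sample_id, .data$gene)
}

#' Delta-Ct relative expression
#'
#' For each biological sample the reference Ct is the arithmetic mean of
#' the reference genes' mean Cts; dCt = Ct_target - Ct_ref and relative
#' expression = efficiency^(-dCt). Per (species, tissue, gene) the mean
#' and standard deviation over biological replicates are reported, with
#' `rel_expr` computed from the mean dCt.
#'
#' @param sample_means output of [aggregate_replicates()].
#' @param target_genes genes to quantify; default: every non-reference
#'   gene present.
#' @param reference_genes housekeeping gene names; every sample must carry
#'   all of them.
#' @param efficiency amplification efficiency (fold change per cycle);
#'   default 2, the value implied by the classical delta-Ct method.
#' @return tibble classed `relative_expression` with `species_code`,
#'   `tissue`, `gene`, `n_bio`, `mean_dct`, `sd_dct`, `rel_expr`; the
#'   per-sample dCt values are in attribute `per_sample`. The
#'   mean-of-references normalization is recorded in attribute
#'   `normalization`.
#' @examples
#' ct <- gen_ct_table(seed = 1)
#' delta_ct(aggregate_replicates(ct), reference_genes = c("ACT", "UBQ"))
#' @export
delta_ct <- function(sample_means, target_genes = NULL,
                     reference_genes, efficiency = 2) {
  stopifnot(length(reference_genes) >= 1, efficiency > 1)
  samples <- unique(sample_means$sample_id)
  refs <- filter(sample_means, .data$gene %in% reference_genes)
  ref_check <- refs |> group_by(.data$sample_id) |>
    summarise(n_ref = dplyr::n_distinct(.data$gene), .groups = "drop")
  incomplete <- union(
    setdiff(samples, ref_check$sample_id),
    ref_check$sample_id[ref_check$n_ref < length(reference_genes)]
  )
  if (length(incomplete) > 0) {
    abort(paste0("missing reference gene measurement(s) for sample(s): ",
                 paste(incomplete, collapse = ", ")))
  }
  ref_ct <- refs |> group_by(.data$sample_id) |>
    summarise(ref_ct = mean(.data$mean_ct), .groups = "drop")
  target_genes <- target_genes %||% setdiff(unique(sample_means$gene), reference_genes)
  per_sample <- sample_means |>
    filter(.data$gene %in% target_genes) |>
    left_join(ref_ct, by = "sample_id") |>
    mutate(dct = .data$mean_ct - .data$ref_ct,
           rel_expr = efficiency^(-.data$dct))
  out <- per_sample |>
    group_by(.data$species_code, .data$tissue, .data$gene) |>
    summarise(
      n_bio = n(),
      mean_dct = mean(.data$dct),
      sd_dct = ifelse(n() > 1, sd(.data$dct), 0),
      .groups = "drop"
    ) |>
    mutate(rel_expr = efficiency^(-.data$mean_dct))
  class(out) <- c("relative_expression", class(out))
  attr(out, "per_sample") <- per_sample
  attr(out, "efficiency") <- efficiency
  attr(out, "reference_genes") <- reference_genes
  attr(out, "normalization") <-
    "reference Ct = arithmetic mean of reference-gene mean Cts per sample (assumption: references averaged, not used separately)"
  out
}

#' @export
tidy.relative_expression <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @export
glance.relative_expression <- function(x, ...) {
  tibble(
    n_conditions = nrow(x),
    n_genes = dplyr::n_distinct(x$gene),
    efficiency = attr(x, "efficiency"),
    reference_genes = paste(attr(x, "reference_genes"), collapse = ",")
  )
}
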