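# End-to-end pipeline: scan -> markers -> classify -> phylo -> promoters
# -> expression -> report. Stages communicate only through files in the
# run directory so any stage can be inspected and re-run; a JSON manifest
# (written last) records the config snapshot, seed, input checksums, stage
# outputs and warnings. Identical config + seed gives byte-identical
# outputs.

#' Built-in pipeline configuration profiles
#'
#' * `"table2"`: marker discovery, heterozygosity profiling and panel
#'   validation on the packaged 38-individual *SABP2* genotype fixture;
#'   no simulation.
#' * `"synthetic-full"`: every stage on synthetic data with known ground
#'   truth — simulated gene family (scan, classify, phylogeny with
#'   bootstrap), simulated promoters (motif frequency), simulated Ct table
#'   (relative expression).
#'
#' @param name profile name.
#' @param seed integer seed recorded in the config.
#' @return config list consumable by [run_pipeline()].
#' @export
mesa_profile <- function(name = c("table2", "synthetic-full"), seed = 1L) {
  name <- match.arg(name)
  base <- list(
    profile = name, seed = as.integer(seed),
    theta = 0.9, require_contrast_fixed = TRUE, target_group = "high",
    reference_genes = c("ACT", "UBQ"),
    motif_dictionary = mesa_example("motifs.yaml")
  )
  if (name == "table2") {
    base$stages <- c("scan", "classify")
    base$allele_matrix <- mesa_example("table2_sabp2.tsv")
  } else {
    base$stages <- c("simulate", "scan", "classify", "phylo", "promoters", "expression")
    base$bootstrap_reps <- 100L
  }
  base
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("no such config file: ", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config$seed <- as.integer(config$seed %||% 1L)
  config$theta <- config$theta %||% 0.9
  config$require_contrast_fixed <- config$require_contrast_fixed %||% TRUE
  config$target_group <- config$target_group %||% "high"
  if (length(config$stages %||% character(0)) == 0) abort("config enables no stages")
  config
}

write_stage_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  path
}

#' Run the full analysis pipeline
#'
#' @param config a config list (see [mesa_profile()]) or path to a YAML
#'   file with the same fields.
#' @param out_dir run directory; created if needed.
#' @return the run manifest (list, also written to
#'   `<out_dir>/manifest.json`), invisibly a `mesa_run` object with the
#'   stage results attached.
#' @examples
#' \donttest{
#' run <- run_pipeline(mesa_profile("table2"), tempfile("run"))
#' run$manifest$stage_outputs
#' }
#' @export
run_pipeline <- function(config, out_dir) {
  config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings <- character(0)
  outputs <- character(0)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage ", sQuote(name), " failed: ", conditionMessage(e)))
    })
  }
  inputs <- character(0)

  # --- inputs: fixture matrix or simulated family -------------------------
  if ("simulate" %in% config$stages) {
    fam <- stage("simulate", gen_gene_family(seed = config$seed))
    fam_path <- file.path(out_dir, "family.fna")
    write_fasta(fam$sequences, fam_path)
    outputs <- c(outputs, fam_path)
    results$family <- fam
    matrix <- stage("simulate", {
      alignment_to_matrix(as_alignment(fam$sequences))
    })
  } else if (!is.null(config$allele_matrix)) {
    inputs <- c(inputs, config$allele_matrix)
    matrix <- stage("scan", read_allele_matrix(config$allele_matrix))
  } else {
    matrix <- NULL
  }

  # --- scan: heterozygosity + diagnostic markers --------------------------
  if ("scan" %in% config$stages) {
    if (is.null(matrix)) abort("stage 'scan' failed: no allele matrix input")
    markers <- stage("scan", find_diagnostic_snps(
      matrix, config$target_group, theta = config$theta,
      require_contrast_fixed = config$require_contrast_fixed
    ))
    results$markers <- markers
    outputs <- c(outputs, write_stage_tsv(markers, file.path(out_dir, "markers.tsv")))
    het_all <- heterozygosity_profile(matrix)
    het_low <- heterozygosity_profile(matrix, "low")
    het_high <- heterozygosity_profile(matrix, "high")
    het <- bind_rows(
      mutate(het_all, subset = "all"),
      mutate(het_high, subset = "high"),
      mutate(het_low, subset = "low")
    )
    results$heterozygosity <- het
    outputs <- c(outputs, write_stage_tsv(het, file.path(out_dir, "heterozygosity.tsv")))
    # recomputed-profile note: published prose counted four high-group
    # (med-excluded) heterozygous marker positions; the recount from the
    # genotype table itself may differ and is reported as-is.
    if ("med" %in% matrix$species_code) {
      no_med <- allele_matrix(filter(as_tibble(matrix), .data$species_code != "med"))
      prof <- heterozygosity_profile(no_med, "high")
      warnings <- c(warnings, paste0(
        "high-group heterozygous marker positions excluding med recomputed as {",
        paste(attr(prof, "het_positions"), collapse = ","),
        "} (n=", length(attr(prof, "het_positions")),
        "); prose reports of 'four of six' differ from the genotype table recount"
      ))
    }
  }

  # --- classify: validate the panel on every individual -------------------
  if ("classify" %in% config$stages) {
    if (is.null(results$markers)) abort("stage 'classify' failed: no marker panel")
    cls <- stage("classify", classify_matrix(results$markers, matrix))
    results$classification <- cls
    outputs <- c(outputs, write_stage_tsv(cls, file.path(out_dir, "classification.tsv")))
  }

  # --- phylo: NJ + bootstrap + monophyly ----------------------------------
  if ("phylo" %in% config$stages) {
    aln <- as_alignment(results$family$sequences)
    tr <- stage("phylo", bootstrap_support(
      aln, n_reps = config$bootstrap_reps %||% 100L, seed = config$seed
    ))
    results$tree <- tr
    nwk_path <- file.path(out_dir, "tree.nwk")
    write_newick(tr, nwk_path)
    outputs <- c(outputs, nwk_path)
    high_ids <- aln$id[aln$group == "high"]
    mono <- is_group_monophyletic(tr, high_ids)
    supp <- attr(tr, "support")
    key <- mono$bipartition
    mono_tbl <- tibble(
      group = "high", monophyletic = mono$monophyletic,
      support = if (mono$monophyletic && !is.null(supp)) {
        canon <- if (aln$id[1] %in% high_ids) {
          paste(sort(setdiff(aln$id, high_ids)), collapse = "|")
        } else key
        supp[[canon]] %||% NA_real_
      } else NA_real_
    )
    results$monophyly <- mono_tbl
    outputs <- c(outputs, write_stage_tsv(mono_tbl, file.path(out_dir, "monophyly.tsv")))
    warnings <- c(warnings, paste0(
      "phylogeny computed by p-distance + neighbor joining with column bootstrap ",
      "(distance-based substitute for likelihood tree building)"
    ))
  }

  # --- promoters ----------------------------------------------------------
  if ("promoters" %in% config$stages) {
    patterns <- read_motifs(config$motif_dictionary)
    inputs <- c(inputs, config$motif_dictionary)
    prom <- stage("promoters", gen_promoters(seed = config$seed, patterns = patterns))
    freq <- stage("promoters", motif_frequency_table(prom$sequences, patterns))
    results$promoters <- prom
    results$motif_frequency <- freq
    outputs <- c(outputs, write_stage_tsv(freq, file.path(out_dir, "motif_frequency.tsv")))
    outputs <- c(outputs, write_stage_tsv(attr(freq, "hits"),
                                          file.path(out_dir, "motif_hits.tsv")))
  }

  # --- expression ---------------------------------------------------------
  if ("expression" %in% config$stages) {
    ct <- stage("expression", gen_ct_table(seed = config$seed,
                                           reference_genes = config$reference_genes))
    agg <- aggregate_replicates(ct)
    rel <- stage("expression", delta_ct(agg, reference_genes = config$reference_genes))
    results$ct_table <- ct
    results$expression <- rel
    outputs <- c(outputs, write_stage_tsv(ct, file.path(out_dir, "ct_table.tsv")))
    outputs <- c(outputs, write_stage_tsv(rel, file.path(out_dir, "relative_expression.tsv")))
  }

  manifest <- list(
    config = config[setdiff(names(config), "stages")],
    stages = config$stages,
    seed = config$seed,
    input_checksums = as.list(setNames(unname(tools::md5sum(inputs)), basename(inputs))),
    stage_outputs = basename(outputs),
    output_checksums = as.list(setNames(unname(tools::md5sum(outputs)), basename(outputs))),
    package_version = as.character(utils::packageVersion("mesamarker")),
    warnings = warnings
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out <- list(manifest = manifest, results = results, out_dir = out_dir)
  class(out) <- "mesa_run"
  invisible(out)
}

#' @export
print.mesa_run <- function(x, ...) {
  cat("<mesa_run>", x$manifest$config$profile %||% "custom", "\n")
  cat("  stages: ", paste(x$manifest$stages, collapse = ", "), "\n")
  cat("  outputs in ", x$out_dir, ":\n    ",
      paste(x$manifest$stage_outputs, collapse = "\n    "), "\n", sep = "")
  if (length(x$manifest$warnings)) {
    cat("  notes:\n    ", paste(x$manifest$warnings, collapse = "\n    "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
glance.mesa_run <- function(x, ...) {
  tibble(
    profile = x$manifest$config$profile %||% "custom",
    seed = x$manifest$seed,
    n_stages = length(x$manifest$stages),
    n_outputs = length(x$manifest$stage_outputs),
    n_markers = if (!is.null(x$results$markers)) nrow(x$results$markers) else NA_integer_
  )
}
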