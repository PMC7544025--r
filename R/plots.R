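# ggplot2 views of the main result types.

#' @export
autoplot.diagnostic_markers <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = factor(.data$position), y = .data$penetrance)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = attr(object, "theta") %||% 0.9, linetype = 2) +
    geom_text(aes(label = .data$allele), vjust = -0.4) +
    scale_y_continuous(limits = c(0, 1.08), expand = c(0, 0)) +
    labs(x = "position (bp)", y = "penetrance in target group",
         title = "Group-diagnostic SNP markers",
         subtitle = "bar label = diagnostic allele; dashed line = penetrance threshold") +
    theme_minimal()
}

#' Plot a heterozygosity profile
#'
#' @param profile output of [heterozygosity_profile()].
#' @return a ggplot.
#' @export
plot_heterozygosity <- function(profile) {
  ggplot(profile, aes(x = factor(.data$position), y = .data$n_het)) +
    geom_col(fill = "darkorange") +
    labs(x = "position (bp)", y = "heterozygous calls",
         title = paste0("Heterozygous consensus calls (subset: ",
                        attr(profile, "subset") %||% "all", ")")) +
    theme_minimal()
}

#' @export
autoplot.motif_frequency <- function(object, ...) {
  long <- pivot_longer(as_tibble(object), -c("species_code", "group"),
                       names_to = "motif", values_to = "count")
  ggplot(long, aes(x = .data$motif, y = .data$count, fill = .data$group)) +
    geom_col(position = "dodge") +
    facet_wrap(~species_code) +
    labs(x = NULL, y = "hits per promoter",
         title = "Cis-element frequencies by species") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.relative_expression <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = interaction(.data$species_code, .data$tissue, sep = " "),
             y = .data$rel_expr, fill = .data$tissue)) +
    geom_col(position = "dodge") +
    facet_wrap(~gene, scales = "free_y") +
    labs(x = NULL, y = "relative expression (2^-dCt)",
         title = "Tissue-specific relative expression") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
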