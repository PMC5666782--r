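#' Haplotype frequency spectrum
#'
#' Bar chart of clone counts per haplotype, dominant first.
#'
#' @param object A `haplotype_tbl`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.haplotype_tbl <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(hap_id = factor(.data$hap_id, levels = .data$hap_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hap_id, y = .data$total_count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "haplotype", y = "clones",
                  title = sprintf("%s %s: %d clones, %d haplotypes",
                                  attr(object, "species"), attr(object, "gene"),
                                  attr(object, "n_clones"), nrow(object))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Intragenomic vs intergenomic divergence
#'
#' Point-range plot of the grand intragenomic and intergenomic means with
#' their standard errors.
#'
#' @param object A `divergence_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.divergence_summary <- function(object, ...) {
  g <- glance(object)
  df <- tibble(
    type = c("intragenomic", "intergenomic"),
    mean_pct = c(g$intra_mean_pct, g$inter_mean_pct),
    se_pct = c(g$intra_se_pct, g$inter_se_pct)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$type, y = .data$mean_pct)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_pct - .data$se_pct,
      ymax = .data$mean_pct + .data$se_pct)) +
    ggplot2::labs(x = NULL, y = "mean p-distance (%)",
                  title = sprintf("%s %s divergence partition",
                                  object$species %||% "",
                                  object$gene %||% "")) +
    ggplot2::theme_minimal()
}

#' Dominant-haplotype frequency by individual and gene
#'
#' Grouped bar chart comparing the single-pass sequencing likelihood proxy
#' (per-individual dominant-haplotype frequency) between two genes.
#'
#' @param table1_gene_a,table1_gene_b Per-individual summaries from
#'   [summarize_clone_library()] (or rows of [thrips_clone_summary()]).
#' @param genes Length-2 character vector of gene labels.
#' @return A ggplot.
#' @export
plot_dominant_frequency <- function(table1_gene_a, table1_gene_b,
                                    genes = c("mtCO1", "ITS2")) {
  df <- bind_rows(
    mutate(filter(table1_gene_a, .data$individual_id != "All clones"),
           gene = genes[1L]),
    mutate(filter(table1_gene_b, .data$individual_id != "All clones"),
           gene = genes[2L])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$individual_id,
                                   y = .data$dominant_freq_pct,
                                   fill = .data$gene)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::scale_fill_grey(start = 0.3, end = 0.7) +
    ggplot2::labs(x = "individual", y = "dominant haplotype frequency (%)",
                  fill = "gene") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
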