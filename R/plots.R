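#' RSCU bar chart
#'
#' Codon-usage figure in the conventional style: one bar group per
#' amino-acid family (Leu and Ser split into their codon classes), one bar
#' per codon, height = RSCU.
#'
#' @param object A [rscu()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mito_rscu <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$rscu))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family, y = .data$rscu,
                                   group = .data$codon,
                                   fill = stringr::str_sub(.data$codon, 3, 3))) +
    ggplot2::geom_col(position = ggplot2::position_dodge2(preserve = "single"),
                      colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = NULL, y = "RSCU", fill = "3rd base") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Linear gene-arrangement map
#'
#' One row per taxon, genes as tiles in genomic order: protein-coding genes
#' white, tRNAs green, rRNAs grey, the control region blue; genes belonging
#' to a rearranged cluster relative to the reference are outlined in red.
#'
#' @param orders List of [gene_order()] objects.
#' @param reference Reference order for highlighting (default ancestral).
#' @return A ggplot object.
#' @export
plot_gene_map <- function(orders, reference = ancestral_insect_order()) {
  df <- purrr::map_dfr(orders, function(o) {
    ev <- suppressMessages(diff_against(o, reference))
    moved <- unique(unlist(ev$genes))
    tibble(taxon = order_taxon(o), pos = seq_len(nrow(o)), gene = o$gene,
           strand = o$strand, category = gene_category(o$gene),
           rearranged = o$gene %in% moved)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$taxon)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$category,
                                    colour = .data$rearranged),
                       width = 0.95, height = 0.8, linewidth = 0.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$gene), size = 1.8, angle = 90) +
    ggplot2::scale_fill_manual(values = c(PCG = "white", tRNA = "#74c476",
                                          rRNA = "grey85", CR = "#9ecae1")) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "grey60"),
                                 guide = "none") +
    ggplot2::labs(x = "position in gene order", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
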