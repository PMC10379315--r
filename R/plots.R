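# ggplot2 views of the main result types.

#' Plot per-allele read frequencies
#'
#' Dot plot of the read frequency at which each allele was observed per
#' animal and amplicon, on a log scale, with the threshold of resolution as
#' a horizontal reference line.
#'
#' @param aft Output of [allele_frequency_table()].
#' @param freq_threshold Reference line (0.002 = 0.2% of reads).
#' @return A ggplot object.
#' @export
plot_allele_frequencies <- function(aft, freq_threshold = 0.002) {
  ggplot2::ggplot(aft, ggplot2::aes(x = .data$allele, y = .data$frequency,
                                    colour = .data$amplicon)) +
    ggplot2::geom_jitter(width = 0.2, height = 0, size = 0.8, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = freq_threshold, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "read frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6))
}

#' Plot locus read-share distributions
#'
#' Box plots of the per-animal share of reads per locus within each class II
#' gene.
#'
#' @param shares Output of [locus_read_proportions()].
#' @return A ggplot object.
#' @export
plot_locus_proportions <- function(shares) {
  ggplot2::ggplot(shares, ggplot2::aes(x = .data$locus, y = .data$share)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "share of gene reads") +
    ggplot2::theme_minimal()
}

#' Plot MHCI-MHCII linkage weights
#'
#' Heat map of the co-segregation weight between class I and class II
#' haplotypes (the tabular form of an alluvial linkage plot).
#'
#' @param cells Output of [linkage_table()].
#' @return A ggplot object.
#' @export
plot_linkage <- function(cells) {
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$hap1, y = .data$hap2,
                                      fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "MHCI haplotype", y = "MHCII haplotype") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' @describeIn plot_allele_frequencies autoplot method for inferred
#'   haplotypes: haplotype-by-allele presence tiles, faceted nowhere, with
#'   confirmation encoded in the fill.
#' @param object An `ela_haplotypes` object.
#' @param ... Unused.
#' @export
autoplot.ela_haplotypes <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$allele, y = .data$id,
                                     fill = .data$confirmed)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::labs(x = NULL, y = NULL, fill = "confirmed") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5, size = 6))
}
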