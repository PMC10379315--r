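# Cohort-level summaries: locus read proportions, allele frequency tables,
# MHCI-MHCII linkage and haplotype-table statistics.

#' Per-animal locus read proportions
#'
#' Within each class II gene (DQA, DQB, DRB) and animal, the share of reads
#' attributed to each locus (DQA1/DQA2, DQB1/DQB2, DRB1/DRB2/DRB3, ...).
#' Shares sum to 1 per animal and gene; animals without reads for a gene are
#' omitted from that gene's rows.
#'
#' @param calls Final class II call sets with `assigned_name`, `frequency`,
#'   and `status` in called/recovered.
#' @param locus_map Named character vector: allele name -> locus label
#'   (e.g. `"DRB1"`).
#' @return Tibble `animal`, `gene`, `locus`, `share`.
#' @export
locus_read_proportions <- function(calls, locus_map) {
  calls |>
    filter(.data$status %in% c("called", "recovered"),
           .data$assigned_name %in% names(locus_map)) |>
    mutate(locus = unname(locus_map[.data$assigned_name]),
           gene = sub("[0-9]+$", "", .data$locus)) |>
    group_by(animal = .data$sample_id, .data$gene, .data$locus) |>
    summarise(reads = sum(.data$read_count), .groups = "drop_last") |>
    mutate(share = .data$reads / sum(.data$reads)) |>
    ungroup() |>
    select("animal", "gene", "locus", "share")
}

#' Cohort summary of locus shares
#'
#' @param shares Output of [locus_read_proportions()].
#' @return Tibble `gene`, `locus`, `median`, `q1`, `q3`, `min`, `max`, `n`.
#' @export
locus_share_summary <- function(shares) {
  shares |>
    group_by(.data$gene, .data$locus) |>
    summarise(median = median(.data$share),
              q1 = quantile(.data$share, 0.25),
              q3 = quantile(.data$share, 0.75),
              min = min(.data$share), max = max(.data$share),
              n = dplyr::n(), .groups = "drop")
}

#' Long-format allele read-frequency table
#'
#' One row per (animal, amplicon, allele present), with the read frequency
#' at which the allele was observed, suitable for log-scale plotting against
#' the 0.2% threshold of resolution. Recovered entries (below threshold) are
#' flagged.
#'
#' @param calls Final call sets with `assigned_name`.
#' @param freq_threshold Threshold used for the `below_threshold` flag.
#' @return Tibble `allele`, `amplicon`, `animal`, `frequency`, `status`,
#'   `below_threshold`.
#' @export
allele_frequency_table <- function(calls, freq_threshold = 0.002) {
  calls |>
    filter(.data$status %in% c("called", "recovered"),
           !is.na(.data$assigned_name)) |>
    transmute(allele = .data$assigned_name, amplicon = .data$amplicon,
              animal = .data$sample_id, frequency = .data$frequency,
              status = .data$status,
              below_threshold = .data$frequency < freq_threshold)
}

#' MHCI-MHCII linkage table
#'
#' Each animal assigned in both classes contributes total weight 1,
#' distributed uniformly over the (class I haplotype, class II haplotype)
#' pairings consistent with its diplotypes: 1 pairing for a double
#' homozygote, up to 4 for a double heterozygote (phase across the two
#' regions is unobservable from unphased genotypes). Animals assigned in
#' only one class are excluded and counted.
#'
#' @param assign1,assign2 Assignment tibbles (class I and class II) from
#'   [infer_haplotypes()].
#' @return Tibble `hap1`, `hap2`, `weight`; the number of animals excluded
#'   for missing assignments is in the `"n_excluded"` attribute.
#' @export
linkage_table <- function(assign1, assign2) {
  a1 <- assign1 |> filter(!is.na(.data$hap1)) |>
    select("animal", I1 = "hap1", I2 = "hap2")
  a2 <- assign2 |> filter(!is.na(.data$hap1)) |>
    select("animal", II1 = "hap1", II2 = "hap2")
  both <- inner_join(a1, a2, by = "animal")
  n_excluded <- dplyr::n_distinct(c(a1$animal, a2$animal)) - nrow(both)
  cells <- both |>
    rowwise() |>
    reframe({
      g <- expand.grid(hap1 = c(.data$I1, .data$I2),
                       hap2 = c(.data$II1, .data$II2),
                       stringsAsFactors = FALSE)
      g$weight <- 1 / nrow(g)
      g
    }) |>
    group_by(.data$hap1, .data$hap2) |>
    summarise(weight = sum(.data$weight), .groups = "drop")
  attr(cells, "n_excluded") <- n_excluded
  cells
}
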