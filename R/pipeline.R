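# End-to-end convenience wrapper: raw pairs to named calls and haplotypes.

#' Run the genotyping pipeline on a multiplexed run
#'
#' Chains the pipeline stages: demultiplex by MID combination, merge pairs
#' by overlap, mean-quality filter (>Q28), assign and trim amplicon primers,
#' dereplicate per sample and amplicon, flag shadow/chimera artifacts, apply
#' the threshold of resolution, run the cohort-wide recovery loop, assign
#' names against the reference database, and build per-class genotype
#' matrices (class I amplicons unioned per sample).
#'
#' @param pairs Pair table (see [read_paired_fastq()] / [simulate_reads()]).
#' @param scheme A [mid_scheme()].
#' @param db Reference database ([load_reference_db()]); may be empty
#'   (every sequence then founds a novel group).
#' @param country Cohort country code for novel names.
#' @param defs Amplicon panel.
#' @param cfg A [calling_config()].
#' @param min_overlap,max_mismatch_frac Merge parameters.
#' @param quality_threshold Mean-Phred threshold (strict).
#' @param max_primer_mismatches Per-primer tolerance for amplicon assignment.
#' @return List with `routing` (read-conservation report), `calls` (final
#'   named cohort call sets), `nomenclature` (naming report), `db` (grown
#'   database), `genotypes` (list of `genotype_matrix` per class).
#' @export
genotype_pipeline <- function(pairs, scheme, db = NULL,
                              country = c("gb", "is", "no"),
                              defs = amplicon_defs(),
                              cfg = calling_config(),
                              min_overlap = 10L, max_mismatch_frac = 0.25,
                              quality_threshold = 28,
                              max_primer_mismatches = 1L) {
  country <- match.arg(country)
  if (is.null(db)) db <- empty_refdb()
  dmx <- demultiplex(pairs, scheme)
  routed <- dmx |> filter(.data$sample_id != "undetermined")

  # dereplicate identical pairs before the overlap scan: identical pairs
  # merge identically
  uniq <- routed |>
    count(.data$sample_id, .data$fwd_seq, .data$fwd_qual,
          .data$rev_seq, .data$rev_qual, name = "n_pairs")
  merged <- merge_pairs(uniq, min_overlap = min_overlap,
                        max_mismatch_frac = max_mismatch_frac)
  merged <- quality_filter(merged, threshold = quality_threshold)
  ok <- merged |>
    filter(.data$merged, .data$qc_pass) |>
    group_by(.data$sample_id, .data$sequence) |>
    summarise(n_pairs = sum(.data$n_pairs), .groups = "drop")
  asg <- assign_amplicons(ok, defs, max_primer_mismatches = max_primer_mismatches)

  routing <- tibble(
    stage = c("input_pairs", "demultiplexed", "merged", "qc_pass", "assigned"),
    n = c(nrow(pairs), sum(uniq$n_pairs),
          sum(merged$n_pairs[merged$merged]),
          sum(merged$n_pairs[merged$merged & merged$qc_pass]),
          sum(asg$n_pairs[!is.na(asg$amplicon)]))
  )

  inserts <- asg |>
    filter(!is.na(.data$amplicon)) |>
    select("sample_id", "amplicon", insert = "insert", n = "n_pairs")
  calls <- dereplicate(inserts) |>
    denoise_artifacts(cfg) |>
    apply_threshold(cfg) |>
    recover_alleles(cfg = cfg)

  # name called + recovered sequences
  genes <- setNames(defs$gene, defs$name)
  final <- calls |> filter(.data$status %in% c("called", "recovered"))
  queries <- final |>
    transmute(sample_id = .data$sample_id, gene = unname(genes[.data$amplicon]),
              nt_seq = .data$sequence, read_count = .data$read_count)
  registry <- nomenclature_registry(country, db)
  named <- assign_nomenclature(queries, db, registry)
  final$assigned_name <- named$report$assigned_name
  calls <- calls |>
    left_join(final |> distinct(.data$sample_id, .data$amplicon,
                                .data$sequence, .data$assigned_name),
              by = c("sample_id", "amplicon", "sequence"))

  mhci_amps <- defs$name[genes[defs$name] == "MHCI"]
  gm <- list(
    MHCI = build_genotype_matrix(
      merge_mhci_amplicons(calls, mhci_amplicons = mhci_amps)),
    MHCII = build_genotype_matrix(
      calls |> filter(!.data$amplicon %in% mhci_amps))
  )
  list(routing = routing, calls = calls, nomenclature = named$report,
       db = named$db, genotypes = gm)
}
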