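# Allele calling: collapse primer-trimmed inserts into candidate alleles,
# remove PCR/sequencing artifacts, apply the threshold of resolution, and run
# the cohort-wide allele recovery loop.

#' Calling configuration
#'
#' @param freq_threshold Threshold of resolution: entries at or above this
#'   read frequency are called (0.002 = 0.2% of reads; the boundary is
#'   inclusive).
#' @param shadow_max_mismatch A sequence within this many substitutions of a
#'   much more abundant one is a candidate shadow artifact.
#' @param shadow_ratio Maximum child/parent count ratio for a shadow
#'   (0.1: the parent must be at least 10x more abundant).
#' @param chimera_parent_ratio Each chimera parent must have at least this
#'   multiple of the child's count.
#' @param recovery_min_reads Minimum read count for a sub-threshold entry to
#'   be recovered.
#' @return A list of class `calling_config`.
#' @export
calling_config <- function(freq_threshold = 0.002, shadow_max_mismatch = 1L,
                           shadow_ratio = 0.1, chimera_parent_ratio = 1.0,
                           recovery_min_reads = 2L) {
  stopifnot(freq_threshold > 0, freq_threshold < 1,
            shadow_ratio > 0, shadow_ratio <= 1,
            chimera_parent_ratio > 0, chimera_parent_ratio <= 1 ||
              chimera_parent_ratio >= 1) # any positive multiple is meaningful
  structure(list(freq_threshold = freq_threshold,
                 shadow_max_mismatch = as.integer(shadow_max_mismatch),
                 shadow_ratio = shadow_ratio,
                 chimera_parent_ratio = chimera_parent_ratio,
                 recovery_min_reads = as.integer(recovery_min_reads)),
            class = "calling_config")
}

#' Dereplicate inserts into a call set
#'
#' Collapses identical insert sequences per sample and amplicon, keeping read
#' counts and frequencies (over all reads of that sample and amplicon).
#' Entries are ordered by descending count, then sequence, so the output is
#' invariant to the input read order.
#'
#' @param inserts Tibble with columns `sample_id`, `amplicon`, `insert`
#'   (one row per read), or pre-counted rows with an `n` column.
#' @return Call-set tibble: `sample_id`, `amplicon`, `sequence`,
#'   `read_count`, `frequency`, `status` (all `"provisional"`).
#' @export
dereplicate <- function(inserts) {
  if (nrow(inserts) == 0) {
    return(tibble(sample_id = character(), amplicon = character(),
                  sequence = character(), read_count = integer(),
                  frequency = numeric(), status = character()))
  }
  counted <- if ("n" %in% names(inserts)) {
    inserts |>
      group_by(.data$sample_id, .data$amplicon, sequence = .data$insert) |>
      summarise(read_count = sum(.data$n), .groups = "drop")
  } else {
    inserts |>
      count(.data$sample_id, .data$amplicon, sequence = .data$insert,
            name = "read_count")
  }
  counted |>
    group_by(.data$sample_id, .data$amplicon) |>
    mutate(frequency = .data$read_count / sum(.data$read_count)) |>
    ungroup() |>
    arrange(.data$sample_id, .data$amplicon,
            desc(.data$read_count), .data$sequence) |>
    mutate(status = "provisional")
}

#' Flag shadow and chimera artifacts
#'
#' Within each sample and amplicon, in descending-count order: an entry is a
#' *shadow* when it lies within `shadow_max_mismatch` substitutions of a
#' non-artifact entry at least `1/shadow_ratio` times more abundant; an entry
#' is a *chimera* when it equals a prefix of one non-artifact entry joined to
#' a suffix of another at some internal breakpoint and both parents have at
#' least `chimera_parent_ratio` times its count. Frequencies are recomputed
#' over surviving (non-artifact) reads.
#'
#' @param calls A call set from [dereplicate()].
#' @param cfg A [calling_config()].
#' @return The call set with `status` updated to `artifact_shadow` /
#'   `artifact_chimera` where flagged, and frequencies recomputed.
#' @export
denoise_artifacts <- function(calls, cfg = calling_config()) {
  if (nrow(calls) == 0) return(calls)
  calls |>
    group_by(.data$sample_id, .data$amplicon) |>
    group_modify(~ denoise_group(.x, cfg)) |>
    ungroup() |>
    group_by(.data$sample_id, .data$amplicon) |>
    mutate(frequency = ifelse(
      startsWith(.data$status, "artifact"),
      .data$frequency,
      .data$read_count / sum(.data$read_count[!startsWith(.data$status, "artifact")])
    )) |>
    ungroup()
}

denoise_group <- function(g, cfg) {
  g <- arrange(g, desc(.data$read_count), .data$sequence)
  status <- g$status
  sh <- .shadow_flags(g$sequence, as.numeric(g$read_count),
                      cfg$shadow_ratio, cfg$shadow_max_mismatch)
  status[sh] <- "artifact_shadow"
  ch <- .chimera_flags(g$sequence, as.numeric(g$read_count),
                       alive = !sh, parent_ratio = cfg$chimera_parent_ratio)
  status[ch & status != "artifact_shadow"] <- "artifact_chimera"
  g$status <- status
  g
}

#' Apply the threshold of resolution
#'
#' Non-artifact entries at or above `freq_threshold` (frequencies over
#' non-artifact reads) become `called`; the rest become `sub_threshold`.
#' Artifact flags are untouched.
#'
#' @inheritParams denoise_artifacts
#' @export
apply_threshold <- function(calls, cfg = calling_config()) {
  calls |>
    mutate(status = case_when(
      startsWith(.data$status, "artifact") ~ .data$status,
      .data$frequency >= cfg$freq_threshold ~ "called",
      TRUE ~ "sub_threshold"
    ))
}

#' Cohort-wide allele recovery loop
#'
#' A sub-threshold entry is *recovered* when its sequence exactly (full
#' length) matches a confirmed allele -- a sequence called in at least one
#' animal of the cohort (or supplied as a validated reference) -- and it has
#' at least `recovery_min_reads` reads. Recovered entries do not expand the
#' confirmed set, so the fixpoint is reached in a single pass and the result
#' does not depend on sample order. This is the mechanism that rescues lowly
#' expressed alleles which only exceed the threshold in homozygotes
#' (a "double-dose" of the haplotype carrying them).
#'
#' @param calls Cohort call sets after [apply_threshold()].
#' @param confirmed Optional extra confirmed sequences (character vector).
#' @param cfg A [calling_config()].
#' @export
recover_alleles <- function(calls, confirmed = NULL, cfg = calling_config()) {
  confirmed_set <- union(unique(calls$sequence[calls$status == "called"]),
                         confirmed %||% character(0))
  calls |>
    mutate(status = ifelse(
      .data$status == "sub_threshold" &
        .data$sequence %in% confirmed_set &
        .data$read_count >= cfg$recovery_min_reads,
      "recovered", .data$status
    ))
}

#' Union the two class I amplicons per sample
#'
#' A class I allele is present in a sample when it is called or recovered in
#' either of the two MHCI amplicons (some alleles are only amplified by one
#' primer pair). When a composite map is supplied, segment names from the two
#' amplicons that belong to one composite allele are renamed to the composite
#' name and collapse to a single record; names without a composite mapping
#' are retained as distinct (possibly short-form, single-amplicon) allele
#' records.
#'
#' @param calls Named cohort call sets (must carry `assigned_name`).
#' @param mhci_amplicons Names of the two class I amplicons.
#' @param composite_map Optional tibble with columns `assigned_name`,
#'   `composite_name`.
#' @return Per-sample allele table: `sample_id`, `allele`, `support`
#'   (maximum frequency across contributing amplicons), `status`
#'   (`called` if called in either amplicon, else `recovered`), and
#'   `amplicons` (comma-joined contributing amplicons).
#' @export
merge_mhci_amplicons <- function(calls,
                                 mhci_amplicons = c("MHCI_For1Rev2.2", "MHCI_For3.2Rev1"),
                                 composite_map = NULL) {
  stopifnot("assigned_name" %in% names(calls))
  x <- calls |>
    filter(.data$amplicon %in% mhci_amplicons,
           .data$status %in% c("called", "recovered"),
           !is.na(.data$assigned_name))
  if (!is.null(composite_map)) {
    x <- x |>
      left_join(composite_map, by = "assigned_name") |>
      mutate(assigned_name = coalesce(.data$composite_name, .data$assigned_name)) |>
      select(-"composite_name")
  }
  x |>
    group_by(.data$sample_id, allele = .data$assigned_name) |>
    summarise(
      support = max(.data$frequency),
      status = if (any(.data$status == "called")) "called" else "recovered",
      amplicons = paste(sort(unique(.data$amplicon)), collapse = ","),
      .groups = "drop"
    )
}
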