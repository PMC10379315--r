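# Packaged haplotype tables and their summary statistics.
#
# The package ships transcriptions of the published ELA haplotype tables as
# TSV fixtures (allele names without the "Eqca-" prefix, as printed). Two
# shapes exist: class I tables carry a semicolon-joined allele list (plus,
# for the Icelandic/Norwegian cohort, the one reliably haplotype-assignable
# universal allele in its own column); class II tables carry one column per
# locus (DQA1..3, DQB1..3, DRA, DRB1..3). A cell holding two names separated
# by "/" is one locus cell whose allele could not be resolved between the two
# names; it counts as one expressed gene. One known typesetting error in the
# class II Icelandic/Norwegian table (a DRB2 name printed in a DQB3 cell) is
# kept verbatim and flagged via `typo_flag`; locus-class counts exclude
# flagged cells.

HP_TABLES <- c("mhci_standard_thoroughbred", "mhci_universal_thoroughbred",
               "mhcii_thoroughbred", "mhci_icenor", "mhcii_icenor")

#' Load a packaged haplotype table
#'
#' @param table One of `"mhci_standard_thoroughbred"`,
#'   `"mhci_universal_thoroughbred"`, `"mhcii_thoroughbred"`,
#'   `"mhci_icenor"`, `"mhcii_icenor"`; or a path to a TSV in the same
#'   layout.
#' @return A validated tibble of class `hp_table` with parsed id columns
#'   (`family_number`, `subtype_letter`, `unconfirmed`, `partial`,
#'   `mhc_class`) and a `total_occurrences` column summing the occurrence
#'   columns.
#' @export
haplotype_table <- function(table) {
  path <- if (file.exists(table)) {
    table
  } else {
    stopifnot(table %in% HP_TABLES)
    system.file("extdata", paste0("table_", table, ".tsv"), package = "elatyper")
  }
  t <- as_tibble(utils::read.delim(path, colClasses = "character", fill = TRUE,
                                   check.names = FALSE))
  occ_cols <- grep("^occ", names(t), value = TRUE)
  if (length(occ_cols) == 0) occ_cols <- "occurrences"
  for (col in c(occ_cols, intersect(c("n_expressed", "n_standard", "n_universal"),
                                    names(t)))) {
    t[[col]] <- as.integer(t[[col]])
  }
  if (!"typo_flag" %in% names(t)) t$typo_flag <- ""
  t$typo_flag[is.na(t$typo_flag)] <- ""
  ids <- parse_haplotype_id(t$haplotype)
  t <- dplyr::bind_cols(t, ids)
  t$total_occurrences <- rowSums(as.matrix(t[occ_cols]))
  attr(t, "occ_cols") <- occ_cols
  validate_hp_table(t)
  class(t) <- c("hp_table", class(t))
  t
}

#' Parse haplotype ids
#'
#' Ids have the form `[un][p]HP<class>.<family>[letter]`, e.g. `HP1.6a`,
#' `unHP2.40`, `pHP2.26`, `unpHP2.41`.
#'
#' @param x Character vector of ids.
#' @return Tibble with `mhc_class`, `family_number`, `subtype_letter`,
#'   `unconfirmed`, `partial`.
#' @export
parse_haplotype_id <- function(x) {
  m <- str_match(x, "^(un)?(p)?HP([12])\\.([0-9]+)([a-z])?$")
  if (any(is.na(m[, 1]))) {
    abort(paste0("unparseable haplotype id(s): ",
                 paste(x[is.na(m[, 1])], collapse = ", ")))
  }
  tibble(
    mhc_class = ifelse(m[, 4] == "1", "MHCI", "MHCII"),
    family_number = as.integer(m[, 5]),
    subtype_letter = ifelse(is.na(m[, 6]), "", m[, 6]),
    unconfirmed = !is.na(m[, 3 - 1]),
    partial = !is.na(m[, 3])
  )
}

validate_hp_table <- function(t) {
  bad <- which(t$unconfirmed != (t$total_occurrences < 2))
  if (length(bad) > 0) {
    abort(paste0("rows where the 'un' prefix disagrees with summed occurrences: ",
                 paste(t$haplotype[bad], collapse = ", ")))
  }
  invisible(t)
}

hp_locus_cols <- function(t) {
  intersect(c("DQA1", "DQA2", "DQA3", "DQB1", "DQB2", "DQB3",
              "DRA", "DRB1", "DRB2", "DRB3"), names(t))
}

# Count expressed locus cells of one class (DQA/DQB/DRA/DRB) in a row,
# excluding typo-flagged cells.
count_locus_class <- function(t, cls) {
  cols <- grep(paste0("^", cls), hp_locus_cols(t), value = TRUE)
  if (length(cols) == 0) return(rep(NA_integer_, nrow(t)))
  vapply(seq_len(nrow(t)), function(i) {
    cells <- unlist(t[i, cols])
    flagged <- strsplit(t$typo_flag[i], ";")[[1]]
    keep <- !(cols %in% flagged)
    sum(!is.na(cells[keep]) & nzchar(cells[keep]))
  }, integer(1))
}

#' Summary statistics of a haplotype table
#'
#' Computes, per variant family (haplotypes sharing a family number) and for
#' the table overall: family counts and confirmation (summed occurrences of
#' at least 2 across a family's rows), counts of families with multiple
#' subtype rows, cross-breed sharing (occurrences in every breed column),
#' and -- depending on the table shape -- the mean/min/max of the standard
#' and total expressed-gene columns, or the per-family locus-class count
#' distributions (DQA/DQB/DRA/DRB, taken from the family's first listed
#' subtype row, typo-flagged cells excluded).
#'
#' @param t An `hp_table` from [haplotype_table()] (or a live pool exported
#'   in the same layout).
#' @return A list of class `hp_table_summary` with elements `families`
#'   (per-family tibble) and `stats` (named list of scalars and count
#'   tables).
#' @export
summarize_haplotype_table <- function(t) {
  occ_cols <- attr(t, "occ_cols") %||% grep("^occ", names(t), value = TRUE)
  per_class <- lapply(c(DQA = "DQA", DQB = "DQB", DRA = "DRA", DRB = "DRB"),
                      function(cl) count_locus_class(t, cl))
  t2 <- t
  for (cl in names(per_class)) t2[[paste0("n_", cl)]] <- per_class[[cl]]

  fam <- t2 |>
    group_by(.data$family_number) |>
    summarise(
      n_subtypes = dplyr::n(),
      total_occurrences = sum(.data$total_occurrences),
      confirmed = sum(.data$total_occurrences) >= 2,
      shared_across_breeds = if (length(occ_cols) > 1) {
        all(vapply(occ_cols, function(cc) sum(dplyr::pick(dplyr::all_of(cc))[[1]]) > 0,
                   logical(1)))
      } else NA,
      n_DQA = .data$n_DQA[1], n_DQB = .data$n_DQB[1],
      n_DRA = .data$n_DRA[1], n_DRB = .data$n_DRB[1],
      partial = .data$partial[1],
      .groups = "drop"
    )

  stats <- list(
    n_rows = nrow(t),
    n_families = nrow(fam),
    n_confirmed_families = sum(fam$confirmed),
    n_unconfirmed_rows = sum(t$unconfirmed),
    n_families_multivariant = sum(fam$n_subtypes >= 2),
    n_families_shared = if (length(occ_cols) > 1) sum(fam$shared_across_breeds) else NA,
    n_partial = sum(t$partial)
  )
  if ("n_standard" %in% names(t) && nrow(t) > 0) {
    stats$mean_standard <- mean(t$n_standard)
    stats$min_standard <- min(t$n_standard)
    stats$max_standard <- max(t$n_standard)
  }
  if ("n_expressed" %in% names(t) && nrow(t) > 0) {
    stats$mean_expressed <- mean(t$n_expressed)
    stats$min_expressed <- min(t$n_expressed)
    stats$max_expressed <- max(t$n_expressed)
  }
  if (!all(is.na(fam$n_DQA))) {
    stats$dqa_distribution <- table(fam$n_DQA)
    stats$dqb_distribution <- table(fam$n_DQB)
    stats$drb_distribution <- table(fam$n_DRB)
  }
  structure(list(families = fam, stats = stats), class = "hp_table_summary")
}

#' Combine haplotype tables across cohorts
#'
#' Binds the id columns of several haplotype tables (e.g. the Thoroughbred
#' and Icelandic/Norwegian cohorts of one class) and summarises each variant
#' family across cohorts: the number of distinct variant rows (the same id
#' appearing in two cohorts is one variant; different subtype letters are
#' different variants) and total occurrences.
#'
#' @param ... `hp_table` objects of one MHC class.
#' @return Tibble `family_number`, `n_variants`, `total_occurrences`,
#'   `confirmed`.
#' @export
combine_haplotype_tables <- function(...) {
  tabs <- list(...)
  bound <- dplyr::bind_rows(lapply(tabs, function(t) {
    tibble(haplotype = t$haplotype, family_number = t$family_number,
           mhc_class = t$mhc_class, total_occurrences = t$total_occurrences)
  }))
  stopifnot(length(unique(bound$mhc_class)) == 1)
  bound |>
    group_by(.data$family_number) |>
    summarise(n_variants = dplyr::n_distinct(.data$haplotype),
              total_occurrences = sum(.data$total_occurrences),
              confirmed = sum(.data$total_occurrences) >= 2,
              .groups = "drop")
}

#' @export
print.hp_table_summary <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<hp_table_summary> %d rows, %d families (%d confirmed, %d with multiple variants)\n",
              s$n_rows, s$n_families, s$n_confirmed_families,
              s$n_families_multivariant))
  if (!is.null(s$mean_standard)) {
    cat(sprintf("  standard genes per haplotype: mean %.1f, range %d-%d\n",
                s$mean_standard, s$min_standard, s$max_standard))
  }
  if (!is.null(s$dqa_distribution)) {
    cat("  DQA count distribution (family representatives):\n")
    print(s$dqa_distribution)
  }
  invisible(x)
}
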