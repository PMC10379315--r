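# Amplicon panel definitions.

#' Load the amplicon panel
#'
#' Reads an amplicon definition YAML (one entry per primer pair with the
#' IUPAC primer sequences, the insert size after primer removal, the library
#' pool ratio and the registered translation frame). The packaged default
#' describes the six-amplicon ELA panel: two overlapping class I amplicons
#' (378 and 318 bp inserts, jointly covering 410 bp of the polymorphic
#' exon 2/3 region) and one amplicon each for DRA, DRB, DQA and DQB
#' (360, 341, 370 and 351 bp), pooled at 30:30:10:10:10:10.
#'
#' @param path YAML file; default is the packaged panel.
#' @return Tibble with columns `name`, `gene`, `fwd_primer`, `rev_primer`,
#'   `insert_length`, `pool_ratio`, `frame_offset`.
#' @export
amplicon_defs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "amplicons.yaml", package = "elatyper")
  }
  y <- yaml::read_yaml(path)
  defs <- dplyr::bind_rows(lapply(y$amplicons, as_tibble))
  stopifnot(all(nzchar(defs$fwd_primer)), all(nzchar(defs$rev_primer)),
            all(defs$insert_length > 0))
  defs
}

#' Assign merged reads to amplicons and trim primers
#'
#' Each merged read is matched against every amplicon definition: the forward
#' primer at the 5' end and the reverse complement of the reverse primer at
#' the 3' end, in both orientations of the read, with IUPAC-aware matching
#' (K = G/T, Y = C/T, S = C/G, M = A/C, R = A/G, ...). A definition is
#' admissible when each primer matches with at most `max_primer_mismatches`
#' mismatches; the definition with the fewest total mismatches wins, and the
#' primers are removed from the returned insert. Ties between definitions
#' leave the read unassigned with reason `"ambiguous"`; no admissible
#' definition leaves it unassigned with reason `"no_primer_match"`.
#'
#' @param reads Tibble with a `sequence` column (merged reads).
#' @param defs Amplicon definitions from [amplicon_defs()].
#' @param max_primer_mismatches Per-primer mismatch tolerance (default 1,
#'   matching the single-base primer/allele mismatches documented for the
#'   panel).
#' @return `reads` with columns `amplicon`, `insert` and `assign_reason`
#'   added; unassigned rows have `amplicon = NA`.
#' @export
assign_amplicons <- function(reads, defs, max_primer_mismatches = 1L) {
  stopifnot("sequence" %in% names(reads))
  defs$rp_rc <- revcomp(defs$rev_primer)
  res <- lapply(reads$sequence, assign_one, defs = defs,
                tol = max_primer_mismatches)
  reads$amplicon <- vapply(res, `[[`, character(1), "amplicon")
  reads$insert <- vapply(res, `[[`, character(1), "insert")
  reads$assign_reason <- vapply(res, `[[`, character(1), "reason")
  reads
}

assign_one <- function(seq, defs, tol) {
  if (is.na(seq)) {
    return(list(amplicon = NA_character_, insert = NA_character_, reason = "unmerged"))
  }
  best <- NULL
  best_mm <- Inf
  tied <- FALSE
  for (orient in c("fwd", "rev")) {
    s <- if (orient == "fwd") seq else revcomp(seq)
    n <- nchar(s)
    for (i in seq_len(nrow(defs))) {
      fp <- defs$fwd_primer[i]
      rp_rc <- defs$rp_rc[i]
      lf <- nchar(fp)
      lr <- nchar(rp_rc)
      if (n < lf + lr + 1) next
      mm_f <- primer_mismatches(fp, substr(s, 1, lf))
      mm_r <- primer_mismatches(rp_rc, substr(s, n - lr + 1, n))
      if (is.na(mm_f) || is.na(mm_r) || mm_f > tol || mm_r > tol) next
      mm <- mm_f + mm_r
      if (mm < best_mm) {
        best_mm <- mm
        best <- list(amplicon = defs$name[i],
                     insert = substr(s, lf + 1, n - lr),
                     reason = "assigned")
        tied <- FALSE
      } else if (mm == best_mm && !identical(best$amplicon, defs$name[i])) {
        tied <- TRUE
      }
    }
  }
  if (is.null(best)) {
    list(amplicon = NA_character_, insert = NA_character_, reason = "no_primer_match")
  } else if (tied) {
    list(amplicon = NA_character_, insert = NA_character_, reason = "ambiguous")
  } else {
    best
  }
}
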