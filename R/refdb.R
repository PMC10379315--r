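# Reference allele database: IPD-style FASTA in, tibble of named alleles out.
#
# Allele names follow the "Eqca-<locus>*<group>:<allele>" convention, e.g.
# "Eqca-1*001:01" (locus tag "1", allelic group "001") or
# "Eqca-MHCI*gb11:01:02" (locus tag "MHCI", group "gb11"). The locus tag maps
# onto one of five genes (MHCI, DRA, DRB, DQA, DQB); the <=4 amino-acid
# grouping rule is applied within a gene only.

#' Parse IPD-style allele names
#'
#' Splits names of the form `Eqca-<locus>*<group>:<allele>` into their fields
#' and maps the locus tag onto the gene it belongs to (numeric tags, `N` and
#' `MHCI` are class I; `DRA`/`DRB`/`DQA`/`DQB` tags, with or without a locus
#' number, are class II).
#'
#' @param full_name Character vector of allele names.
#' @return A tibble with columns `full_name`, `locus_tag`, `group_field`,
#'   `allele_field`, `gene`, and `group_key` (`Eqca-<locus>*<group>`, the
#'   allelic-group identity used throughout).
#' @export
parse_allele_name <- function(full_name) {
  m <- str_match(full_name, "^Eqca-([A-Za-z0-9]+)\\*([A-Za-z0-9]+)(?::(.+))?$")
  bad <- is.na(m[, 1])
  if (any(bad)) {
    abort(paste0("malformed allele name(s): ", paste(full_name[bad], collapse = ", ")))
  }
  locus_tag <- m[, 2]
  gene <- dplyr::case_when(
    str_detect(locus_tag, "^DRA") ~ "DRA",
    str_detect(locus_tag, "^DRB") ~ "DRB",
    str_detect(locus_tag, "^DQA") ~ "DQA",
    str_detect(locus_tag, "^DQB") ~ "DQB",
    TRUE ~ "MHCI"
  )
  tibble(
    full_name = full_name,
    locus_tag = locus_tag,
    group_field = m[, 3],
    allele_field = ifelse(is.na(m[, 4]), "", m[, 4]),
    gene = gene,
    group_key = paste0("Eqca-", locus_tag, "*", m[, 3])
  )
}

#' Load a reference allele database from FASTA
#'
#' Reads an IPD-style FASTA whose headers carry allele names in
#' `Eqca-<locus>*<group>:<allele>` form (anything after the first whitespace
#' is treated as a description and dropped), parses each name, translates each
#' sequence in its gene's registered reading frame, and returns the database
#' as a tibble. Duplicated names are rejected. The reading frame per gene is
#' chosen as the frame in which the largest fraction of that gene's reference
#' alleles translates without internal stops (the amplicons start mid-exon,
#' so no start codon is available to anchor the frame); a warning is issued
#' when fewer than 90% translate stop-free in the chosen frame.
#'
#' @param fasta_source Path to a FASTA file.
#' @return A tibble of class `ela_refdb` with columns `full_name`,
#'   `locus_tag`, `group_field`, `allele_field`, `gene`, `group_key`,
#'   `nt_seq`, `aa_seq`, `classification`; the per-gene frame registry is
#'   stored in the `frames` attribute.
#' @export
load_reference_db <- function(fasta_source) {
  seqs <- Biostrings::readDNAStringSet(fasta_source)
  if (length(seqs) == 0) {
    warn("empty reference FASTA: returning an empty database")
    return(empty_refdb())
  }
  nm <- sub("\\s.*$", "", names(seqs))
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0) {
    abort(paste0("duplicate allele name(s) in reference FASTA: ",
                 paste(unique(dup), collapse = ", ")))
  }
  nt <- toupper(as.character(seqs))
  if (any(!grepl("^[ACGT]+$", nt))) {
    abort(paste0("non-ACGT characters in record(s): ",
                 paste(nm[!grepl("^[ACGT]+$", nt)], collapse = ", ")))
  }
  db <- parse_allele_name(nm)
  db$nt_seq <- unname(nt)
  frames <- register_frames(db)
  db$aa_seq <- vapply(seq_len(nrow(db)), function(i) {
    translate_amplicon(db$nt_seq[i], frames[[db$gene[i]]])
  }, character(1))
  db$classification <- "known_ipd"
  new_refdb(db, frames)
}

new_refdb <- function(db, frames) {
  db <- as_tibble(db)
  attr(db, "frames") <- frames
  class(db) <- c("ela_refdb", class(db))
  db
}

empty_refdb <- function() {
  new_refdb(
    tibble(full_name = character(), locus_tag = character(),
           group_field = character(), allele_field = character(),
           gene = character(), group_key = character(),
           nt_seq = character(), aa_seq = character(),
           classification = character()),
    frames = list(MHCI = 0L, DRA = 0L, DRB = 0L, DQA = 0L, DQB = 0L)
  )
}

#' @export
db_frames <- function(db) attr(db, "frames") %||%
  list(MHCI = 0L, DRA = 0L, DRB = 0L, DQA = 0L, DQB = 0L)

# Pick, per gene, the frame in which most reference alleles are stop-free.
register_frames <- function(db) {
  frames <- list(MHCI = 0L, DRA = 0L, DRB = 0L, DQA = 0L, DQB = 0L)
  for (g in unique(db$gene)) {
    nts <- db$nt_seq[db$gene == g]
    frac <- vapply(0:2, function(f) {
      aa <- vapply(nts, translate_amplicon, character(1), frame_offset = f)
      mean(!grepl("\\*", aa))
    }, numeric(1))
    best <- which.max(frac) - 1L
    if (frac[best + 1L] < 0.9) {
      warn(sprintf("gene %s: only %.0f%% of reference alleles translate stop-free in frame %d",
                   g, 100 * frac[best + 1L], best))
    }
    frames[[g]] <- best
  }
  frames
}

#' Translate an amplicon sequence
#'
#' Translates complete codons starting at `frame_offset`; any trailing partial
#' codon is dropped. Internal stop codons are kept as `*` (classification
#' refuses sequences that fail to translate cleanly; see
#' [classify_sequence()]).
#'
#' @param nt_seq A single nucleotide string (ACGT).
#' @param frame_offset Reading-frame offset, one of 0, 1, 2.
#' @return The amino-acid string.
#' @export
translate_amplicon <- function(nt_seq, frame_offset = 0L) {
  if (length(frame_offset) != 1 || !frame_offset %in% 0:2) {
    abort("frame_offset must be 0, 1 or 2")
  }
  n <- nchar(nt_seq)
  ncod <- (n - frame_offset) %/% 3L
  if (ncod < 1) abort("sequence too short to translate in this frame")
  starts <- frame_offset + 3L * (seq_len(ncod) - 1L) + 1L
  codons <- substring(nt_seq, starts, starts + 2L)
  aa <- unname(GENETIC_CODE_TABLE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

GENETIC_CODE_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aa, codons)
})

#' Amino-acid distance between two sequences
#'
#' Equal-length sequences are compared position by position (Hamming
#' distance). Unequal lengths are compared over a global pairwise alignment
#' (match +1, mismatch -1, gap -2), counting substituted plus
#' inserted/deleted positions; among co-optimal alignments the smallest such
#' count is reported. An empty string is at distance `nchar(other)`. The
#' distance is symmetric.
#'
#' @param a,b Amino-acid strings.
#' @return Non-negative integer distance.
#' @export
aa_distance <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(nchar(a) + nchar(b))
  if (nchar(a) == nchar(b)) {
    return(sum(utf8ToInt(a) != utf8ToInt(b)))
  }
  .aa_align_distance(a, b)
}
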