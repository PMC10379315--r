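# Demultiplexing MID-tagged paired reads and FASTQ I/O.

#' Read paired FASTQ files into a pair table
#'
#' @param fwd_path,rev_path Paths to the forward and reverse FASTQ files
#'   (gzip allowed). Records are paired by position.
#' @return Tibble with columns `read_id`, `fwd_seq`, `fwd_qual`, `rev_seq`,
#'   `rev_qual`.
#' @export
read_paired_fastq <- function(fwd_path, rev_path) {
  f <- Biostrings::readDNAStringSet(fwd_path, format = "fastq", with.qualities = TRUE)
  r <- Biostrings::readDNAStringSet(rev_path, format = "fastq", with.qualities = TRUE)
  if (length(f) != length(r)) abort("forward and reverse FASTQ differ in record count")
  tibble(
    read_id = sub("\\s.*$", "", names(f)),
    fwd_seq = as.character(f),
    fwd_qual = as.character(S4Vectors::mcols(f)$qualities),
    rev_seq = as.character(r),
    rev_qual = as.character(S4Vectors::mcols(r)$qualities)
  )
}

#' Write a pair table to paired FASTQ files
#'
#' @param pairs Pair table as produced by [read_paired_fastq()] or
#'   [simulate_reads()].
#' @param fwd_path,rev_path Output paths.
#' @return `pairs`, invisibly.
#' @export
write_paired_fastq <- function(pairs, fwd_path, rev_path) {
  wr <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  wr(pairs$fwd_seq, pairs$fwd_qual, pairs$read_id, fwd_path)
  wr(pairs$rev_seq, pairs$rev_qual, pairs$read_id, rev_path)
  invisible(pairs)
}

#' Build or read a MID scheme
#'
#' A MID scheme maps a (forward tag, reverse tag) pair to a sample. Tags must
#' have a fixed length within the scheme, tag pairs must be unique, and a
#' scheme is limited to 192 samples per run.
#'
#' @param sample_id,fwd_tag,rev_tag Equal-length character vectors.
#' @return Tibble of class `mid_scheme`.
#' @export
mid_scheme <- function(sample_id, fwd_tag, rev_tag) {
  s <- tibble(sample_id = as.character(sample_id),
              fwd_tag = toupper(fwd_tag), rev_tag = toupper(rev_tag))
  if (nrow(s) > 192) abort("a MID scheme is limited to 192 samples per run")
  if (anyDuplicated(s$sample_id)) abort("duplicate sample ids in MID scheme")
  if (anyDuplicated(paste(s$fwd_tag, s$rev_tag))) {
    abort("duplicate (fwd_tag, rev_tag) pairs in MID scheme")
  }
  if (length(unique(c(nchar(s$fwd_tag), nchar(s$rev_tag)))) > 1) {
    abort("MID tags must have a fixed length within a scheme")
  }
  class(s) <- c("mid_scheme", class(s))
  s
}

#' @rdname mid_scheme
#' @param path TSV file with columns `sample_id`, `fwd_tag`, `rev_tag`.
#' @export
read_mid_scheme <- function(path) {
  s <- utils::read.delim(path, colClasses = "character")
  mid_scheme(s$sample_id, s$fwd_tag, s$rev_tag)
}

#' Demultiplex a pair table by MID combination
#'
#' Reads whose forward and reverse sequences begin with an exactly matching
#' (forward tag, reverse tag) pair are routed to that sample, with the tags
#' (and their quality characters) removed; all other reads land in the
#' `"undetermined"` bucket unmodified. Matching is exact: tags are short and
#' tag-collision errors are costlier than the loss of a few reads.
#'
#' @param pairs Pair table (see [read_paired_fastq()]).
#' @param scheme A [mid_scheme()].
#' @return `pairs` with a `sample_id` column added and tags stripped from
#'   routed reads. The routing report (`sample_id`, `n`) is attached as the
#'   `"report"` attribute and returned by [demux_report()].
#' @export
demultiplex <- function(pairs, scheme) {
  stopifnot(inherits(scheme, "mid_scheme"))
  tl <- nchar(scheme$fwd_tag[1])
  key <- paste(substr(pairs$fwd_seq, 1, tl), substr(pairs$rev_seq, 1, tl))
  idx <- match(key, paste(scheme$fwd_tag, scheme$rev_tag))
  out <- pairs
  out$sample_id <- ifelse(is.na(idx), "undetermined", scheme$sample_id[idx])
  hit <- !is.na(idx)
  out$fwd_seq[hit] <- substr(pairs$fwd_seq[hit], tl + 1L, nchar(pairs$fwd_seq[hit]))
  out$rev_seq[hit] <- substr(pairs$rev_seq[hit], tl + 1L, nchar(pairs$rev_seq[hit]))
  if ("fwd_qual" %in% names(out)) {
    out$fwd_qual[hit] <- substr(pairs$fwd_qual[hit], tl + 1L, nchar(pairs$fwd_qual[hit]))
    out$rev_qual[hit] <- substr(pairs$rev_qual[hit], tl + 1L, nchar(pairs$rev_qual[hit]))
  }
  report <- out |>
    count(.data$sample_id, name = "n") |>
    arrange(.data$sample_id)
  attr(out, "report") <- report
  out
}

#' @rdname demultiplex
#' @param x A demultiplexed pair table.
#' @export
demux_report <- function(x) attr(x, "report")

#' Merge read pairs by overlap
#'
#' FLASH-style merging: the reverse read is reverse-complemented and every
#' candidate overlap with the forward read of length at least `min_overlap`
#' is scored; among overlaps whose mismatch fraction is at most
#' `max_mismatch_frac`, the one with the most matching bases is chosen.
#' Disagreeing overlap bases are resolved towards the base with the higher
#' quality score (ties towards the forward read); overlap qualities take the
#' per-position maximum. Merged length equals
#' `nchar(fwd) + nchar(rev) - overlap`. Pairs with no admissible overlap are
#' kept with `merged = FALSE` and an `NA` sequence.
#'
#' @param pairs Pair table (tags already removed).
#' @param min_overlap Minimum admissible overlap length (bases).
#' @param max_mismatch_frac Maximum fraction of mismatching bases within the
#'   overlap.
#' @return `pairs` with columns `sequence`, `quality`, `overlap`, `merged`
#'   added.
#' @export
merge_pairs <- function(pairs, min_overlap = 10L, max_mismatch_frac = 0.25) {
  has_q <- "fwd_qual" %in% names(pairs)
  rc <- revcomp(pairs$rev_seq)
  rq <- if (has_q) {
    vapply(pairs$rev_qual, function(q) intToUtf8(rev(utf8ToInt(q))), character(1),
           USE.NAMES = FALSE)
  } else {
    strrep("I", nchar(pairs$rev_seq))
  }
  fq <- if (has_q) pairs$fwd_qual else strrep("I", nchar(pairs$fwd_seq))
  res <- .merge_pairs_cpp(pairs$fwd_seq, rc, fq, rq,
                          as.integer(min_overlap), max_mismatch_frac)
  out <- pairs
  out$sequence <- res$sequence
  out$quality <- res$quality
  out$overlap <- res$overlap
  out$merged <- !is.na(res$sequence)
  out
}

#' Mean-quality filter for merged reads
#'
#' A merged read passes when its mean Phred quality is strictly greater than
#' `threshold` (Q28 by default). Reads without quality strings fail with
#' reason `"missing_quality"`.
#'
#' @param reads Tibble with `quality` column.
#' @param threshold Mean Phred threshold; strict inequality.
#' @return `reads` with `mean_quality`, `qc_pass`, `qc_reason` added.
#' @export
quality_filter <- function(reads, threshold = 28) {
  mq <- mean_phred(reads$quality)
  reads$mean_quality <- mq
  reads$qc_pass <- !is.na(mq) & mq > threshold
  reads$qc_reason <- dplyr::case_when(
    is.na(mq) ~ "missing_quality",
    mq > threshold ~ "pass",
    TRUE ~ "below_threshold"
  )
  reads
}
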