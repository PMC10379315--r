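# Low-level sequence helpers shared across the pipeline.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of DNA strings
#'
#' IUPAC-aware reverse complement, vectorised over a character vector.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# Bitmask encoding of bases (A=1, C=2, G=4, T=8); an IUPAC code's mask is the
# union of the bases it allows. A target base matches a primer position when
# the AND of the two masks is non-zero.
.base_bits <- local({
  v <- integer(127)
  for (code in names(IUPAC_SETS)) {
    bits <- sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[IUPAC_SETS[[code]]])
    v[utf8ToInt(code)] <- bits
  }
  v
})

# Number of mismatches between a primer (IUPAC-degenerate) and a same-length
# target window (plain ACGT); NA when lengths differ.
primer_mismatches <- function(primer, target) {
  if (nchar(primer) != nchar(target)) return(NA_integer_)
  pm <- .base_bits[utf8ToInt(primer)]
  tm <- .base_bits[utf8ToInt(target)]
  sum(bitwAnd(pm, tm) == 0L)
}

# Phred string <-> integer scores (Sanger +33 encoding).
phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

int_to_phred <- function(scores) {
  vapply(scores, function(s) intToUtf8(s + 33L), character(1))
}

mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (is.na(q) || !nzchar(q)) return(NA_real_)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}

# Canonical key for an allele set (order-independent identity of haplotypes).
set_key <- function(alleles) {
  paste(sort(unique(alleles)), collapse = "|")
}

key_to_set <- function(key) {
  if (!nzchar(key)) return(character(0))
  strsplit(key, "|", fixed = TRUE)[[1]]
}

# Random DNA of given lengths (respects the caller's RNG state).
random_dna <- function(n, len) {
  vapply(rep_len(len, n), function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

# Random coding-style DNA: stop-free in frame 0 so reference panels translate
# cleanly. Length must be >= 3.
random_coding_dna <- function(n, len) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  codons <- setdiff(codons, stops)
  vapply(rep_len(len, n), function(l) {
    nc <- l %/% 3L
    s <- paste(sample(codons, nc, replace = TRUE), collapse = "")
    rem <- l - 3L * nc
    if (rem > 0) s <- paste0(s, paste(sample(c("A", "C"), rem, replace = TRUE), collapse = ""))
    s
  }, character(1))
}

# Apply substitution errors at a per-base rate to a character vector of
# reads. The per-read error count is binomial; only reads with errors are
# touched.
mutate_bases <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  lens <- nchar(seqs)
  k <- stats::rbinom(length(seqs), lens, rate)
  hit <- which(k > 0)
  for (i in hit) {
    v <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(lens[i], k[i])
    v[pos] <- vapply(v[pos], function(b) sample(setdiff(bases, b), 1),
                     character(1))
    seqs[i] <- paste(v, collapse = "")
  }
  seqs
}
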