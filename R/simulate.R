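# Cohort and read simulator: ground truth for end-to-end validation.
#
# The simulator emulates the statistical structure the pipeline assumes:
# diploid animals drawn as independent haplotype pairs; class I haplotypes
# carrying 6-16 alleles including a small set of universal alleles shared by
# every haplotype; class II haplotypes with a fixed locus layout (1 DRA,
# 2 DQA, 2 DQB, 2-3 DRB); per-allele expression weights spanning ~3 orders
# of magnitude (log-uniform); per-amplicon library pool ratios
# 30:30:10:10:10:10; primer-mismatch-driven allele dropout; uniform
# substitution sequencing error; and MID-tagged 300 bp paired reads.

#' Simulator configuration
#'
#' @param n_animals Animals in the cohort.
#' @param n_haplotypes Haplotypes per class (single integer, used for both).
#' @param haplotype_freqs Optional frequency vector (defaults to uniform);
#'   recycled per class.
#' @param mhci_allele_range Min/max standard + universal alleles per class I
#'   haplotype (inclusive; the observed span of expressed class I genes).
#' @param n_universal Class I universal alleles present on every haplotype.
#' @param drb3_prob Probability a class II haplotype carries a third DRB
#'   locus.
#' @param expression_decades Span of per-allele expression weights in log10
#'   units (weights are log-uniform over this many decades).
#' @param reads_per_sample Total read pairs per animal, split across
#'   amplicons by the panel pool ratios.
#' @param error_rate Per-base substitution error rate applied to reads.
#' @param primer_mismatch Optional tibble (`allele`, `amplicon`,
#'   `mismatches`) of primer-site mismatch counts; alleles exceeding
#'   `mismatch_tolerance` in an amplicon drop out of that amplicon.
#' @param mismatch_tolerance Primer mismatches tolerated before dropout.
#' @param chimera_rate Fraction of reads replaced by two-parent chimeras
#'   (off by default; used to exercise the artifact filter).
#' @param mid_length MID tag length.
#' @param read_length Read length (300 bp chemistry).
#' @param defs Amplicon panel (see [amplicon_defs()]).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_animals = 96, n_haplotypes = 10,
                       haplotype_freqs = NULL,
                       mhci_allele_range = c(6, 16), n_universal = 2,
                       drb3_prob = 0.5, expression_decades = 3,
                       reads_per_sample = 6000, error_rate = 0.001,
                       primer_mismatch = NULL, mismatch_tolerance = 1L,
                       chimera_rate = 0, mid_length = 8L, read_length = 300L,
                       defs = amplicon_defs()) {
  freqs <- haplotype_freqs %||% rep(1 / n_haplotypes, n_haplotypes)
  stopifnot(length(freqs) == n_haplotypes,
            abs(sum(freqs) - 1) < 1e-8,
            all(freqs >= 0), error_rate >= 0, error_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1,
            n_universal < mhci_allele_range[1])
  structure(list(
    n_animals = n_animals, n_haplotypes = n_haplotypes,
    haplotype_freqs = freqs, mhci_allele_range = mhci_allele_range,
    n_universal = n_universal, drb3_prob = drb3_prob,
    expression_decades = expression_decades,
    reads_per_sample = reads_per_sample, error_rate = error_rate,
    primer_mismatch = primer_mismatch,
    mismatch_tolerance = as.integer(mismatch_tolerance),
    chimera_rate = chimera_rate, mid_length = as.integer(mid_length),
    read_length = as.integer(read_length), defs = defs
  ), class = "sim_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Resolve IUPAC degeneracies to concrete bases (first allowed base).
concretize <- function(seq) {
  chartr("RYSWKMBDHVN", "ACCAGACAAAA", seq)
}

#' Simulate a cohort with ground truth
#'
#' Draws haplotype allele complements (class I: universal alleles on every
#' haplotype plus per-haplotype standard alleles; class II: one allele per
#' locus in the layout), per-allele amplicon-region sequences and expression
#' weights, and animals as independent haplotype pairs from the frequency
#' vector (homozygotes arise naturally). Expected read fractions per
#' (animal, amplicon) are expression weights times allele dose, renormalised
#' over non-dropped alleles.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the truth is a pure function of (cfg, seed).
#' @return List of class `sim_truth`: `alleles` (catalog with sequences per
#'   amplicon and expression weights), `haplotypes` (long tibble class /
#'   hap_id / allele), `animals` (animal, class, hap1, hap2), `expected`
#'   (animal, amplicon, allele, expected_fraction), and `cfg`.
#' @export
simulate_cohort <- function(cfg, seed = 1L) {
  with_seed(seed, {
    defs <- cfg$defs
    mhci_amps <- defs$name[defs$gene == "MHCI"]
    # ---- class I allele catalog ----
    n_std_per_hap <- sample(seq(cfg$mhci_allele_range[1] - cfg$n_universal,
                                cfg$mhci_allele_range[2] - cfg$n_universal),
                            cfg$n_haplotypes, replace = TRUE)
    n_std <- sum(n_std_per_hap)
    uni_names <- sprintf("U%02d", seq_len(cfg$n_universal))
    std_names <- sprintf("S%03d", seq_len(n_std))
    hap_alleles_I <- lapply(seq_len(cfg$n_haplotypes), function(h) {
      start <- cumsum(c(0, n_std_per_hap))[h]
      c(uni_names, std_names[start + seq_len(n_std_per_hap[h])])
    })
    # ---- class II allele catalog ----
    loci_II <- function() c("DRA", "DQA1", "DQA2", "DQB1", "DQB2", "DRB1", "DRB2",
                            if (runif(1) < cfg$drb3_prob) "DRB3")
    hap_loci_II <- lapply(seq_len(cfg$n_haplotypes), function(h) loci_II())
    hap_alleles_II <- lapply(seq_len(cfg$n_haplotypes), function(h) {
      paste0(hap_loci_II[[h]], sprintf(".H%02d", h))
    })
    allele_locus_II <- setNames(
      unlist(hap_loci_II),
      unlist(hap_alleles_II)
    )
    # ---- sequences per allele and amplicon ----
    catalog <- dplyr::bind_rows(
      tibble(allele = rep(c(uni_names, std_names), each = length(mhci_amps)),
             gene = "MHCI",
             locus = "MHCI",
             amplicon = rep(mhci_amps, cfg$n_universal + n_std)),
      {
        a2 <- unique(unlist(hap_alleles_II))
        g2 <- sub("[0-9]+$", "", unname(allele_locus_II[a2]))
        tibble(allele = a2, gene = g2, locus = unname(allele_locus_II[a2]),
               amplicon = defs$name[match(g2, defs$gene)])
      }
    )
    ins_len <- defs$insert_length[match(catalog$amplicon, defs$name)]
    catalog$sequence <- random_coding_dna(nrow(catalog), ins_len)
    # expression weight per allele: log-uniform over the configured decades
    alleles <- unique(catalog$allele)
    w <- 10^runif(length(alleles), -cfg$expression_decades, 0)
    catalog$expression <- w[match(catalog$allele, alleles)]
    # ---- animals ----
    draw <- function(n) sample.int(cfg$n_haplotypes, n, replace = TRUE,
                                   prob = cfg$haplotype_freqs)
    animals <- tibble(
      animal = rep(sprintf("A%03d", seq_len(cfg$n_animals)), 2),
      class = rep(c("MHCI", "MHCII"), each = cfg$n_animals),
      hap1 = c(draw(cfg$n_animals), draw(cfg$n_animals)),
      hap2 = c(draw(cfg$n_animals), draw(cfg$n_animals))
    )
    haplotypes <- dplyr::bind_rows(
      tibble(class = "MHCI",
             hap_id = rep(seq_len(cfg$n_haplotypes), lengths(hap_alleles_I)),
             allele = unlist(hap_alleles_I)),
      tibble(class = "MHCII",
             hap_id = rep(seq_len(cfg$n_haplotypes), lengths(hap_alleles_II)),
             allele = unlist(hap_alleles_II))
    )
    expected <- expected_fractions(animals, haplotypes, catalog, cfg)
    structure(list(alleles = catalog, haplotypes = haplotypes,
                   animals = animals, expected = expected, cfg = cfg),
              class = "sim_truth")
  })
}

# Per (animal, amplicon, allele) expected read fraction: expression x dose,
# dropout applied, renormalised within the amplicon.
expected_fractions <- function(animals, haplotypes, catalog, cfg) {
  dose <- animals |>
    pivot_longer(c("hap1", "hap2"), values_to = "hap_id") |>
    inner_join(haplotypes, by = c("class", "hap_id"),
               relationship = "many-to-many") |>
    count(.data$animal, .data$allele, name = "dose")
  x <- dose |>
    inner_join(catalog, by = "allele", relationship = "many-to-many") |>
    mutate(weight = .data$dose * .data$expression)
  if (!is.null(cfg$primer_mismatch)) {
    pm <- cfg$primer_mismatch |> filter(.data$mismatches > cfg$mismatch_tolerance)
    x <- x |> anti_join(pm, by = c("allele", "amplicon"))
  }
  x |>
    group_by(.data$animal, .data$amplicon) |>
    mutate(expected_fraction = .data$weight / sum(.data$weight)) |>
    ungroup() |>
    select("animal", "amplicon", "allele", "expected_fraction")
}

#' Extract a truth genotype matrix
#'
#' The presence/support matrix the haplotyper would see under perfect
#' calling: every allele of the animal's two haplotypes is present with its
#' maximum expected read fraction across amplicons.
#'
#' @param truth A `sim_truth`.
#' @param class `"MHCI"` or `"MHCII"`.
#' @return A `genotype_matrix` tibble (`animal`, `allele`, `support`).
#' @export
truth_genotype_matrix <- function(truth, class = c("MHCI", "MHCII")) {
  class <- match.arg(class)
  cls_alleles <- truth$haplotypes$allele[truth$haplotypes$class == class]
  m <- truth$expected |>
    filter(.data$allele %in% cls_alleles) |>
    group_by(.data$animal, .data$allele) |>
    summarise(support = max(.data$expected_fraction), .groups = "drop")
  structure(m, class = c("genotype_matrix", class(m)))
}

#' Simulate MID-tagged paired reads
#'
#' Reads are drawn multinomially per (animal, amplicon) from the expected
#' fractions; the amplicon template is the concretised forward primer, the
#' allele insert and the reverse complement of the reverse primer; forward /
#' reverse reads are 300 bp windows from either end with the animal's MID
#' tags prepended; substitution errors are applied per base; qualities are
#' constant Q35. With a zero error rate the channel is lossless: the
#' dereplicated pipeline output equals the truth alleles.
#'
#' @param truth A `sim_truth` from [simulate_cohort()].
#' @param seed Integer seed.
#' @return Pair table (`read_id`, `fwd_seq`, `fwd_qual`, `rev_seq`,
#'   `rev_qual`) with the MID scheme in the `"scheme"` attribute and the
#'   per-read truth allele in the `truth_allele` column.
#' @export
simulate_reads <- function(truth, seed = 1L) {
  cfg <- truth$cfg
  with_seed(seed, {
    defs <- cfg$defs
    ids <- unique(truth$animals$animal)
    tags <- unique_tags(2L * length(ids), cfg$mid_length)
    scheme <- mid_scheme(ids,
                         tags[seq_along(ids)],
                         tags[length(ids) + seq_along(ids)])
    # templates per (allele, amplicon)
    cat <- truth$alleles
    di <- match(cat$amplicon, defs$name)
    n_mm <- rep(0L, nrow(cat))
    if (!is.null(cfg$primer_mismatch)) {
      pmi <- match(paste(cat$allele, cat$amplicon),
                   paste(cfg$primer_mismatch$allele, cfg$primer_mismatch$amplicon))
      n_mm <- ifelse(is.na(pmi), 0L, cfg$primer_mismatch$mismatches[pmi])
    }
    fwd_site <- vapply(seq_len(nrow(cat)), function(i) {
      site <- concretize(defs$fwd_primer[di[i]])
      if (n_mm[i] > 0) site <- mutate_k(site, n_mm[i])
      site
    }, character(1))
    cat$template <- paste0(fwd_site, cat$sequence,
                           revcomp(concretize(defs$rev_primer[di])))
    templ_key <- paste(cat$allele, cat$amplicon)

    n_amp <- nrow(defs)
    ef_split <- split(truth$expected,
                      paste(truth$expected$animal, truth$expected$amplicon))
    out <- vector("list", length(ids))
    for (ai in seq_along(ids)) {
      an <- ids[ai]
      amp_n <- as.integer(rmultinom(1, cfg$reads_per_sample, defs$pool_ratio))
      rows <- list()
      for (k in seq_len(n_amp)) {
        if (amp_n[k] == 0) next
        ef <- ef_split[[paste(an, defs$name[k])]]
        if (is.null(ef) || nrow(ef) == 0) next
        cnt <- as.integer(rmultinom(1, amp_n[k], ef$expected_fraction))
        keep <- cnt > 0
        if (!any(keep)) next
        rows[[k]] <- tibble(
          animal = an, amplicon = defs$name[k],
          truth_allele = rep(ef$allele[keep], cnt[keep])
        )
      }
      out[[ai]] <- dplyr::bind_rows(rows)
    }
    reads <- dplyr::bind_rows(out)
    if (nrow(reads) == 0) {
      empty <- tibble(read_id = character(), fwd_seq = character(),
                      fwd_qual = character(), rev_seq = character(),
                      rev_qual = character(), truth_allele = character())
      attr(empty, "scheme") <- scheme
      return(empty)
    }
    templ <- cat$template[match(paste(reads$truth_allele, reads$amplicon), templ_key)]
    # optional chimeras: replace a fraction of reads by two-parent joins
    if (cfg$chimera_rate > 0) {
      is_chi <- runif(nrow(reads)) < cfg$chimera_rate
      idx <- which(is_chi)
      for (i in idx) {
        same <- which(reads$animal == reads$animal[i] &
                        reads$amplicon == reads$amplicon[i])
        if (length(same) < 2) next
        j <- sample(same, 1)
        bp <- sample(seq(20, nchar(templ[i]) - 20), 1)
        templ[i] <- paste0(substr(templ[i], 1, bp),
                           substr(templ[j], bp + 1, nchar(templ[j])))
      }
    }
    si <- match(reads$animal, scheme$sample_id)
    rl <- cfg$read_length - cfg$mid_length
    fwd <- paste0(scheme$fwd_tag[si], substr(templ, 1, rl))
    rc <- revcomp(templ)
    rev <- paste0(scheme$rev_tag[si], substr(rc, 1, rl))
    fwd <- mutate_bases(fwd, cfg$error_rate)
    rev <- mutate_bases(rev, cfg$error_rate)
    q <- strrep(intToUtf8(35 + 33), nchar(fwd))
    pairs <- tibble(
      read_id = sprintf("sim_%07d", seq_along(fwd)),
      fwd_seq = fwd, fwd_qual = q,
      rev_seq = rev, rev_qual = strrep(intToUtf8(35 + 33), nchar(rev)),
      truth_allele = reads$truth_allele,
      truth_amplicon = reads$amplicon
    )
    attr(pairs, "scheme") <- scheme
    pairs
  })
}

# n distinct random tags of the given length.
unique_tags <- function(n, len) {
  tags <- character(0)
  while (length(tags) < n) {
    tags <- unique(c(tags, random_dna(n, len)))
  }
  tags[seq_len(n)]
}

# Mutate exactly k positions of a sequence (used for primer-site mismatches).
mutate_k <- function(seq, k) {
  v <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(v), k)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}
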