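# Cohort and read simulation: determinism, structure, dropout, pool ratios.

test_that("the truth is a pure function of config and seed", {
  cfg <- sim_config(n_animals = 20, n_haplotypes = 4, reads_per_sample = 200)
  t1 <- simulate_cohort(cfg, seed = 3)
  t2 <- simulate_cohort(cfg, seed = 3)
  expect_identical(t1$haplotypes, t2$haplotypes)
  expect_identical(t1$animals, t2$animals)
  expect_identical(t1$expected, t2$expected)
  r1 <- simulate_reads(t1, seed = 4)
  r2 <- simulate_reads(t2, seed = 4)
  expect_identical(r1$fwd_seq, r2$fwd_seq)
  expect_identical(r1$rev_seq, r2$rev_seq)
})

test_that("a degenerate frequency vector makes every animal homozygous", {
  cfg <- sim_config(n_animals = 15, n_haplotypes = 1, haplotype_freqs = 1,
                    reads_per_sample = 0)
  truth <- simulate_cohort(cfg, seed = 1)
  expect_true(all(truth$animals$hap1 == 1 & truth$animals$hap2 == 1))
})

test_that("homozygote fraction follows Hardy-Weinberg expectation", {
  cfg <- sim_config(n_animals = 4000, n_haplotypes = 2,
                    haplotype_freqs = c(0.5, 0.5), reads_per_sample = 0)
  truth <- simulate_cohort(cfg, seed = 9)
  a <- truth$animals[truth$animals$class == "MHCI", ]
  hom <- mean(a$hap1 == a$hap2)
  se <- sqrt(0.5 * 0.5 / 4000)
  expect_lt(abs(hom - 0.5), 3 * se)
})

test_that("expected read fractions sum to one per animal and amplicon", {
  cfg <- sim_config(n_animals = 10, n_haplotypes = 3, reads_per_sample = 0)
  truth <- simulate_cohort(cfg, seed = 2)
  sums <- truth$expected |>
    dplyr::group_by(animal, amplicon) |>
    dplyr::summarise(s = sum(expected_fraction), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("class I haplotypes span the configured allele range with shared universals", {
  cfg <- sim_config(n_animals = 5, n_haplotypes = 8, reads_per_sample = 0,
                    mhci_allele_range = c(6, 16), n_universal = 2)
  truth <- simulate_cohort(cfg, seed = 5)
  h <- truth$haplotypes[truth$haplotypes$class == "MHCI", ]
  sizes <- tapply(h$allele, h$hap_id, length)
  expect_true(all(sizes >= 6 & sizes <= 16))
  uni <- tapply(h$allele, h$hap_id, function(a) sum(grepl("^U", a)))
  expect_true(all(uni == 2))
  # class II layout: 1 DRA, 2 DQA, 2 DQB, 2-3 DRB
  h2 <- truth$haplotypes[truth$haplotypes$class == "MHCII", ]
  for (id in unique(h2$hap_id)) {
    loci <- sub("\\.H[0-9]+$", "", h2$allele[h2$hap_id == id])
    expect_equal(sum(loci == "DRA"), 1)
    expect_equal(sum(grepl("^DQA", loci)), 2)
    expect_equal(sum(grepl("^DQB", loci)), 2)
    expect_true(sum(grepl("^DRB", loci)) %in% 2:3)
  }
})

test_that("primer mismatches beyond tolerance drop an allele from one amplicon only", {
  cfg0 <- sim_config(n_animals = 6, n_haplotypes = 2, reads_per_sample = 0)
  t0 <- simulate_cohort(cfg0, seed = 11)
  victim <- t0$haplotypes$allele[t0$haplotypes$class == "MHCI"][1]
  cfg <- sim_config(n_animals = 6, n_haplotypes = 2, reads_per_sample = 500,
                    error_rate = 0,
                    primer_mismatch = tibble::tibble(
                      allele = victim, amplicon = "MHCI_For1Rev2.2",
                      mismatches = 2L))
  truth <- simulate_cohort(cfg, seed = 11)
  exp_f1 <- truth$expected[truth$expected$amplicon == "MHCI_For1Rev2.2", ]
  exp_f3 <- truth$expected[truth$expected$amplicon == "MHCI_For3.2Rev1", ]
  expect_false(victim %in% exp_f1$allele)
  expect_true(victim %in% exp_f3$allele)
  reads <- simulate_reads(truth, seed = 12)
  expect_false(any(reads$truth_allele == victim &
                     reads$truth_amplicon == "MHCI_For1Rev2.2"))
  expect_true(any(reads$truth_allele == victim &
                    reads$truth_amplicon == "MHCI_For3.2Rev1"))
})

test_that("amplicon read shares follow the 30:30:10:10:10:10 pool ratios", {
  cfg <- sim_config(n_animals = 4, n_haplotypes = 2, reads_per_sample = 5000,
                    error_rate = 0)
  truth <- simulate_cohort(cfg, seed = 21)
  reads <- simulate_reads(truth, seed = 22)
  # recover amplicon identity through the pipeline assignment
  scheme <- attr(reads, "scheme")
  dmx <- demultiplex(reads, scheme)
  m <- merge_pairs(dmx[dmx$sample_id != "undetermined", ])
  asg <- assign_amplicons(m[m$merged, ], amplicon_defs())
  shares <- prop.table(table(asg$amplicon))
  defs <- amplicon_defs()
  for (nm in defs$name) {
    expect_lt(abs(shares[[nm]] - defs$pool_ratio[defs$name == nm]), 0.02)
  }
})

test_that("a zero-error channel reproduces truth alleles exactly after dereplication", {
  cfg <- sim_config(n_animals = 4, n_haplotypes = 2, reads_per_sample = 3000,
                    error_rate = 0)
  truth <- simulate_cohort(cfg, seed = 31)
  reads <- simulate_reads(truth, seed = 32)
  res <- genotype_pipeline(reads, attr(reads, "scheme"))
  seqs <- truth$alleles[, c("allele", "amplicon", "sequence")]
  obs <- res$calls |>
    dplyr::inner_join(seqs, by = c("amplicon", "sequence"))
  # every called sequence is a truth allele sequence of that amplicon
  called <- res$calls[res$calls$status %in% c("called", "recovered"), ]
  expect_true(all(called$sequence %in% seqs$sequence))
  # and the called set equals the truth alleles whose realised read
  # frequency is at or above the threshold, per sample and amplicon
  realised <- reads |>
    dplyr::count(attr(reads, "scheme")$sample_id[match(
      substr(reads$fwd_seq, 1, 8),
      attr(reads, "scheme")$fwd_tag)],
      truth_amplicon, truth_allele) |>
    stats::setNames(c("animal", "amplicon", "allele", "n")) |>
    dplyr::group_by(animal, amplicon) |>
    dplyr::mutate(freq = n / sum(n)) |>
    dplyr::ungroup()
  above <- realised[realised$freq >= 0.002, ]
  above <- dplyr::inner_join(above, seqs, by = c("allele", "amplicon"))
  hit <- dplyr::left_join(
    above, called[called$status == "called", ],
    by = c("animal" = "sample_id", "amplicon", "sequence"))
  expect_true(all(!is.na(hit$status)))
  expect_equal(nrow(above), sum(called$status == "called"))
})

test_that("chimeric reads are generated on demand and flagged by the caller", {
  cfg <- sim_config(n_animals = 2, n_haplotypes = 2, reads_per_sample = 4000,
                    error_rate = 0, chimera_rate = 0.01)
  truth <- simulate_cohort(cfg, seed = 41)
  reads <- simulate_reads(truth, seed = 42)
  res <- genotype_pipeline(reads, attr(reads, "scheme"))
  seqs <- truth$alleles$sequence
  flagged <- res$calls[startsWith(res$calls$status, "artifact"), ]
  called <- res$calls[res$calls$status %in% c("called", "recovered"), ]
  expect_true(all(called$sequence %in% seqs))
})
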