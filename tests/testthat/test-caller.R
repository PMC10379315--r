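# Dereplication, artifact filtering, threshold of resolution, recovery loop.

ins_tbl <- function(seqs, sample = "S1", amplicon = "DRA") {
  tibble::tibble(sample_id = sample, amplicon = amplicon, insert = seqs)
}

test_that("dereplication collapses identical sequences and is order-invariant", {
  set.seed(20)
  a <- elatyper:::random_dna(1, 40)
  b <- elatyper:::random_dna(1, 40)
  calls <- dereplicate(ins_tbl(c(rep(a, 80), rep(b, 20))))
  expect_equal(nrow(calls), 2)
  expect_equal(calls$read_count, c(80L, 20L))
  expect_equal(calls$frequency, c(0.8, 0.2))
  expect_equal(calls$status, rep("provisional", 2))

  perm <- dereplicate(ins_tbl(sample(c(rep(a, 80), rep(b, 20)))))
  expect_equal(calls, perm)

  single <- dereplicate(ins_tbl(rep(a, 50)))
  expect_equal(single$read_count, 50L)
  expect_equal(single$frequency, 1)
  expect_equal(nrow(dereplicate(ins_tbl(character(0)))), 0)
})

test_that("shadow artifacts are flagged by proximity and abundance ratio", {
  set.seed(21)
  a <- elatyper:::random_dna(1, 60)
  b <- a; substr(b, 10, 10) <- setdiff(c("A", "C", "G", "T"), substr(a, 10, 10))[1]
  calls <- dereplicate(ins_tbl(c(rep(a, 1000), rep(b, 8))))
  den <- denoise_artifacts(calls)
  expect_equal(den$status[den$sequence == b], "artifact_shadow")
  expect_equal(den$status[den$sequence == a], "provisional")
  # frequencies recomputed over surviving reads
  expect_equal(den$frequency[den$sequence == a], 1)

  # too abundant to be a shadow (ratio > 0.1)
  calls2 <- dereplicate(ins_tbl(c(rep(a, 1000), rep(b, 200))))
  den2 <- denoise_artifacts(calls2)
  expect_equal(sort(den2$status), rep("provisional", 2))

  # single-entry call set unchanged
  one <- denoise_artifacts(dereplicate(ins_tbl(rep(a, 10))))
  expect_equal(one$status, "provisional")
})

test_that("chimeras are flagged by breakpoint scan against abundant parents", {
  set.seed(22)
  a <- elatyper:::random_dna(1, 360)
  d <- elatyper:::random_dna(1, 360)
  chim <- paste0(substr(a, 1, 200), substr(d, 201, 360))
  calls <- dereplicate(ins_tbl(c(rep(a, 500), rep(d, 400), rep(chim, 30))))
  den <- denoise_artifacts(calls)
  expect_equal(den$status[den$sequence == chim], "artifact_chimera")
  expect_equal(den$status[den$sequence == a], "provisional")
  expect_equal(den$status[den$sequence == d], "provisional")
  # a chimera needs both parents at least as abundant as itself
  calls2 <- dereplicate(ins_tbl(c(rep(a, 500), rep(d, 20), rep(chim, 30))))
  den2 <- denoise_artifacts(calls2)
  expect_equal(den2$status[den2$sequence == chim], "provisional")
})

test_that("the 0.2% threshold is boundary-inclusive", {
  set.seed(23)
  seqs <- elatyper:::random_dna(4, 30)
  counts <- c(7975, 25, 20, 15) # 0.25%, 0.20%, 0.15% of 10,000 non-artifact reads
  calls <- dereplicate(ins_tbl(rep(seqs, counts)))
  thr <- apply_threshold(denoise_artifacts(calls))
  st <- setNames(thr$status, thr$sequence)
  expect_equal(unname(st[seqs[2]]), "called")       # 0.25%
  expect_equal(unname(st[seqs[3]]), "called")       # exactly 0.20%
  expect_equal(unname(st[seqs[4]]), "sub_threshold") # 0.15%
})

test_that("raising the threshold never adds called entries", {
  set.seed(24)
  seqs <- elatyper:::random_dna(8, 30)
  calls <- dereplicate(ins_tbl(rep(seqs, c(4000, 2000, 1000, 500, 200, 100, 50, 8))))
  den <- denoise_artifacts(calls)
  called_at <- function(t) {
    x <- apply_threshold(den, calling_config(freq_threshold = t))
    sort(x$sequence[x$status == "called"])
  }
  prev <- called_at(0.0005)
  for (t in c(0.002, 0.01, 0.05, 0.2)) {
    cur <- called_at(t)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("recovery requires an exact cohort-confirmed match and enough reads", {
  set.seed(25)
  a <- elatyper:::random_dna(1, 50)   # confirmed in S2, sub-threshold in S1
  b <- elatyper:::random_dna(1, 50)   # sub-threshold everywhere
  fill1 <- elatyper:::random_dna(1, 50)
  fill2 <- elatyper:::random_dna(1, 50)
  cohort <- dplyr::bind_rows(
    ins_tbl(c(rep(fill1, 8978), rep(a, 11), rep(b, 11)), sample = "S1"),
    ins_tbl(c(rep(fill2, 9900), rep(a, 100)), sample = "S2")
  )
  calls <- recover_alleles(apply_threshold(denoise_artifacts(dereplicate(cohort))))
  s1 <- calls[calls$sample_id == "S1", ]
  expect_equal(s1$status[s1$sequence == a], "recovered") # 0.12%, matches S2 call
  expect_equal(s1$status[s1$sequence == b], "sub_threshold")
  s2 <- calls[calls$sample_id == "S2", ]
  expect_equal(s2$status[s2$sequence == a], "called") # 1%
})

test_that("recovery is order-independent and recovered entries stay sub-threshold support", {
  set.seed(26)
  a <- elatyper:::random_dna(1, 50)
  f <- elatyper:::random_dna(3, 50)
  cohort <- dplyr::bind_rows(
    ins_tbl(c(rep(f[1], 9985), rep(a, 15)), sample = "S1"),
    ins_tbl(c(rep(f[2], 9960), rep(a, 40)), sample = "S2"),
    ins_tbl(c(rep(f[3], 9985), rep(a, 15)), sample = "S3")
  )
  base <- apply_threshold(denoise_artifacts(dereplicate(cohort)))
  r1 <- recover_alleles(base)
  r2 <- recover_alleles(base[sample(seq_len(nrow(base))), ]) |>
    dplyr::arrange(sample_id, amplicon, dplyr::desc(read_count), sequence)
  expect_equal(r1 |> dplyr::arrange(sample_id, amplicon, dplyr::desc(read_count), sequence),
               r2)
  # every recovered sequence equals a called sequence somewhere in the cohort
  rec <- r1$sequence[r1$status == "recovered"]
  expect_true(all(rec %in% r1$sequence[r1$status == "called"]))
})

test_that("the homozygote double-dose route recovers heterozygote sub-threshold alleles", {
  set.seed(27)
  low <- elatyper:::random_dna(1, 50)
  f <- elatyper:::random_dna(3, 50)
  cohort <- dplyr::bind_rows(
    ins_tbl(c(rep(f[1], 9960), rep(low, 40)), sample = "hom"),  # 0.40%: double dose
    ins_tbl(c(rep(f[2], 9985), rep(low, 15)), sample = "het1"), # 0.15%
    ins_tbl(c(rep(f[3], 9985), rep(low, 15)), sample = "het2")  # 0.15%
  )
  calls <- recover_alleles(apply_threshold(denoise_artifacts(dereplicate(cohort))))
  st <- calls[calls$sequence == low, c("sample_id", "status")]
  expect_equal(st$status[st$sample_id == "hom"], "called")
  expect_equal(st$status[st$sample_id == "het1"], "recovered")
  expect_equal(st$status[st$sample_id == "het2"], "recovered")
})

test_that("class I amplicon union keeps alleles seen by either primer pair once", {
  calls <- tibble::tibble(
    sample_id = "S1",
    amplicon = c("MHCI_For1Rev2.2", "MHCI_For1Rev2.2", "MHCI_For3.2Rev1"),
    sequence = c("AAA", "CCC", "GGG"),
    read_count = c(50L, 10L, 30L),
    frequency = c(0.5, 0.05, 0.3),
    status = c("called", "called", "recovered"),
    assigned_name = c("Eqca-1*001:01", "Eqca-MHCI*gb2:01", "Eqca-1*001:01")
  )
  merged <- merge_mhci_amplicons(calls)
  expect_equal(nrow(merged), 2)
  one <- merged[merged$allele == "Eqca-1*001:01", ]
  expect_equal(one$support, 0.5)       # max frequency across amplicons
  expect_equal(one$status, "called")   # called in either amplicon wins
  expect_equal(one$amplicons, "MHCI_For1Rev2.2,MHCI_For3.2Rev1")
  # a single-amplicon (short-form) allele is present
  expect_true("Eqca-MHCI*gb2:01" %in% merged$allele)
})
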