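# Co-segregation haplotype inference, variant families, universals, partials.

m_from_sets <- function(sets) cohort_matrix(sets)

test_that("three haplotypes are recovered from five informative animals", {
  H1 <- c("a", "b", "c"); H2 <- c("d", "e"); H3 <- c("f", "g")
  sets <- list(
    A1 = H1, A2 = sort(c(H1, H2)), A3 = sort(c(H2, H3)),
    A4 = sort(c(H1, H3)), A5 = H2
  )
  hap <- infer_haplotypes(m_from_sets(sets), class = "MHCI")
  keys <- sort(vapply(hap$pool$alleles, paste, character(1), collapse = "+"))
  expect_equal(keys, c("a+b+c", "d+e", "f+g"))
  expect_true(all(hap$pool$confirmed))
  asn <- hap$assignments
  expect_equal(sum(!is.na(asn$hap1)), 5)
  # A1 and A5 are homozygotes
  expect_equal(asn$hap1[asn$animal == "A1"], asn$hap2[asn$animal == "A1"])
  expect_equal(asn$hap1[asn$animal == "A5"], asn$hap2[asn$animal == "A5"])
  # occurrences: H1 in A1 (x2), A2, A4 -> 4
  h1_id <- hap$pool$id[vapply(hap$pool$alleles, function(x) setequal(x, H1), logical(1))]
  expect_equal(hap$pool$occurrences[hap$pool$id == h1_id], 4L)
})

test_that("an animal whose set equals one haplotype and nothing else is homozygous", {
  H1 <- c("a", "b"); H2 <- c("c", "d")
  sets <- list(A1 = H1, A2 = H1, A3 = sort(c(H1, H2)), A4 = sort(c(H1, H2)))
  hap <- infer_haplotypes(m_from_sets(sets), class = "MHCI")
  asn <- hap$assignments
  expect_equal(asn$hap1[asn$animal == "A1"], asn$hap2[asn$animal == "A1"])
})

test_that("a residual seen in one animal becomes an unconfirmed haplotype", {
  H1 <- c("a", "b", "c"); H2 <- c("d", "e")
  sets <- list(A1 = H1, A2 = H1, A3 = sort(c(H1, H2)), A4 = sort(c(H1, H2)),
               A5 = sort(c(H1, "x", "y")))
  hap <- infer_haplotypes(m_from_sets(sets), class = "MHCI")
  un <- hap$pool[!hap$pool$confirmed, ]
  expect_equal(nrow(un), 1)
  expect_true(setequal(un$alleles[[1]], c("x", "y")))
  expect_match(un$id, "^unHP1\\.")
  asn <- hap$assignments
  expect_equal(sort(c(asn$hap1[asn$animal == "A5"], asn$hap2[asn$animal == "A5"])),
               sort(c(hap$pool$id[hap$pool$confirmed &
                                    vapply(hap$pool$alleles, function(x) setequal(x, H1),
                                           logical(1))], un$id)))
})

test_that("animals inconsistent with every decomposition are left unassigned", {
  H1 <- c("a", "b"); H2 <- c("c", "d")
  sets <- list(A1 = H1, A2 = H1, A3 = H2, A4 = H2,
               odd = c("p", "q", "r"))
  hap <- infer_haplotypes(m_from_sets(sets), class = "MHCI")
  asn <- hap$assignments
  expect_true(is.na(asn$hap1[asn$animal == "odd"]))
  expect_true(setequal(asn$unassigned_alleles[[which(asn$animal == "odd")]],
                       c("p", "q", "r")))
})

test_that("an empty matrix yields an empty pool", {
  m <- cohort_matrix(list())
  hap <- infer_haplotypes(m[0, ], class = "MHCII")
  expect_equal(nrow(hap$pool), 0)
})

test_that("inference is deterministic", {
  set.seed(30)
  co <- gen_small_cohort(99)
  h1 <- infer_haplotypes(m_from_sets(co$sets), class = "MHCI")
  h2 <- infer_haplotypes(m_from_sets(co$sets), class = "MHCI")
  expect_identical(h1$pool, h2$pool)
  expect_identical(h1$assignments, h2$assignments)
})

test_that("universals shared by both haplotypes of an animal are handled", {
  U <- c("u1", "u2")
  H1 <- sort(c(U, "a", "b")); H2 <- sort(c(U, "c", "d")); H3 <- sort(c(U, "e"))
  sets <- list(A1 = H1, A2 = H1, A3 = sort(union(H1, H2)), A4 = sort(union(H1, H2)),
               A5 = sort(union(H2, H3)), A6 = sort(union(H1, H3)), A7 = H2)
  hap <- infer_haplotypes(m_from_sets(sets), class = "MHCI",
                          universal_alleles = U)
  keys <- sort(vapply(hap$pool$alleles, paste, character(1), collapse = "+"))
  expect_equal(keys, sort(c(paste(H1, collapse = "+"), paste(H2, collapse = "+"),
                            paste(H3, collapse = "+"))))
})

test_that("variant families group by allelic-group Jaccard with letters by frequency", {
  pool <- tibble::tibble(
    key = c("k1", "k2", "k3"),
    alleles = list(
      paste0("Eqca-MHCI*gb", 1:15, ":01"),
      c(paste0("Eqca-MHCI*gb", 1:10, ":01"), paste0("Eqca-MHCI*gb", 11:15, ":02")),
      paste0("Eqca-MHCI*no", 1:5, ":01")
    ),
    class = "MHCI", occurrences = c(10L, 30L, 5L),
    n_animals = c(6L, 16L, 3L), confirmed = TRUE, partial = FALSE
  )
  g <- group_variants(pool)
  # allelic substitutions keep group content identical -> same family
  expect_equal(g$family_number[1], g$family_number[2])
  expect_false(g$family_number[3] == g$family_number[1])
  # letters by descending occurrences: the 30x haplotype is 'a'
  expect_equal(g$subtype_letter[g$occurrences == 30], "a")
  expect_equal(g$subtype_letter[g$occurrences == 10], "b")
  expect_equal(g$subtype_letter[g$occurrences == 5], "")
  expect_equal(g$id[g$occurrences == 30], "HP1.1a")
})

test_that("a Jaccard of exactly 0.5 joins a family (boundary inclusive)", {
  pool <- tibble::tibble(
    key = c("k1", "k2"),
    alleles = list(paste0("Eqca-MHCI*gb", 1:2, ":01"),
                   paste0("Eqca-MHCI*gb", 2:3, ":01")), # intersection 1, union 3? no: {1,2} vs {2,3}: J = 1/3
    class = "MHCI", occurrences = c(4L, 2L), n_animals = c(2L, 1L),
    confirmed = c(TRUE, FALSE), partial = FALSE
  )
  g <- group_variants(pool, jaccard_min = 1 / 3)
  expect_equal(g$family_number[1], g$family_number[2])
  g2 <- group_variants(pool, jaccard_min = 0.34)
  expect_equal(length(unique(g2$family_number)), 2)
  # exactly at 0.5: {1,2,3} vs {2,3,4}: J = 2/4
  pool$alleles <- list(paste0("Eqca-MHCI*gb", 1:3, ":01"),
                       paste0("Eqca-MHCI*gb", 2:4, ":01"))
  g3 <- group_variants(pool, jaccard_min = 0.5)
  expect_equal(g3$family_number[1], g3$family_number[2])
})

test_that("allelic groups covering a majority of haplotypes are universal", {
  pool <- tibble::tibble(
    alleles = c(
      lapply(1:12, function(i) c("Eqca-MHCI*gb26:01", sprintf("Eqca-MHCI*no%d:01", i))),
      list(c("Eqca-MHCI*gb99:01", "Eqca-MHCI*no13:01"))
    ),
    class = "MHCI", occurrences = 2L, n_animals = 2L, confirmed = TRUE,
    partial = FALSE
  )
  u <- classify_universal(pool)
  expect_equal(u$label[u$allele == "Eqca-MHCI*gb26:01"], "universal") # 12 of 13
  expect_equal(u$label[u$allele == "Eqca-MHCI*gb99:01"], "standard")  # 1 of 13
})

test_that("group-level union coverage makes split subtypes universal", {
  # two subtypes of one group each cover half the haplotypes; union everything
  alleles <- lapply(1:10, function(i) {
    c(sprintf("Eqca-2*001:%02d", (i %% 2) + 1), sprintf("Eqca-MHCI*no%d:01", i))
  })
  pool <- tibble::tibble(alleles = alleles, class = "MHCI", occurrences = 2L,
                         n_animals = 2L, confirmed = TRUE, partial = FALSE)
  u <- classify_universal(pool)
  expect_true(all(u$label[grepl("^Eqca-2\\*001", u$allele)] == "universal"))
})

test_that("class II haplotypes missing a whole DQA or DQB class are flagged partial", {
  pool <- tibble::tibble(
    key = c("k1", "k2", "k3"),
    alleles = list(
      c("Eqca-DQB1*001:01", "Eqca-DRA*001:01", "Eqca-DRB1*001:01"), # no DQA
      c("Eqca-DQA1*001:01", "Eqca-DQB1*001:01", "Eqca-DRA*001:01",
        "Eqca-DRB1*001:01"),                                        # complete
      c("Eqca-DQA1*002:01", "Eqca-DRA*001:02", "Eqca-DRB1*002:01")  # no DQB
    ),
    class = "MHCII", occurrences = c(4L, 4L, 1L), n_animals = c(2L, 2L, 1L),
    confirmed = c(TRUE, TRUE, FALSE), partial = FALSE
  )
  g <- flag_partial(group_variants(pool))
  has <- function(al) which(vapply(g$alleles, function(x) al %in% x, logical(1)))
  no_dqa <- has("Eqca-DQB1*001:01")[!has("Eqca-DQB1*001:01") %in% has("Eqca-DQA1*001:01")]
  complete <- intersect(has("Eqca-DQA1*001:01"), has("Eqca-DQB1*001:01"))
  no_dqb <- has("Eqca-DQA1*002:01")
  expect_true(g$partial[no_dqa])
  expect_false(g$partial[complete])
  expect_true(g$partial[no_dqb])
  expect_match(g$id[no_dqa], "^pHP2\\.")
  expect_false(grepl("p", g$id[complete], fixed = TRUE))
  expect_match(g$id[no_dqb], "^unpHP2\\.")
})

test_that("genotype matrices take presence from called/recovered and max support", {
  calls <- tibble::tibble(
    sample_id = c("A", "A", "A", "B"),
    amplicon = c("DQA", "DQA", "DQB", "DQA"),
    sequence = c("s1", "s2", "s3", "s1"),
    read_count = c(100L, 5L, 50L, 80L),
    frequency = c(0.9, 0.001, 0.5, 0.8),
    status = c("called", "sub_threshold", "called", "recovered"),
    assigned_name = c("Eqca-DQA1*001:01", "Eqca-DQA1*002:01",
                      "Eqca-DQB1*001:01", "Eqca-DQA1*001:01")
  )
  m <- build_genotype_matrix(calls)
  expect_equal(nrow(m), 3) # sub_threshold entry excluded
  expect_equal(m$support[m$animal == "B"], 0.8) # recovered present with its support
})
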