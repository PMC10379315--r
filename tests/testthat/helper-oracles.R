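# Independent oracles and fixture builders used across the suite.

# ---- translation oracle: Biostrings codon-by-codon ----
oracle_translate <- function(nt, frame) {
  ncod <- (nchar(nt) - frame) %/% 3L
  sub <- substr(nt, frame + 1L, frame + 3L * ncod)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

# ---- alignment-distance oracle: plain R dynamic programme ----
# Maximise score (match +1, mismatch -1, gap -2); among co-optimal
# alignments minimise substituted + indel positions.
oracle_aa_distance <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(nchar(a) + nchar(b))
  if (nchar(a) == nchar(b)) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    return(sum(av != bv))
  }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1); D <- matrix(0, n + 1, m + 1)
  S[1, ] <- -2 * (0:m); D[1, ] <- 0:m
  S[, 1] <- -2 * (0:n); D[, 1] <- 0:n
  for (i in 1:n) for (j in 1:m) {
    match <- av[i] == bv[j]
    cand_s <- c(S[i, j] + ifelse(match, 1, -1), S[i, j + 1] - 2, S[i + 1, j] - 2)
    cand_d <- c(D[i, j] + ifelse(match, 0, 1), D[i, j + 1] + 1, D[i + 1, j] + 1)
    best <- max(cand_s)
    S[i + 1, j + 1] <- best
    D[i + 1, j + 1] <- min(cand_d[cand_s == best])
  }
  D[n + 1, m + 1]
}

# ---- overlap oracle: score every offset, no pruning ----
# Returns c(overlap, matches), or c(0, 0) when no admissible overlap.
# Tie-break: most matches, then longest overlap.
oracle_overlap <- function(fwd, rev_rc, min_overlap = 10, max_mismatch_frac = 0.25) {
  fv <- utf8ToInt(fwd); rv <- utf8ToInt(rev_rc)
  nf <- length(fv); nr <- length(rv)
  best <- c(0L, -1L)
  for (o in seq(min_overlap, min(nf, nr))) {
    m <- sum(fv[(nf - o + 1):nf] == rv[1:o])
    if ((o - m) / o <= max_mismatch_frac &&
        (m > best[2] || (m == best[2] && o > best[1]))) {
      best <- c(o, m)
    }
  }
  if (best[2] < 0) c(0L, 0L) else best
}

# ---- small-cohort generator for haplotype-inference tests ----
# Disjoint haplotypes in the identifiable co-segregation regime: every
# haplotype is carried by >= 2 animals and recurs in >= 2 distinct diplotype
# contexts (otherwise a haplotype pair that only ever co-occurs is
# indistinguishable from a homozygous union); total alleles <= 12,
# animals <= 8.
gen_small_cohort <- function(seed) {
  set.seed(seed)
  repeat {
    n_hap <- sample(2:4, 1)
    sizes <- sample(2:4, n_hap, replace = TRUE)
    while (sum(sizes) > 12) sizes <- sizes - 1L
    if (any(sizes < 1)) next
    pool_alleles <- paste0("a", seq_len(sum(sizes)))
    haps <- split(pool_alleles, rep(seq_len(n_hap), sizes))
    n_animals <- sample(max(4, n_hap + 1):8, 1)
    dip <- cbind(sample(n_hap, n_animals, replace = TRUE),
                 sample(n_hap, n_animals, replace = TRUE))
    carriers <- vapply(seq_len(n_hap), function(h) {
      sum(dip[, 1] == h | dip[, 2] == h)
    }, integer(1))
    if (!all(carriers >= 2)) next
    contexts <- vapply(seq_len(n_hap), function(h) {
      rows <- dip[dip[, 1] == h | dip[, 2] == h, , drop = FALSE]
      length(unique(apply(t(apply(rows, 1, sort)), 1, paste, collapse = "/")))
    }, integer(1))
    if (!all(contexts >= 2)) next
    # seedability: co-segregation inference starts from homozygotes and
    # resolves the rest by residual chaining; require the closure to reach
    # every haplotype
    known <- unique(dip[dip[, 1] == dip[, 2], 1])
    repeat {
      new <- unique(c(dip[dip[, 1] %in% known, 2], dip[dip[, 2] %in% known, 1]))
      if (all(new %in% known)) break
      known <- union(known, new)
    }
    if (length(setdiff(seq_len(n_hap), known)) > 0) next
    sets <- lapply(seq_len(n_animals), function(i) {
      sort(unique(c(haps[[dip[i, 1]]], haps[[dip[i, 2]]])))
    })
    names(sets) <- sprintf("an%02d", seq_len(n_animals))
    return(list(haps = haps, dip = dip, sets = sets))
  }
}

cohort_matrix <- function(sets) {
  tibble::tibble(
    animal = rep(names(sets), lengths(sets)),
    allele = unlist(sets),
    support = 0.05
  ) |> structure(class = c("genotype_matrix", class(tibble::tibble())))
}

# ---- exhaustive-search oracle over consistent diplotype decompositions ----
# Finds ALL minimal pools of allele sets such that every animal's set is the
# union of two pool members (one member taken twice = homozygote); overlap
# between the two members must be within `shareable`. Returns a list of
# pools (each a sorted character vector of set keys).
oracle_min_pools <- function(sets, shareable = character(0)) {
  skey <- function(x) paste(sort(x), collapse = "|")
  decomps <- lapply(sets, function(S) {
    n <- length(S)
    out <- list()
    # enumerate c over subsets of S (bitmask); partner d = (S \ c) + e,
    # e subset of c-intersect-shareable
    for (mask in 1:(2^n - 1)) {
      cc <- S[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
      rest <- setdiff(S, cc)
      sh <- intersect(cc, shareable)
      emasks <- if (length(sh) == 0) list(character(0)) else {
        lapply(0:(2^length(sh) - 1), function(em) {
          sh[bitwAnd(em, 2^(seq_along(sh) - 1)) > 0]
        })
      }
      for (e in emasks) {
        dd <- sort(c(rest, e))
        if (length(dd) == 0) {
          if (length(cc) == n) out[[length(out) + 1]] <- c(skey(cc), skey(cc))
          next
        }
        k1 <- skey(cc); k2 <- skey(dd)
        if (k1 == k2 && length(cc) != n) next
        out[[length(out) + 1]] <- sort(c(k1, k2))
      }
    }
    unique(out)
  })
  # iterative deepening on pool size
  animal_order <- order(lengths(decomps))
  decomps <- decomps[animal_order]
  found <- list()
  search <- function(idx, pool, budget) {
    if (idx > length(decomps)) {
      found[[length(found) + 1]] <<- sort(pool)
      return(invisible())
    }
    d <- decomps[[idx]]
    covered <- vapply(d, function(p) all(p %in% pool), logical(1))
    if (any(covered)) {
      search(idx + 1, pool, budget)
      # also allow adding members (other decompositions) within budget --
      # needed for completeness of "all minimal pools": skip, since any
      # extra member would exceed minimal size elsewhere or be found via
      # another branch
    } else {
      for (p in d) {
        new <- setdiff(p, pool)
        if (length(new) <= budget) {
          search(idx + 1, c(pool, new), budget - length(new))
        }
      }
    }
    invisible()
  }
  for (k in 1:6) {
    found <- list()
    search(1, character(0), k)
    if (length(found) > 0) {
      return(unique(found[lengths(found) == min(lengths(found))]))
    }
  }
  list()
}

# ---- evaluation of inferred haplotypes against simulator truth ----
eval_inference <- function(truth, hap, cls) {
  truth_sets <- truth$haplotypes[truth$haplotypes$class == cls, ]
  truth_keys <- vapply(split(truth_sets$allele, truth_sets$hap_id),
                       function(a) paste(sort(a), collapse = "|"), character(1))
  found <- vapply(hap$pool$alleles, function(a) paste(sort(a), collapse = "|"),
                  character(1))
  poolkey <- stats::setNames(found, hap$pool$id)
  tru <- truth$animals[truth$animals$class == cls, ]
  asn <- hap$assignments
  ok <- mapply(function(an, h1, h2) {
    t <- tru[tru$animal == an, ]
    truk <- sort(c(truth_keys[as.character(t$hap1)],
                   truth_keys[as.character(t$hap2)]))
    if (is.na(h1)) return(FALSE)
    identical(unname(truk), unname(sort(c(poolkey[h1], poolkey[h2]))))
  }, asn$animal, asn$hap1, asn$hap2)
  list(hap_recovery = mean(truth_keys %in% found), diplotype_acc = mean(ok))
}

# ---- toy reference FASTA builder ----
write_toy_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(mapply(function(n, s) c(paste0(">", n), s),
                           names(records), records, SIMPLIFY = FALSE)),
             path)
  path
}
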