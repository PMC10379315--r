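# Haplotype inference from recurrent co-segregation of alleles.
#
# An animal's expressed genotype is the union of the allele sets of its two
# (unphased) haplotypes. Haplotypes are therefore only identifiable through
# recurrence: a set of alleles recurring across animals -- as a whole
# (putative homozygotes, or the same diplotype) or as the residual left after
# removing a known haplotype -- is evidence of one chromosome's allele
# complement. A candidate confirmed when seen in at least `min_support_animals`
# distinct animals; a set seen in a single animal stays putative ("un"
# prefix).

#' Build a genotype matrix from final calls
#'
#' One column (allele) per assigned name; presence means called or recovered;
#' support is the maximum read frequency across contributing amplicons.
#'
#' @param calls Cohort call sets carrying `assigned_name` and `status`
#'   (class I calls should first go through [merge_mhci_amplicons()]; its
#'   output is also accepted directly).
#' @return A long tibble of class `genotype_matrix` with columns `animal`,
#'   `allele`, `support`.
#' @export
build_genotype_matrix <- function(calls) {
  if (all(c("allele", "support") %in% names(calls))) {
    m <- calls |>
      group_by(animal = .data$sample_id, .data$allele) |>
      summarise(support = max(.data$support), .groups = "drop")
  } else {
    stopifnot("assigned_name" %in% names(calls))
    m <- calls |>
      filter(.data$status %in% c("called", "recovered"),
             !is.na(.data$assigned_name)) |>
      group_by(animal = .data$sample_id, allele = .data$assigned_name) |>
      summarise(support = max(.data$frequency), .groups = "drop")
  }
  class(m) <- c("genotype_matrix", class(m))
  m
}

#' Infer haplotypes by co-segregation
#'
#' Iterative inference over one MHC class:
#' \enumerate{
#'   \item Candidate haplotypes are seeded with every animal's full allele
#'     set (putative homozygotes and repeated diplotypes).
#'   \item For every animal containing a candidate as a subset, the residual
#'     alleles propose a further candidate (both the plain residual and the
#'     residual plus the animal's shareable alleles, since the two haplotypes
#'     of one animal may share near-universal alleles); repeated to a
#'     fixpoint.
#'   \item A minimal explaining pool is selected greedily by recurrence
#'     (candidates appearing in the decompositions of the most animals
#'     first), then pruned.
#'   \item Animals are assigned the decomposition over the pool that
#'     maximises total haplotype usage; an animal whose set equals one
#'     haplotype and nothing else is a homozygote. Animals containing exactly
#'     one confirmed haplotype plus a residual yield an unconfirmed
#'     haplotype; animals inconsistent with every decomposition are left
#'     fully unassigned.
#' }
#' Two haplotypes of one animal may only overlap in *shareable* alleles:
#' those supplied in `universal_alleles`, or (by default) alleles present in
#' at least `shared_allele_frac` of animals.
#'
#' Occurrences count homozygotes twice; confirmation counts distinct animals
#' (`>= min_support_animals`). Family/subtype identities and ids are assigned
#' by [group_variants()], which is applied to the pool before returning.
#'
#' @param m A `genotype_matrix` (one class).
#' @param class `"MHCI"` or `"MHCII"` (used for haplotype ids HP1.x / HP2.x).
#' @param min_support_animals Distinct animals required for confirmation.
#' @param shared_allele_frac Animal-fraction at or above which an allele is
#'   treated as shareable between the two haplotypes of one animal.
#' @param universal_alleles Optional explicit shareable alleles (overrides
#'   auto-detection).
#' @param min_animals_for_shared Auto-detection of shareable alleles is only
#'   attempted in cohorts of at least this many animals: in small cohorts a
#'   frequent haplotype's private alleles are indistinguishable from
#'   universal ones by animal frequency.
#' @param jaccard_min Family-grouping threshold passed to [group_variants()].
#' @return An object of class `ela_haplotypes`: list with `pool` (tibble:
#'   `id`, `class`, `family_number`, `subtype_letter`, `alleles` list-column,
#'   `occurrences`, `n_animals`, `confirmed`, `partial`) and `assignments`
#'   (tibble: `animal`, `hap1`, `hap2`, `unassigned_alleles` list-column,
#'   `ambiguous`).
#' @export
infer_haplotypes <- function(m, class = c("MHCI", "MHCII"),
                             min_support_animals = 2L,
                             shared_allele_frac = 0.9,
                             universal_alleles = NULL,
                             min_animals_for_shared = 20L,
                             jaccard_min = 0.5) {
  class <- match.arg(class)
  if (nrow(m) == 0) return(empty_haplotypes(class))
  sets <- split(m$allele, m$animal)
  sets <- lapply(sets, function(a) sort(unique(a)))
  # canonical animal order: ascending set size, ties by id
  ord <- order(lengths(sets), names(sets))
  sets <- sets[ord]
  animals <- names(sets)
  n_animals <- length(animals)
  support <- m |> group_by(.data$animal, .data$allele) |>
    summarise(support = max(.data$support), .groups = "drop")

  shareable <- universal_alleles %||% {
    if (n_animals >= min_animals_for_shared) {
      tab <- table(unlist(lapply(sets, unique)))
      names(tab)[tab >= shared_allele_frac * n_animals]
    } else {
      character(0)
    }
  }

  cand <- generate_candidates(sets, shareable)
  decomps <- lapply(sets, animal_decompositions, cand = cand, shareable = shareable)
  pool_keys <- select_pool(decomps)

  asn <- assign_animals(sets, decomps, pool_keys, min_support_animals, shareable)
  build_haplotype_object(asn, sets, class, min_support_animals, jaccard_min)
}

empty_haplotypes <- function(class) {
  structure(list(
    pool = tibble(id = character(), class = character(),
                  family_number = integer(), subtype_letter = character(),
                  alleles = list(), occurrences = integer(),
                  n_animals = integer(), confirmed = logical(),
                  partial = logical()),
    assignments = tibble(animal = character(), hap1 = character(),
                         hap2 = character(), unassigned_alleles = list(),
                         ambiguous = logical())
  ), class = "ela_haplotypes")
}

# Candidate generation: full sets, then residual closure.
generate_candidates <- function(sets, shareable, max_rounds = 4L, max_cand = 5000L) {
  keys <- unique(vapply(sets, set_key, character(1)))
  cand <- lapply(keys, key_to_set)
  names(cand) <- keys
  for (round in seq_len(max_rounds)) {
    new_keys <- character(0)
    for (S in sets) {
      sh <- intersect(shareable, S)
      for (c in cand) {
        if (length(c) >= length(S)) next
        if (!all(c %in% S)) next
        r1 <- setdiff(S, c)
        if (length(r1) > 0) {
          k1 <- set_key(r1)
          if (is.null(cand[[k1]])) new_keys <- c(new_keys, k1)
          r2 <- sort(union(r1, sh))
          k2 <- set_key(r2)
          if (is.null(cand[[k2]])) new_keys <- c(new_keys, k2)
        }
      }
    }
    new_keys <- unique(new_keys)
    if (length(new_keys) == 0) break
    for (k in new_keys) cand[[k]] <- key_to_set(k)
    if (length(cand) > max_cand) break
  }
  cand
}

# All decompositions of one animal's set over the candidate list:
# unordered pairs (c, d), c union d == S, overlap restricted to shareable
# alleles (a homozygote, c == d == S, is always admissible). A candidate
# consisting solely of shareable (universal) alleles carries no
# distinguishing content and cannot act as a haplotype unless it is the
# animal's entire set.
animal_decompositions <- function(S, cand, shareable) {
  subs <- keep(cand, ~ all(.x %in% S) &&
                 (length(setdiff(.x, shareable)) > 0 || length(.x) == length(S)))
  keys <- names(subs)
  out <- list()
  nsub <- length(subs)
  key_S <- set_key(S)
  for (i in seq_len(nsub)) {
    for (j in i:nsub) {
      ci <- subs[[i]]; cj <- subs[[j]]
      if (length(ci) + length(cj) < length(S)) next
      if (keys[i] == keys[j]) {
        if (keys[i] != key_S) next # homozygote must equal the full set
      } else {
        ov <- intersect(ci, cj)
        if (length(setdiff(ov, shareable)) > 0) next
        if (length(union(ci, cj)) != length(S)) next
      }
      out[[length(out) + 1L]] <- c(keys[i], keys[j])
    }
  }
  out
}

# Greedy pool selection by recurrence, then reverse pruning.
select_pool <- function(decomps) {
  all_pairs <- unlist(decomps, recursive = FALSE)
  if (length(all_pairs) == 0) return(character(0))
  # how many animals does each candidate appear in (in any decomposition)?
  touch <- lapply(decomps, function(d) unique(unlist(d)))
  touch_tab <- table(unlist(touch))
  explained <- function(P) {
    vapply(decomps, function(d) {
      any(vapply(d, function(p) all(p %in% P), logical(1)))
    }, logical(1))
  }
  P <- character(0)
  decomposable <- lengths(decomps) > 0
  repeat {
    ex <- explained(P)
    todo <- which(decomposable & !ex)
    if (length(todo) == 0) break
    # candidates appearing in decompositions of still-unexplained animals
    cands <- unique(unlist(lapply(decomps[todo], unlist)))
    cands <- setdiff(cands, P)
    if (length(cands) == 0) break
    # order candidates by (1) recurrence -- how many animals carry the
    # candidate in some decomposition, (2) anchoring -- whether it completes
    # a decomposition with a haplotype already in the pool (one-known-plus-
    # residual evidence beats positing a never-seen set as a homozygote),
    # (3) size -- a residual and the same residual with shareable
    # (universal) alleles re-attached explain the same animals, and
    # haplotypes carry their universal alleles
    anchored <- vapply(cands, function(cc) {
      any(vapply(todo, function(a) {
        any(vapply(decomps[[a]], function(p) {
          cc %in% p && all(p %in% c(P, cc)) && any(setdiff(p, cc) %in% P)
        }, logical(1)))
      }, logical(1)))
    }, logical(1))
    sc <- touch_tab[cands]
    sc[is.na(sc)] <- 0
    # a candidate recurring in a single animal joins the pool only when
    # anchored on an already-selected haplotype: a non-recurrent,
    # non-anchored set is not evidence of a haplotype and its animal stays
    # unassigned
    admissible <- anchored | as.numeric(sc) >= 2
    if (!any(admissible)) break
    cands <- cands[admissible]
    anchored <- anchored[admissible]
    sc <- sc[admissible]
    sz <- lengths(lapply(cands, key_to_set))
    best <- cands[order(-as.numeric(sc), -anchored, -sz, cands)][1]
    P <- c(P, best)
    if (length(P) > 2L * length(decomps)) break
  }
  # prune: drop candidates not needed, least-recurrent first; among ties the
  # smaller (universal-stripped) duplicate is offered for removal before the
  # fuller one
  ex0 <- explained(P)
  for (p in P[order(as.numeric(touch_tab[P]),
                    lengths(lapply(P, key_to_set)), P)]) {
    P2 <- setdiff(P, p)
    if (identical(explained(P2), ex0)) P <- P2
  }
  P
}

# Per-animal assignment over the selected pool.
assign_animals <- function(sets, decomps, pool_keys, min_support_animals, shareable) {
  animals <- names(sets)
  # provisional usage: animals explained per candidate, for tie-breaking
  usage <- table(unlist(lapply(decomps, function(d) {
    unique(unlist(keep(d, ~ all(.x %in% pool_keys))))
  })))
  hap1 <- hap2 <- rep(NA_character_, length(animals))
  extra <- vector("list", length(animals))
  ambiguous <- logical(length(animals))
  unassigned <- vector("list", length(animals))
  for (i in seq_along(animals)) {
    S <- sets[[i]]
    d_ok <- keep(decomps[[i]], ~ all(.x %in% pool_keys))
    if (length(d_ok) > 0) {
      sc <- vapply(d_ok, function(p) {
        sum(as.numeric(usage[p]), na.rm = TRUE)
      }, numeric(1))
      best <- which(sc == max(sc))
      if (length(best) > 1) ambiguous[i] <- TRUE
      pick <- d_ok[best]
      sz <- vapply(pick, function(p) length(key_to_set(p[1])) +
                     length(key_to_set(p[2])), numeric(1))
      pick <- pick[order(-sz, vapply(pick, paste, character(1),
                                     collapse = "+"))][[1]]
      hap1[i] <- pick[1]
      hap2[i] <- pick[2]
      unassigned[[i]] <- character(0)
      next
    }
    # no decomposition: try one confirmed haplotype + residual (putative)
    confirmed_keys <- names(usage)[as.numeric(usage) >= min_support_animals]
    fit <- keep(confirmed_keys, function(k) all(key_to_set(k) %in% S))
    fit <- intersect(fit, pool_keys)
    if (length(fit) > 0) {
      sc <- as.numeric(usage[fit])
      h <- fit[order(-sc, fit)][1]
      r <- setdiff(S, key_to_set(h))
      if (length(r) > 0) {
        hap1[i] <- h
        hap2[i] <- set_key(r)
        unassigned[[i]] <- character(0)
        next
      }
    }
    unassigned[[i]] <- S
  }
  tibble(animal = animals, hap1 = hap1, hap2 = hap2,
         unassigned_alleles = unassigned, ambiguous = ambiguous)
}

build_haplotype_object <- function(asn, sets, class, min_support_animals, jaccard_min) {
  used <- tibble(
    animal = rep(asn$animal, 2),
    key = c(asn$hap1, asn$hap2)
  ) |>
    filter(!is.na(.data$key))
  if (nrow(used) == 0) {
    obj <- empty_haplotypes(class)
    obj$assignments <- asn
    return(obj)
  }
  pool <- used |>
    group_by(.data$key) |>
    summarise(occurrences = dplyr::n(),
              n_animals = dplyr::n_distinct(.data$animal), .groups = "drop") |>
    mutate(confirmed = .data$n_animals >= min_support_animals,
           alleles = lapply(.data$key, key_to_set),
           class = class, partial = FALSE)
  pool <- group_variants(pool, jaccard_min = jaccard_min)
  # rewrite assignments in terms of ids
  id_of <- setNames(pool$id, pool$key)
  asn$hap1 <- unname(id_of[asn$hap1])
  asn$hap2 <- unname(id_of[asn$hap2])
  structure(list(pool = select(pool, -"key"), assignments = asn),
            class = "ela_haplotypes")
}

#' Group haplotypes into variant families and assign ids
#'
#' Haplotypes are clustered by single linkage on the Jaccard similarity of
#' their allelic-group content (allele names collapsed to locus+group, so an
#' allelic substitution within a group still matches). Clusters are families,
#' numbered by descending total occurrences (ties by allele content);
#' within a family, subtype letters a, b, c, ... follow descending
#' occurrences. Families with a single member get no letter. Ids are
#' `[un][p]HP<1|2>.<family><letter>`: "un" for unconfirmed (single-animal)
#' haplotypes, "p" for partial class II haplotypes (see [flag_partial()]).
#'
#' @param pool Haplotype pool tibble with `alleles` (list-column), `class`,
#'   `occurrences`, `confirmed`, `partial` columns (a `key` column is
#'   preserved if present).
#' @param jaccard_min Minimum Jaccard similarity to link two haplotypes into
#'   one family (boundary inclusive).
#' @return The pool with `family_number`, `subtype_letter` and `id` columns.
#' @export
group_variants <- function(pool, jaccard_min = 0.5) {
  n <- nrow(pool)
  if (n == 0) {
    pool$family_number <- integer(0)
    pool$subtype_letter <- character(0)
    pool$id <- character(0)
    return(pool)
  }
  groups <- lapply(pool$alleles, allele_groups)
  # single-linkage components over the Jaccard >= threshold graph
  comp <- seq_len(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      jac <- length(intersect(groups[[i]], groups[[j]])) /
        length(union(groups[[i]], groups[[j]]))
      if (jac >= jaccard_min) {
        old <- comp[j]
        comp[comp == old] <- comp[i]
      }
    }
  }
  fam_occ <- tapply(pool$occurrences, comp, sum)
  fam_key <- tapply(vapply(pool$alleles, set_key, character(1)), comp, min)
  fam_order <- names(fam_occ)[order(-as.numeric(fam_occ), fam_key)]
  fam_num <- setNames(seq_along(fam_order), fam_order)
  pool$family_number <- as.integer(fam_num[as.character(comp)])
  pool <- pool |>
    group_by(.data$family_number) |>
    arrange(desc(.data$occurrences),
            vapply(.data$alleles, set_key, character(1)), .by_group = TRUE) |>
    mutate(subtype_letter = if (dplyr::n() == 1) "" else letters[dplyr::row_number()]) |>
    ungroup() |>
    arrange(.data$family_number, .data$subtype_letter)
  class_num <- ifelse(pool$class == "MHCI", 1L, 2L)
  pool$id <- paste0(ifelse(pool$confirmed, "", "un"),
                    ifelse(pool$partial, "p", ""),
                    "HP", class_num, ".", pool$family_number,
                    pool$subtype_letter)
  pool
}

# Collapse an allele name to its allelic-group identity (locus + group);
# the "Eqca-" prefix is optional, as in the published tables.
allele_groups <- function(alleles) {
  unique(allele_groups_vec(alleles))
}

#' Classify allelic groups as universal or standard
#'
#' An allelic group (alleles sharing locus tag and group field) is
#' *universal* when at least one of its members occurs in more than
#' `majority_frac` of the haplotypes in the pool; all members inherit the
#' label. Intended for class I pools.
#'
#' @param x An `ela_haplotypes` object or a pool tibble with an `alleles`
#'   list-column.
#' @param majority_frac Fraction of haplotypes a group must exceed.
#' @return Tibble with `allele`, `group`, `label` (universal/standard).
#' @export
classify_universal <- function(x, majority_frac = 0.5) {
  pool <- if (inherits(x, "ela_haplotypes")) x$pool else x
  n_h <- nrow(pool)
  per_hap <- lapply(pool$alleles, unique)
  alleles <- sort(unique(unlist(per_hap)))
  grp <- setNames(allele_groups_vec(alleles), alleles)
  # group coverage: haplotypes containing >= 1 member of the group
  cover <- vapply(unique(grp), function(g) {
    members <- alleles[grp == g]
    sum(vapply(per_hap, function(h) any(members %in% h), logical(1)))
  }, numeric(1))
  universal_groups <- names(cover)[cover > majority_frac * n_h]
  tibble(allele = alleles,
         group = unname(grp),
         label = ifelse(grp %in% universal_groups, "universal", "standard"))
}

allele_groups_vec <- function(a) {
  pat <- "^((Eqca-)?[A-Za-z0-9]+\\*[A-Za-z0-9]+).*$"
  ok <- grepl(pat, a)
  ifelse(ok, sub(pat, "\\1", a), a)
}

#' Flag partially characterised class II haplotypes
#'
#' A class II haplotype missing an entire DQA or DQB locus class is marked
#' partial and its id gains a "p" after any "un" prefix.
#'
#' @param x An `ela_haplotypes` object (class II) or its pool tibble.
#' @param class_map Named character vector mapping allele name to locus class
#'   (`"DQA"`, `"DQB"`, `"DRA"`, `"DRB"`); unmapped alleles are classed by
#'   their parsed locus tag when possible.
#' @return The input with `partial` and `id` updated.
#' @export
flag_partial <- function(x, class_map = NULL) {
  pool <- if (inherits(x, "ela_haplotypes")) x$pool else x
  get_class <- function(a) {
    if (!is.null(class_map) && a %in% names(class_map)) return(class_map[[a]])
    m <- str_match(a, "^Eqca-(DQA|DQB|DRA|DRB)")[, 2]
    if (is.na(m)) "" else m
  }
  old_id <- pool$id
  pool$partial <- vapply(pool$alleles, function(al) {
    cl <- vapply(al, get_class, character(1))
    !("DQA" %in% cl) || !("DQB" %in% cl)
  }, logical(1))
  pool$id <- paste0(ifelse(pool$confirmed, "", "un"),
                    ifelse(pool$partial, "p", ""),
                    "HP", ifelse(pool$class == "MHCI", 1L, 2L), ".",
                    pool$family_number, pool$subtype_letter)
  if (inherits(x, "ela_haplotypes")) {
    id_map <- setNames(pool$id, old_id)
    x$pool <- pool
    x$assignments$hap1 <- unname(ifelse(is.na(x$assignments$hap1), NA,
                                        id_map[x$assignments$hap1]))
    x$assignments$hap2 <- unname(ifelse(is.na(x$assignments$hap2), NA,
                                        id_map[x$assignments$hap2]))
    x
  } else {
    pool
  }
}
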