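# Nomenclature: assigning IPD-style names to observed amplicon sequences.
#
# The rules, applied within one gene (MHCI, DRA, DRB, DQA, DQB):
#   * nucleotide-identical to a database entry      -> known_ipd (its name)
#   * amino-acid identical, nucleotide different    -> synonymous_variant
#       (matched name + next two-letter suffix, e.g. Eqca-7*002:01:AA)
#   * 1-4 aa differences from the nearest entry     -> novel_in_group
#       (group name + next two-letter suffix, e.g. Eqca-4*001:AA)
#   * >4 aa differences from every same-gene entry  -> novel_group
#       (Eqca-<gene>*<country><n>:01, e.g. Eqca-MHCI*gb19:01)
# Accepted queries are added to the database so that later queries are
# compared against them as well.

#' Create a nomenclature registry
#'
#' The registry issues names deterministically: novel-group numbers count up
#' per (gene, country) and letter suffixes are issued per allelic group in
#' the order AA, AB, ..., AZ, BA, ... Existing letter suffixes and
#' country-coded group numbers in `db` are absorbed so no name is issued
#' twice.
#'
#' @param country One of `"gb"`, `"is"`, `"no"` (Great Britain, Iceland,
#'   Norway): the cohort of first detection, embedded in novel-group names.
#' @param db Optional [load_reference_db()] database whose names seed the
#'   issued-name set and counters.
#' @return An `ela_registry` object.
#' @export
nomenclature_registry <- function(country = c("gb", "is", "no"), db = NULL) {
  country <- match.arg(country)
  reg <- structure(
    list(country = country,
         group_counter = integer(0),
         suffix_counter = integer(0),
         issued = character(0)),
    class = "ela_registry"
  )
  if (!is.null(db) && nrow(db) > 0) {
    reg$issued <- db$full_name
    # absorb numeric country-coded groups, e.g. gb19 -> counter at least 19
    m <- str_match(db$group_field, "^(gb|is|no)([0-9]+)$")
    ok <- !is.na(m[, 1])
    if (any(ok)) {
      keys <- paste0(db$gene[ok], ".", m[ok, 2])
      for (i in seq_along(keys)) {
        n <- as.integer(m[ok, 3][i])
        cur <- reg$group_counter[keys[i]]
        if (is.na(cur) || n > cur) reg$group_counter[keys[i]] <- n
      }
    }
    # absorb issued two-letter suffixes per group
    sfx <- str_match(db$allele_field, "(?:^|:)([A-Z]{2})$")[, 2]
    ok <- !is.na(sfx)
    if (any(ok)) {
      for (i in which(ok)) {
        key <- db$group_key[i]
        n <- suffix_index(sfx[i])
        cur <- reg$suffix_counter[key]
        if (is.na(cur) || n > cur) reg$suffix_counter[key] <- n
      }
    }
  }
  reg
}

suffix_code <- function(i) {
  if (i > 26L * 26L) abort("two-letter suffix space exhausted")
  paste0(LETTERS[(i - 1L) %/% 26L + 1L], LETTERS[(i - 1L) %% 26L + 1L])
}

suffix_index <- function(code) {
  v <- utf8ToInt(code) - utf8ToInt("A")
  v[1] * 26L + v[2] + 1L
}

#' Issue the next name from a registry
#'
#' @param registry An `ela_registry`.
#' @param gene Gene the sequence came from.
#' @param kind `"variant"` (two-letter suffix within `group`) or `"group"`
#'   (a new country-coded allelic group).
#' @param group For `kind = "variant"`: the allelic-group key
#'   (`Eqca-<locus>*<group>`) or a full allele name to suffix (used for
#'   synonymous variants).
#' @return A list with `name` (the issued full name) and `registry` (updated).
#' @export
next_name <- function(registry, gene, kind = c("variant", "group"), group = NULL) {
  kind <- match.arg(kind)
  repeat {
    if (kind == "variant") {
      stopifnot(!is.null(group))
      i <- registry$suffix_counter[group]
      i <- if (is.na(i)) 1L else i + 1L
      registry$suffix_counter[group] <- i
      name <- paste0(group, ":", suffix_code(i))
    } else {
      key <- paste0(gene, ".", registry$country)
      i <- registry$group_counter[key]
      i <- if (is.na(i)) 1L else i + 1L
      registry$group_counter[key] <- i
      name <- paste0("Eqca-", gene, "*", registry$country, i, ":01")
    }
    if (!name %in% registry$issued) break
  }
  registry$issued <- c(registry$issued, name)
  list(name = name, registry = registry)
}

# Nucleotide percent identity, used only to break distance ties between
# groups.
nt_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    return(sum(utf8ToInt(a) == utf8ToInt(b)) / nchar(a))
  }
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "global")
  Biostrings::pid(aln) / 100
}

#' Classify one sequence against the reference database
#'
#' Applies the amino-acid-distance nomenclature rules (see the package
#' vignette). Distance ties between allelic groups are broken towards the
#' group whose nearest allele has the higher nucleotide identity, then
#' towards the lexicographically smallest group name. Accepted queries are
#' appended to the returned database.
#'
#' @param query_nt Primer-trimmed amplicon nucleotide sequence.
#' @param db An `ela_refdb`.
#' @param gene Gene of the amplicon that produced the read.
#' @param registry An `ela_registry`.
#' @param query_id Identifier reported back in the result.
#' @return A list with `result` (one-row tibble: `query_id`, `assigned_name`,
#'   `classification`, `nearest_reference`, `aa_distance`, `nt_identical`),
#'   `db` (possibly grown) and `registry` (possibly advanced).
#' @export
classify_sequence <- function(query_nt, db, gene, registry, query_id = NA_character_) {
  stopifnot(gene %in% c("MHCI", "DRA", "DRB", "DQA", "DQB"))
  frame <- db_frames(db)[[gene]]
  aa <- tryCatch(translate_amplicon(query_nt, frame), error = function(e) NA_character_)
  if (is.na(aa) || grepl("\\*", aa)) {
    return(list(result = tibble(
      query_id = query_id, assigned_name = NA_character_,
      classification = "untranslatable", nearest_reference = NA_character_,
      aa_distance = NA_integer_, nt_identical = FALSE
    ), db = db, registry = registry))
  }
  sub <- db[db$gene == gene, , drop = FALSE]

  hit <- which(sub$nt_seq == query_nt)
  if (length(hit) > 0) {
    e <- sub[hit[1], ]
    return(list(result = tibble(
      query_id = query_id, assigned_name = e$full_name,
      classification = "known_ipd", nearest_reference = e$full_name,
      aa_distance = 0L, nt_identical = TRUE
    ), db = db, registry = registry))
  }

  if (nrow(sub) == 0) {
    d_min <- Inf
  } else {
    d <- vapply(sub$aa_seq, aa_distance, numeric(1), b = aa, USE.NAMES = FALSE)
    d_min <- min(d)
  }

  if (is.finite(d_min) && d_min == 0) {
    # amino-acid identical but nucleotide different: synonymous variant,
    # suffixed onto the matched allele's full name
    cand <- sub[which(d == 0), ]
    cand <- cand[order(cand$full_name), ]
    base <- cand[1, ]
    nn <- next_name(registry, gene, "variant", group = base$full_name)
    res <- tibble(
      query_id = query_id, assigned_name = nn$name,
      classification = "synonymous_variant", nearest_reference = base$full_name,
      aa_distance = 0L, nt_identical = FALSE
    )
    db2 <- accept_query(db, nn$name, gene, query_nt, aa, "synonymous_variant")
    return(list(result = res, db = db2, registry = nn$registry))
  }

  if (is.finite(d_min) && d_min <= 4) {
    cand <- sub[which(d == d_min), ]
    if (length(unique(cand$group_key)) > 1) {
      ident <- vapply(cand$nt_seq, nt_identity, numeric(1), b = query_nt, USE.NAMES = FALSE)
      cand <- cand[ident == max(ident), , drop = FALSE]
    }
    cand <- cand[order(cand$group_key, cand$full_name), ]
    base <- cand[1, ]
    nn <- next_name(registry, gene, "variant", group = base$group_key)
    res <- tibble(
      query_id = query_id, assigned_name = nn$name,
      classification = "novel_in_group", nearest_reference = base$full_name,
      aa_distance = as.integer(d_min), nt_identical = FALSE
    )
    db2 <- accept_query(db, nn$name, gene, query_nt, aa, "novel_in_group")
    return(list(result = res, db = db2, registry = nn$registry))
  }

  nearest <- if (nrow(sub) > 0) sub$full_name[which.min(d)] else NA_character_
  nn <- next_name(registry, gene, "group")
  res <- tibble(
    query_id = query_id, assigned_name = nn$name,
    classification = "novel_group", nearest_reference = nearest,
    aa_distance = if (is.finite(d_min)) as.integer(d_min) else NA_integer_,
    nt_identical = FALSE
  )
  db2 <- accept_query(db, nn$name, gene, query_nt, aa, "novel_group")
  list(result = res, db = db2, registry = nn$registry)
}

accept_query <- function(db, name, gene, nt, aa, classification) {
  row <- parse_allele_name(name)
  row$nt_seq <- nt
  row$aa_seq <- aa
  row$classification <- classification
  # gene identity comes from the amplicon, not from the parsed tag
  row$gene <- gene
  new_refdb(dplyr::bind_rows(db, row), db_frames(db))
}

#' Name every sequence in a cohort
#'
#' Classifies a table of called sequences in the canonical cohort order
#' (by sample id, then descending read count, then sequence) so that
#' whole-cohort naming is reproducible, threading the growing database and
#' registry through [classify_sequence()]. Sequences already assigned (same
#' nucleotide sequence seen in an earlier sample) reuse their name.
#'
#' @param queries Tibble with columns `gene`, `nt_seq`, and optionally
#'   `sample_id`, `read_count`, `query_id`.
#' @param db An `ela_refdb`.
#' @param registry An `ela_registry`.
#' @return List with `report` (one row per input row, in input order), `db`,
#'   `registry`.
#' @export
assign_nomenclature <- function(queries, db, registry) {
  stopifnot(all(c("gene", "nt_seq") %in% names(queries)))
  q <- as_tibble(queries)
  if (!"sample_id" %in% names(q)) q$sample_id <- ""
  if (!"read_count" %in% names(q)) q$read_count <- 0L
  if (!"query_id" %in% names(q)) {
    q$query_id <- paste0(q$sample_id, ":", q$gene, ":", seq_len(nrow(q)))
  }
  ord <- order(q$sample_id, -q$read_count, q$nt_seq)
  rows <- vector("list", nrow(q))
  for (i in ord) {
    r <- classify_sequence(q$nt_seq[i], db, q$gene[i], registry, q$query_id[i])
    db <- r$db
    registry <- r$registry
    rows[[i]] <- r$result
  }
  list(report = dplyr::bind_rows(rows), db = db, registry = registry)
}
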