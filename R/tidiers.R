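# broom-style methods for inferred haplotype objects.

#' Tidy an inferred haplotype pool
#'
#' One row per (haplotype, allele), with the haplotype's family, subtype and
#' confirmation status.
#'
#' @param x An `ela_haplotypes` object.
#' @param ... Unused.
#' @export
tidy.ela_haplotypes <- function(x, ...) {
  x$pool |>
    mutate(n_alleles = lengths(.data$alleles)) |>
    tidyr::unnest_longer(col = "alleles", values_to = "allele") |>
    select("id", "class", "family_number", "subtype_letter", "allele",
           "n_alleles", "occurrences", "n_animals", "confirmed", "partial")
}

#' One-row summary of a haplotype inference
#'
#' @param x An `ela_haplotypes` object.
#' @param ... Unused.
#' @export
glance.ela_haplotypes <- function(x, ...) {
  a <- x$assignments
  tibble(
    n_haplotypes = nrow(x$pool),
    n_confirmed = sum(x$pool$confirmed),
    n_families = dplyr::n_distinct(x$pool$family_number),
    n_animals = nrow(a),
    n_homozygous = sum(!is.na(a$hap1) & a$hap1 == a$hap2),
    n_unassigned = sum(is.na(a$hap1)),
    n_ambiguous = sum(a$ambiguous),
    mean_alleles_per_haplotype = mean(lengths(x$pool$alleles))
  )
}

#' @export
print.ela_haplotypes <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<ela_haplotypes> %d haplotypes (%d confirmed) in %d families; %d animals (%d homozygous, %d unassigned)\n",
    g$n_haplotypes, g$n_confirmed, g$n_families, g$n_animals,
    g$n_homozygous, g$n_unassigned))
  print(select(x$pool, -"alleles"), n = 10)
  invisible(x)
}
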