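---
title: "Genotyping the expressed equine MHC: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping the expressed equine MHC: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elatyper)
```

This vignette is the package's own account of the methods it implements:
what each stage assumes, which tunable parameters matter and why their
defaults are what they are, what the simulator does and does not emulate,
and where the design was genuinely open.

## The measurement model

An animal's expressed MHC repertoire is sampled by six cDNA PCRs — two
overlapping class I amplicons and one each for DRA, DRB, DQA and DQB —
pooled at 30:30:10:10:10:10, MID-tagged and sequenced 2 × 300 bp. The
quantity observed per (animal, amplicon) is a vector of read counts over
insert sequences. Three properties of this channel drive the design:

* **PCR bias.** Primer–template mismatches distort amplification
  efficiency, up to complete allele dropout when polymorphism hits the
  primer binding site. Read frequency is therefore treated as a *detection*
  signal, never as an expression estimate; the two class I amplicons
  provide partial redundancy against dropout, and an allele is accepted if
  it is seen in either.
* **Wide expression spread.** Per-allele read frequencies span roughly
  three orders of magnitude. The weakest alleles hover around the threshold
  of resolution and are reliably visible only in homozygotes, which carry a
  double dose of the haplotype; this motivates the cohort-wide recovery
  loop.
* **Amplification artifacts.** Point-error "shadows" of abundant templates
  and PCR chimeras must be removed before frequencies are interpreted.

## Stage-by-stage choices

**Demultiplexing.** MID matching is exact. Tags are short; one-off matching
would trade a small read gain for cross-sample contamination, which is the
costlier error for genotyping. Unmatched pairs are kept in an
`undetermined` bucket so totals are conserved.

**Merging.** For each pair the reverse read is reverse-complemented and all
overlaps of length ≥ `min_overlap` (10 bp) are scored; among overlaps with
mismatch fraction ≤ `max_mismatch_frac` (0.25) the one with the most
matching bases wins, ties going to the longer overlap. Disagreeing bases
resolve to the higher quality score, ties to the forward read; overlap
qualities take the per-position maximum. This reproduces the standard
overlap-merging behaviour without depending on an external merger binary;
a brute-force scan over all offsets is kept in the test suite as the
oracle.

**Quality filter.** The only published constraint is a quality threshold of
Q28; the aggregation is not stated, so the package interprets it as the
*mean* Phred score of the merged read with a strict `>` comparison, both
exposed as parameters.

**Amplicon assignment.** Primers match IUPAC-degenerately at both ends, in
both read orientations, with at most `max_primer_mismatches` (default 1)
per primer — single-base primer/allele mismatches are documented for this
panel, so zero tolerance would systematically drop known alleles. The
best (fewest-mismatch) amplicon wins; ties leave the read unassigned as
`ambiguous` rather than guessing.

**Artifact removal.** The original pipeline removes artifacts but does not
print its rules, so the rules here are this package's own, conservative and
configurable (`calling_config()`):

* *Shadows*: an entry within `shadow_max_mismatch` (1) substitutions of an
  entry at least `1/shadow_ratio` (10×) more abundant. The 10× margin keeps
  genuine 1-nt-apart allele pairs (which exist in these gene families)
  callable unless their abundances differ by an order of magnitude.
* *Chimeras*: an entry exactly equal to a prefix of one surviving entry
  joined to a suffix of another at some internal breakpoint, both parents
  at least `chimera_parent_ratio` (1×) as abundant. Parents are capped at
  the 30 most abundant entries: chimeras form from abundant templates, and
  the cap bounds the scan.

Frequencies are recomputed over non-artifact reads — the denominator choice
is deliberate and documented because the published "% of reads" leaves it
open.

**Threshold and recovery.** An entry is *called* at frequency ≥ 0.2%
(`freq_threshold = 0.002`); the boundary is inclusive (the published rule
is ambiguous; inclusivity is exposed in the configuration). A
sub-threshold entry is *recovered* when its sequence exactly — full
length — matches an allele called in at least one animal, and it has at
least `recovery_min_reads` (2) reads. Exact identity is required to
prevent artifact laundering through the recovery route. Recovered entries
do not expand the confirmed set, so the loop reaches its fixpoint in one
pass and is independent of sample order.

**Nomenclature.** Sequences are translated in a per-gene reading frame
registered at database load time: the frame in which the largest fraction
of that gene's reference alleles is stop-free (the amplicons start
mid-exon, so no start codon anchors the frame; a warning is raised below
90%). Distances are amino-acid differences: Hamming for equal lengths, and
for unequal lengths a global alignment (match +1, mismatch −1, gap −2)
counting substituted plus indel positions, minimised among co-optimal
alignments so the reported distance is deterministic. The ≤4/>4 rule is
applied within a gene only, with gene identity taken from the amplicon
that produced the read, never from sequence similarity. Distance ties
between groups break towards higher nucleotide identity, then the
lexicographically smaller group name. Whole-amplicon translations are
compared (not an exon-2-only window): the amplicons were designed around
the polymorphic exons and the reference entries are stored over the same
coordinates, so the comparison is like-for-like. Naming is deterministic
given the canonical cohort order (sample id, then descending read count):
novel members of existing groups and synonymous variants draw two-letter
suffixes AA, AB, ... from a per-group counter; novel groups draw
per-(gene, country) numbers with country codes gb/is/no. Accepted queries
join the database so later queries compare against them.

**Haplotype inference.** Genotypes are unphased unions, so a haplotype is
identifiable only through recurrence. The procedure: (i) seed candidates
with every animal's full set (putative homozygotes and repeated
diplotypes); (ii) for each animal containing a candidate as a subset,
propose the residual — both as-is and with the animal's *shareable*
alleles re-attached, since the two haplotypes of one animal may share
near-universal alleles — and iterate to a fixpoint; (iii) select a pool
greedily by recurrence (candidates present in the most animals first, with
ties towards candidates anchored on an already-selected haplotype and then
towards the fuller variant), admitting a single-animal candidate only when
anchored on a confirmed haplotype; (iv) prune redundant members, offering
universal-stripped duplicates for removal before their fuller twins;
(v) assign each animal the decomposition maximising total pool usage
(ties flagged `ambiguous` and resolved deterministically towards the
fuller decomposition). An animal matching exactly one confirmed haplotype
plus a residual yields an unconfirmed (`un`) haplotype; an animal
containing no confirmed haplotype at all is left fully unassigned.
Confirmation requires recurrence in ≥ 2 distinct animals; homozygotes
count twice towards occurrences but once towards confirmation.

*Shareable alleles.* By default, alleles present in ≥ 90% of animals
(`shared_allele_frac`) are treated as shareable between an animal's two
haplotypes — the behaviour of near-universal class I alleles. Auto-
detection is only attempted in cohorts of ≥ 20 animals
(`min_animals_for_shared`): in smaller cohorts a frequent haplotype's
private alleles are indistinguishable from universal ones by animal
frequency, so nothing is auto-shared (an explicit `universal_alleles`
vector overrides either way).

*Identifiability.* A haplotype pair that only ever co-occurs is
indistinguishable from a homozygous union of their alleles; haplotypes
sharing standard (non-universal) alleles between different haplotypes
("blocks") can make the true decomposition inadmissible under the
overlap-within-shareable rule. The property suites therefore test the
regime the method is designed for — each haplotype recurring in at least
two animals and at least two diplotype contexts, reachable from homozygote
seeds by residual chaining — and the exhaustive-search oracle returns *all*
minimal pools so that genuinely ambiguous cohorts do not produce spurious
disagreements.

**Families, subtypes, universals, partials.** Variant families are
single-linkage clusters at Jaccard ≥ 0.5 (inclusive) on allelic-*group*
content, so an allelic substitution within a group still matches; 0.5 is
this package's operationalisation of the informal published grouping and is
configurable. Families are numbered by descending total occurrences,
subtypes lettered a, b, c likewise; ids follow `[un][p]HP<class>.<family><letter>`.
An allelic group is *universal* when at least one member sits on more than
half the haplotypes (`majority_frac = 0.5`), all members inheriting the
label — group-level union coverage, so subtypes that split a group's
presence still count. Class II haplotypes with no DQA or no DQB allele are
flagged partial (`p`).

**Linkage.** Phase across the class I and class II regions is unobservable
from unphased genotypes, so each doubly assigned animal distributes weight
1 uniformly over the (class I, class II) haplotype pairings consistent with
its diplotypes — 1 cell for a double homozygote, up to 4 for a double
heterozygote. Total weight equals the number of doubly assigned animals.

## The simulator

`sim_config()` / `simulate_cohort()` / `simulate_reads()` emulate: diploid
animals drawn as independent haplotype pairs from a frequency vector
(homozygotes arise naturally at Hardy–Weinberg rates); class I haplotypes
of 6–16 alleles including `n_universal` (2) alleles shared by every
haplotype; class II haplotypes with a fixed locus layout (1 DRA, 2 DQA,
2 DQB, 2–3 DRB); per-allele expression weights log-uniform over 3 decades;
per-amplicon pool ratios 30:30:10:10:10:10; primer-site mismatches with
dropout above a tolerance; uniform substitution error; MID-tagged 300 bp
paired reads at constant Q35; optional chimera generation to exercise the
artifact filter. All randomness flows from the seed.

It does **not** model: position-dependent Illumina error profiles or
quality decay, indels, PhiX, cross-haplotype "blocks" of shared standard
alleles, pedigree structure, or locus-specific primer efficiencies beyond
the mismatch/dropout mechanism. Passing end-to-end tests therefore
demonstrate the pipeline's correctness under its stated assumptions, not
robustness to every artefact of real runs — in particular the block
phenomenon seen in real cohorts is a documented limitation of the
haplotyper's overlap rule above.

## Problem sizes and numerical conventions

The test suite and acceptance script run at desk scale, chosen so the
statistics they check are meaningful: benign-regime inference uses 100
animals × 10 haplotypes × 5 seeds per class; the end-to-end run uses 8–12
animals at 12,000 read pairs each (depth at which the 0.2% threshold
corresponds to several reads per amplicon, as in a production run);
oracle-equivalence cohorts are ≤ 8 animals × ≤ 12 alleles so exhaustive
search over all consistent diplotype decompositions is feasible; merging is
cross-checked against the all-offsets oracle on 1,000 simulated pairs.

Degenerate inputs are defined, not errors: empty FASTA → empty database
with a warning; empty call set → empty call set; empty genotype matrix →
empty pool; an animal with zero alleles in a class is excluded from that
class's matrix. Reported distances, names, pools, ids and assignments are
deterministic functions of their inputs under the documented orderings and
tie-breaks.

## Known limitations

* Haplotypes sharing standard alleles ("blocks") violate the
  overlap-within-shareable decomposition rule; affected animals fall back
  to one-confirmed-plus-residual or unassigned.
* Cohorts without homozygote (or repeated-set) seeds are unidentifiable for
  the co-segregation procedure; pools then collapse to repeated diplotype
  unions.
* The two class I amplicons are named independently; segments of one
  composite allele are only merged into a single record when a composite
  map is supplied (`merge_mhci_amplicons()`), otherwise both are kept as
  distinct (short-form) records.
* Read frequency is not an expression estimate; `locus_read_proportions()`
  summarises read shares, and any expression interpretation inherits the
  PCR bias caveat.
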