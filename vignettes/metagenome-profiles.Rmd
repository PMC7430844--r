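---
title: "Abundance metrics, subset semantics and the query engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abundance metrics, subset semantics and the query engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaprof)
```

## The problem

Assembly-based metagenomic pipelines leave the analyst with very large
per-feature tables: every predicted gene (ORF) on every contig, with a
taxonomic lineage, functional annotations against one or more databases
(KEGG orthologs, COGs, PFAM domains, ...), and per-sample mapped read and
base counts. `metaprof` turns a directory of such tables into a single
project object, recomputes every aggregate profile from the ORF level, and
provides the subsetting, querying and exporting operations needed to ask
biological questions of the data without hand-written bookkeeping.

## Abundance metrics

All metrics are defined per sample, on a features-by-samples matrix whose
rows fix the *denominator universe* — this is the single idea from which
all subsetting semantics below follow.

**Reads and bases** are raw mapped counts, summed over ORFs for contigs,
bins, functions and taxa. They are the right input for count-based
statistics downstream; the package deliberately performs no differential
abundance testing itself.

**TPM** is computed in two steps: each feature's reads are divided by the
feature length in kilobases (RPK), and each RPK is divided by the sample's
total RPK over *all* features in the universe, times one million. TPM of a
feature is therefore the expected number of hits to that feature when
drawing one million length-corrected observations from the sample. Every
column of a TPM matrix sums to 10^6 by construction, which the test suite
asserts at the ORF, contig and function levels.

**Function-level aggregation** sums the reads of all ORFs annotated to a
function and divides by the *assembly-wide average length* of that
function's genes (one number per function, not per sample). Two
consequences are worth stating plainly:

* function TPMs are comparable across samples of the same project but not
  across projects (the average gene length is a property of the assembly);
* an ORF with several annotations in one database counts fully toward each
  of them, so function reads are not additive to total reads. This matches
  the additive aggregation convention of the field and is asserted by a
  dedicated test.

ORFs with no annotation in a database accumulate into an always-present
`Unclassified` row, and that row participates in the TPM denominator: the
universe is *all* features, so classified TPMs do not inflate when
annotation rates are low. Empty `Unclassified` rows have an undefined
average gene length; their RPK is defined as 0 so the row never poisons the
denominator.

**Copy number** estimates the average number of copies of a function per
genome as the ratio of the function's aggregated coverage (mapped bases per
bp) to the coverage of a universal single-copy gene in the same universe.
The default marker is COG0468, the RecA/RadA recombinase, present exactly
once in essentially every prokaryotic genome; its own copy number is
therefore exactly 1 in every sample, which doubles as a built-in sanity
check. An alternative mode uses the per-sample median coverage of a
configurable list of universal single-copy genes; the shipped default is
15 single-copy ribosomal-protein and translation COGs
(`default_usicgs()`), and every export records the list actually used —
the list is configuration, not a constant of the method. Samples with zero
marker coverage get `NA` copy numbers with a warning; a universe with no
marker at all is an error in `compute_copy_number()` but a warning (with
`NA` values) during project loading, since loading marker-free data must
still succeed.

**Taxonomy percent** is `100 * reads per taxon / total sequenced reads`.
The denominator is the *sequenced* read total, not the mapped total, so an
explicit `Unmapped` row absorbs the difference and percent columns sum to
exactly 100. ORFs without an assignment at the requested rank fall into
`Unclassified`. Lineages are rank-prefixed strings
(`k_Bacteria;p_...;g_Prevotella`); matching at a rank is exact string
equality of that component, and a missing rank terminates the lineage. By
default taxonomy is aggregated from ORF-level lineages (the quantity that
function subsets intersect with); a `taxonomy_source: contig` config
switch aggregates ORF reads by the host contig's consensus lineage
instead.

## Subset semantics

Three subset verbs share one engine and differ only in how they choose the
ORF universe and which denominators they recompute:

| metric | `subset_tax` / `subset_bins` | `subset_fun` |
|---|---|---|
| reads / bases | re-aggregated | re-aggregated |
| TPM | **rescaled** (default) | never — copied from parent |
| copy number | **rescaled** (default) | never — copied from parent |
| percent | never rescaled | recomputed from matched reads, parent denominator |

`subset_tax` and `subset_bins` select *contigs* (by lineage at a rank, or
by bin membership) and keep every ORF on them, even ORFs whose own lineage
disagrees with the contig consensus — this changes the child's
`Unclassified` rows and is intentional: the selection unit is the contig.
With rescaling on (the default), TPM denominators and the marker coverage
are recomputed inside the subset, so TPMs read "per million genes of the
selected taxon" and copy numbers "per genome of the selected taxon".
Percentages are *never* rescaled: a selected genus keeps exactly the share
of the whole metagenome it had in the parent, and the non-selected reads
move into `Unmapped` so columns still sum to 100.

`subset_fun` selects *ORFs* whose annotations match the patterns
(case-insensitive substring against identifiers, names and, by default,
every level of the functional hierarchy; regular expressions with
`use_regex = TRUE`), plus their host contigs for context. Profiles are
computed from the matching ORFs only. TPM and copy numbers are copied from
the parent — a function's abundance "per million genes in the metagenome"
is unchanged by the act of selecting it. With rescaling off in a
tax/bin subset the same copying rule applies row-for-row. Taxonomy in a
function subset keeps all parent taxa rows (zero-filled where the subset
has no reads) so that multi-panel figures over several subsets stay
aligned.

`combine_projects()` unions children of the same parent (identical sample
lists and total read counts are required — interpreting any of the
normalised metrics across different denominators would be meaningless).
Duplicate rows must agree and are counted once. Combining all the genus
subsets of a project with rescaling restores the full project's profiles
exactly, which the test suite asserts.

## The query language

Interactive contig-level visualization tools degrade when fed hundreds of
thousands of contigs, so the package includes a small boolean language for
prefiltering, evaluated per contig:

```
tax:genus = 'Prevotella' AND (cov['S1'] > 5 OR cov['S2'] > 5)
fun contains 'tryptophan' AND NOT tax:phylum = 'Firmicutes'
```

Precedence is `NOT` > `AND` > `OR`, parentheses group, keywords are
case-insensitive, string literals are single-quoted. Three predicate
families exist: `tax:<rank>` tests the contig's lineage component (`=`,
`!=`, `contains`, `matches`); `fun` (optionally `fun:kegg` etc.) is true
iff at least one ORF on the contig carries a matching annotation, with
`=` meaning exact identifier match and `contains`/`matches` also searching
names and hierarchy levels; `cov|tpm|reads['<sample>']` compares the
contig's per-sample value. An unassigned rank satisfies only `!=`, so
`NOT (tax:r = x)` and `tax:r != x` coincide and complement laws hold
exactly — the suite checks evaluation against a per-contig brute-force
oracle on randomized expression trees, plus De Morgan and monotonicity
laws. String matching is case-insensitive throughout; the regex dialect is
R's POSIX extended dialect as used by `grepl()`.

`filter_for_display()` refuses selections above `max_contigs`
(default 20,000, configurable) with the offending count — an
order-of-magnitude guard below the contig counts that make interactive
displays unusable — and otherwise returns a non-rescaled child project
plus a per-contig metadata table ready for import elsewhere.

## The synthetic-project generator

`generate_project()` emulates the *count structure* of a real project with
known ground truth: log-normal genome abundances normalised per sample
(sd on the log scale 1.0 — about an order-of-magnitude spread between
common and rare genomes, typical of gut communities); one ORF per function
copy with integer copy counts drawn from {0,1,2,3} with probabilities
(0.3, 0.4, 0.2, 0.1); exactly one COG0468 marker per genome; two
unannotated and one taxonomically unclassified filler ORFs per genome; ORF
lengths uniform on 300–3000 bp; reads multinomial with probability
proportional to abundance × ORF length; bases = reads × 150 bp; a mapped
fraction of 0.9, so the 10% remainder exercises the `Unmapped` accounting.
ORFs are packed onto contigs (3–6 per contig, 50 bp intergenic gaps), so
contig lengths emerge from ORF packing rather than being drawn directly —
equivalent for every metric in scope, all of which consume counts and
coverages.

Under this model the coverage-ratio copy-number estimator converges to the
abundance-weighted mean copy count
`sum_g a_gs c_gf / sum_g a_gs`, because the expected per-ORF coverage is
proportional to genome abundance and independent of ORF length.
`truth_report()` evaluates this and the expected genus percentages in
closed form from the recorded truth (no resampling), and the suite checks
recovery within 10% relative error at a depth of 10^6 reads per sample
over 20 replicates, plus monotone error shrinkage from 10^4 to 10^6.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: multi-mapping reads and intergenic mappings
(contig counts are exactly the ORF sums here; the loader never asserts
that equality on real data), chimeric or misassembled contigs,
misannotation, strain-level variation within a genome bin, and
compositional coupling between genome abundances beyond the normalisation
itself.

## Numerical and design choices

* **Aggregates are always recomputed from ORF rows.** Pre-aggregated
  contig counts found on disk are cross-checked and a warning logged above
  0.5% discrepancy; versions of upstream pipelines differ, and a single
  source of truth beats trusting derived tables.
* **Coordinates** are 1-based inclusive; `length_bp = stop − start + 1` is
  validated. Strand is stored but no metric consumes it.
* **Round-trip precision.** Count matrices survive write/read exactly
  (integer arithmetic); coverages and other doubles are written with 13
  significant digits, comfortably inside the 1e-9 relative tolerance the
  round-trip tests assert. Files are UTF-8, LF-terminated, `.`-decimal.
* **Missing values** propagate as explicit `NA`, never silently as 0, with
  one documented exception: a sample whose RPK column is all zero gets an
  all-zero TPM column plus a warning, since there is nothing to normalise
  against.
* **Ties** in `top_features()` are broken lexicographically by label, and
  the `Other` row absorbs excluded rows so column sums are conserved
  exactly.
* **Unclassified rows are always materialized** in function profiles, even
  when empty, so column sums are meaningful and subset/parent row sets
  align.
* The loader accepts an optional `functions.tsv` (database, identifier,
  name, hierarchy path) giving function names and hierarchies a plain-text
  home; without it, matching falls back to identifiers only.
* Rendering of figures is deliberately left to the caller: the exporters
  return plot-ready matrices and long tables (`top_features`,
  `function_heatmap_data`, `function_by_taxon_data`) rather than images,
  and the tests target those data structures.

## Problem sizes used by the test suite

The suite builds everything it tests at run time: a hand-checkable
two-genus fixture (6 ORFs, 2 samples) for every exact arithmetic assertion,
50 small random projects (2–4 genomes, depth 2,000) for the TPM and percent
invariants, 200 randomized query/fixture cases for the oracle equivalence,
and 20 replicates at depth 10^6 reads/sample for parameter recovery. These
sizes keep the full suite under a minute on one CPU while still separating
correct from incorrect denominators by orders of magnitude.

## Known limitations

* Function TPMs use assembly-wide average gene lengths and are not
  comparable across projects.
* TPM and percent are compositional; the package exports raw counts
  precisely so that downstream statistics can be done with count-aware
  methods, and takes no position on which.
* Copy numbers assume the marker is truly single-copy and present; in
  heavily incomplete universes (tiny bins) the marker's coverage estimate
  is noisy and rescaled copy numbers inherit that noise.
* The loader's dialect is its own; adapting an external pipeline's column
  layout is a mechanical mapping but not automatic.
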