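---
title: "Characterizing full-length HLA allele sequences with hlafull"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing full-length HLA allele sequences with hlafull}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlafull)
```

## The problem

The HLA genes are the most polymorphic loci in the human genome, yet a large
fraction of the alleles catalogued in the IPD-IMGT/HLA database are known only
over the exons encoding the peptide-binding groove (exons 2 and 3 for class I,
exon 2 for class II). When a laboratory resolves an allele to full length —
introns, 5'UTR and 3'UTR included — a series of analytic questions follows:
which allele is the right comparison reference, which positions differ and in
which gene feature, how many nucleotides of the coding and non-coding sequence
are new to the database, does the pattern of differences point to an
intragenic gene-conversion event, which lineage of its allele group does the
sequence belong to, and are homopolymer tracts involved (a known weak spot of
every sequencing chemistry)?

`hlafull` implements this workflow as composable, deterministic functions:
nomenclature and gene models, reference selection, difference cataloguing,
nucleotide accounting, conversion-breakpoint inference, lineage
phylogenetics, serotype motifs and homopolymer analysis — plus a synthetic
allele-family generator that provides ground truth for every inference step.

## Coordinate system and gene models

All positions are IMGT-style genomic coordinates: position 1 is the first
base of exon 1, 5'UTR positions are negative counting back from −1, and there
is no position 0. A difference is reported the way the field writes it:
`I6 C2605T` (intron 6, reference C at 2605, query T), `5'UTR G-415A`,
`I1 3205_3206insA`.

A gene model is an ordered feature-length list (`UTR5`, `E1`, `I1`, ...,
`UTR3`). The package ships canonical models for HLA-A, -B, -C, -DQA1, -DQB1
and -DPA1. The exon lengths are fixed by the coding arithmetic of database
submissions (e.g. HLA-A coding exons 73/270/276/276/117/33/48/5 nt, so a
class I allele previously known over exons 2–3 gains 552 coding nt when
resolved to full length). Published reports do not print intron and UTR
lengths, and reference UTR lengths genuinely vary between alleles; the
shipped intron/UTR lengths are therefore IMGT-scale values chosen to be
consistent with the genomic positions that appear in difference reports
(e.g. 2605 in intron 6 of HLA-A, 3974 in exon 2 of DQA1 at cDNA position
199, the DQB1 span −150..6502). Consequently, *coding* added-nucleotide
counts are recomputed from models, while *non-coding* counts are taken from
records — the same division the source tables themselves imply.

Class II exon lengths are not printed either; they were derived so that every
published per-row footnote sum holds simultaneously and each CDS is divisible
by three (DQA1 85/249/279/155; DQB1 85/270/282/111/24/14; DPA1
100/246/282/155). These are design constants of the package's models, stated
here so that downstream users know what is anchored (exon sums, difference
positions) and what is conventional (individual intron lengths).

## Reference selection

The comparison reference for a query is the first allele (lowest allele
name) of the query's allele group with a known genomic sequence. Two
fallbacks occur in practice and are encoded in `select_reference()`:

1. the first allele does not cover the required span (typically a truncated
   3'UTR) — the lowest-ordered group member that does cover it is used, or
   failing that the member with the longest coverage, both flagged
   `fallback`;
2. the group has no usable genomic record at all — a configured cross-group
   reference is used, flagged `cross_group`.

A flagged reference corresponds to the hash/footnote annotations of curated
extension tables.

## Difference cataloguing

`align_pair()` produces a global affine-gap alignment (match +1, mismatch −1,
gap open −4, gap extend −0.5 per base). Alleles of one group are
near-identical, so the alignment is essentially anchoring; the scoring
defaults only matter for rendering indels compactly. Tie-breaking among
co-optimal alignments is delegated to the underlying aligner and is
deterministic for fixed inputs; tests assert score optimality against an
independent dynamic-programming oracle rather than a particular gap
placement. `catalogue_differences()` walks the alignment in reference
coordinates, labels every event with its feature, merges adjacent inserted
or deleted bases into single events, and renders the standard notation.

IUPAC ambiguity codes are compared set-wise: when one code's base set
contains the other (an `N` against anything, an `R` against an `A`), the
column is non-comparable and skipped; two codes with disjoint or
partially-overlapping sets are a reportable difference. This mirrors how
unknown stretches in curated alignments are treated as non-comparable rather
than as differences.

## Nucleotide accounting

`count_added_nucleotides()` compares a previously-known feature set (plus a
previous 3'UTR coverage end) with a newly resolved record. Newly resolved
exons sum into `coding_added`; newly resolved UTRs/introns — including a
partial 3'UTR extension beyond the previous coverage end — sum into
`noncoding_added`. The account conserves territory: coding plus non-coding
additions always equal the length of newly resolved sequence, a property the
test suite checks over random models and random known-subsets.

## Gene-conversion inference

Given a query, its group reference, and a candidate donor allele, an
*informative site* is a position where reference and donor carry different
unambiguous bases. The query's base at such a site indicates local ancestry:
`matches_ref`, `matches_donor`, or `matches_neither` (a candidate residual
point mutation, set aside). Because every retained site matches exactly one
parent, the segmentation of the site sequence into maximal same-parent runs
is the path with the global minimum number of source switches; the open
interval between the last site of one segment and the first site of the next
is a *breakpoint interval* containing the true crossover. Tests verify
minimality against a dynamic-programming oracle over all two-state patterns
up to length 15, and verify on seeded synthetic recombinants that the true
breakpoints always lie inside the reported intervals when no homoplasy is
injected.

`scan_donor_panel()` ranks candidate donors by (fewest residual mutations,
fewest switches, allele-name order) and calls a conversion only when the
best segmentation has at least one switch and **every** segment carries at
least `min_sites_per_segment = 2` informative sites. A single shared site is
indistinguishable from a point mutation, so multi-site support is required;
single-site cases remain speculative rather than called. Co-optimal donors
are all listed (dual attribution, as when two database alleles are identical
over the informative region).

## Lineage phylogenetics

The distance between two aligned sequences is the square root of their
mismatch fraction, `sqrt(mismatches / comparable sites)`, with pairwise
deletion: a gap or ambiguity in either row removes the column from both
counts. "Percentage difference" is interpreted as a fraction in [0, 1]
before the square root, so distances (and tree scale bars) are in
sqrt-fraction units. Trees are built with neighbor joining by default
(`build_tree(dm, method = "nj")`, with a `upgma` switch), negative estimated
branch lengths clamped to zero. On noise-free additive matrices NJ recovers
the generating tree exactly — an oracle property the suite exercises over
random 5–10-taxon trees.

`mask_alignment()` restricts an alignment to a genomic window and removes
excluded features before distances are computed — e.g. a DQB1*03 analysis
over −150..6502 *without exon 2*, so that serotype-carrying exon-2 variation
cannot dominate the non-coding lineage signal.

`extract_clusters(tree, k)` cuts the tree into `k` leaf clusters by removing
its longest edges, internal edges first (decreasing length, ties by edge
index), then pendant edges, until the leaves fall into `k` components.
Removing only internal edges — the textbook phrasing — cannot produce
singleton clusters (a pendant leaf stays attached to its stem), so the
pendant extension is needed for the degenerate `k = leaf count` case;
removing a pendant edge of a single-leaf component leaves the count
unchanged, hence removal proceeds until exactly `k` leaf-bearing components
exist. For well-separated lineages the removed edges are precisely the long
inter-lineage internal edges.

## Serotype motifs and homopolymers

The DQ7/DQ8/DQ9 serotypes of DQB1*03 alleles are determined by mature
beta-chain residues 45 and 57: ED or EA → DQ7, GA → DQ8, GD → DQ9. The rule
ships as data (`dq_serotype_rule()`), not code, with verification positions
74/84/85 — invariant across the three serotypes — checked for equality only,
since their actual residues are not asserted anywhere in the package.
`translate_exon2()` handles the split codon at the exon-1/exon-2 boundary
(the reading frame follows from the summed length of the preceding exons)
and maps residues to mature numbering via the locus signal-peptide length
(32 residues for DQB1).

`find_homopolymers()` reports every maximal single-base run of at least
`min_len` nucleotides, with `min_len = 7` by default: replication slippage —
and with it both true length polymorphism and sequencing error — sets in at
tract lengths of about 7–10. `compare_homopolymer_lengths()` measures the
tract containing a given genomic position across a set of records (e.g. the
intron-1 A-tract of DQA1), flagging records in which the position is not
resolved.

## The synthetic family generator

`generate_family()` draws a root sequence over the model span, mutates
lineage founders at the between-lineage rate, and members at the
within-lineage rate, all substitutions uniform over the three alternative
bases (no transition/transversion bias is asserted anywhere, so none is
modelled). Allele names encode the lineage as the allele group, so group
logic and lineage truth coincide. The default indel rate is 0, which keeps
families columnar on model coordinates — alignments are then trivial and
every downstream module can be scored against truth without a multiple
aligner; an indel mode exists to exercise insertion rendering.
`make_recombinant()` builds mosaics with known breakpoints;
`degrade_to_partial()` reduces records to a kept feature subset, emulating
the partially known database state.

What the generator does *not* emulate: real HLA haplotype structure and
linkage, locus-specific base composition, alignment uncertainty from repeat
regions, or sequencing error. Passing tests therefore demonstrate the
correctness of the inference logic under clean lineage/mosaic structure, not
robustness to noisy real-world alignments.

## Numerical and design choices

* Distances: pairwise deletion; a pair with zero comparable sites is an
  error, not a zero.
* NJ: negative branch-length estimates clamped to 0; Newick output at 6
  significant digits.
* Alignment: IUPAC ambiguity handled set-wise (see above); alignment
  tie-breaking is the aligner's, tests pin the score only.
* Conversion calls: `min_sites_per_segment = 2`; report rendering
  "between 695-726 and 810-900" style.
* Extension-table fixtures are hand-transcribed TSVs with a provenance
  header; all totals are re-derived from rows at run time, never stored. A
  few 5'/3' column splits in the UTR table are typographically ambiguous in
  the source; the transcription notes them and chooses the split consistent
  with neighbouring rows (the ambiguity does not affect any derived count).
* Problem sizes in tests and in `scripts/acceptance.R`: 200 breakpoint
  replicates on 1.5 kb sequences with an informative scaffold every ~50 nt,
  40 donor-panel replicates at 2% divergence, 100 NJ recovery replicates on
  5–10 taxa, 100 three-lineage families (between 0.05, within 0.01, 3×4
  alleles on a 1.1 kb toy model). These sizes give stable rates while
  keeping a full run in minutes.

## Known limitations

* The per-allele *non-coding* added counts depend on per-allele reference
  UTR lengths that published tables do not state; they are treated as data,
  not recomputed.
* Conversion inference assumes columnar coordinates (no-indel projection
  onto the reference); interlocus conversion across different gene models is
  out of scope.
* No statistical significance is attached to a conversion call — the
  multi-site support rule is a plausibility filter, not a p-value.
* Reproducing published lineage figures exactly would require the actual
  database allele sequences, which are not redistributed here; the
  reproducible surface is cluster-level behaviour on families with known
  truth.
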