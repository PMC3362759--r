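---
title: "Methods: quantifying epigenomic signal around alternative and constitutive splice sites"
author: "episplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying epigenomic signal around alternative and constitutive splice sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episplice)
library(data.table)
```

## The question and the comparison groups

Splicing decisions are made co-transcriptionally, while the template is
chromatin, so chromatin state around splice sites could carry information
the spliceosome uses. `episplice` asks, feature by feature, whether an
epigenomic signal (CpG density, CpG methylation, histone-mark or
protein-binding ChIP reads, nucleosome occupancy) differs between the
splice sites of *alternatively spliced exons* (ASEs) and those of
*constitutive internal exons* (CNEs), the invariant exons that form the
natural reference group.

Five ASE types are recognized from pairs of transcript isoforms of one
gene, using internal exons only:

* **ES** — exon skipping (single exon): an internal exon of one isoform is
  absent from the other, which joins the two flanking junctions directly.
* **ME** — mutually exclusive exons: two non-overlapping exons between a
  shared upstream donor and shared downstream acceptor, each present in
  exactly one isoform. Both exons contribute their acceptor and donor as
  independent observations, because inclusion cannot be attributed to one
  of them.
* **A3SS / A5SS** — alternative acceptor / donor choice: overlapping exons
  that share one boundary and differ at the other, with the introns
  flanking the differing boundary spliced from a shared far junction. The
  analyzed sites are those of the *longer* alternative exon.
* **IR** — intron retention: an exon of one isoform spans exactly two
  consecutive exons of the other; the analyzed donor and acceptor are the
  5' and 3' boundaries of the retained intron.

Cassette-exon superclasses, multi-exon skipping and alternative first/last
exons are out of scope. Exons lying within 2000 bp of a transcript start
or end are excluded (`filter_positional()`), because promoter- and
terminator-proximal chromatin has its own strong signatures that would
confound the comparison.

Acceptor and donor are *transcript-orientation* labels: on the minus
strand the genomic roles flip. All internal coordinates are 0-based
half-open; GTF and BED conversion happens only at the I/O boundary.

### The binary/decimal bookkeeping

For audit purposes a gene can be summarized by `segment_gene()`: the union
of all exon boundaries partitions the locus into segments, each transcript
becomes a bit-vector (1 = segment exonic), and `encode_decimal()` packs
the pattern into a decimal code with the most significant bit at the
transcript 5' end. Classification itself uses the geometric predicates
above, which are fully determined by the event definitions; the coding is
a derived, logged representation, not the decision procedure.

### Resolution of open design points

* A3SS/A5SS ties (equal-length alternatives) cannot occur: two exons
  sharing one boundary and differing at the other necessarily differ in
  length. The tie branch exists defensively and logs a warning.
* An exon matching two event configurations against different partners is
  reported under both types; each type is compared to CNE independently.
* A CNE must be present, with identical boundaries and internal, in
  *every* transcript whose span covers it; single-transcript genes
  therefore contribute CNEs.
* "Coding" status is taken from `transcript_biotype`/`gene_biotype`
  attributes when present, else from the presence of CDS features; files
  with neither are assumed coding, since the substrate is expected to be a
  coding-transcript annotation already.

## Signal tracks

Three track kinds share one query interface (`collect_levels()` resolves
the dispatch):

* **sequence CpG** (`track_sequence()`): counts of CG dinucleotides fully
  inside a region, indexed once from the genome FASTA. CpG is its own
  reverse complement, so counting one strand suffices.
* **methylation** (`read_methylation()`): calls from both strands of a CpG
  are merged into one functional site; a site is methylated if any merged
  call is. Region level = percentage of CpG sites methylated; a region
  without CpG sites is *missing*, not zero — a percentage of nothing is
  undefined, and such observations are excluded from tests rather than
  imputed.
* **reads** (`load_reads()`): BED6 alignments extended to 200 bp in the
  direction of their strand (the extension approximates the sequenced
  fragment), clamped at position 0 without dropping reads. Raw reads are
  used: no deduplication, no depth normalization. Region level = number of
  extended reads overlapping the region by at least 1 bp.

## Bins, profiles, smoothing

Each splice site contributes an **exonic** and an **intronic** bin of 100
bp anchored at the boundary (`make_bins()`); an event's acceptor + donor
pair therefore spans 4 bins. 100 bp keeps the exonic bin inside a typical
(147 bp) exon; a 50-bp variant is available as a robustness check via
`bin_length`. Exons shorter than 200 bp can make the two exonic bins of
one exon overlap; both are kept, since every site is an independent
observation.

Metaprofiles (`position_profile()`) cover −500..+200 around acceptors and
−200..+500 around donors, offsets in transcript orientation with negative
values on the intronic side of the acceptor (and the exonic side of the
donor). Per position, read tracks contribute coverage; CpG tracks the
percentage of sites carrying a CpG; methylation the percentage of
per-position CpGs that are methylated. CG and mCG profiles are smoothed
with a centered 147-bp moving average (the typical exon length), truncated
at the window edges; read profiles are *not* smoothed because the 200-bp
extension already low-passes them.

## The test, its direction, and multiplicity

For every (feature, event type, bin) cell, observations from all splice
sites and all cell lines pool as independent observations and are compared
to the CNE observations of the same feature and bin with a one-tailed
**Welch** t-test (`one_tailed_t()`). Welch rather than pooled variance:
the ASE group is much smaller than the CNE group and count variances track
their means, so equal variances cannot be assumed. Pooling across lines
means a pattern consistent across cell lines sharpens the p-value while an
inconsistent one dilutes it — a deliberate conservatism.

The tail is chosen *post hoc* as the direction of the observed mean
difference, and the cell reports that direction plus its one-tailed p.
Exactly equal means give p = 0.5 with direction resolved to
`higher_in_CNE` (an arbitrary but deterministic convention, flagged
degenerate when both samples are constant). A consequence worth stating
plainly: under the null, the probability that a cell shows *some*
direction with p < α is 2α; the probability of a specific directional
false claim is α. The suite's null simulation therefore measures the
directional error rate, which is the rate that matters for any one signed
claim in the matrix.

Bonferroni correction (`bonferroni()`) uses, by default, the number of
populated cells in the run (features × 5 types × 4 bins when complete) —
the most conservative interpretable family; the family size is logged and
overridable. Significance is `p_adj < 0.01`, strictly.

### Corrections

Two optional corrections address known confounders of ChIP signal, applied
to the per-bin observations before testing (and available per position for
profiles):

* **input subtraction** (`correct_input()`): feature − input, per bin and
  cell line; negative values are preserved because flooring would bias
  sites lacking ChIP signal.
* **nucleosome division** (`correct_nucleosome()`): feature / (nucleosome
  + pseudocount), since histone marks are only meaningful where
  nucleosomes exist. The pseudocount (default 1 read) guards
  zero-occupancy bins at desk scale; a constant occupancy track provably
  leaves every p-value unchanged (scale invariance of t), which the suite
  verifies numerically.

## The signed log-p matrix and clustering

Each tested cell becomes a matrix entry: `-log10(p)` if the feature is
higher in the ASE, `log10(p)` if higher in CNE, so sign encodes direction
and magnitude encodes strength (`build_matrix()`; rows = features, 20
columns = 5 types × 4 bins). Missing cells are `NA` in the matrix and are
imputed to 0 — "no evidence either way" — before clustering.

K-means (`kmeans_cluster()`, k = 4 for features) runs directly on the
signed log-p row vectors under Euclidean geometry with 25 seeded restarts,
keeping the restart with minimal within-cluster sum of squares. Feeding
k-means a precomputed distance matrix is not a well-defined algorithm, so
the package clusters the coordinate vectors themselves, which is the
standard formalization of the same intent. Labels are canonicalized by
ordering centroids along the first principal coordinate, so a seed fully
determines the output. Two degenerate regimes are handled exactly rather
than delegated: k equal to the number of distinct rows (each distinct row
its own centroid) and k exceeding it (duplicates co-cluster; logged).

AS types are clustered the same way (k = 2) after transposing the matrix
into one vector of (feature × bin) entries per type; with opposing
association signs this recovers the exon-skipping-related class {ES, ME}
versus the splice-site-selection class {A3SS, A5SS, IR}. `classical_mds()`
provides a 2-D embedding (double-centered eigendecomposition of Euclidean
distances) with axis signs fixed by the largest-magnitude loading.

## The synthetic-data generator

`sim_config()` + `generate_genes()` build a toy genome whose geometry
isolates each concern:

* one gene per planted event, two transcripts realizing exactly that event
  on an internal exon; CNE-only genes carry two identical transcripts;
* internal exons of 147 bp (typical exon length, and > 100 bp so exonic
  bins fit), introns of 1000 bp (bins never collide across sites),
  terminal exons of 2100 bp (so internal exons always clear the 2000-bp
  positional filter — filter testing is isolated via deliberately planted
  near-TSS genes with short terminal exons);
* strands alternate so every code path sees both orientations;
* the sequence is i.i.d. uniform ACGT (about one CpG per 16 bp; a target
  CpG density can be planted instead).

Read tracks are Poisson: start rate λ per bp (default 0.2, i.e. 20
expected starts per 100-bp bin), multiplied by the planted effect
`m(feature, type)` inside ±500 bp of the affected type's splice sites.
Effects are multiplicative because ChIP count data scale that way.
Methylomes make every genomic CpG a functional site, methylated with
baseline probability 0.6 (replaceable per event type inside effect
windows). Every planted effect is recorded in the truth tables; all output
is a deterministic function of the config seed.

What the generator does **not** emulate: mappability and sequence
composition bias, fragment-size distributions, replicate structure,
between-cell-line heterogeneity, expression-coupled transcription effects,
and genuine genomic feature correlations (e.g. CpG islands at promoters).
A green suite therefore certifies the machinery — coordinate handling,
counting, the test's calibration, recovery of effects of realistic size —
not the biological conclusions one would draw from real data.

## Problem sizes and numerical choices

The test suite validates the classifier against an independently coded
brute-force oracle on 200 random multi-isoform genes, the counting
primitives against naive loops on hundreds of random instances (to 1e-12),
the Welch p against the closed form (to 1e-10) with a 10,000-replicate
null calibration at n = 50 per group, and planted-effect recovery at 300
events per type × 2 cell lines over 20 independently seeded read
generations. The acceptance script reruns the pipeline at 150 events per
type over 5 seeded track generations and reports recovery rates, the
directional type-I error (2000 replicates), and clustering recovery; these
sizes give stable rates while keeping a full run in minutes on one core.

Numerical conventions collected in one place: half-open interval
arithmetic with ≥1-bp overlap semantics; smoothing windows must be odd and
truncate at edges; p-values are capped below at the smallest positive
double in the constant-but-unequal degenerate case; log base 10 for the
signed transform (base only rescales); division pseudocount 1; alpha 0.01
strict; Bonferroni family = populated cells.

## Limitations

Absolute p-values from the original genome-scale setting are not
recoverable at synthetic scale — the Bonferroni family there (all features
× types × bins across a full annotation) and the observation counts are
orders of magnitude larger, and the exact family the original analysis
used is not stated; directions, significance patterns and cluster
structure are the reproducible objects. The classifier set may differ at
rare complex loci from junction-coding variants of the same definitions.
Transcript-level expression is not controlled for: a feature tracking
transcription itself will associate with AS without being causal for it.
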