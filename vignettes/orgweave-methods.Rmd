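---
title: "Detecting organelle-to-nuclear transfers and curating long-read plant assemblies with orgweave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting organelle-to-nuclear transfers and curating long-read plant assemblies with orgweave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgweave)
```

## Background

Plant nuclear genomes continuously acquire DNA from their own organelles.
Fragments of the mitochondrial genome inserted into chromosomes are called
NUMTs, fragments of the plastid (chloroplast) genome NUPTs. Two further
situations complicate the bookkeeping. First, plastid genes are frequently
resident in plant mitochondrial genomes, so a nuclear insertion of such a
segment matches both organelle genomes and cannot be attributed to either —
we call these ambiguous transfers NUM/PTs. Second, mitochondrial and plastid
fragments can insert in tandem at a single locus; such composite insertions
(NUMPTs) are biologically one event and should be reported as one region.

`orgweave` implements this four-way classification as a reusable pipeline,
together with the curation steps that surround it in a long-read plant
genome project: screening an assembly for low-complexity and
organelle-derived contigs, scanning for telomere tracts to judge
telomere-to-telomere completeness, profiling tandem and ribosomal DNA
arrays, and classifying contig-to-reference-scaffold relationships.
A deterministic synthetic-genome generator plants every feature class with
a machine-readable truth table, so each stage is tested end to end without
any external data.

## The transfer pipeline

The pipeline consumes pairwise local alignments of the mitochondrial and
plastid genomes against the nuclear contigs. Alignment is deliberately
pluggable: any 12-column tabular (BLAST `-outfmt 6`) or PAF hit table is
accepted through `read_alignments()`, and `run_blastn()` wraps NCBI BLAST+
when FASTA inputs are given. Internally every interval is 0-based,
half-open, with target coordinates ascending and the original orientation
kept as strand metadata; format conventions (1-based GFF3, reversed
minus-strand BLAST subject coordinates, TRF's inclusive coordinates) are
converted only at the I/O boundary. A single internal convention is the
cheapest way to avoid off-by-one drift between stages.

Four thresholds drive the calling, exposed in `transfer_config()` with the
boundary semantics applied literally:

* **Hit filter** — a hit survives if its alignment length is *strictly
  greater than* 100 bp and its percent identity is *at least* 85. We apply
  the identity bound as `>= 85.0` on the reported value; whether an aligner
  rounds before reporting is outside the package's control and recorded in
  the output provenance.
* **Source assignment** — surviving hits are unioned per organelle into
  mitochondrial (M) and plastid (P) segments. An M and a P segment whose
  reciprocal overlap (intersection over the shorter segment) reaches 0.5
  are replaced by one ambiguous (A) segment spanning their union. The 0.5
  reciprocal-overlap operationalization is a design choice: "cannot be
  distinguished" needs a quantitative proxy, and requiring half of the
  shorter segment to be shared keeps incidental edge overlaps from
  erasing genuine tandem structure.
* **Merging** — segments on one contig merge into a region when the gap
  between them is *strictly less than* 300 bp, nested segments being
  absorbed. Merging is cross-source by necessity: a tandem NUMPT can only
  arise when an M and a P segment are allowed to join. The implementation
  is a linear sweep over start-sorted segments; the test suite checks it
  against an independent quadratic transitive-closure oracle on a thousand
  random segment sets, and verifies permutation invariance and idempotence.
* **Classification** — with `S` the set of segment sources excluding A:
  `{M}` is a NUMT, `{P}` a NUPT, `{M, P}` a NUMPT, and an all-ambiguous
  region a NUM/PT. Mixed sets containing A classify by their unambiguous
  members: an ambiguous segment cannot overturn positive evidence of
  origin. Region identity is reported as the maximum over supporting hits
  and is never used for re-filtering after the merge.
* **Junction validation** — an insertion boundary is supported when at
  least one long-read alignment covers at least 50 bp on each side of it;
  boundaries that no read alignment overlaps at all are reported as
  `untested` rather than failed. One spanning read suffices by default
  (configurable); the check is meant to catch assembly chimeras, whose
  boundaries coincide with read ends systematically, not to estimate
  coverage.

## Assembly QC screens

**Low-complexity contigs.** Contigs consisting only of simple repeats are
flagged by normalized k-mer Shannon entropy: `H = -Σ p log2 p` over
observed k-mer frequencies, divided by `log2(min(4^k, positions))`. With
`k = 21` a pure 36 bp satellite contig contains at most 36 distinct
21-mers and scores ≈ 0.33, while random sequence scores > 0.99, so the
default threshold of 0.5 separates the two sharply and is insensitive to
contig length. The statistic, k and the cutoff are all configurable — an
entropy screen is a convention, and sharp class separation matters more
than the particular constant.

**Organelle-derived contigs.** Because organellar DNA is present in many
copies per cell, contigs assembled from it show read depths tens to
hundreds of times the nuclear background (the conditions emulated by the
generator: ~27x nuclear, ~500x organelle). A contig is flagged when its
mean depth exceeds 5x the median over all contigs *and* at least half of
its length is covered by organelle-genome homology. The conjunction
replaces a manual "inspect the deepest contigs, then confirm by BLAST"
step; depth alone is insufficient because collapsed nuclear repeats are
also deep.

**Telomeres.** Non-overlapping exact copies of the plant telomere motif
`TTTAGGG` (and its reverse complement) are counted in terminal windows of
10 kb; a terminus with at least 25 copies is telomere-positive, and
contigs are classed `both_telomeres` / `left_only` / `right_only` /
`none`. Exact matching is intentional: the canonical motif is invariant
enough in plants that degenerate-motif search adds parameters without
changing desk-scale conclusions. The 25-copy default is a decision, made
configurable because no published cutoff exists.

## Tandem and rDNA arrays

`detect_tandem_runs()` is an exact-match scanner: position `i` is compared
with `i + p` for each candidate period, maximal match runs become
candidate arrays, and overlapping candidates are resolved in favour of
more copies, then smaller period (so a homopolymer is period 1, not 2).
It is quadratic in the period range and intended for unit discovery in
regions of interest; genome-scale, divergence-tolerant discovery is the
role of Tandem Repeats Finder, whose `.dat` output `read_trf_dat()`
ingests.

rDNA arrays are profiled from an rRNA gene-hit table (from any homology
tool, or expanded from the generator's truth via `rdna_truth_to_hits()`);
detecting rRNA genes is deliberately out of scope. Hits cluster into an
array when consecutive hits lie within 20 kb; clusters with fewer than two
copies of their most frequent gene are labelled `cluster`, not `array`,
since scattered rRNA pseudogene fragments are common. Unit lengths are the
start-to-start distances of the most frequent gene label, summarised by
the local maxima of a 100 bp-binned histogram with a 20% prominence floor
(bin width and prominence are decisions; each mode is reported as the
median of its bin's samples so estimates stay on the data rather than on
bin centres). The headline copy number is the count of the most frequent
gene label, with per-gene minima and maxima alongside — unit fragments
routinely carry one gene of a unit but not the rest. A 35S array is
L-type (linked) when at least half of its units have a 5S hit within 5 kb;
the genome-level call is S-type only when no array is linked.

## Contig-to-scaffold relationships and centromere candidates

Relationships between assembly contigs and reference scaffolds are called
from nucleotide alignment coverage alone (gene-order synteny inference is
out of scope). Per reference, merged hit coverage per query produces a
profile, then: a single query covering ≥ 80% is `one_to_one`; two queries
each ≥ 25%, anchored in opposite terminal tenths of the reference,
disjoint, jointly covering ≥ 80% of the non-gap length and separated by an
uncovered central gap ≥ 5% are an `arm_pair` — the signature of a
chromosome split at an unassembled central repeat; coverage reached only
by three or more queries is `complex`. The thresholds are configurable
decisions and every call carries its evidence values, because the
underlying biological judgement was originally made by eye from synteny
plots.

Candidate centromeres are the quantitative form of the dense off-diagonal
rectangle seen in self-alignment dot plots: per 100 kb window the fraction
covered by off-diagonal self-hits is standardized within the contig, and
windows with z > 2 merge into candidates. A z-score needs contrast, so a
contig must contain enough windows for the background to define a scale;
contigs whose windows are uniformly covered (or uniformly empty) yield no
candidates by construction.

## The synthetic data generator

`simulation_config()` fixes the study conditions the package is tested
under; the defaults are the generator's definition of those conditions,
not tuning knobs:

* 10 nuclear contigs of 500 kb of i.i.d. uniform background; a 150 kb
  plastome and a 300 kb mitogenome; 5 shared 2 kb blocks copied from the
  plastome into the mitogenome at exactly 1% divergence.
* 40 NUMTs, 30 NUPTs, 10 tandem NUMPTs (internal gap drawn uniformly from
  0–299 bp so the merge rule must join them) and 10 NUM/PTs (copies of
  shared blocks), each 200–5,000 bp at 5% divergence; an optional switch
  plants "broken" tandem pairs with gaps of 300–800 bp to exercise the
  negative case. Planted features keep ≥ 400 bp of background between
  them so the merge rule cannot fuse distinct truths.
* telomere tracts of 120 exact `TTTAGGG` copies per planned terminus;
  two interstitial satellite arrays of a fixed 36 bp unit; one rDNA-like
  array of 30 exact 11.4 kb units; two 50 kb pure-satellite contigs; and
  verbatim plastome/mitogenome copies as contigs `orgP`/`orgM`.
* long reads of mean 15 kb at 27x over nuclear contigs and 500x over the
  organelle genomes, substitution errors at 0.2%.

Determinism is strict: the organelle, nuclear and read stages seed R's
RNG with `seed`, `seed + 1` and `seed + 2` respectively and consume one
stream each in documented order, so identical configurations are
byte-identical across runs.

The generator emulates what the threshold rules need and nothing more:
uniform base composition (no GC skew or isochores), exact repeat units,
substitution-only divergence and error (no indels), uniform read sampling
(no coverage waviness or chimeras), and no heterozygosity or transposon
evolution. Passing tests therefore demonstrate that the rules are
implemented correctly and recover planted truth under realistic
signal-to-threshold margins — not that the thresholds themselves are
optimal for any particular real genome, where divergence structure,
indels and assembler behaviour add noise these fixtures do not model.

Read simulation returns metadata (source, coordinates, strand, error
count) and materialises sequences or FASTQ only on request;
`reads_to_alignments()` converts the metadata into the hit table of an
idealised perfect mapper. Depth and junction screens consume that table in
the tests, which isolates the rules under test from mapper behaviour;
tables from a real mapper (PAF) drop in unchanged through
`read_alignments()`.

## Numerical choices and degenerate inputs

* Interval arithmetic is integral throughout; merge/overlap comparisons
  are strict or inclusive exactly as the rule wordings state (length
  > 100; identity ≥ 85; gap < 300; junction span ≥ 50; domain majority
  > 0.5; relabel probability < 0.5; pseudogene statistic < 75).
* The repeat-library relabeling rule takes the larger of the Class I and
  Class II probabilities; pseudogene percent alignment length is relative
  to the query, and the mean-or-maximum test defaults to OR — all three
  choices configurable, since the conventions vary between annotation
  projects.
* k-mers containing `N` are excluded from entropy; an entropy denominator
  of zero (a single k-mer position) returns 0. Ambiguity codes in input
  FASTA are coerced to `N` with a logged count rather than rejected.
* Ties in tandem-run resolution break toward smaller period, then
  position; ties in depth best-alignment selection break on stable order.
* Degenerate inputs warn and continue where a sensible value exists
  (contig shorter than the telomere motif: zero counts; window longer
  than the contig: one whole-contig window; TRF rows with non-positive
  length: skipped) and stop where none does (duplicate FASTA ids, unknown
  contigs in alignment tables, probabilities outside [0, 1], empty
  arrays).

## Problem sizes

The shipped tests and the acceptance script run the full generator
conditions above (a ~6 Mb assembly, ~25,000 simulated reads, organelle
alignment with BLAST+), 1,000 random merge-oracle trials, 50 seeded
unit-length fixtures and a 9-reference comparison fixture; the complete
suite finishes in a few minutes on one CPU. These sizes were chosen so
that every planted feature class occurs often enough for exact-count
checks to be meaningful while keeping the fixtures quick to regenerate
from scratch.

## Known limitations

* Transfers are detected only down to the hit filter's floor: insertions
  ≤ 100 bp, or diverged beyond 85% identity, are invisible by design.
* NUM/PT ambiguity is resolved purely by reciprocal overlap of M and P
  homology; gene-level annotation of the shared content is not attempted.
* The exact-match tandem detector does not tolerate unit divergence or
  indels; use TRF output for divergent satellites.
* Relationship calls use nucleotide coverage only and inherit its blind
  spots (highly diverged arms, large inversions covered symmetrically).
* The depth screen assumes a unimodal nuclear depth background; it is not
  a general contamination classifier and performs no taxonomic inference.
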