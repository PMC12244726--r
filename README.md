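# orgweave

Detection and classification of organelle-to-nuclear DNA transfers, and the
curation toolkit around them, for long-read plant genome assemblies.

Plant nuclear genomes continuously capture fragments of their own organelle
genomes. `orgweave` finds these insertions from organelle-versus-nuclear
alignments and classifies each merged insertion region into four categories:

| Category | Meaning |
|----------|---------|
| **NUMT** | nuclear insertion of mitochondrial DNA |
| **NUPT** | nuclear insertion of plastid (chloroplast) DNA |
| **NUM/PT** | insertion whose source cannot be distinguished (e.g. a gene present in both organelle genomes) |
| **NUMPT** | complex insertion carrying mitochondrial and plastid segments in tandem |

The calling rules: a hit survives when its alignment length exceeds 100 bp at
≥ 85% identity; surviving hits are collapsed per source, a mitochondrial and a
plastid segment with reciprocal overlap ≥ 0.5 become one *ambiguous* segment,
segments separated by less than 300 bp merge into one region, and the region's
category follows from the set of its segment sources. Insertion junctions are
validated by long-read alignments covering at least 50 bp on each side of each
boundary, which flags assembly chimeras.

Around the transfer pipeline the package provides the standard curation
screens of a long-read plant assembly project:

* **Assembly QC** — normalized k-mer Shannon entropy to flag contigs made
  only of simple repeats; per-contig read depth with organelle-homology
  confirmation to flag organelle-derived contigs; `TTTAGGG` telomere
  scanning with telomere-to-telomere completeness calls.
* **Repeat and rDNA arrays** — exact tandem-run detection, Tandem Repeats
  Finder `.dat` ingestion, rDNA array clustering with unit-length modes and
  copy counts, and S-type/L-type 5S–35S linkage calls.
* **Annotation hygiene** — transposon-gene flagging when more than half of a
  gene's Pfam domain descriptions match transposon-related terms; removal of
  genes with neither external support nor functional annotation; repeat
  library relabeling to `unclassified` below 0.5 classification probability;
  pseudogene flagging when mean or maximum percent alignment length falls
  below 75%.
* **Assembly comparison** — contig-to-reference relationship calls
  (`one_to_one`, `arm_pair`, `complex`) from alignment coverage, and windowed
  off-diagonal self-alignment density to nominate candidate centromere
  regions.
* **Synthetic truth** — a deterministic generator that plants every feature
  class (insertions, telomeres, satellites, rDNA arrays, repeat-only and
  organelle contigs, long reads at category-specific depths) together with a
  truth table, so the whole pipeline is testable offline.

## Worked example

Generate a small synthetic assembly with planted transfers, then run the
pipeline against it:

```r
library(orgweave)

cfg <- simulation_config(seed = 1, n_contigs = 4, contig_length = 200000,
                         n_numt = 8, n_nupt = 6, n_numpt = 3,
                         n_numpt_ambiguous = 3, rdna_copies = 12)
out <- simulate_genome_set(cfg, "demo")          # writes FASTA + truth
write_fasta(out$contigs[sprintf("ctg%02d", 1:4)], "demo/nuclear.fasta")

res <- run_transfer_pipeline(
  nuclear_fasta = "demo/nuclear.fasta",
  mito_fasta    = "demo/mitome.fasta",
  plastid_fasta = "demo/plastome.fasta",
  read_hits     = reads_to_alignments(out$reads),
  out_dir       = "demo/transfers")
res$summary
#>   category count total_length
#> 1     NUMT     8        24468
#> 2     NUPT     6         8255
#> 3   NUM_PT     3         4546
#> 4    NUMPT     3        14140
```

The summary reports, per category, how many insertion regions were called
and their summed length in bp — here exactly the planted 8/6/3/3. Each
region row carries its contig interval, category, supporting sources and
junction status:

```r
head(res$regions[, c("contig_id", "start", "end", "category",
                     "left_validated", "right_validated")], 3)
#>   contig_id  start    end category left_validated right_validated
#> 1     ctg01   8765  12151     NUPT            yes             yes
#> 2     ctg01 111964 114005     NUPT            yes             yes
#> 3     ctg01 126817 129760    NUMPT            yes             yes
```

`left_validated = "yes"` means at least one simulated read spans ≥ 50 bp on
both sides of that insertion boundary, so the junction is not an assembly
artifact. The same results are written as `demo/transfers/transfers.gff3`
(1-based GFF3 with a `Category` attribute) and `summary.tsv`.

A thin command-line front end over the same functions is installed at
`inst/cli/orgweave.R` (`simulate`, `transfers`, `qc` subcommands).

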