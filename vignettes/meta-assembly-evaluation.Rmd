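---
title: "Meta-assembly construction and seven-metric assembly ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-assembly construction and seven-metric assembly ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metassemblr)
```

## The problem and the model

De novo transcriptome assemblers disagree: on the same read library,
different tools (and different k-mer settings) reconstruct overlapping but
distinct contig sets. This matters most for single-end libraries with
variable read lengths (50–270 nt, IonTorrent-style), where no assembler has
a clear advantage. The meta-assembly approach treats the assemblers as an
ensemble: all candidate assemblies are concatenated and then reduced to a
non-redundant set by removing **every contig whose sequence is a substring
of at least one other contig**. The surviving set keeps each region of the
transcriptome represented by the longest reconstruction any assembler
achieved, while exact sub-sequences contribute nothing and are dropped.

Two modelling commitments follow from strand ambiguity and duplication:

* a contig contained in the *reverse complement* of another is also
  redundant (default; `consider_revcomp = FALSE` restores a strict
  forward-only reading);
* exact duplicates collapse to one survivor, chosen as the
  lexicographically smallest id, so results are deterministic.

When a contig is contained in several retained contigs, the reported
container is the longest one (ties again by smallest id). These tie-breaks
carry no biological meaning; they only make reports reproducible.

## Redundancy removal: algorithm and complexity

A naive implementation checks all O(n²) contig pairs with a string search —
fine as a test oracle, hopeless for six-figure contig counts. The package
instead builds an Aho–Corasick-style dictionary of all contig sequences
(`Biostrings::PDict` with a trusted-band prefix) and streams every contig
through it once, yielding the complete containment relation in roughly
O(total sequence length). Contigs are then processed longest-first: one is
removed iff an already-retained contig contains it. Containment is
transitive, so this greedy pass removes exactly the contigs contained in
the final retained set; the test suite checks equivalence against the
quadratic oracle on planted instances up to n = 500, plus idempotence and
order-insensitivity of the retained sequence set. Every removed/container
pair is re-verified with a fixed-string search before reporting. Patterns
whose band would contain an ambiguous base fall back to direct string
search; all IUPAC codes other than N are mapped to N on input so the
alphabet stays closed for k-mer machinery.

## The seven quality metrics

| # | metric | engine | direction |
|---|--------|--------|-----------|
| 1 | N50 | `n50()` | higher |
| 2 | median contig length | `length_stats()` | higher |
| 3 | markers recovered (complete + fragmented) | `cds_recovery()` on a marker FASTA | higher |
| 4 | % contigs with CDS homology | `cds_recovery()` | higher |
| 5 | CDS detected | `cds_recovery()` | higher |
| 6 | CDS ≥ 95 % covered | `cds_recovery()` | higher |
| 7 | % reads pseudo-mapped | `build_index()` + `map_rate()` | higher |

Marker recovery (metric 3) is deliberately generic: any marker FASTA is
scored through the same CDS-coverage engine, with *complete* meaning
coverage ≥ 0.95 and *fragmented* meaning detected below that, and the
metric is the single summed count. This preserves the ranking slot that
marker-completeness tools occupy without reimplementing profile-HMM
machinery, which is out of scope here.

### Normalization and ranking

Each metric column is min–max scaled to [0, 1] (the cited normalization
brings every parameter onto a common 0-to-1 range; min–max is the scheme
with exactly that property), then summed per assembly. Two numerical
choices deserve note:

* **Degenerate columns** (all assemblies equal, including the
  single-assembly case) normalize to 1.0 for everyone. A constant column
  cannot change the ranking; 1.0 avoids spuriously penalizing all
  assemblies on an uninformative metric.
* The ranking is invariant under any strictly increasing affine transform
  of a raw column — a property the tests exercise — so unit choices
  (nt vs. kb, % vs. fraction) cannot reorder assemblies.

### Alignment engine

`local_align()` is a seed-and-extend aligner: exact shared k-mers
(default k = 31) anchor ungapped extensions scored +1/−2 with X-drop 20;
both strands are searched; overlapping hits on one diagonal are merged;
hits below 70 % identity or shorter than k are dropped. Ungapped extension
is adequate for same-species CDS recovery and keeps the brute-force test
oracle tractable; the thresholds are package defaults, not published
values, and are exposed as parameters. Per-CDS coverage is the union of
qualifying hit spans over *all* contigs (a single-best-contig mode is
available via `single_best_contig = TRUE`).

### Pseudo-alignment

`map_rate()` makes a mapped/unmapped decision per read: a read maps iff at
least `min_frac` (default 0.5) of its canonical k-mers are present in the
index and the intersection of their contig sets, skipping absent k-mers,
is non-empty. This emulates pseudo-alignment compatibility without an
equivalence-class De Bruijn structure, which would only be needed for
abundance estimation. The default `min_frac = 0.5` tolerates the indel-rich
errors of single-end IonTorrent reads; k = 31 is the common pseudo-aligner
default. The in-memory hash index is designed for the package's evaluation
scale (thousands of contigs), not for genome-scale indexing.

### Read filtering

`filter_reads()` keeps a read iff its arithmetic mean Phred score is
≥ 20 and its length is within [50, 270]. All boundaries are inclusive:
"below 20", "below 50" and "above 270" are read strictly, so a mean of
exactly 20 and lengths of exactly 50 or 270 pass. The mean is taken in
Phred space (not error-probability space), matching the default behaviour
of common read-filtering tools; the thresholds are parameters. Reads
failing several rules are counted once, with priority
too-short → too-long → low-quality, so the reason counts partition the
removed set.

### ORF scanning

`find_orfs()` reports complete ORFs (ATG to in-frame stop) in all six
frames with protein length ≥ 30 residues by default, the conventional
minimum for calling a contig protein-coding here. Only the leftmost ATG
per (frame, stop) pair is reported, which avoids quadratic nested calls;
partial ORFs (no stop before the contig end) are opt-in via
`complete_only = FALSE`. Coordinates are 0-based half-open on the forward
strand (BED-style), with a 1-based GFF3-style export in `write_orfs()`.
The 30-residue threshold counts residues excluding the stop.

## The synthetic-data generator

`synth_config()` fixes the study conditions all tests run under:

* **transcripts** — 100 sequences of 300–3000 nt at GC 0.45 (a typical
  plant-coding composition), each carrying one planted complete ORF of
  30–300 codons so ORF scanning and coding-only filtering always have
  signal;
* **assemblies** — 4 candidates (the usual several-assembler setting),
  one contig per transcript: full-length, or a ≥ 200 nt fragment with
  probability 0.3; per-base substitutions at 0.005; strand flipped with
  probability 1/2; then 30 % planted duplicates, each an exact substring
  (≥ 200 nt) of an already-mutated contig, flagged in the provenance
  table — so redundancy-removal ground truth stays exact even with
  sequencing-error simulation on;
* **reads** — 2000 single-end reads, lengths uniform on [50, 270], strand
  uniform, substitutions at 0.01, with 10 % of reads given low per-base
  qualities (mean Phred < 20) as a known positive class for the filter.

Each generator draws from its own stream (`seed` plus a fixed offset), so
the three are independently byte-reproducible. What the generator does
*not* emulate: homopolymer indel errors (the dominant IonTorrent mode),
expression-level variation, chimeric contigs and alternative isoforms.
Passing tests therefore demonstrate correctness of the algorithms under
substitution noise and planted redundancy, not robustness to every
artefact of real libraries.

## Problem sizes and determinism

The test suite runs the dedup oracle on 100 random instances up to n = 500
contigs (lengths 50–2000 nt), the ORF oracle on 50 random 1 kb contigs,
and pseudo-mapping calibration on 10 000 constructed reads; the end-to-end
examples use 10–50 transcripts. These sizes make the full suite complete
in minutes on one CPU while still exercising the indexes' non-trivial code
paths. Every stochastic test fixes its seed; repeated runs of
`run_evaluate()` produce byte-identical reports, which is itself under
test.

## Known limitations

* Containment is exact: near-identical contigs that differ by even one
  base are both retained (clustering at < 100 % identity is a different
  operation, deliberately out of scope).
* The aligner is ungapped; a long indel splits a hit in two, which can
  slightly undercount coverage near 0.95.
* `overlap_sets()` handles up to six sets; the optional base-graphics Venn
  figure is drawn for up to three.
* The k-mer structures live in R environments — appropriate for evaluation
  workloads, not for indexing mammalian-scale assemblies.
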