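# metassemblr

Tools for building and evaluating de novo **transcriptome meta-assemblies**.

No single assembler reconstructs a transcriptome completely: each tool (and
each k-mer setting) recovers a different subset of transcripts, especially on
single-end, variable-length libraries such as IonTorrent data. A practical
remedy is to run several assemblers and fuse their outputs into one
*meta-assembly*: concatenate the candidate assemblies, then apply
**redundancy reduction** — remove every contig whose sequence is a substring
of at least one other contig in the set (optionally also counting
reverse-complement containment, since de novo contigs are strand-ambiguous).
`metassemblr` implements that construction, plus a seven-metric scoring
scheme to decide which assembly — individual or meta — is best.

## The method

For each assembly *j* of *k* candidates, seven quality parameters are
computed:

1. N50 of contig lengths;
2. median contig length;
3. marker genes recovered (complete, coverage ≥ 0.95, plus fragmented);
4. % of contigs with homology to a reference CDS set;
5. number of reference CDS detected;
6. number of reference CDS with ≥ 95 % of their length covered by aligned
   contigs;
7. % of library reads pseudo-aligned back to the assembly.

Each raw parameter *Rᵢⱼ* (metric *i*, assembly *j*) is min–max normalized
over the vector *Vᵢ = (Rᵢ₁, …, Rᵢₖ)*:

```
Nᵢⱼ = (Rᵢⱼ − min Vᵢ) / (max Vᵢ − min Vᵢ)
```

so every metric lies in [0, 1], the normalized parameters are summed per
assembly, and assemblies are ranked by the sum; the assembly with the
highest sum is considered the best. CDS detection is additionally
decomposed into exclusive Venn regions across assemblies to show what each
assembler contributes uniquely.

Homology and marker recovery use a built-in seed-and-extend aligner (exact
shared k-mers, ungapped X-drop extension); read mapping uses canonical
k-mer pseudo-alignment. A synthetic-data generator produces transcripts,
redundant multi-source assemblies and IonTorrent-like reads with full
ground-truth provenance, so the entire pipeline is testable offline.

## Worked example

```r
library(metassemblr)

cfg <- synth_config(n_transcripts = 50, n_reads = 2000, seed = 1)
tr  <- simulate_transcripts(cfg)
sa  <- simulate_assemblies(tr$transcripts, cfg)   # 4 redundant assemblies
rd  <- simulate_reads(tr$transcripts, cfg)
kept <- filter_reads(rd$reads)$reads              # mean Q >= 20, 50-270 nt

meta <- run_meta(sa$assemblies)
#> meta-assembly: 260 -> 197 contigs (75.8% of initial)

asm <- c(sa$assemblies, list(meta$assembly))
names(asm) <- c(paste0("asm", 1:4), "meta")
ev <- run_evaluate(asm, reference = tr$transcripts,
                   markers = tr$transcripts[1:10], reads = kept)
round(ev$rank$sums, 2)
#> asm1 asm2 asm3 asm4 meta
#> 3.12 3.92 4.30 5.65 6.41
ev$rank$order
#> [1] "meta" "asm4" "asm3" "asm2" "asm1"
```

The 260 merged contigs include 60 planted substring duplicates; redundancy
removal keeps 197 (75.8 % of the input — it also catches cross-assembly
duplicates that escaped mutation). The meta-assembly detects all 50
reference CDS, covers all 50 to ≥ 95 %, maps 74.2 % of the filtered reads,
and ranks first with the highest summed normalized score (6.41 of a
possible 7).

The same stages are scriptable from a shell via `exec/metassemblr`
(subcommands `simulate`, `merge`, `dedup`, `stats`, `cds`, `maprate`,
`rank`, `venn`, `evaluate`, `meta`).

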