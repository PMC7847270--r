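# perlscan

Discovery and characterization of large germline-specific expression
loci and piRNA signatures.

In late zebrafish primordial germ cell (PGC) development, very large
(≥ 250 kb) mostly non-genic genomic regions become transcribed
specifically in the germline.  These loci ("PERLs") are
transposon-rich, produce 23–33 nt piRNAs, and sit preferentially in
closed (B) chromatin.  `perlscan` is an R/Bioconductor-style package
for analysts working with this kind of data.  It provides:

* **PERL calling** from replicated base-level coverage: per-base RPM
  cutoff (default 0.25) with 3000 bp joining, merging of expressed
  regions closer than 3 kb, removal of clusters sharing > 10 % of
  their bases with whole-organism ("fish") clusters, a 250 kb size
  floor, exclusion of regions already expressed at 1–2 dpf, and
  cross-timepoint union-merging.
* **Ping-pong signature analysis**: opposite-strand read pairs are
  tallied by 5′-overlap `k` = 1..30, and the 10-nt signature is scored
  as `Z = (P10 − M)/SD`, with `M` and `SD` the mean and standard
  deviation of the background tallies at `k ∈ {1..9, 11..30}`.
* **Small RNA profiles**: per-element sense/antisense bias with
  rank-sum comparisons, length histograms, positional nucleotide bias
  (1U/10A) and the downstream-U processing signature read from the
  genome.
* **Matched-background enrichment**: 100 size- and chromosome-matched
  shuffled background sets (excluding the loci themselves), base
  overlap with TE classes and A/B compartments, piRNA density and
  expression dynamics with Wilcoxon tests.
* **Gene sets and clustering**: fold-change ≥ 30 & FDR < 0.01
  selection per timepoint, exclusive (UpSet-style) intersection
  counts, the stable PGC-specific gene set, and Pearson-distance
  ward.D expression clustering.
* A **synthetic-data generator** that plants loci, biases, TE
  enrichment and gene archetypes with known truth, plus a
  `run_pipeline()` orchestrator that runs everything end to end,
  deterministically under one seed.

Intervals are `GRanges`, coverage is Rle-based, file I/O goes through
`rtracklayer`/`Biostrings` (BED, GTF, FASTA, bedGraph, chrom.sizes).

## Worked example

Simulate a small dataset with two planted 300–400 kb PGC-specific
loci, call PERLs at the published parameters, and score the ping-pong
signature of the 6 dpf small RNA library:

```r
library(perlscan)
cfg <- sim_config(n_chroms = 2, chrom_length = 2e6, n_genes = 40,
                  n_perls = 2, perl_length = c(3e5, 4e5),
                  smallrna_n_reads = 4000, n_psg = 12)
sim <- simulate_dataset(cfg, seed = 11)
called <- call_perls(sim$totalrna$PGC, sim$totalrna$fish,
                     sim$art$layout)
called$perls
#> GRanges object with 2 ranges and 2 metadata columns:
#>       seqnames         ranges strand |          id source_timepoints
#>          <Rle>      <IRanges>  <Rle> | <character>       <character>
#>   [1]     chr1 952942-1309107      * |    PERL_001        6dpf,10dpf
#>   [2]     chr2 722140-1113631      * |    PERL_002        6dpf,10dpf

pingpong(do.call(c, sim$smallrna$reads[["6dpf"]]))
#> ping-pong profile: P10 = 3654  M = 35.069  SD = 6.9433  Z = 521.21
pingpong(do.call(c, sim$smallrna$reads[["1dpf"]]))
#> ping-pong profile: P10 = 257  M = 16.31  SD = 4.4329  Z = 54.297
```

Both planted loci are recovered (called only at 6 and 10 dpf, as
planted), and the ping-pong Z-score is an order of magnitude higher at
6 dpf — where 30 % of reads were emitted as 10-nt-overlap partners —
than at 1 dpf (2 %).  The full file-based workflow, from simulation to
result tables (PERL catalog with per-sample RPKM and piRNA density,
intergenic proportions, ping-pong/strand-bias/nucleotide tables, TE
clustering with clade enrichment, background enrichment, gene sets) is

```r
run_pipeline("my_run", seed = 7)
```

and is byte-reproducible under a fixed seed.  A thin command-line
front-end is installed at `inst/scripts/perlscan`.

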