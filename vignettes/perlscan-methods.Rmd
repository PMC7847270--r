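---
title: "Calling germline-specific expression loci and piRNA signatures with perlscan"
author: "perlscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling germline-specific expression loci and piRNA signatures with perlscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perlscan)
library(GenomicRanges)
```

## The problem

During zebrafish germline development, primordial germ cells (PGCs)
activate transcription of very large, mostly non-genic genomic regions
late in their maturation (from roughly 3–6 days post-fertilization).
These loci produce Piwi-interacting RNAs (piRNAs), are rich in
transposable elements (TEs), and sit preferentially in closed (B)
chromatin compartments.  `perlscan` implements the computational side
of this biology as a reusable pipeline:

1. a stepwise **caller** for large PGC-specific expression loci
   ("PERLs") from replicated, depth-normalized coverage;
2. **intergenic transcription** quantification;
3. **small RNA analytics**: ping-pong signature Z-scores,
   sense/antisense bias, length profiles, positional nucleotide bias
   (1U/10A), and the downstream-U processing signature;
4. **enrichment statistics** against size- and chromosome-matched
   shuffled backgrounds;
5. **gene-set selection** (fold-change/FDR thresholds, exclusive
   "UpSet" intersection accounting) and Pearson/Ward expression
   clustering;
6. a **synthetic-data generator** that plants all of the above
   structure so every stage can be validated against known truth.

## The PERL caller

The caller operates on base-level coverage, one track per (timepoint,
tissue), in five steps with these defaults (all exposed via
`perl_config()`):

| step | rule | default |
|------|------|---------|
| 1 | per-base cutoff on replicate-mean RPM coverage; above-cutoff bases within `join_gap` bp are joined into expressed regions | cutoff 0.25, join 3000 bp (inclusive) |
| 2 | expressed regions closer than `merge_gap` are merged into clusters | < 3000 bp (strict) |
| 3 | PGC clusters sharing more than `specificity_max_overlap` of their bases with whole-fish clusters are dropped | > 10 % (strict) |
| 4 | clusters below `min_size` are dropped | 250 kb (inclusive) |
| 5 | candidates overlapping early (1–2 dpf) PGC clusters by more than 10 % of their bases are dropped; survivors from all candidate timepoints are union-merged | |

Boundary semantics matter and are tested explicitly: the step-1
joining rule is inclusive ("within 3000 bp"), the step-2 merge is
strict ("less than 3 kb"), bases exactly at the coverage cutoff pass,
a cluster of exactly 250,000 bp survives, and a candidate overlapping
fish clusters by exactly 10 % is retained.

Three choices were genuinely open and are resolved as follows:

* **Normalization.** Coverage is scaled to reads per million mapped
  (RPM) per replicate before averaging, and the 0.25 cutoff is
  interpreted on that scale.  RPM is the simplest depth normalization
  consistent with a "mean (normalized) coverage" definition; both the
  scale and the cutoff are configurable.
* **Early-timepoint exclusion.** "Present at 1–2 dpf" is
  operationalized as base-overlap fraction > 10 % with 1–2 dpf PGC
  expression clusters, reusing the step-3 threshold, since no separate
  threshold is defined for this step.
* **Specificity filtering** compares against *unfiltered* fish
  clusters (before any size selection), the more conservative reading;
  and 3 dpf candidates are not required to persist to a later
  timepoint.

Internally every interval lives in a `GRanges` (1-based, closed);
BED input/output converts at the boundary.  All bp quantities (gaps,
widths, overlap fractions) are representation-independent.

## Small RNA statistics

**Ping-pong.** For every opposite-strand read pair on one chromosome
that genomically overlaps by at least one base, the 5′-to-5′ overlap
`k = q − p + 1` (with `p` the plus-read 5′ and `q` the minus-read 5′)
is tallied with the product of the two read weights, for `k` in 1..30.
The signature statistic is

$$ Z = \frac{P_{10} - M}{SD} $$

where `P10` is the tally at `k = 10` and `M`, `SD` are the mean and
sample (n−1) standard deviation of the 29 background tallies at
`k ∈ {1..9, 11..30}`.  A population-SD variant is available
(`sd_type = "population"`); sample SD is the conservative default.
The implementation is verified exactly against an O(n²) all-pairs
enumeration, including weighted reads.

One statistical property deserves emphasis: because `SD` is estimated
from only 29 bins, the null distribution of `Z` is `1.017·t(28)`, not
standard normal.  Its true coverage of `|Z| < 2` is ≈ 0.941, so in 100
independent null libraries one should *expect* about 94 — not 95 or
more — to fall inside ±2.  Related: permuting the strand labels of a
single library is not a clean null either, because all permuted
replicates share that library's positional sampling noise (pairs
between fixed positions keep their fixed `k`), and any planted
ping-pong pair keeps its orientation with probability ~1/4.  The
package's null-calibration test therefore draws fresh read positions
per replicate.

**Strand bias** is the per-element sense fraction of fully contained
reads; distributions are compared across conditions with a two-sided
Wilcoxon rank-sum test (normal approximation with continuity
correction; ties are expected in fraction data).

**Nucleotide bias** tallies per-position base frequencies over
read-oriented sequences; the downstream-U statistic reads the genomic
base immediately 3′ of each read's end *on the read's strand*
(reverse-complemented for minus-strand reads), skipping reads at
chromosome edges.

**TE clustering** uses `hclust` on `as.dist(1 - cor(t(x)))` with
`method = "ward.D"` — Ward's criterion applied to unsquared Pearson
dissimilarities — and a `cutree` cut; zero-variance rows are excluded
with a warning because their correlation is undefined.  Clade
enrichment of a cluster is the upper-tail hypergeometric probability
`P(X ≥ k)` via `phyper`.

## Matched-background enrichment

Backgrounds are built per region: an interval of identical length on
the same chromosome, placed uniformly at random by rejection sampling
against an exclusion set (by default the regions themselves), 100
independent sets by default.  Placements within a set may overlap one
another — only the exclusion set is avoided — matching the semantics
of chromosome-constrained interval shuffling with an exclusion list.
Per-region background values are averaged across sets before
region-level comparisons; set-level means drive the one-sided
empirical p-value, and a two-sided rank-sum test compares per-region
distributions.  Rejection sampling gives up with a hard error after
`max_tries` attempts, which will trigger when a region's chromosome
has no room for a disjoint copy — chromosomes must be comfortably
larger than the regions being shuffled.

## Gene sets

A gene is PGC-specific at a timepoint iff fold-change ≥ 30 (inclusive)
and FDR < 0.01 (exclusive).  The stable set is
the intersection across all five dpf timepoints, and exclusive
intersection counts partition the union of the per-timepoint sets
(asserted property).  Expression profiles are row z-scaled (mean 0,
sample SD 1; constant rows are flagged and dropped) before
Pearson/ward.D clustering; cluster labels are deterministic (by
decreasing size, then first gene id) so reruns are reproducible.  The
DE statistics themselves are inputs — upstream model fitting is out of
scope by design.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults define the study conditions: 3 chromosomes of
10 Mb; 6 planted loci of 300–600 kb induced bidirectionally in PGC
libraries at 6 and 10 dpf only; 300 genes in four temporal archetypes
(maternal decay, 6 dpf peak, late rise, 2–3 dpf peak) expressed
identically in both tissues; TE classes at 5 % (LTR), 5 % (non-LTR
retro) and 10 % (DNA) base density with retro classes 3× denser inside
planted loci; alternating 500 kb A/B blocks with planted loci forced
into B with probability 0.8; small RNA libraries of 30,000 reads drawn
inside TE copies with Normal(27, 1.5) lengths clipped to 18–40 nt, an
antisense fraction of 0.9 (0 hpf–3 dpf) decaying to 0.6 (6–10 dpf), a
ping-pong partner fraction of 0.02 early rising to 0.3 at ≥ 6 dpf, a
1U bias of 0.8 on antisense reads and a 10A bias of 0.7 on sense
partners.

Two generator-level choices are worth recording:

* **Background transcription rate** defaults to 1e-5 reads per base
  per replicate.  At desk-scale depth, RPM normalization makes any
  covered base exceed the 0.25 cutoff, so background reads chained at
  the 3 kb join gap directly set how much of the genome ends up inside
  spurious expression clusters.  At 1e-5 those clusters cover well
  under 1 % of the genome and are removed by the size filter; at
  ~10× higher rates they chain into chromosome-scale clusters in
  *both* tissues and the specificity filter (correctly) rejects
  everything, including real loci.  This mirrors a real property of
  the method — it requires background transcription to be sparse
  relative to the join gap — rather than a tuning convenience.
* **Genome scale.** The genome is scaled (30 Mb total) but all caller
  thresholds are kept at their published values (0.25 / 3000 bp /
  250 kb), so the caller is exercised at its real operating point.

The generator does *not* model splicing, sequencing error, quality
scores, GC bias, mappability, multimapping ambiguity or a downstream-U
processing bias.  Passing tests therefore demonstrate algorithmic
correctness on idealized libraries, not robustness to alignment
artifacts of real data.

## A small worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_chroms = 2, chrom_length = 2e6, n_genes = 40,
                  n_perls = 2, perl_length = c(3e5, 4e5),
                  smallrna_n_reads = 4000, n_psg = 12)
sim <- simulate_dataset(cfg, seed = 11)
called <- call_perls(sim$totalrna$PGC, sim$totalrna$fish,
                     sim$art$layout)
called$perls
pingpong(do.call(c, sim$smallrna$reads[["6dpf"]]))
```

The full pipeline — simulation to result tables, consuming its own
files on disk — is `run_pipeline(out_dir, seed = 7)`; reruns with one
seed are byte-identical.

## Problem sizes used by the test suite

Unit tests run on 2 × 2 Mb genomes with 2 planted loci and 4,000-read
small RNA libraries; the acceptance-level checks use the full default
configuration (3 × 10 Mb, 6 loci, 30,000-read libraries) for locus
recovery, background matching and end-to-end determinism, and
brute-force oracles (per-base containment counting, all-pairs
ping-pong enumeration, repeated pairwise merging, pmf enumeration) on
instances small enough to enumerate exactly.

## Known limitations

* The caller assumes deduplicated, uniquely placed reads (unit
  weights); multimapper handling belongs upstream.
* Coverage tracks are dense in memory per chromosome (Rle-compressed);
  genomes far beyond a few hundred Mb per chromosome may need
  per-chromosome streaming.
* The ping-pong Z-score's null is t-like (29 background bins), so ±2
  is a ~94 % band, not 95 % — worth remembering when screening many
  libraries.
* Empirical enrichment p-values have resolution 1/`n_sets` (0.01 at
  the default 100 sets).
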