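# multiwayc

Multiway chromatin contact processing and single-allele topology analysis
in R.

Long-read proximity-ligation experiments sequence chromatin *concatemers*:
single molecules formed by ligating restriction fragments that were
spatially close in the nucleus. Each read is therefore a multiway contact —
an ordered set of genomic fragments co-located on one allele. `multiwayc`
is for computational genomicists working with such data (or building
methods for it). It covers the full path from alignments to biology:

* **Fragment processing** — PAF split alignments of one read are cleaned
  by an overlap rule (merge when the genomic projections of the overlapped
  read portion coincide within 50 bp, else drop the shorter fragment),
  combined across two alignment passes, annotated against the in-silico
  restriction digest (match ends within 30 bp), and filtered (drop only
  fragments with mapq < 10 *and* no match end).
* **Virtual pairwise contacts** — an order-*n* read yields C(n,2) pairs
  (*n*−1 adjacent, the rest non-adjacent), written in juicer "medium"
  format; binned sparse matrices with iterative-correction balancing,
  compartment eigenvectors (sign-oriented by an active-chromatin marker),
  and diamond insulation scores.
* **Spanning statistics** — how many loop anchors, TADs and A/B
  compartments the fragments of each read touch, with exact percentage
  bookkeeping, plus inter/intra-domain enrichment of the adj and non-adj
  pair subsets (observed / expected, expected = global inter fraction ×
  subset size).
* **Trans-chromosomal hubs** — negative binomial enrichment of 1-Mb trans
  bin pairs (method-of-moments fit, Bonferroni, enrichment score ≥ 2,
  adjusted p < 0.01), a diagonal-neighbour consistency rule, ≥ 20 distinct
  partners per bin, and partitioning of significant regions into two hubs
  by a Gaussian mixture on the binary link matrix with a 0.9 contact-ratio
  retention threshold.
* **Single-allele topology clustering** — binary read × bin occupancy
  matrices over a region (1 kb bins under 200 kb, else 5 kb), Ward
  clustering, per-cluster relative bin frequencies (hits / cluster reads),
  CTCF fragment and pairwise-contact frequencies, viewpoint subsampling
  (100 draws, Welch + Bonferroni), three-way co-occurrence, and
  promoter/enhancer multiway read classes (BP/SG/MG, NE/SE/ME).
* **Methylation** — per-read CpG probability thresholding (> 0.75
  methylated, < 0.25 unmethylated), per-CpG ratios and classes, paired
  loop-anchor methylation correlation against a shuffled null with the
  Fisher z comparison, CTCF loop groups, methylation-only A/B compartment
  classification, and a GC-bias regression slope.
* **A synthetic generator** — plants compartments, TADs, convergent-CTCF
  loops, trans hub bins and structured methylation, then emits noisy PAF
  alignments (split fragments, end jitter, low-mapq, gap-pass) plus a
  truth table, so every stage above is testable against known ground
  truth.

## Worked example

```r
library(multiwayc)

cfg    <- sim_config(n_reads = 2000)          # 3 chromosomes, 45 Mb total
genome <- build_genome(cfg, seed = 1)
arch   <- plant_architecture(genome, cfg, seed = 1)
sim    <- simulate_reads(genome, arch, cfg, seed = 1)

mw    <- process_paf(sim$paf, sim$gap_paf, genome)
pairs <- decompose_pairwise(mw)
```

This prints (numbers from the run above):

```
reads: 2000   fragments: 6410
pairs: 9712   adj: 4410   trans: 2206
```

2000 simulated concatemers carry 6410 cleaned fragments (split alignments
merged back, gap-pass fragments re-inserted, every fragment end matching a
restriction boundary). Decomposition yields 9712 virtual pairs — exactly
Σ C(nᵢ,2) over the per-read orders — of which 4410 are read-order
neighbours (Σ (nᵢ−1)) and 2206 connect different chromosomes, matching the
configured 38% trans-read rate.

Percentage bookkeeping is exact arithmetic on counts. For example, a
loop-anchor span tally of 9586 / 501 / 26 one-, two- and three-anchor
reads among 10,113 anchored reads prints as:

```r
span_percentages(c(9586, 501, 26), 10113)
#> [1] 94.79  4.95  0.26
```

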