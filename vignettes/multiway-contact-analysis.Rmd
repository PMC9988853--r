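---
title: "Multiway chromatin contact analysis with multiwayc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiway chromatin contact analysis with multiwayc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiwayc)
library(data.table)
set.seed(1)
```

## The problem

Long-read proximity-ligation (Pore-C-style) experiments sequence chromatin
concatemers: single DNA molecules formed by ligating several restriction
fragments that were crosslink-proximal in the nucleus. Each sequenced read
therefore reports a *multiway* contact — a set of genomic loci co-located on
one allele — rather than the pairwise contacts of Hi-C. `multiwayc`
implements the computational side of such an assay: it turns per-read
split alignments into clean multiway contact records, decomposes them into
virtual pairwise contacts for comparison with Hi-C-style analyses, and
provides the downstream statistics that exploit the multiway structure:
structural-unit spanning, trans-chromosomal hub detection, single-allele
topology clustering, regulatory multiway models, and per-read CpG
methylation coupled to chromatin structure.

Because the package is meant to be testable without sequencing data, it
ships a first-class synthetic generator that plants a known architecture
(compartments, TADs, loops, trans hubs, methylation structure) and emits
noisy PAF alignments plus a truth set, so every downstream stage can be
checked against planted ground truth.

## Fragment processing

Alignment of a concatemer read yields several fragments with gaps and
overlaps on the read. The cleaning rules are:

* **Overlap resolution.** Two fragments that overlap on *read* coordinates
  are merged into their union (on both axes, mapq = max) when they sit on
  the same chromosome and strand and the genomic projections of the
  overlapped read portion agree within 50 bp at both ends; otherwise the
  fragment with the shorter read span is discarded. The rule is applied to
  a fixed point and is idempotent. The overlap axis is a genuine design
  choice: we judge overlap on read coordinates because concatemer fragments
  tile the read, while genomic coincidence decides merge-vs-drop. Both
  tolerances are arguments.
* **Two alignment passes.** Unaligned read gaps can be realigned with a
  more permissive setting; gap-pass fragments are accepted only where they
  do not overlap a primary fragment's read interval by more than the same
  50 bp tolerance, so conflicts resolve in favour of the primary pass.
* **Restriction annotation.** A fragment end matching an in-silico
  digestion boundary (cut site or chromosome end) within 30 bp is a "match
  end"; both ends matched means fully digested.
* **Filtering.** A fragment is dropped only when its mapq is below 10 *and*
  it has no match end; digestion evidence rescues low-mapq fragments.

Ties in the drop rule (equal read spans) keep the higher-mapq, then the
earlier fragment, so the pipeline is deterministic. No duplicate-read
removal is performed: the library type this models is unamplified, so two
reads are never PCR copies of one molecule.

```{r fragproc}
cfg <- sim_config(chromosomes = data.frame(name = c("chr1", "chr2"),
                                           length = c(6e6, 4e6)),
                  n_reads = 300)
genome <- build_genome(cfg, seed = 1)
arch <- plant_architecture(genome, cfg, seed = 2)
sim <- simulate_reads(genome, arch, cfg, seed = 3)
mw <- process_paf(sim$paf, sim$gap_paf, genome)
mw[1:3, .(read_id, frag_index, n, chrom, start, end, strand, frag_class)]
```

## Virtual pairwise contacts

A read with $n$ fragments yields $\binom{n}{2}$ virtual pairs, $n-1$ of
them between read-order neighbours (*adj* pairs) and the rest *non-adj*.
Pair position is the fragment midpoint throughout (binning and distances);
this midpoint convention is the same one the read-bin occupancy matrix
uses, adopted globally for consistency. Pairs can be written in the juicer
"medium" text format (strand 0/16, 1-based positions, restriction-fragment
indices) for interoperability.

Contact matrices are binned sparse symmetric count matrices with
iterative-correction balancing (multiplicative per-bin weights equalising
row sums; zero-coverage bins masked). Two simplified track reimplementations
operate on the balanced matrix:

* **Compartment eigenvector** (default 100 kb): per chromosome, the
  observed/expected matrix uses a per-stratum expected over log-spaced
  distance bins; the leading eigenvector of its correlation matrix is
  oriented so bins richer in an active-chromatin marker track are positive
  (compartment A). Chromosomes with fewer than 10 usable bins are skipped;
  constant matrices are flagged degenerate rather than labeled.
* **Insulation score** (default 50 kb, windows 2/5/10 bins): the mean
  balanced signal in the diamond window crossing each bin, log2-normalised
  to the chromosome mean; edge bins are masked. Planted boundaries appear
  as local minima (possibly two-bin plateaus, since a boundary between
  bins $b$ and $b+1$ depresses both).

These are deliberately simple reimplementations of standard tracks — they
reproduce planted structure in the tests and are not tuned to reproduce any
particular external tool bin-for-bin.

## Spanning statistics and adj/non-adj enrichment

Per-read spanning classifiers count distinct loop anchors, distinct TADs
(within a region, with an "outside fragment" class taking precedence), and
A/B compartment patterns (single/multi A, single/multi B, and mixed
patterns, with abutting one-A-one-B intervals distinguished from separated
ones). All tallies are reported with percentages rounded to two decimals
through one shared bookkeeping helper, so printed percentages are exact
arithmetic on integer counts.

The adj/non-adj enrichment score for inter-domain contacts is
`observed / (global inter fraction x subset size)`; a subset distributed
like the pool scores 1 by construction.

## Trans-chromosomal enrichment and hubs

Trans contacts are binned at 1 Mb. Under the null that trans contacts
scatter randomly, a negative binomial is fitted by method of moments to the
pooled per-pair counts — by default over **all** possible trans bin pairs,
zeros included, because the null universe is every pair, not just observed
ones; a Poisson fallback handles variance at or below the mean. The
enrichment score is observed/fitted-mean (a marginal-product expected model
is available as an option, since the published method does not specify
marginal adjustment; global is the default). Significance requires
enrichment score >= 2 and Bonferroni-adjusted p < 0.01, then a
diagonal-neighbour rule: pair $(i,j)$ is kept only when $(i-1,j-1)$ and
$(i+1,j+1)$ are also significant ("consecutive bins" read literally as the
diagonal neighbours; chromosome-edge pairs fail by definition), and a bin
is reported only with >= 20 distinct partners. On null multinomial
scatter this pipeline's family-wise error stays within the Bonferroni
budget, and a planted enriched block is recovered with <1% false bins —
note that the global moment fit deliberately absorbs planted dispersion, so
very large planted fractions would shrink power; that behaviour is inherent
to a pooled null.

Hub partitioning clusters the rows of the binary significant-link adjacency
matrix into two sets with a Gaussian mixture model (spherical components,
mclust's deterministic hierarchical initialisation; k-means with 10
restarts as a fallback), then retains regions whose contact ratio — the
fraction of their significant links staying inside their set — is at least
0.9. Labels are stable under region permutation up to the usual label swap.

## Single-allele topology clustering

Reads with at least `min_fragments` fragment midpoints in a region of
interest become rows of a binary occupancy matrix P (1 kb bins below 200 kb
region size, else 5 kb). Ward linkage on euclidean row distances groups
reads into topology clusters. The published procedure cut the dendrogram by
eye; the deterministic surrogate here picks the k in 2..6 with the largest
gap between successive merge heights, and k is always overridable.
`min_fragments` defaults to 3 (the locus-level analyses used three or more
fragments; 5 matches the stricter "more than four" variant).

Per-cluster bin tracks divide bin hit counts by cluster read count — exact
rationals. Viewpoint analysis subsamples each cluster 100 times (fraction
0.5 without replacement; the subsample size is unstated in the source
procedure, so it is an explicit, seed-controlled parameter), computes
per-bin viewpoint co-occurrence frequencies normalised by subsample size,
and compares clusters per bin with a two-sided Welch test under Bonferroni
correction at adjusted p < 0.01. Because the 100 draws resample the same
finite read sets, the test detects any real difference between the cluster
read sets, not generative differences; the tests therefore validate it on
literally identical versus planted-different occupancy rows.

The regulatory models classify reads by element-bin content (2 kb bins;
promoter-priority for the promoter model, enhancer-priority for the
enhancer model): BP/SG/MG and NE/SE/ME as mutually exclusive classes;
reads with several promoter fragments and no enhancer have no class in the
enhancer model and are logged as unclassified. Interaction-frequency strata
use the 25th/75th percentiles with the boundary values assigned upward
(a value at the 25th percentile is Q2, at the 75th Q3).

## Methylation

Per-read CpG probabilities (unit or 0-255 scale) are thresholded:
methylated above 0.75 (191/255), unmethylated below 0.25 — the published
threshold defines only the methylated side, so the unmethylated cut is its
symmetric counterpart and configurable; intermediate calls are ambiguous
and excluded downstream. Per-CpG summaries report ratio and class (high
>= 0.6, low <= 0.4) for sites with >= 5 informative calls.

For loops, reads carrying fragments in both anchors with >= 3 CpGs per
side contribute one (anchor-a level, anchor-b level) observation; the
Pearson correlation across observations is compared to a shuffled null
(second anchor permuted across reads) with the Fisher z statistic
$z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2)/
\sqrt{1/(n_1-3) + 1/(n_2-3)}$. Anchor levels default to mean probability
rather than binarised calls: with the few CpGs a restriction fragment
carries, binarisation attenuates correlations strongly, while probability
means recover the generator's planted coupling within +/-0.05.

Methylation-based compartment classification summarises each compartment
interval by 100-kb bin means of CpG ratios and labels an interval A when
its mean exceeds both neighbours with a significant two-sided Welch test at
alpha = 0.05 (B when below both); the test choice is a documented default
since the source names none. Chromosome-end intervals use their single
neighbour; intervals with fewer than two covered bins stay unlabeled. The
GC-bias diagnostic is the OLS slope of GC% on log10 bin count.

## The synthetic generator

`sim_config()` fixes the study conditions; the defaults are chosen once:

* three chromosomes (20/15/10 Mb) — large enough for megabase structure,
  small enough that the full suite runs in minutes on one CPU;
* exponential restriction spacings with mean 256 bp (the expected spacing
  of a 4-cutter motif); sequence mode scans GATC when sequence is given;
* 400 kb compartments, 200 kb TADs and 10 kb loop anchors, close to the
  published median unit sizes (400 kb compartments, 185 kb TADs);
* order distribution geometrically decaying over 2..12 (most reads order
  2-4) and a 38% trans-read fraction, matching the reported share of reads
  with fragments from nonhomologous chromosomes;
* noise defaults: split-alignment rate 0.10 with <= 50 bp overlaps (to
  exercise the merge rule), end jitter sd 5 bp, low-mapq fraction 0.05,
  gap-pass fraction 0.10;
* methylation: site-level two-component emission (states drawn with
  compartment-specific weight, A 0.8 / B 0.6, probabilities near 0.9/0.1),
  and continuous CpG-island-like levels inside loop anchors with a
  read-level shared component giving the planted anchor correlation 0.5.

Cluster templates make topology recovery well-defined: each TAD is cut into
2K slices and cluster z owns two interleaved slices, so reads of different
clusters occupy disjoint bin sets at high fidelity. A read's cluster label
is drawn *before* fragment sampling. The optional `focus_region` emulates
extracting the reads of one region from a deep dataset by seeding a
configurable fraction of reads there — the desk-scale equivalent of the
region extraction a real analysis performs.

What the generator does **not** emulate: base-level sequencing error,
signal-level nanopore artefacts, mappability and GC-coverage bias, PCR
duplicates (the modelled library is unamplified), genuine polymer-physics
distance decay (the kernel is a configurable power law), or site-level
methylation heterogeneity inside loop anchors. Passing tests therefore
demonstrate algorithmic correctness against planted structure, not
biological fidelity of any particular dataset.

## Numerical choices and limitations

* Coordinates are 0-based half-open everywhere internally; writers convert
  (juicer medium positions are 1-based, BED stays 0-based).
* Balancing converges when the row-sum coefficient of variation drops
  below `tol` (default 1e-5); non-convergence warns and returns the last
  iterate.
* The O/E expected uses log-spaced distance strata (quarter-powers of 2),
  not per-diagonal means; with few bins per stratum the eigenvector is
  noisier on short chromosomes, hence the 10-bin minimum.
* Ward clustering is deterministic; the automatic k is a surrogate for a
  visual dendrogram cut and will pick 2 when clusters overlap heavily.
* The NB fit is global; with a large planted (or real) enriched fraction
  the moment estimate of dispersion grows and power drops — use the
  marginal expected model to probe sensitivity.
* Problem sizes in the test-suite simulations (hundreds to a few thousand
  reads, 100-500 bins, 200 null replicates) were chosen so the whole suite
  runs in a few minutes on a single CPU while keeping each planted effect
  several standard errors away from its acceptance threshold.
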