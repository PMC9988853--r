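#' Simulation configuration for the synthetic concatemer generator
#'
#' Collects every tunable of the generator with defaults chosen to emulate a
#' DpnII-digested human-like dataset at desk scale: GATC-like restriction
#' spacing (256 bp expected), megabase-scale alternating A/B compartments
#' tiled by TADs with convergent-CTCF loops at TAD borders, a realistic
#' multiway order distribution (most reads of order 2-4, a tail up to 12),
#' roughly 38% of reads carrying at least one trans-chromosomal fragment, and
#' alignment noise (split alignments, end jitter, a low-mapq fraction).
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp).
#' @param site_spacing mean restriction-site spacing (bp) in model mode.
#' @param n_reads number of concatemer reads to simulate.
#' @param order_probs named numeric vector of fragment-order probabilities;
#'   names are orders (all >= 2). Default: orders 2..12 with geometrically
#'   decaying weight.
#' @param n_clusters number of planted single-allele topology clusters.
#' @param cluster_weights mixing weights of the topology clusters.
#' @param cluster_fidelity probability that a cis partner fragment is drawn
#'   from the read's cluster template instead of the distance-decay kernel.
#' @param cross_unit_rate probability that a template draw uses a neighbouring
#'   TAD's template rather than the seed TAD's.
#' @param decay_exponent exponent of the genomic distance-decay kernel.
#' @param trans_rate fraction of reads with at least one trans fragment.
#' @param hub_weight probability that a trans read targets a planted hub
#'   bin pair rather than a uniform trans location.
#' @param loop_pair_rate probability that a read places fragments in both
#'   anchors of one planted loop (substrate for anchor-methylation coupling).
#' @param split_rate probability that an emitted fragment is split into two
#'   overlapping same-strand alignments.
#' @param jitter_sd standard deviation (bp) of genomic end jitter.
#' @param low_mapq_rate fraction of fragments assigned mapq < 10.
#' @param gap_pass_rate fraction of fragments emitted in the gap-realignment
#'   PAF instead of the primary PAF.
#' @param comp_size,tad_size,anchor_size planted compartment / TAD / loop
#'   anchor sizes (bp).
#' @param promoter_density,enhancer_density planted elements per 100 kb of
#'   A compartment.
#' @param telomere_size,centromere_size sizes (bp) of planted telomere and
#'   centromere intervals.
#' @param n_hub_bins planted trans-enriched 1-Mb bins per hub label.
#' @param cpg_spacing CpG grid spacing (bp).
#' @param anchor_cpg_spacing denser CpG grid spacing inside loop anchors
#'   (CpG-island-like).
#' @param anchor_mean mean methylation level of loop-anchor fragments,
#'   independent of compartment.
#' @param meth_a_mean,meth_b_mean mean methylation level in A/B compartments.
#' @param meth_level_sd per-fragment latent level standard deviation.
#' @param cpg_noise_sd per-CpG probability noise standard deviation.
#' @param anchor_rho planted correlation of methylation levels between paired
#'   loop-anchor fragments of one read.
#' @param focus_region optional list(chrom, start, end); with probability
#'   `focus_weight` a read's seed fragment is drawn from this region,
#'   emulating the region extraction used for topology clustering of a deep
#'   dataset.
#' @param focus_weight probability that a read seeds in `focus_region`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(chromosomes = data.frame(
                         name = c("chr1", "chr2", "chr3"),
                         length = c(20e6, 15e6, 10e6)),
                       site_spacing = 256,
                       n_reads = 5000,
                       order_probs = NULL,
                       n_clusters = 3,
                       cluster_weights = c(0.45, 0.30, 0.25),
                       cluster_fidelity = 0.85,
                       cross_unit_rate = 0.10,
                       decay_exponent = -1,
                       trans_rate = 0.38,
                       hub_weight = 0.5,
                       loop_pair_rate = 0.05,
                       split_rate = 0.10,
                       jitter_sd = 5,
                       low_mapq_rate = 0.05,
                       gap_pass_rate = 0.10,
                       comp_size = 4e5,
                       tad_size = 2e5,
                       anchor_size = 1e4,
                       promoter_density = 1,
                       enhancer_density = 2,
                       telomere_size = 5e4,
                       centromere_size = 1e6,
                       n_hub_bins = 10,
                       cpg_spacing = 100,
                       anchor_cpg_spacing = 25,
                       anchor_mean = 0.7,
                       meth_a_mean = 0.8,
                       meth_b_mean = 0.6,
                       meth_level_sd = 0.05,
                       cpg_noise_sd = 0.02,
                       anchor_rho = 0.5,
                       focus_region = NULL,
                       focus_weight = 0.9) {
  if (is.null(order_probs)) {
    w <- 0.55^(0:10)
    order_probs <- setNames(w / sum(w), 2:12)
  }
  orders <- as.integer(names(order_probs))
  if (any(is.na(orders)) || min(orders) < 2L) {
    stop("order_probs must be named by integer orders >= 2")
  }
  probs <- c(cluster_weights, cluster_fidelity, cross_unit_rate, trans_rate,
             hub_weight, loop_pair_rate, split_rate, low_mapq_rate,
             gap_pass_rate, order_probs)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  cfg <- list(
    chromosomes = as.data.table(chromosomes),
    site_spacing = site_spacing, n_reads = n_reads,
    order_probs = order_probs / sum(order_probs),
    n_clusters = as.integer(n_clusters),
    cluster_weights = cluster_weights / sum(cluster_weights),
    cluster_fidelity = cluster_fidelity, cross_unit_rate = cross_unit_rate,
    decay_exponent = decay_exponent, trans_rate = trans_rate,
    hub_weight = hub_weight, loop_pair_rate = loop_pair_rate,
    split_rate = split_rate, jitter_sd = jitter_sd,
    low_mapq_rate = low_mapq_rate, gap_pass_rate = gap_pass_rate,
    comp_size = comp_size, tad_size = tad_size, anchor_size = anchor_size,
    promoter_density = promoter_density, enhancer_density = enhancer_density,
    telomere_size = telomere_size, centromere_size = centromere_size,
    n_hub_bins = n_hub_bins, cpg_spacing = cpg_spacing,
    anchor_cpg_spacing = anchor_cpg_spacing, anchor_mean = anchor_mean,
    meth_a_mean = meth_a_mean, meth_b_mean = meth_b_mean,
    meth_level_sd = meth_level_sd, cpg_noise_sd = cpg_noise_sd,
    anchor_rho = anchor_rho, focus_region = focus_region,
    focus_weight = focus_weight)
  structure(cfg, class = "sim_config")
}

#' Build a genome model with restriction sites
#'
#' In sequence mode the restriction sites are the 0-based start positions of
#' every GATC occurrence (DpnII cuts 5' of the motif). In model mode sites are
#' drawn with i.i.d. exponential spacings of configured mean, giving a
#' realistic density without requiring sequence.
#'
#' @param config a [sim_config()].
#' @param fasta optional named character vector of chromosome sequences; names
#'   must cover every chromosome declared in `config`.
#' @param seed RNG seed used in model mode.
#' @param motif restriction motif scanned in sequence mode (default GATC).
#' @return object of class `genome_model`: a chromosome table plus a named
#'   list of strictly increasing 0-based cut positions per chromosome.
#' @export
build_genome <- function(config, fasta = NULL, seed = 1, motif = "GATC") {
  chroms <- as.data.table(config$chromosomes)
  if (nrow(chroms) == 0L) stop("at least one chromosome must be declared")
  if (!is.null(fasta)) {
    missing <- setdiff(chroms$name, names(fasta))
    if (length(missing)) {
      stop("chromosome(s) absent from fasta: ", paste(missing, collapse = ", "))
    }
    sites <- lapply(chroms$name, function(ch) {
      s <- toupper(fasta[[ch]])
      m <- gregexpr(motif, s, fixed = TRUE)[[1]]
      if (length(m) == 1L && m[1] == -1L) integer() else as.integer(m) - 1L
    })
    chroms[, length := nchar(fasta[name])]
  } else {
    set.seed(seed)
    sites <- lapply(seq_len(nrow(chroms)), function(i) {
      len <- chroms$length[i]
      n_exp <- ceiling(len / config$site_spacing * 1.2) + 50L
      pos <- cumsum(rexp(n_exp, rate = 1 / config$site_spacing))
      while (pos[length(pos)] < len) {
        pos <- c(pos, pos[length(pos)] +
                   cumsum(rexp(n_exp, rate = 1 / config$site_spacing)))
      }
      unique(as.integer(floor(pos[pos >= 1 & pos < len])))
    })
  }
  names(sites) <- chroms$name
  structure(list(chromosomes = chroms[, list(name, length)], sites = sites),
            class = "genome_model")
}

#' Restriction fragment boundaries for one chromosome
#'
#' Fragment boundaries are the cut sites plus the chromosome ends, so every
#' base belongs to exactly one in-silico digestion fragment.
#'
#' @param genome a `genome_model`.
#' @param chrom chromosome name.
#' @return data.table with 0-based half-open `start`, `end` per fragment.
#' @export
restriction_fragments <- function(genome, chrom) {
  len <- genome$chromosomes[name == chrom, length]
  if (!length(len)) stop("unknown chromosome: ", chrom)
  b <- unique(c(0L, genome$sites[[chrom]], as.integer(len)))
  data.table(start = head(b, -1L), end = tail(b, -1L))
}

#' Restriction fragment index of genomic positions
#'
#' @param genome a `genome_model`.
#' @param chrom chromosome name (scalar).
#' @param pos 0-based positions.
#' @return integer fragment indices (1-based along the chromosome).
#' @export
fragment_index <- function(genome, chrom, pos) {
  sites <- genome$sites[[chrom]]
  if (is.null(sites)) stop("unknown chromosome: ", chrom)
  findInterval(pos, sites) + 1L
}

#' Plant a 3D architecture on a genome model
#'
#' Lays down alternating A/B compartments tiling each chromosome, TADs tiling
#' each compartment, a loop between convergent CTCF sites at each TAD's
#' borders ('+' motif at the left anchor, '-' at the right), promoters and
#' enhancers inside A compartments, telomeres at chromosome ends, one
#' centromere per chromosome, and two disjoint sets of trans-enriched 1-Mb
#' hub bins (active hubs in A compartments, inactive in B).
#'
#' @param genome a `genome_model`.
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return object of class `architecture_model` (a list of interval tables).
#' @export
plant_architecture <- function(genome, config, seed = 1) {
  set.seed(seed)
  chroms <- genome$chromosomes
  if (any(chroms$length < 2 * config$comp_size)) {
    stop("chromosome too short for requested compartment size")
  }
  if (config$tad_size > config$comp_size ||
      config$anchor_size * 2 > config$tad_size) {
    stop("structure sizes are inconsistent (need anchor*2 <= tad <= compartment)")
  }
  comp <- rbindlist(lapply(seq_len(nrow(chroms)), function(i) {
    len <- chroms$length[i]
    b <- unique(c(seq(0, len, by = config$comp_size), len))
    k <- length(b) - 1L
    data.table(chrom = chroms$name[i], start = as.integer(head(b, -1L)),
               end = as.integer(tail(b, -1L)),
               label = rep(c("A", "B"), length.out = k))
  }))
  comp[, comp_id := seq_len(.N)]
  tads <- comp[, {
    w <- end - start
    nt <- pmax(1L, floor(w / config$tad_size))
    b <- as.integer(round(seq(start, end, length.out = nt + 1L)))
    list(start = head(b, -1L), end = tail(b, -1L))
  }, by = list(chrom, comp_id)][, list(chrom, start, end, comp_id)]
  tads[, tad_id := seq_len(.N)]
  a <- config$anchor_size
  loops <- tads[, list(chrom, a_start = start, a_end = start + as.integer(a),
                       b_start = end - as.integer(a), b_end = end,
                       tad_id = tad_id)]
  loops[, loop_id := seq_len(.N)]
  ctcf <- rbind(
    loops[, list(chrom, pos = (a_start + a_end) %/% 2L, strand = "+",
                 loop_id = loop_id, side = "a")],
    loops[, list(chrom, pos = (b_start + b_end) %/% 2L, strand = "-",
                 loop_id = loop_id, side = "b")])
  setorder(ctcf, chrom, pos)
  acomp <- comp[label == "A"]
  place <- function(density, width = 2000L) {
    acomp[, {
      n <- max(0L, round(density * (end - start) / 1e5))
      if (n == 0L) list(start = integer(), end = integer()) else {
        s <- as.integer(sort(sample.int(end - start - width, n)) + start)
        list(start = s, end = s + width)
      }
    }, by = list(chrom, comp_id)][, list(chrom, start, end)]
  }
  promoters <- place(config$promoter_density)
  enhancers <- place(config$enhancer_density)
  telo <- chroms[, {
    t <- as.integer(config$telomere_size)
    list(start = c(0L, as.integer(length) - t),
         end = c(t, as.integer(length)))
  }, by = name][, list(chrom = name, start, end)]
  cent <- chroms[, {
    mid <- floor(length / 2 / 1e6) * 1e6
    list(start = as.integer(mid),
         end = as.integer(mid + config$centromere_size))
  }, by = name][, list(chrom = name, start, end)]
  bins1mb <- chroms[, {
    nb <- ceiling(length / 1e6)
    list(start = as.integer((seq_len(nb) - 1L) * 1e6),
         end = as.integer(pmin(seq_len(nb) * 1e6, length)))
  }, by = name][, list(chrom = name, start, end)]
  bins1mb[, bin_id := seq_len(.N)]
  mid_lab <- comp$label[.pos_interval_idx(bins1mb$chrom, .mid(bins1mb$start, bins1mb$end), comp)]
  avoid <- unique(c(
    .overlap_pairs(bins1mb, telo)$q_idx, .overlap_pairs(bins1mb, cent)$q_idx))
  cand_a <- setdiff(which(mid_lab == "A"), avoid)
  cand_b <- setdiff(which(mid_lab == "B"), avoid)
  n_hub <- min(config$n_hub_bins, length(cand_a), length(cand_b))
  hub <- rbind(
    bins1mb[sort(sample(cand_a, n_hub))][, label := "active"],
    bins1mb[sort(sample(cand_b, n_hub))][, label := "inactive"])
  structure(list(compartments = comp, tads = tads, loops = loops,
                 ctcf_sites = ctcf, promoters = promoters,
                 enhancers = enhancers, telomeres = telo, centromeres = cent,
                 hub_bins = hub, bins_1mb = bins1mb),
            class = "architecture_model")
}
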