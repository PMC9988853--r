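# Concatemer read simulation.
#
# Each read draws a topology-cluster label first, then samples whole
# restriction fragments: a uniform seed fragment and partners from a
# distance-decay kernel mixed with cluster-template draws, so clustering
# recovery is well-defined. Trans reads oversample planted hub bin pairs.
# Noise (split alignments, end jitter, low mapq, gap-pass withholding) is
# applied only at PAF emission; the truth tables keep the clean fragments.

# inverse-CDF sampler for P(d) ~ (d)^gamma on [dmin, dmax]
.sample_decay <- function(n, dmin, dmax, gamma = -1) {
  u <- runif(n)
  if (abs(gamma + 1) < 1e-9) {
    dmin * (dmax / dmin)^u
  } else {
    g1 <- gamma + 1
    (dmin^g1 + u * (dmax^g1 - dmin^g1))^(1 / g1)
  }
}

#' Simulate concatemer reads with a planted truth set
#'
#' @param genome a `genome_model`.
#' @param arch an `architecture_model` from [plant_architecture()].
#' @param config a [sim_config()].
#' @param seed RNG seed; the whole output is reproducible bit-for-bit.
#' @return a list with `truth_reads` (read_id, n, cluster, has_trans),
#'   `truth_fragments` (clean per-fragment records in read order with unit
#'   memberships), `paf` and `gap_paf` (noisy PAF records as data.tables),
#'   and `hub_pairs` (planted trans-enriched 1-Mb bin pairs).
#' @export
simulate_reads <- function(genome, arch, config, seed = 1) {
  set.seed(seed)
  chroms <- genome$chromosomes
  K <- config$n_clusters
  # per-chromosome fragment tables with unit memberships
  finfo <- lapply(chroms$name, function(ch) {
    fr <- restriction_fragments(genome, ch)
    fr[, mid := .mid(start, end)]
    fr[, chrom := ch]
    tad_i <- .pos_interval_idx(fr$chrom, fr$mid, arch$tads)
    fr[, tad_id := arch$tads$tad_id[tad_i]]
    comp_i <- .pos_interval_idx(fr$chrom, fr$mid, arch$compartments)
    fr[, comp_id := arch$compartments$comp_id[comp_i]]
    fr[, comp_label := arch$compartments$label[comp_i]]
    # cluster template: each TAD is cut into 2K slices; cluster z owns the
    # slices with index z-1 (mod K), i.e. two disjoint chunks per TAD
    ts <- arch$tads$start[tad_i]
    te <- arch$tads$end[tad_i]
    sw <- (te - ts) / (2 * K)
    slice <- pmin(floor((fr$mid - ts) / sw), 2 * K - 1)
    fr[, template := as.integer(slice %% K) + 1L]
    fr[is.na(tad_id), template := NA_integer_]
    fr
  })
  names(finfo) <- chroms$name
  chrom_w <- chroms$length / sum(chroms$length)
  orders <- as.integer(names(config$order_probs))
  hub <- arch$hub_bins
  loops <- arch$loops
  # pre-draw read-level variables
  nr <- config$n_reads
  n_frag <- orders[sample.int(length(orders), nr, replace = TRUE,
                              prob = config$order_probs)]
  z <- sample.int(K, nr, replace = TRUE, prob = config$cluster_weights)
  is_trans <- runif(nr) < config$trans_rate
  is_hub <- is_trans & runif(nr) < config$hub_weight
  is_looppair <- runif(nr) < config$loop_pair_rate

  # uniform fragment in [chrom, lo, hi); returns row of finfo[[chrom]]
  pick_in <- function(ch, lo, hi) {
    fr <- finfo[[ch]]
    i1 <- findInterval(lo, fr$mid) + 1L
    i2 <- findInterval(hi - 1L, fr$mid)
    if (i2 < i1) return(NA_integer_)
    if (i1 == i2) i1 else sample(i1:i2, 1L)
  }

  out <- vector("list", nr)
  for (r in seq_len(nr)) {
    n <- n_frag[r]
    n_trans <- 0L
    trans_rows <- NULL
    seed_ch <- sample(chroms$name, 1L, prob = chrom_w)
    if (is_trans[r]) {
      n_trans <- min(n - 1L, 1L + rpois(1L, 0.5))
      if (is_hub[r] && nrow(hub) >= 2L) {
        lab <- sample(unique(hub$label), 1L)
        hb <- hub[label == lab]
        cross <- which(outer(hb$chrom, hb$chrom, "!="), arr.ind = TRUE)
        cross <- cross[cross[, 1] < cross[, 2], , drop = FALSE]
        if (nrow(cross) > 0L && n >= 2L) {
          pick <- cross[sample.int(nrow(cross), 1L), ]
          n_trans <- max(n_trans, 2L)
          n_trans <- min(n_trans, n)
          b1 <- hb[pick[1]]; b2 <- hb[pick[2]]
          trans_rows <- list(
            c(b1$chrom, pick_in(b1$chrom, b1$start, b1$end)),
            c(b2$chrom, pick_in(b2$chrom, b2$start, b2$end)))
          seed_ch <- sample(setdiff(chroms$name, c(b1$chrom, b2$chrom)), 1L)
        }
      }
      extra <- n_trans - length(trans_rows %||% list())
      if (extra > 0L) {
        for (k in seq_len(extra)) {
          ch <- sample(setdiff(chroms$name, seed_ch), 1L)
          trans_rows <- c(trans_rows,
                          list(c(ch, sample.int(nrow(finfo[[ch]]), 1L))))
        }
      }
      n_trans <- length(trans_rows)
    }
    n_cis <- n - n_trans
    cis_idx <- integer()
    if (n_cis > 0L) {
      focus <- config$focus_region
      if (!is.null(focus) && runif(1) < config$focus_weight) {
        seed_ch <- focus$chrom
        fr <- finfo[[seed_ch]]
        s <- pick_in(seed_ch, focus$start, focus$end)
        if (is.na(s)) s <- sample.int(nrow(fr), 1L)
      } else {
        fr <- finfo[[seed_ch]]
        s <- sample.int(nrow(fr), 1L)
      }
      cis_idx <- s
      if (n_cis > 1L) {
        seed_tad <- fr$tad_id[s]
        for (k in seq_len(n_cis - 1L)) {
          use_template <- !is.na(seed_tad) && runif(1) < config$cluster_fidelity
          idx <- NA_integer_
          if (use_template) {
            tgt_tad <- seed_tad
            if (runif(1) < config$cross_unit_rate) {
              nb <- arch$tads[chrom == seed_ch &
                              abs(tad_id - seed_tad) == 1L, tad_id]
              if (length(nb)) tgt_tad <- nb[sample.int(length(nb), 1L)]
            }
            pool <- which(fr$tad_id == tgt_tad & fr$template == z[r])
            if (length(pool)) idx <- pool[sample.int(length(pool), 1L)]
          }
          if (is.na(idx)) {
            d <- .sample_decay(1L, 1000, chroms[name == seed_ch, length],
                               config$decay_exponent)
            pos <- fr$mid[s] + round(d) * sample(c(-1L, 1L), 1L)
            pos <- min(max(pos, 0), chroms[name == seed_ch, length] - 1L)
            idx <- findInterval(pos, fr$mid)
            idx <- min(max(idx, 1L), nrow(fr))
          }
          cis_idx <- c(cis_idx, idx)
        }
      }
      # loop-pair event: relocate two cis fragments onto the anchors of a
      # loop on the seed chromosome
      loop_id_r <- NA_integer_
      if (is_looppair[r] && n_cis >= 2L) {
        lps <- loops[chrom == seed_ch]
        if (nrow(lps)) {
          lp <- lps[sample.int(nrow(lps), 1L)]
          ia <- pick_in(seed_ch, lp$a_start, lp$a_end)
          ib <- pick_in(seed_ch, lp$b_start, lp$b_end)
          if (!is.na(ia) && !is.na(ib)) {
            cis_idx[1:2] <- c(ia, ib)
            loop_id_r <- lp$loop_id
          }
        }
      }
    } else loop_id_r <- NA_integer_
    frs <- rbindlist(c(
      if (length(cis_idx)) list(finfo[[seed_ch]][cis_idx,
        list(chrom, start, end, tad_id, comp_id, comp_label)]),
      lapply(trans_rows, function(tr) {
        finfo[[tr[1]]][as.integer(tr[2]),
          list(chrom, start, end, tad_id, comp_id, comp_label)]
      })))
    frs[, loop_anchor := NA_character_]
    frs[, loop_id := NA_integer_]
    if (!is.na(loop_id_r)) {
      frs$loop_anchor[1:2] <- c("a", "b")
      frs$loop_id[1:2] <- loop_id_r
    }
    frs <- frs[sample.int(nrow(frs))]   # read order is a random permutation
    frs[, strand := sample(c("+", "-"), .N, replace = TRUE)]
    len <- frs$end - frs$start
    frs[, read_end := cumsum(len)]
    frs[, read_start := read_end - len]
    frs[, read_id := sprintf("read%06d", r)]
    frs[, frag_index := seq_len(.N)]
    out[[r]] <- frs
  }
  truth_fragments <- rbindlist(out)
  setcolorder(truth_fragments,
              c("read_id", "frag_index", "chrom", "start", "end", "strand",
                "read_start", "read_end"))
  truth_reads <- truth_fragments[, list(
    n = .N, has_trans = length(unique(chrom)) > 1L), by = read_id]
  truth_reads[, cluster := z[as.integer(sub("read", "", read_id))]]
  # planted trans-enriched bin pairs: all cross-chromosome pairs inside a
  # hub label set
  hp <- list()
  for (lab in unique(hub$label)) {
    hb <- hub[label == lab]
    if (nrow(hb) >= 2L) {
      cb <- utils::combn(seq_len(nrow(hb)), 2L)
      keep <- hb$chrom[cb[1, ]] != hb$chrom[cb[2, ]]
      hp[[lab]] <- data.table(
        bin_i = pmin(hb$bin_id[cb[1, keep]], hb$bin_id[cb[2, keep]]),
        bin_j = pmax(hb$bin_id[cb[1, keep]], hb$bin_id[cb[2, keep]]),
        label = lab)
    }
  }
  hub_pairs <- rbindlist(hp)
  emitted <- .emit_paf(truth_fragments, genome, config)
  list(truth_reads = truth_reads, truth_fragments = truth_fragments,
       paf = emitted$paf, gap_paf = emitted$gap_paf, hub_pairs = hub_pairs,
       config = config)
}

# apply alignment noise and produce PAF tables (12 mandatory columns,
# 0-based half-open, mapq in column 12)
.emit_paf <- function(truth_fragments, genome, config) {
  fr <- copy(truth_fragments)
  lens <- setNames(as.numeric(genome$chromosomes$length),
                   genome$chromosomes$name)
  fr[, tlen := lens[chrom]]
  fr[, mapq := ifelse(runif(.N) < config$low_mapq_rate,
                      sample(0:9, .N, replace = TRUE), 60L)]
  fr[, pass := ifelse(runif(.N) < config$gap_pass_rate, "gap", "primary")]
  qlen <- fr[, list(qlen = max(read_end)), by = read_id]
  fr <- merge(fr, qlen, by = "read_id", sort = FALSE)
  rows <- vector("list", nrow(fr))
  do_split <- runif(nrow(fr)) < config$split_rate & fr$pass == "primary" &
    (fr$end - fr$start) >= 60L
  for (i in seq_len(nrow(fr))) {
    f <- fr[i]
    if (do_split[i]) {
      L <- f$end - f$start
      cpt <- floor(L * runif(1, 0.3, 0.7))
      ov <- sample(5:45, 1L)
      ov <- min(ov, L - cpt - 1L)
      if (f$strand == "+") {
        g1 <- c(f$start, f$start + cpt + ov); g2 <- c(f$start + cpt, f$end)
      } else {
        g1 <- c(f$end - cpt - ov, f$end); g2 <- c(f$start, f$end - cpt)
      }
      rows[[i]] <- data.table(
        read_id = f$read_id, qlen = f$qlen,
        read_start = c(f$read_start, f$read_start + cpt),
        read_end = c(f$read_start + cpt + ov, f$read_end),
        strand = f$strand, chrom = f$chrom, tlen = f$tlen,
        start = c(g1[1], g2[1]), end = c(g1[2], g2[2]),
        mapq = f$mapq, pass = f$pass)
    } else {
      rows[[i]] <- data.table(
        read_id = f$read_id, qlen = f$qlen, read_start = f$read_start,
        read_end = f$read_end, strand = f$strand, chrom = f$chrom,
        tlen = f$tlen, start = f$start, end = f$end, mapq = f$mapq,
        pass = f$pass)
    }
  }
  paf <- rbindlist(rows)
  if (config$jitter_sd > 0) {
    paf[, start := pmax(0L, start + as.integer(round(rnorm(.N, 0, config$jitter_sd))))]
    paf[, end := pmin(as.integer(tlen),
                      end + as.integer(round(rnorm(.N, 0, config$jitter_sd))))]
    paf[end <= start, end := start + 1L]
  }
  for (cc in c("read_start", "read_end", "start", "end", "qlen", "tlen")) {
    paf[, (cc) := as.integer(get(cc))]
  }
  paf[, alen := pmin(read_end - read_start, end - start)]
  paf[, nmatch := as.integer(round(alen * 0.95))]
  cols <- c("read_id", "qlen", "read_start", "read_end", "strand", "chrom",
            "tlen", "start", "end", "nmatch", "alen", "mapq")
  list(paf = paf[pass == "primary", cols, with = FALSE],
       gap_paf = paf[pass == "gap", cols, with = FALSE])
}

#' Write PAF records to a file
#'
#' @param paf data.table as produced by [simulate_reads()] (12 mandatory PAF
#'   columns, 0-based half-open coordinates).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_paf <- function(paf, path) {
  fwrite(paf, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Simulate per-read CpG methylation probabilities
#'
#' CpGs lie on a fixed genomic grid. Emission follows a two-component model:
#' each CpG site carries a persistent methylated/unmethylated state drawn
#' with a compartment-specific weight (the A/B mean methylation level), and
#' emitted probabilities concentrate near 0.9 / 0.1 accordingly, so per-site
#' call ratios across reads reproduce the compartment means. Fragments lying
#' in loop anchors are treated as homogeneous CpG-island-like regions: their
#' CpGs emit the fragment's continuous latent level instead, and the two
#' anchor fragments of a read's loop pair share a read-level latent component
#' so their mean levels correlate at the planted `anchor_rho`.
#'
#' @param genome a `genome_model`.
#' @param arch an `architecture_model`.
#' @param sim result of [simulate_reads()].
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return data.table (read_id, chrom, pos, probability, true_level).
#' @export
simulate_methylation <- function(genome, arch, sim, config, seed = 1) {
  set.seed(seed)
  fr <- copy(sim$truth_fragments)
  comp_i <- .pos_interval_idx(fr$chrom, .mid(fr$start, fr$end),
                              arch$compartments)
  lab <- arch$compartments$label[comp_i]
  m <- ifelse(is.na(lab), (config$meth_a_mean + config$meth_b_mean) / 2,
              ifelse(lab == "A", config$meth_a_mean, config$meth_b_mean))
  reads <- unique(fr$read_id)
  u <- setNames(rnorm(length(reads)), reads)
  rho <- config$anchor_rho
  e <- rnorm(nrow(fr))
  shared <- !is.na(fr$loop_anchor)
  zlat <- ifelse(shared, sqrt(rho) * u[fr$read_id] + sqrt(1 - rho) * e, e)
  mu <- ifelse(shared, config$anchor_mean, m)
  t_lvl <- pmin(pmax(mu + config$meth_level_sd * zlat, 0.01), 0.99)
  fr[, true_level := t_lvl]
  fr[, anchor_frag := shared]
  fr[, row_id := .I]
  cpg <- fr[, {
    sp <- if (anchor_frag) config$anchor_cpg_spacing else config$cpg_spacing
    p0 <- ceiling(start / sp) * sp
    pos <- if (p0 >= end) integer() else seq.int(p0, end - 1L, by = sp)
    k <- length(pos)
    list(chrom = rep(chrom, k), pos = as.integer(pos),
         true_level = rep(true_level, k),
         anchor_frag = rep(anchor_frag, k))
  }, by = list(read_id, row_id)]
  # persistent two-component site states, shared across reads covering a
  # site; the mixture weight is the site's compartment mean level
  sites <- unique(cpg[, list(chrom, pos)])
  sci <- .pos_interval_idx(sites$chrom, sites$pos, arch$compartments)
  slab <- arch$compartments$label[sci]
  sw <- ifelse(is.na(slab), (config$meth_a_mean + config$meth_b_mean) / 2,
               ifelse(slab == "A", config$meth_a_mean, config$meth_b_mean))
  sites[, state := runif(.N) < sw]
  cpg <- merge(cpg, sites, by = c("chrom", "pos"), sort = FALSE)
  base <- ifelse(cpg$anchor_frag, cpg$true_level,
                 ifelse(cpg$state, 0.9, 0.1))
  cpg[, probability := pmin(pmax(
    base + rnorm(.N, 0, config$cpg_noise_sd), 0.001), 0.999)]
  setorder(cpg, read_id, row_id, pos)
  cpg[, list(read_id, chrom, pos, probability, true_level)]
}
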