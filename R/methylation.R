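# Per-read CpG methylation calling and structure-linked analyses.

#' Threshold per-read CpG probabilities into calls
#'
#' Methylated when probability > `meth_min` (0.75, i.e. 191 on the 255
#' scale), unmethylated when < `unmeth_max` (0.25, the symmetric
#' counterpart), otherwise ambiguous. Probabilities outside `[0, 1]` are
#' rejected and counted.
#'
#' @param records data.frame with read_id, chrom, pos, probability.
#' @param meth_min,unmeth_max call thresholds on the unit scale.
#' @param scale "unit" or "255" (the latter divides by 255 first).
#' @return list(calls = data.table with a `call` column, n_rejected).
#' @export
threshold_calls <- function(records, meth_min = 0.75, unmeth_max = 0.25,
                            scale = c("unit", "255")) {
  scale <- match.arg(scale)
  calls <- as.data.table(records)
  if (scale == "255") calls[, probability := probability / 255]
  bad <- calls$probability < 0 | calls$probability > 1 |
    is.na(calls$probability)
  calls <- calls[!bad]
  calls[, call := ifelse(probability > meth_min, "methylated",
                         ifelse(probability < unmeth_max, "unmethylated",
                                "ambiguous"))]
  list(calls = calls[], n_rejected = sum(bad))
}

#' Aggregate calls into per-CpG methylation summaries
#'
#' Ratio = methylated / (methylated + unmethylated); ambiguous calls are
#' excluded. Class: high when ratio >= 0.6, low when <= 0.4, medium
#' otherwise; sites under `min_coverage` informative calls are reported
#' unclassified (NA class).
#'
#' @param calls call table from [threshold_calls()].
#' @param min_coverage minimum informative coverage (default 5).
#' @return data.table (chrom, pos, coverage, ratio, class).
#' @export
aggregate_cpg <- function(calls, min_coverage = 5) {
  calls <- as.data.table(calls)[call != "ambiguous"]
  out <- calls[, list(coverage = .N,
                      ratio = mean(call == "methylated")),
               by = list(chrom, pos)]
  out[, class := ifelse(coverage < min_coverage, NA_character_,
                        ifelse(ratio >= 0.6, "high",
                               ifelse(ratio <= 0.4, "low", "medium")))]
  setorder(out, chrom, pos)
  out[]
}

# per-(read, loop, side) mean methylation level over anchor CpGs
.anchor_levels <- function(calls, loops, min_cpg, level) {
  calls <- as.data.table(calls)
  loops <- as.data.table(loops)
  if (!"loop_id" %in% names(loops)) loops[, loop_id := seq_len(.N)]
  lvl <- switch(level,
                probability = calls$probability,
                call = as.numeric(calls$call == "methylated"))
  if (level == "call") {
    keep <- calls$call != "ambiguous"
    calls <- calls[keep]; lvl <- lvl[keep]
  }
  calls[, level_val := lvl]
  one_side <- function(side) {
    iv <- if (side == "a") {
      loops[, list(chrom, start = a_start, end = a_end, loop_id)]
    } else {
      loops[, list(chrom, start = b_start, end = b_end, loop_id)]
    }
    idx <- .pos_interval_idx(calls$chrom, calls$pos, iv)
    data.table(read_id = calls$read_id, loop_id = iv$loop_id[idx],
               level_val = calls$level_val)[!is.na(loop_id)][
      , list(n_cpg = .N, level = mean(level_val)),
      by = list(read_id, loop_id)]
  }
  a <- one_side("a"); b <- one_side("b")
  m <- merge(a, b, by = c("read_id", "loop_id"), suffixes = c("_a", "_b"))
  m[n_cpg_a >= min_cpg & n_cpg_b >= min_cpg]
}

#' Methylation correlation between paired loop-anchor fragments
#'
#' For each read carrying fragments in both anchors of a loop with at least
#' `min_cpg` CpGs on each side, the per-side mean methylation level is
#' computed; the Pearson correlation is taken across those (read, loop)
#' observations.
#'
#' @param calls call table from [threshold_calls()] (per-read CpGs).
#' @param loops loop table with chrom, a_start, a_end, b_start, b_end.
#' @param min_cpg minimum CpGs per anchor fragment (default 3).
#' @param level "probability" (mean probability) or "call" (fraction of
#'   methylated calls).
#' @return list(r, n, data, low_n flag when n < 10).
#' @export
anchor_methylation_pcc <- function(calls, loops, min_cpg = 3,
                                   level = c("probability", "call")) {
  level <- match.arg(level)
  m <- .anchor_levels(calls, loops, min_cpg, level)
  n <- nrow(m)
  r <- if (n >= 2L) cor(m$level_a, m$level_b) else NA_real_
  list(r = r, n = n, data = m[], low_n = n < 10L)
}

#' Fisher z comparison of two independent correlations
#'
#' z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3)), two-sided p.
#'
#' @param r1,r2 correlation coefficients.
#' @param n1,n2 sample sizes (> 3).
#' @return list(z, p).
#' @export
fisher_z_test <- function(r1, r2, n1, n2) {
  if (n1 <= 3 || n2 <= 3) stop("Fisher z comparison requires n > 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Shuffled-anchor null correlation and comparison to the observed
#'
#' The second-anchor levels of the qualifying reads are permuted across
#' reads (same n), the null correlation recomputed, and the two
#' correlations compared with the Fisher z test.
#'
#' @param anchor_data `data` from [anchor_methylation_pcc()].
#' @param seed RNG seed for the permutation.
#' @return list(r_obs, r_null, n, z, p).
#' @export
shuffled_null_pcc <- function(anchor_data, seed = 1) {
  m <- as.data.table(anchor_data)
  n <- nrow(m)
  if (n <= 3L) stop("too few qualifying reads (n <= 3)")
  set.seed(seed)
  perm <- sample.int(n)
  r_obs <- cor(m$level_a, m$level_b)
  r_null <- cor(m$level_a, m$level_b[perm])
  fz <- fisher_z_test(r_obs, r_null, n, n)
  list(r_obs = r_obs, r_null = r_null, n = n, z = fz$z, p = fz$p)
}

#' Anchor methylation by CTCF loop group
#'
#' Loops are grouped by how many anchors overlap a CTCF peak (CTCF-both /
#' CTCF-one / CTCF-none). Per group: pooled anchor methylation levels, the
#' paired-anchor Pearson correlation, a Kruskal-Wallis test across groups
#' and Holm-adjusted pairwise Wilcoxon tests.
#'
#' @param anchor_data `data` from [anchor_methylation_pcc()] (read, loop,
#'   per-side levels).
#' @param loops loop table (chrom, a_start, a_end, b_start, b_end, loop_id).
#' @param ctcf_peaks peak intervals (chrom, start, end).
#' @return list(groups = per-loop group, summary = per-group n_loops,
#'   n_reads, mean_level, pcc; kruskal_p; pairwise_p).
#' @export
loop_group_comparison <- function(anchor_data, loops, ctcf_peaks) {
  loops <- as.data.table(loops)
  if (!"loop_id" %in% names(loops)) loops[, loop_id := seq_len(.N)]
  peaks <- as.data.table(ctcf_peaks)
  hit_a <- .overlap_pairs(loops[, list(chrom, start = a_start, end = a_end)],
                          peaks)
  hit_b <- .overlap_pairs(loops[, list(chrom, start = b_start, end = b_end)],
                          peaks)
  n_ctcf <- (seq_len(nrow(loops)) %in% hit_a$q_idx) +
    (seq_len(nrow(loops)) %in% hit_b$q_idx)
  grp <- c("CTCF-none", "CTCF-one", "CTCF-both")[n_ctcf + 1L]
  groups <- data.table(loop_id = loops$loop_id, group = grp)
  m <- merge(as.data.table(anchor_data), groups, by = "loop_id")
  summary <- m[, list(n_reads = .N,
                      mean_level = mean(c(level_a, level_b)),
                      pcc = if (.N >= 3L) cor(level_a, level_b) else NA_real_),
               by = group]
  summary <- merge(summary, groups[, list(n_loops = .N), by = group],
                   by = "group")
  lv <- m[, list(level = c(level_a, level_b)), by = group]
  kw <- if (length(unique(lv$group)) >= 2L) {
    kruskal.test(level ~ factor(group), data = lv)$p.value
  } else NA_real_
  pw <- if (length(unique(lv$group)) >= 2L) {
    stats::pairwise.wilcox.test(lv$level, lv$group,
                                p.adjust.method = "holm")$p.value
  } else NULL
  list(groups = groups[], summary = summary[], kruskal_p = kw,
       pairwise_p = pw)
}

#' Classify compartment intervals from methylation alone
#'
#' Each compartment interval is summarised by mean methylation ratio over
#' `bin_size` bins. An interior interval is called A when its mean exceeds
#' both neighbours with a significant two-sided Welch test on the bin
#' values, B when it is below both neighbours significantly; chromosome-end
#' intervals use their single neighbour. Intervals with fewer than 2 covered
#' bins stay unlabeled.
#'
#' @param compartments intervals (chrom, start, end) with a reference
#'   `label` column used only for the agreement report.
#' @param cpg_summary per-CpG table from [aggregate_cpg()].
#' @param alpha test level (default 0.05).
#' @param bin_size summary bin size (default 100 kb).
#' @return list(labels = data.table with inferred label, agreement =
#'   fraction of labeled intervals matching the reference).
#' @export
compartments_from_methylation <- function(compartments, cpg_summary,
                                          alpha = 0.05, bin_size = 1e5) {
  comp <- as.data.table(compartments)
  comp[, idx := seq_len(.N)]
  cpg <- as.data.table(cpg_summary)
  ci <- .pos_interval_idx(cpg$chrom, cpg$pos, comp)
  cpg[, comp_idx := ci]
  cpg <- cpg[!is.na(comp_idx)]
  cpg[, bin := pos %/% as.integer(bin_size)]
  binmeans <- cpg[, list(m = mean(ratio)), by = list(comp_idx, bin)]
  bm <- split(binmeans$m, binmeans$comp_idx)
  get_bins <- function(i) bm[[as.character(i)]] %||% numeric()
  setorder(comp, chrom, start)
  inferred <- rep(NA_character_, nrow(comp))
  sig_gt <- function(x, y) {
    if (length(x) < 2L || length(y) < 2L) return(0)
    if (stats::sd(c(x, y)) == 0) return(0)
    p <- tryCatch(t.test(x, y)$p.value, error = function(e) 1)
    if (p < alpha) sign(mean(x) - mean(y)) else 0
  }
  ord_idx <- comp$idx
  for (r in seq_len(nrow(comp))) {
    x <- get_bins(ord_idx[r])
    if (length(x) < 2L) next
    nb <- integer()
    if (r > 1L && comp$chrom[r - 1L] == comp$chrom[r]) nb <- c(nb, r - 1L)
    if (r < nrow(comp) && comp$chrom[r + 1L] == comp$chrom[r]) nb <- c(nb, r + 1L)
    if (!length(nb)) next
    cmp <- vapply(nb, function(q) sig_gt(x, get_bins(ord_idx[q])), numeric(1))
    if (all(cmp == 1)) inferred[r] <- "A"
    if (all(cmp == -1)) inferred[r] <- "B"
  }
  labels <- comp[, list(chrom, start, end, idx)]
  labels[, inferred := inferred]
  if ("label" %in% names(comp)) {
    labels[, reference := comp$label]
    lab <- !is.na(inferred)
    agreement <- if (any(lab)) mean(inferred[lab] == comp$label[lab]) else NA_real_
  } else agreement <- NA_real_
  list(labels = labels[], agreement = agreement)
}

#' GC-density bias slope of methylation coverage
#'
#' Ordinary least squares slope of GC percentage on log10 bin count.
#'
#' @param bin_count per-bin read/call counts (> 0).
#' @param gc_fraction per-bin GC fraction (or percentage).
#' @return the fitted slope.
#' @export
gc_bias_slope <- function(bin_count, gc_fraction) {
  ok <- bin_count > 0 & !is.na(bin_count) & !is.na(gc_fraction)
  if (sum(ok) < 3L) stop("need at least 3 covered bins")
  x <- log10(bin_count[ok])
  if (stats::sd(x) == 0) stop("bin counts are single-valued; slope undefined")
  unname(coef(lm(gc_fraction[ok] ~ x))[2])
}
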