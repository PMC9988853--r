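# Single-allele topology clustering: reads x bins occupancy matrices, Ward
# clustering, per-cluster bin frequencies, and regulatory multiway models.

#' Build a binary read-by-bin occupancy matrix over a region
#'
#' Bin size defaults to 1 kb for regions shorter than 200 kb and 5 kb
#' otherwise. A read enters the matrix when at least `min_fragments` of its
#' fragment midpoints fall inside the region; P(i, j) = 1 iff read i has a
#' fragment midpoint in bin j (bins are 0-based half-open, so a midpoint on a
#' bin's left edge belongs to that bin).
#'
#' @param mw multiway fragment data.table.
#' @param region list or data.frame with chrom, start, end.
#' @param bin_size override the default bin-size rule (bp).
#' @param min_fragments minimum in-region fragments per read (default 3).
#' @return object of class `read_bin_matrix`: binary matrix `P` with read
#'   ids as rownames, the region, bin size and bin start coordinates.
#' @export
build_read_bin_matrix <- function(mw, region, bin_size = NULL,
                                  min_fragments = 3) {
  region <- as.data.table(as.list(region))[1]
  width <- region$end - region$start
  stopifnot(width > 0)
  if (is.null(bin_size)) bin_size <- if (width < 2e5) 1e3 else 5e3
  mw <- as.data.table(mw)
  mw[, mid := .mid(start, end)]
  fr <- mw[chrom == region$chrom & mid >= region$start & mid < region$end]
  keep <- fr[, .N, by = read_id][N >= min_fragments, read_id]
  fr <- fr[read_id %in% keep]
  if (nrow(fr) == 0L) stop("no reads qualify for the read-bin matrix")
  M <- as.integer(ceiling(width / bin_size))
  fr[, bin := pmin(as.integer((mid - region$start) %/% bin_size), M - 1L)]
  ids <- sort(unique(fr$read_id))
  P <- matrix(0L, length(ids), M, dimnames = list(ids, NULL))
  P[cbind(match(fr$read_id, ids), fr$bin + 1L)] <- 1L
  structure(list(P = P, region = region, bin_size = bin_size,
                 bin_starts = region$start + bin_size * (seq_len(M) - 1L)),
            class = "read_bin_matrix")
}

#' Ward clustering of occupancy rows
#'
#' Agglomerative Ward linkage on euclidean distances between the rows of P.
#' When `k` is NULL it is chosen as the k in 2..6 with the largest gap
#' between successive merge heights (a deterministic surrogate for cutting
#' the dendrogram by eye).
#'
#' @param rbm a `read_bin_matrix`.
#' @param k number of clusters, or NULL for automatic selection.
#' @return list(labels = named integer vector, k, hclust).
#' @export
cluster_reads <- function(rbm, k = NULL) {
  P <- rbm$P
  N <- nrow(P)
  if (!is.null(k) && N < k) stop("fewer reads than clusters")
  hc <- hclust(dist(P, method = "euclidean"), method = "ward.D2")
  if (is.null(k)) {
    h <- hc$height
    kmax <- min(6L, N - 1L)
    gaps <- vapply(2:kmax, function(kk) {
      h[N - kk + 1L] - h[N - kk]
    }, numeric(1))
    k <- (2:kmax)[which.max(gaps)]
  }
  labels <- cutree(hc, k = k)
  list(labels = labels, k = as.integer(k), hclust = hc)
}

#' Per-cluster relative bin frequency
#'
#' For every cluster and bin: number of member reads hitting the bin divided
#' by the cluster's read count, an exact rational in `[0, 1]`.
#'
#' @param rbm a `read_bin_matrix`.
#' @param labels cluster labels aligned with `rownames(rbm$P)`.
#' @return matrix clusters x bins of relative frequencies; empty clusters
#'   are dropped with a warning.
#' @export
relative_frequency <- function(rbm, labels) {
  P <- rbm$P
  stopifnot(length(labels) == nrow(P))
  cl <- sort(unique(labels))
  sizes <- table(factor(labels, levels = cl))
  if (any(sizes == 0)) {
    warning("empty cluster(s) excluded")
    cl <- cl[sizes > 0]
  }
  out <- t(vapply(cl, function(cc) {
    colSums(P[labels == cc, , drop = FALSE]) / sum(labels == cc)
  }, numeric(ncol(P))))
  rownames(out) <- as.character(cl)
  out
}

#' CTCF fragment and pairwise-contact frequencies per cluster
#'
#' @param rbm a `read_bin_matrix`.
#' @param labels cluster labels.
#' @param ctcf_bins 1-based bin indices containing CTCF sites.
#' @param orientations optional motif orientation per CTCF bin, passed
#'   through for display.
#' @return list(fragment = clusters x ctcf-bin frequency matrix,
#'   pairwise = data.table cluster/bin_a/bin_b/freq, orientations).
#' @export
ctcf_frequencies <- function(rbm, labels, ctcf_bins, orientations = NULL) {
  ctcf_bins <- sort(unique(as.integer(ctcf_bins)))
  if (!length(ctcf_bins)) {
    return(list(fragment = matrix(numeric(), 0, 0),
                pairwise = data.table(cluster = integer(), bin_a = integer(),
                                      bin_b = integer(), freq = numeric()),
                orientations = orientations))
  }
  rf <- relative_frequency(rbm, labels)[, ctcf_bins, drop = FALSE]
  colnames(rf) <- as.character(ctcf_bins)
  P <- rbm$P[, ctcf_bins, drop = FALSE]
  cl <- sort(unique(labels))
  pw <- rbindlist(lapply(cl, function(cc) {
    Q <- P[labels == cc, , drop = FALSE]
    nreads <- nrow(Q)
    co <- crossprod(Q)   # co-occurrence counts over reads
    idx <- which(upper.tri(co), arr.ind = TRUE)
    data.table(cluster = cc, bin_a = ctcf_bins[idx[, 1]],
               bin_b = ctcf_bins[idx[, 2]],
               freq = co[idx] / nreads)
  }))
  list(fragment = rf, pairwise = pw, orientations = orientations)
}

#' Per-cluster distance observed/expected curves
#'
#' Observed = the cluster's distribution of read cover distances (or virtual
#' pairwise contact distances) over log-spaced bins; expected = the same
#' distribution over all reads. Both are normalised to sum to one before the
#' ratio; empty expected bins are masked.
#'
#' @param mw multiway fragment data.table.
#' @param labels named cluster labels (names = read ids).
#' @param what "cover" or "pairs".
#' @param n_breaks number of log-spaced distance bins.
#' @return data.table (cluster, dist_lo, dist_hi, observed, expected, oe).
#' @export
cluster_distance_oe <- function(mw, labels, what = c("cover", "pairs"),
                                n_breaks = 20) {
  what <- match.arg(what)
  mw <- as.data.table(mw)[read_id %in% names(labels)]
  dp <- distance_profiles(mw)
  d <- if (what == "cover") {
    dp$distances[type == "cover"]
  } else {
    dp$distances[type %in% c("adjacent", "separated")]
  }
  d <- d[is.finite(distance) & distance > 0]
  breaks <- exp(seq(log(max(1, min(d$distance))),
                    log(max(d$distance) + 1), length.out = n_breaks + 1L))
  breaks[1] <- breaks[1] * 0.999
  d[, bin := cut(distance, breaks, include.lowest = TRUE, labels = FALSE)]
  d[, cluster := labels[read_id]]
  all_h <- tabulate(d$bin, nbins = n_breaks)
  expected <- all_h / sum(all_h)
  rbindlist(lapply(sort(unique(d$cluster)), function(cc) {
    h <- tabulate(d[cluster == cc, bin], nbins = n_breaks)
    obs <- h / sum(h)
    data.table(cluster = cc, dist_lo = head(breaks, -1L),
               dist_hi = tail(breaks, -1L), observed = obs,
               expected = expected,
               oe = ifelse(expected > 0, obs / expected, NA_real_))
  }))
}

# 2-kb element bins with overlap priority
.element_bins <- function(promoters, enhancers, bin_size = 2000,
                          priority = c("promoter", "enhancer")) {
  priority <- match.arg(priority)
  to_bins <- function(x) {
    x <- as.data.table(x)
    if (nrow(x) == 0L) return(data.table(chrom = character(), bin = integer()))
    unique(x[, {
      b <- seq.int(start %/% bin_size, max(start %/% bin_size,
                                           (end - 1L) %/% bin_size))
      list(bin = b)
    }, by = list(chrom, start, end)][, list(chrom, bin)])
  }
  pb <- to_bins(promoters)
  eb <- to_bins(enhancers)
  both <- merge(pb, eb, by = c("chrom", "bin"))
  if (nrow(both)) {
    if (priority == "promoter") {
      eb <- eb[!both, on = c("chrom", "bin")]
    } else {
      pb <- pb[!both, on = c("chrom", "bin")]
    }
  }
  list(promoter = pb, enhancer = eb, bin_size = bin_size)
}

.count_element_frags <- function(mw, eb) {
  mw <- as.data.table(mw)
  mw[, mid := .mid(start, end)]
  mw[, bin := mid %/% eb$bin_size]
  pj <- mw[eb$promoter, on = c("chrom", "bin"), nomatch = NULL]
  ej <- mw[eb$enhancer, on = c("chrom", "bin"), nomatch = NULL]
  p <- pj[, .N, by = read_id]
  e <- ej[, .N, by = read_id]
  out <- data.table(read_id = unique(mw$read_id))
  out[, n_prom := p$N[match(read_id, p$read_id)]]
  out[, n_enh := e$N[match(read_id, e$read_id)]]
  out[is.na(n_prom), n_prom := 0L]
  out[is.na(n_enh), n_enh := 0L]
  out
}

#' Promoter-interaction model read classes (BP / SG / MG)
#'
#' Overlapping promoter/enhancer 2-kb bins count as promoter bins here.
#' BP = one promoter fragment, no enhancer; SG = one promoter, >= 1
#' enhancer; MG = >= 2 promoter fragments. Reads without promoter fragments
#' are unclassified (NA).
#'
#' @param mw multiway fragment data.table.
#' @param promoters,enhancers element interval tables.
#' @param bin_size element bin size (default 2 kb).
#' @return data.table (read_id, n_prom, n_enh, class).
#' @export
classify_promoter_model <- function(mw, promoters, enhancers,
                                    bin_size = 2000) {
  eb <- .element_bins(promoters, enhancers, bin_size, "promoter")
  cc <- .count_element_frags(mw, eb)
  cc[, class := ifelse(n_prom == 0L, NA_character_,
                       ifelse(n_prom >= 2L, "MG",
                              ifelse(n_enh == 0L, "BP", "SG")))]
  cc[]
}

#' Enhancer-interaction model read classes (NE / SE / ME)
#'
#' Overlapping bins count as enhancer bins here. NE = exactly one promoter
#' fragment and no enhancer; SE = >= 1 promoter and exactly one enhancer;
#' ME = >= 1 promoter and >= 2 enhancers. Other combinations (including
#' several promoters with no enhancer) have no class in this model and come
#' back NA.
#'
#' @inheritParams classify_promoter_model
#' @return data.table (read_id, n_prom, n_enh, class).
#' @export
classify_enhancer_model <- function(mw, promoters, enhancers,
                                    bin_size = 2000) {
  eb <- .element_bins(promoters, enhancers, bin_size, "enhancer")
  cc <- .count_element_frags(mw, eb)
  cc[, class := ifelse(n_prom == 0L, NA_character_,
                       ifelse(n_enh >= 2L, "ME",
                              ifelse(n_enh == 1L, "SE",
                                     ifelse(n_prom == 1L, "NE",
                                            NA_character_))))]
  cc[]
}

#' Viewpoint co-occurrence frequency with cluster subsampling
#'
#' Reads of each cluster are subsampled `n_subsample` times (fraction `frac`
#' without replacement). In each subsample the per-bin frequency is the
#' number of reads that contain a viewpoint fragment AND hit the bin,
#' divided by the subsample size. Per bin, the two clusters' subsample
#' values are compared with a two-sided Welch test, Bonferroni-corrected
#' over bins.
#'
#' @param rbm a `read_bin_matrix`.
#' @param labels cluster labels aligned with rows of P.
#' @param viewpoint_bins 1-based bin indices of the viewpoint.
#' @param clusters the two cluster labels to compare (default: first two).
#' @param n_subsample number of subsample draws (default 100).
#' @param frac subsample fraction (default 0.5).
#' @param seed RNG seed.
#' @param alpha significance level on adjusted p (default 0.01).
#' @return list(summary = per-bin/per-cluster mean and sd, tests = per-bin
#'   p, p_adj, significant).
#' @export
viewpoint_subsample_frequency <- function(rbm, labels, viewpoint_bins,
                                          clusters = NULL, n_subsample = 100,
                                          frac = 0.5, seed = 1,
                                          alpha = 0.01) {
  P <- rbm$P
  vp <- rowSums(P[, viewpoint_bins, drop = FALSE]) > 0
  cl <- sort(unique(labels))
  if (is.null(clusters)) clusters <- cl[1:2]
  stopifnot(length(clusters) == 2L)
  for (cc in clusters) {
    if (!any(vp[labels == cc])) {
      warning("cluster ", cc, " has no viewpoint reads; excluded")
      return(list(summary = NULL, tests = NULL))
    }
  }
  set.seed(seed)
  M <- ncol(P)
  draws <- lapply(clusters, function(cc) {
    rows <- which(labels == cc)
    m <- max(1L, floor(frac * length(rows)))
    t(vapply(seq_len(n_subsample), function(s) {
      sub <- if (frac >= 1) rows else sample(rows, m)
      colSums(P[sub[vp[sub]], , drop = FALSE]) / length(sub)
    }, numeric(M)))
  })
  names(draws) <- as.character(clusters)
  summary <- rbindlist(lapply(seq_along(clusters), function(i) {
    data.table(cluster = clusters[i], bin = seq_len(M),
               mean = colMeans(draws[[i]]),
               sd = apply(draws[[i]], 2, stats::sd))
  }))
  p <- vapply(seq_len(M), function(b) {
    x <- draws[[1]][, b]; y <- draws[[2]][, b]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    }
    tryCatch(t.test(x, y)$p.value, error = function(e) 1)
  }, numeric(1))
  tests <- data.table(bin = seq_len(M), p = p,
                      p_adj = pmin(1, p * M))
  tests[, significant := p_adj < alpha]
  list(summary = summary, tests = tests[])
}

#' Frequency of reads containing fragments in all three elements
#'
#' @param mw multiway fragment data.table.
#' @param elements interval table with exactly three disjoint rows.
#' @return list(count, frequency, n_reads).
#' @export
threeway_cooccurrence <- function(mw, elements) {
  elements <- .validate_intervals(as.data.table(elements), "elements")
  stopifnot(nrow(elements) == 3L)
  .stop_if_overlapping(elements, "elements")
  mw <- as.data.table(mw)
  hits <- .overlap_pairs(mw, elements)
  per_read <- data.table(read_id = mw$read_id[hits$q_idx],
                         el = hits$i_idx)[
    , list(k = length(unique(el))), by = read_id]
  n_reads <- length(unique(mw$read_id))
  cnt <- sum(per_read$k == 3L)
  list(count = cnt, frequency = cnt / n_reads, n_reads = n_reads)
}

#' Interaction-frequency strata (Q1 / Q2 / Q3)
#'
#' Genes are partitioned by the 25th and 75th percentile of their
#' interaction frequency: Q1 below the 25th, Q2 at or above the 25th and
#' below the 75th, Q3 at or above the 75th.
#'
#' @param freq per-gene interaction frequency.
#' @param expression optional per-gene expression values, summarised per
#'   group.
#' @return list(group = factor per gene, summary = per-group n and mean
#'   expression).
#' @export
expression_strata <- function(freq, expression = NULL) {
  q <- quantile(freq, c(0.25, 0.75))
  if (q[1] == q[2]) {
    warning("degenerate percentiles; all genes in Q2")
    grp <- factor(rep("Q2", length(freq)), levels = c("Q1", "Q2", "Q3"))
  } else {
    grp <- factor(ifelse(freq < q[1], "Q1",
                         ifelse(freq < q[2], "Q2", "Q3")),
                  levels = c("Q1", "Q2", "Q3"))
  }
  summary <- data.table(group = levels(grp),
                        n = as.integer(table(grp)))
  if (!is.null(expression)) {
    summary[, mean_expression := vapply(levels(grp), function(g) {
      if (any(grp == g)) mean(expression[grp == g]) else NA_real_
    }, numeric(1))]
  }
  list(group = grp, summary = summary[])
}
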