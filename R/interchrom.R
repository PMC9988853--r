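# Trans-chromosomal contact enrichment, significant-pair selection and hub
# partitioning on 1-Mb bins.

#' Bin trans pairs into a 1-Mb trans contact table
#'
#' @param pairs pair data.table (only rows with `trans == TRUE` are used).
#' @param chrom_sizes data.frame (name, length) or a `genome_model`.
#' @param resolution bin size (default 1 Mb).
#' @return object of class `trans_matrix`: bins table, counts over unordered
#'   trans bin pairs (bin_i < bin_j), resolution, and the number of possible
#'   trans bin pairs.
#' @export
build_trans_matrix <- function(pairs, chrom_sizes, resolution = 1e6) {
  if (inherits(chrom_sizes, "genome_model")) {
    chrom_sizes <- chrom_sizes$chromosomes
  }
  bins <- .make_bins(chrom_sizes, resolution)
  pairs <- as.data.table(pairs)[trans == TRUE]
  if (nrow(pairs) == 0L) {
    warning("no trans pairs; returning empty trans matrix")
    counts <- data.table(bin_i = integer(), bin_j = integer(),
                         count = integer())
  } else {
    b1 <- .bin_of(bins, pairs$chrom1, pairs$pos1, resolution)
    b2 <- .bin_of(bins, pairs$chrom2, pairs$pos2, resolution)
    counts <- data.table(bin_i = pmin(b1, b2), bin_j = pmax(b1, b2))[
      , list(count = .N), by = list(bin_i, bin_j)]
    setorder(counts, bin_i, bin_j)
  }
  nb <- bins[, .N, by = chrom]$N
  n_possible <- (sum(nb)^2 - sum(nb^2)) / 2
  structure(list(bins = bins, counts = counts, resolution = resolution,
                 n_possible = n_possible),
            class = "trans_matrix")
}

#' Categorize trans pairs by telomere / centromere membership
#'
#' A pair lands in "Tel" when at least one end overlaps a telomere, else in
#' "Cent" when at least one end overlaps a centromere, else "Other"
#' (precedence configurable). Both-end subsets are tallied separately.
#'
#' @param pairs pair data.table (trans rows used).
#' @param telomeres,centromeres interval tables.
#' @param precedence "tel" (default) or "cent".
#' @return list(category = per-pair factor, tally, both_end = counts of
#'   both-end telomere/centromere pairs).
#' @export
categorize_pairs <- function(pairs, telomeres, centromeres,
                             precedence = c("tel", "cent")) {
  precedence <- match.arg(precedence)
  pairs <- as.data.table(pairs)[trans == TRUE]
  telomeres <- as.data.table(telomeres)
  centromeres <- as.data.table(centromeres)
  in_tel1 <- !is.na(.pos_interval_idx(pairs$chrom1, pairs$pos1, telomeres))
  in_tel2 <- !is.na(.pos_interval_idx(pairs$chrom2, pairs$pos2, telomeres))
  in_cen1 <- !is.na(.pos_interval_idx(pairs$chrom1, pairs$pos1, centromeres))
  in_cen2 <- !is.na(.pos_interval_idx(pairs$chrom2, pairs$pos2, centromeres))
  tel <- in_tel1 | in_tel2
  cen <- in_cen1 | in_cen2
  cat <- if (precedence == "tel") {
    ifelse(tel, "Tel", ifelse(cen, "Cent", "Other"))
  } else {
    ifelse(cen, "Cent", ifelse(tel, "Tel", "Other"))
  }
  tally <- table(factor(cat, levels = c("Tel", "Cent", "Other")))
  list(category = cat,
       tally = as.data.table(tally, keep.rownames = TRUE)[
         , list(category = V1, count = N)],
       both_end = c(Tel = sum(in_tel1 & in_tel2),
                    Cent = sum(in_cen1 & in_cen2)))
}

#' Negative binomial enrichment of trans bin pairs
#'
#' Under the assumption that trans contacts scatter randomly over bin pairs,
#' a negative binomial is fitted by method of moments to the pooled per-pair
#' count distribution (all possible trans pairs, zeros included, by default)
#' with a Poisson fallback when the variance does not exceed the mean.
#' p = upper tail P(X >= observed), Bonferroni-adjusted over all tested
#' pairs; enrichment score = observed / expected mean.
#'
#' @param tm a `trans_matrix`.
#' @param universe "all" (include structural zeros) or "nonzero".
#' @param expected "global" (one fitted mean) or "marginal" (product of bin
#'   marginals, as an alternative expected model).
#' @param es_min,alpha significance thresholds (default 2 and 0.01).
#' @return data.table of observed pairs with observed, expected,
#'   enrichment_score, p, p_adj, significant; fit parameters in attributes
#'   `fit` and `n_tests`.
#' @export
nb_enrichment <- function(tm, universe = c("all", "nonzero"),
                          expected = c("global", "marginal"),
                          es_min = 2, alpha = 0.01) {
  universe <- match.arg(universe)
  expected <- match.arg(expected)
  cnt <- tm$counts
  if (nrow(cnt) < 1L) stop("empty trans matrix")
  n_tests <- if (universe == "all") tm$n_possible else nrow(cnt)
  x <- cnt$count
  n_zero <- n_tests - nrow(cnt)
  mu <- sum(x) / n_tests
  m2 <- sum(x^2) / n_tests
  v <- m2 - mu^2
  fit <- if (v > mu) {
    list(model = "nb", mu = mu, size = mu^2 / (v - mu))
  } else {
    list(model = "poisson", mu = mu)
  }
  if (fit$model == "poisson" && v <= mu) {
    if (stats::var(x) == 0 && n_zero == 0) message("all counts equal; Poisson fallback")
  }
  ptail <- function(q) {
    if (fit$model == "nb") {
      pnbinom(q - 1L, size = fit$size, mu = fit$mu, lower.tail = FALSE)
    } else {
      ppois(q - 1L, lambda = fit$mu, lower.tail = FALSE)
    }
  }
  out <- copy(cnt)
  setnames(out, "count", "observed")
  if (expected == "global") {
    out[, expected := mu]
  } else {
    marg <- rbind(cnt[, list(bin = bin_i, count)],
                  cnt[, list(bin = bin_j, count)])[
      , list(m = sum(count)), by = bin]
    tot <- sum(cnt$count)
    mi <- marg$m[match(out$bin_i, marg$bin)]
    mj <- marg$m[match(out$bin_j, marg$bin)]
    out[, expected := as.numeric(mi) * mj / (2 * tot)]
  }
  out[, enrichment_score := observed / expected]
  out[, p := ptail(observed)]
  out[, p_adj := pmin(1, p * n_tests)]
  out[, significant := enrichment_score >= es_min & p_adj < alpha]
  setattr(out, "fit", fit)
  setattr(out, "n_tests", n_tests)
  out[]
}

#' Select significant trans bins with the diagonal-neighbour rule
#'
#' A significant pair (i, j) is retained only when the diagonal neighbours
#' (i-1, j-1) and (i+1, j+1) are also significant (neighbours must lie on the
#' same chromosomes; chromosome-edge pairs fail by definition). A bin is
#' reported when it appears in retained pairs with at least `min_partners`
#' distinct partner bins.
#'
#' @param stats result of [nb_enrichment()].
#' @param tm the `trans_matrix` the stats came from.
#' @param min_partners distinct-partner threshold (default 20).
#' @return list(pairs = retained pair table, bins = significant bin ids).
#' @export
select_significant <- function(stats, tm, min_partners = 20) {
  sig <- as.data.table(stats)[significant == TRUE]
  if (nrow(sig) == 0L) return(list(pairs = sig, bins = integer()))
  bins <- tm$bins
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  sigset <- key(sig$bin_i, sig$bin_j)
  same_chrom <- function(a, b) {
    !is.na(a) & !is.na(b) & a >= 1L & b >= 1L & a <= nrow(bins) &
      b <= nrow(bins) & bins$chrom[pmax(a, 1L)] == bins$chrom[pmax(b, 1L)]
  }
  ok_lo <- same_chrom(sig$bin_i - 1L, sig$bin_i) &
    same_chrom(sig$bin_j - 1L, sig$bin_j) &
    key(sig$bin_i - 1L, sig$bin_j - 1L) %in% sigset
  ok_hi <- same_chrom(sig$bin_i + 1L, sig$bin_i) &
    same_chrom(sig$bin_j + 1L, sig$bin_j) &
    key(sig$bin_i + 1L, sig$bin_j + 1L) %in% sigset
  retained <- sig[ok_lo & ok_hi]
  if (nrow(retained) == 0L) return(list(pairs = retained, bins = integer()))
  deg <- rbind(retained[, list(bin = bin_i, other = bin_j)],
               retained[, list(bin = bin_j, other = bin_i)])[
    , list(partners = length(unique(other))), by = bin]
  list(pairs = retained[],
       bins = sort(deg[partners >= min_partners, bin]))
}

#' Partition significant trans regions into two hubs
#'
#' The significant links among regions are written as a binary adjacency
#' matrix whose rows are clustered into two components with a Gaussian
#' mixture model (spherical components, deterministic hierarchical
#' initialisation; k-means with 10 restarts as fallback). Each region's
#' contact ratio is the fraction of its significant links staying inside its
#' assigned set; regions with ratio >= `ratio_min` are retained.
#'
#' @param regions integer vector of region bin ids.
#' @param links data.table of significant pairs (bin_i, bin_j).
#' @param ratio_min retention threshold on the contact ratio (default 0.9).
#' @param seed RNG seed (clustering is deterministic under a fixed seed).
#' @return data.table (region, set, contact_ratio, retained).
#' @export
partition_hubs <- function(regions, links, ratio_min = 0.9, seed = 1) {
  regions <- sort(unique(regions))
  nr <- length(regions)
  if (nr < 2L) stop("at least 2 regions required")
  links <- as.data.table(links)
  M <- matrix(0, nr, nr)
  ii <- match(links$bin_i, regions)
  jj <- match(links$bin_j, regions)
  keep <- !is.na(ii) & !is.na(jj)
  M[cbind(ii[keep], jj[keep])] <- 1
  M[cbind(jj[keep], ii[keep])] <- 1
  set.seed(seed)
  lab <- tryCatch({
    fit <- mclust::Mclust(M, G = 2, modelNames = "EII", verbose = FALSE)
    if (is.null(fit)) stop("mclust failed")
    fit$classification
  }, error = function(e) {
    kmeans(M, centers = 2, nstart = 10)$cluster
  })
  if (length(unique(lab)) < 2L) {
    warning("regions form a single indistinguishable component")
  }
  within <- vapply(seq_len(nr), function(i) {
    nb <- which(M[i, ] > 0)
    if (!length(nb)) return(NA_real_)
    mean(lab[nb] == lab[i])
  }, numeric(1))
  data.table(region = regions, set = as.integer(lab),
             contact_ratio = within,
             retained = !is.na(within) & within >= ratio_min)
}

#' Feature density per region
#'
#' @param regions interval table (1-Mb bins: chrom, start, end).
#' @param features feature intervals (peaks, genes, ...), optionally with a
#'   `value` column for mean-signal mode.
#' @param mode "count" (features per Mb) or "mean" (mean feature value).
#' @return numeric density per region row.
#' @export
region_feature_density <- function(regions, features,
                                   mode = c("count", "mean")) {
  mode <- match.arg(mode)
  regions <- as.data.table(regions)
  features <- as.data.table(features)
  hits <- .overlap_pairs(regions, features)
  if (mode == "count") {
    n <- tabulate(hits$q_idx, nbins = nrow(regions))
    n / ((regions$end - regions$start) / 1e6)
  } else {
    v <- rep(NA_real_, nrow(regions))
    if (nrow(hits)) {
      agg <- data.table(q = hits$q_idx, val = features$value[hits$i_idx])[
        , list(m = mean(val)), by = q]
      v[agg$q] <- agg$m
    }
    v
  }
}
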