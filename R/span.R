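# Structural-unit spanning statistics: how many loop anchors, TADs and
# compartments the fragments of each multiway read touch.

#' Distinct loop anchors covered per read
#'
#' Reads overlapping at least one anchor are classified by the number of
#' distinct anchors their fragments overlap; a read hitting the same anchor
#' twice counts once.
#'
#' @param mw multiway fragment data.table.
#' @param anchors disjoint anchor intervals (chrom, start, end, optional
#'   name).
#' @return list with `per_read` (read_id, k) and `tally` (k, count, pct) --
#'   percentages of the reads with k >= 1, at 2 decimals.
#' @export
span_loop_anchors <- function(mw, anchors) {
  anchors <- .validate_intervals(as.data.table(anchors), "anchors")
  .stop_if_overlapping(anchors, "anchors")
  mw <- as.data.table(mw)
  hits <- .overlap_pairs(mw, anchors)
  per_read <- data.table(read_id = mw$read_id[hits$q_idx],
                         anchor = hits$i_idx)[
    , list(k = length(unique(anchor))), by = read_id]
  tally <- per_read[, list(count = .N), by = k][order(k)]
  tally[, pct := span_percentages(count, sum(count))]
  list(per_read = per_read[], tally = tally[])
}

#' TAD-span classes of reads within a region
#'
#' Reads with at least two fragments overlapping `region` are classified:
#' reads with any fragment outside the region are "has_outside"; the rest by
#' the number of distinct region TADs hit ("one" = exclusively one TAD,
#' otherwise "k_within" for k >= 2).
#'
#' @param mw multiway fragment data.table.
#' @param tads TAD intervals covering the region.
#' @param region list or data.frame with chrom, start, end.
#' @return list with `per_read` (read_id, class, k_tads) and `tally`
#'   (class, count, pct).
#' @export
span_tads <- function(mw, tads, region) {
  region <- as.data.table(as.list(region))[1]
  tads <- .validate_intervals(as.data.table(tads), "tads")
  rt <- tads[chrom == region$chrom & start < region$end & end > region$start]
  setorder(rt, start)
  covered <- nrow(rt) > 0 && min(rt$start) <= region$start &&
    max(rt$end) >= region$end && all(head(rt$end, -1L) >= tail(rt$start, -1L))
  if (!covered) stop("region is not covered by the TAD set")
  mw <- as.data.table(mw)
  mw[, in_region := chrom == region$chrom & start < region$end &
       end > region$start]
  keep <- mw[, sum(in_region) >= 2L, by = read_id][V1 == TRUE, read_id]
  mw <- mw[read_id %in% keep]
  hits <- .overlap_pairs(mw[in_region == TRUE], rt)
  ktab <- data.table(read_id = mw[in_region == TRUE]$read_id[hits$q_idx],
                     tad = hits$i_idx)[
    , list(k_tads = length(unique(tad))), by = read_id]
  outside <- mw[, list(has_outside = any(!in_region)), by = read_id]
  per_read <- merge(outside, ktab, by = "read_id", all.x = TRUE)
  per_read[is.na(k_tads), k_tads := 0L]
  per_read[, class := ifelse(has_outside, "has_outside",
                             ifelse(k_tads <= 1L, "one",
                                    paste0(k_tads, "_within")))]
  tally <- per_read[, list(count = .N), by = class]
  tally[, pct := span_percentages(count, sum(count))]
  list(per_read = per_read[, list(read_id, class, k_tads)], tally = tally[])
}

.comp_pattern <- function(a, b, adjacent) {
  if (a > 0 && b == 0) return(if (a == 1) "A-single" else "A-multi")
  if (b > 0 && a == 0) return(if (b == 1) "B-single" else "B-multi")
  if (a == 0 && b == 0) return(NA_character_)
  if (a > 1 && b == 1) return("multiA-oneB")
  if (b > 1 && a == 1) return("multiB-oneA")
  if (a > 1 && b > 1) return("multiA-multiB")
  if (adjacent) "oneA-oneB-adjacent" else "oneA-oneB-separated"
}

#' Compartment-pattern classification of reads within a region
#'
#' Reads with >= 2 fragments in the region are labeled by how many distinct
#' A and B compartment intervals their in-region fragments occupy. The one-A
#' one-B case distinguishes intervals that abut (share a boundary) from
#' separated ones. Fragments in unlabeled gaps are excluded from the pattern.
#'
#' @param mw multiway fragment data.table.
#' @param compartments intervals with chrom, start, end, label in A/B.
#' @param region list or data.frame with chrom, start, end.
#' @return list with `per_read` (read_id, pattern, n_a, n_b), `tally`
#'   (pattern, count, pct of classified reads) and `summary` with the
#'   derived headline percentages (same-type fraction, multi-A among A-only,
#'   multi-B among B-only, mixed fraction and its sub-patterns).
#' @export
span_compartments <- function(mw, compartments, region) {
  region <- as.data.table(as.list(region))[1]
  comp <- .validate_intervals(as.data.table(compartments), "compartments")
  stopifnot(all(comp$label %in% c("A", "B")))
  mw <- as.data.table(mw)
  mw[, in_region := chrom == region$chrom & start < region$end &
       end > region$start]
  keep <- mw[, sum(in_region) >= 2L, by = read_id][V1 == TRUE, read_id]
  frag <- mw[read_id %in% keep & in_region == TRUE]
  ci <- .pos_interval_idx(frag$chrom, .mid(frag$start, frag$end), comp)
  frag[, comp_row := ci]
  frag <- frag[!is.na(comp_row)]
  per_read <- frag[, {
    rows <- unique(comp_row)
    labs <- comp$label[rows]
    a_rows <- rows[labs == "A"]; b_rows <- rows[labs == "B"]
    adjacent <- FALSE
    if (length(a_rows) == 1L && length(b_rows) == 1L) {
      adjacent <- comp$end[a_rows] == comp$start[b_rows] ||
        comp$end[b_rows] == comp$start[a_rows]
    }
    list(n_a = length(a_rows), n_b = length(b_rows),
         pattern = .comp_pattern(length(a_rows), length(b_rows), adjacent))
  }, by = read_id]
  per_read <- per_read[!is.na(pattern)]
  tally <- per_read[, list(count = .N), by = pattern]
  tally[, pct := span_percentages(count, sum(count))]
  total <- nrow(per_read)
  cnt <- function(p) sum(tally[pattern %in% p, count])
  a_only <- cnt(c("A-single", "A-multi")); b_only <- cnt(c("B-single", "B-multi"))
  mixed <- total - a_only - b_only
  summary <- c(
    same_type_pct = span_percentages(a_only + b_only, total),
    mixed_pct = span_percentages(mixed, total),
    a_multi_of_a_pct = if (a_only > 0) span_percentages(cnt("A-multi"), a_only) else NA_real_,
    b_multi_of_b_pct = if (b_only > 0) span_percentages(cnt("B-multi"), b_only) else NA_real_,
    multiA_oneB_of_mixed_pct = if (mixed > 0) span_percentages(cnt("multiA-oneB"), mixed) else NA_real_,
    multiB_oneA_of_mixed_pct = if (mixed > 0) span_percentages(cnt("multiB-oneA"), mixed) else NA_real_,
    multiA_multiB_of_mixed_pct = if (mixed > 0) span_percentages(cnt("multiA-multiB"), mixed) else NA_real_,
    oneA_oneB_adjacent_of_mixed_pct = if (mixed > 0) span_percentages(cnt("oneA-oneB-adjacent"), mixed) else NA_real_,
    oneA_oneB_separated_of_mixed_pct = if (mixed > 0) span_percentages(cnt("oneA-oneB-separated"), mixed) else NA_real_)
  list(per_read = per_read[], tally = tally[], summary = summary)
}

#' Enrichment of inter-domain contacts in the adj or nonadj subset
#'
#' Expected inter-domain count in a subset = (global inter-domain fraction
#' over all pairs) x subset size; the score divides observed by expected.
#' The complementary intra score is returned as well.
#'
#' @param pairs pair data.table with a logical `inter` column, or supply
#'   `domains` to derive it (inter = ends in different domain intervals;
#'   pairs with an end outside every domain are dropped).
#' @param subset "adj" or "nonadj".
#' @param domains optional domain intervals (chrom, start, end, optional
#'   label); when `label_filter` is given only pairs with both ends in
#'   domains of that label are used.
#' @param label_filter optional domain label (e.g. "A" for A-A contacts).
#' @return list(inter_score, intra_score, observed, expected, n_subset,
#'   global_fraction). Undefined (empty subset) yields NA scores with a
#'   warning.
#' @export
adjnonadj_enrichment <- function(pairs, subset = c("adj", "nonadj"),
                                 domains = NULL, label_filter = NULL) {
  subset <- match.arg(subset)
  pairs <- as.data.table(pairs)
  if (!"inter" %in% names(pairs)) {
    if (is.null(domains)) stop("either an inter column or domains is required")
    domains <- as.data.table(domains)
    d1 <- .pos_interval_idx(pairs$chrom1, pairs$pos1, domains)
    d2 <- .pos_interval_idx(pairs$chrom2, pairs$pos2, domains)
    ok <- !is.na(d1) & !is.na(d2)
    if (!is.null(label_filter)) {
      ok <- ok & domains$label[d1] == label_filter &
        domains$label[d2] == label_filter
    }
    pairs <- pairs[ok]
    pairs[, inter := d1[ok] != d2[ok]]
  }
  n_sub <- sum(pairs$adjacency == subset)
  if (n_sub == 0L || nrow(pairs) == 0L) {
    warning("empty subset; enrichment undefined")
    return(list(inter_score = NA_real_, intra_score = NA_real_,
                observed = NA_real_, expected = NA_real_, n_subset = n_sub,
                global_fraction = NA_real_))
  }
  gf <- mean(pairs$inter)
  obs <- sum(pairs$inter & pairs$adjacency == subset)
  exp_ <- gf * n_sub
  gi <- 1 - gf
  obs_i <- sum(!pairs$inter & pairs$adjacency == subset)
  list(inter_score = if (exp_ > 0) obs / exp_ else NA_real_,
       intra_score = if (gi > 0) obs_i / (gi * n_sub) else NA_real_,
       observed = obs, expected = exp_, n_subset = n_sub,
       global_fraction = gf)
}
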