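#' @import data.table
#' @importFrom stats rexp runif rnorm rpois rbinom cor dist hclust cutree kmeans
#'   pnbinom ppois quantile t.test kruskal.test pnorm lm coef sd var rmultinom
#'   p.adjust wilcox.test setNames ave
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percentage bookkeeping at a fixed printed precision
#'
#' Converts category counts into percentages of a total, rounded to a fixed
#' number of decimals. All tally reports in the package (loop-anchor, TAD and
#' compartment span classes, methylation classes) go through this helper so
#' that printed percentages are reproducible arithmetic on integer counts.
#'
#' @param counts integer vector of category counts (may be named).
#' @param total positive count the percentages refer to; defaults to
#'   `sum(counts)`.
#' @param digits decimals to keep (default 2).
#' @return numeric vector of percentages, same names as `counts`.
#' @export
span_percentages <- function(counts, total = sum(counts), digits = 2) {
  stopifnot(length(total) == 1L, total > 0, all(counts >= 0))
  round(100 * counts / total, digits)
}

# midpoint of 0-based half-open interval
.mid <- function(start, end) (start + end) %/% 2L

# row index of the (non-overlapping, per-chromosome) interval containing each
# position, NA when the position is in no interval
.pos_interval_idx <- function(chrom, pos, ints) {
  res <- rep(NA_integer_, length(pos))
  ints_chrom <- ints$chrom
  for (ch in unique(chrom)) {
    ii <- which(ints_chrom == ch)
    sel <- which(chrom == ch)
    if (!length(ii) || !length(sel)) next
    o <- ii[order(ints$start[ii])]
    k <- findInterval(pos[sel], ints$start[o])
    ok <- k >= 1L & pos[sel] < ints$end[o][pmax(k, 1L)]
    res[sel[ok]] <- o[k[ok]]
  }
  res
}

# all (query row, interval row) overlap hits between two 0-based half-open
# interval tables with columns chrom/start/end
.overlap_pairs <- function(q, ints) {
  if (nrow(q) == 0L || nrow(ints) == 0L) {
    return(data.table(q_idx = integer(), i_idx = integer()))
  }
  a <- data.table(chrom = q$chrom, start = q$start, end = q$end - 1L,
                  q_idx = seq_len(nrow(q)))
  b <- data.table(chrom = ints$chrom, start = ints$start, end = ints$end - 1L,
                  i_idx = seq_len(nrow(ints)))
  setkey(b, chrom, start, end)
  ov <- foverlaps(a, b, type = "any", nomatch = NULL)
  ov[, list(q_idx = q_idx, i_idx = i_idx)]
}

.validate_intervals <- function(x, what = "interval table") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    stop(what, " must have columns chrom, start, end")
  }
  if (any(x$end <= x$start)) stop(what, " has intervals with end <= start")
  invisible(x)
}

.stop_if_overlapping <- function(x, what = "intervals") {
  x <- as.data.table(x)[order(chrom, start)]
  bad <- x[, any(head(end, -1L) > tail(start, -1L)), by = chrom]$V1
  if (any(bad)) stop(what, " must be disjoint")
  invisible(x)
}

#' Write an interval table as BED
#'
#' @param x data.frame with chrom, start, end and optionally name/score.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as.data.table(x)
  cols <- intersect(c("chrom", "start", "end", "name", "label", "score"), names(x))
  fwrite(x[, cols, with = FALSE], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write a per-bin score track as bedGraph
#'
#' @param x data.frame with chrom, start, end, score.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  x <- as.data.table(x)
  fwrite(x[, list(chrom, start, end, score)], path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}
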