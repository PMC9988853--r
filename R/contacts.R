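# Virtual pairwise contacts and binned matrices.
#
# A read of order n yields C(n,2) pairwise contacts, n-1 of them between
# read-order neighbours ("adj"), the rest "nonadj". Pair position is the
# fragment midpoint throughout (binning, distances).

#' Decompose multiway reads into virtual pairwise contacts
#'
#' @param mw multiway fragment data.table from [assemble_multiway()].
#' @param chrom_levels optional chromosome order used to orient pairs;
#'   defaults to sorted unique chromosomes.
#' @return data.table with one row per pair: fragment a/b (chrom, midpoint
#'   `pos`, strand, mapq), `adjacency` ("adj"/"nonadj") and `trans` flag.
#'   Ends are ordered by (chromosome order, midpoint). Reads with n < 2
#'   contribute nothing.
#' @export
decompose_pairwise <- function(mw, chrom_levels = NULL) {
  mw <- as.data.table(mw)
  g <- mw[n >= 2L]
  empty <- data.table(read_id = character(), chrom1 = character(),
                      pos1 = integer(), strand1 = character(),
                      mapq1 = integer(), chrom2 = character(),
                      pos2 = integer(), strand2 = character(),
                      mapq2 = integer(), adjacency = character(),
                      trans = logical())
  if (nrow(g) == 0L) {
    message("no reads with n >= 2; returning empty pair set")
    return(empty)
  }
  if (is.null(chrom_levels)) chrom_levels <- sort(unique(g$chrom))
  setorder(g, read_id, frag_index)
  g[, mid := .mid(start, end)]
  pairs <- g[, {
    m <- .N
    i <- rep(seq_len(m - 1L), (m - 1L):1L)
    j <- sequence((m - 1L):1L) + i
    list(chrom1 = chrom[i], pos1 = mid[i], strand1 = strand[i],
         mapq1 = mapq[i], chrom2 = chrom[j], pos2 = mid[j],
         strand2 = strand[j], mapq2 = mapq[j],
         adjacency = ifelse(j == i + 1L, "adj", "nonadj"))
  }, by = read_id]
  pairs[, trans := chrom1 != chrom2]
  o1 <- match(pairs$chrom1, chrom_levels)
  o2 <- match(pairs$chrom2, chrom_levels)
  swap <- o2 < o1 | (o1 == o2 & pairs$pos2 < pairs$pos1)
  if (any(swap)) {
    sw <- function(a, b) {
      tmp <- pairs[[a]][swap]
      pairs[swap, (a) := get(b)]
      pairs[swap, (b) := tmp]
    }
    sw("chrom1", "chrom2"); sw("pos1", "pos2")
    sw("strand1", "strand2"); sw("mapq1", "mapq2")
  }
  pairs[]
}

#' Write pairs in juicer "medium" text format
#'
#' One line per pair: readname str1 chr1 pos1 frag1 str2 chr2 pos2 frag2
#' mapq1 mapq2. Strand is encoded 0 (+) / 16 (-), positions are 1-based,
#' frag fields are restriction-fragment indices when a genome is given
#' (otherwise 0 and 1).
#'
#' @param pairs pair data.table from [decompose_pairwise()].
#' @param path output file.
#' @param genome optional `genome_model` for restriction-fragment indices.
#' @return number of records written, invisibly.
#' @export
write_pairs_medium <- function(pairs, path, genome = NULL) {
  pairs <- as.data.table(pairs)
  if (is.null(genome)) {
    f1 <- rep(0L, nrow(pairs)); f2 <- rep(1L, nrow(pairs))
  } else {
    f1 <- integer(nrow(pairs)); f2 <- integer(nrow(pairs))
    for (ch in unique(c(pairs$chrom1, pairs$chrom2))) {
      i1 <- which(pairs$chrom1 == ch)
      i2 <- which(pairs$chrom2 == ch)
      if (length(i1)) f1[i1] <- fragment_index(genome, ch, pairs$pos1[i1])
      if (length(i2)) f2[i2] <- fragment_index(genome, ch, pairs$pos2[i2])
    }
  }
  out <- data.table(
    readname = pairs$read_id,
    str1 = ifelse(pairs$strand1 == "-", 16L, 0L), chr1 = pairs$chrom1,
    pos1 = pairs$pos1 + 1L, frag1 = f1,
    str2 = ifelse(pairs$strand2 == "-", 16L, 0L), chr2 = pairs$chrom2,
    pos2 = pairs$pos2 + 1L, frag2 = f2,
    mapq1 = pairs$mapq1, mapq2 = pairs$mapq2)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open output: ", conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(do.call(paste, c(out, sep = " ")), con)
  invisible(nrow(out))
}

#' Read juicer medium pairs text back into a pair table
#' @param path input file.
#' @return data.table mirroring [decompose_pairwise()] output columns.
#' @export
read_pairs_medium <- function(path) {
  dt <- fread(path, header = FALSE,
              col.names = c("readname", "str1", "chr1", "pos1", "frag1",
                            "str2", "chr2", "pos2", "frag2", "mapq1",
                            "mapq2"))
  data.table(read_id = dt$readname,
             chrom1 = dt$chr1, pos1 = dt$pos1 - 1L,
             strand1 = ifelse(dt$str1 == 16L, "-", "+"), mapq1 = dt$mapq1,
             chrom2 = dt$chr2, pos2 = dt$pos2 - 1L,
             strand2 = ifelse(dt$str2 == 16L, "-", "+"), mapq2 = dt$mapq2,
             trans = dt$chr1 != dt$chr2)
}

# global bin table over a chromosome-sizes table
.make_bins <- function(chrom_sizes, resolution) {
  cs <- as.data.table(chrom_sizes)
  if (!"name" %in% names(cs)) setnames(cs, 1:2, c("name", "length"))
  bins <- cs[, {
    nb <- ceiling(length / resolution)
    list(start = as.integer((seq_len(nb) - 1L) * resolution),
         end = as.integer(pmin(seq_len(nb) * resolution, length)))
  }, by = name]
  setnames(bins, "name", "chrom")
  bins[, bin_id := seq_len(.N)]
  bins[]
}

.bin_of <- function(bins, chrom, pos, resolution) {
  first <- bins[, list(first = bin_id[1], nb = .N), by = chrom]
  m <- match(chrom, first$chrom)
  if (anyNA(m)) stop("position on chromosome absent from bin table")
  rel <- pos %/% resolution
  clip <- rel > first$nb[m] - 1L
  if (any(clip)) {
    warning(sum(clip), " position(s) beyond chromosome end clipped to last bin")
    rel <- pmin(rel, first$nb[m] - 1L)
  }
  as.integer(first$first[m] + rel)
}

#' Bin pairwise contacts into a sparse symmetric matrix
#'
#' @param pairs pair data.table.
#' @param chrom_sizes data.frame (name, length) or a `genome_model`.
#' @param resolution bin size in bp.
#' @return object of class `contact_matrix`: bins table, upper-triangular
#'   sparse count matrix (total mass = number of pairs), resolution, and
#'   (after [balance_ic()]) balancing weights.
#' @export
bin_pairs <- function(pairs, chrom_sizes, resolution) {
  stopifnot(resolution > 0)
  if (inherits(chrom_sizes, "genome_model")) {
    chrom_sizes <- chrom_sizes$chromosomes
  }
  bins <- .make_bins(chrom_sizes, resolution)
  pairs <- as.data.table(pairs)
  b1 <- .bin_of(bins, pairs$chrom1, pairs$pos1, resolution)
  b2 <- .bin_of(bins, pairs$chrom2, pairs$pos2, resolution)
  i <- pmin(b1, b2); j <- pmax(b1, b2)
  mat <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                              dims = c(nrow(bins), nrow(bins)))
  structure(list(bins = bins, mat = mat, resolution = resolution,
                 weights = NULL),
            class = "contact_matrix")
}

#' Dense symmetric counts of a contact matrix (optionally one chromosome)
#' @param cm a `contact_matrix`.
#' @param chrom optional chromosome name.
#' @param balanced apply balancing weights (requires [balance_ic()]).
#' @return list(mat = dense symmetric matrix, bins = matching bin table).
#' @export
dense_matrix <- function(cm, chrom = NULL, balanced = FALSE) {
  sel <- chrom
  idx <- if (is.null(sel)) cm$bins$bin_id else cm$bins[chrom %in% sel, bin_id]
  M <- as.matrix(cm$mat[idx, idx, drop = FALSE])
  M <- M + t(M)
  diag(M) <- diag(M) / 2
  if (balanced) {
    if (is.null(cm$weights)) stop("matrix is not balanced; run balance_ic()")
    w <- cm$weights[idx]
    M <- M * outer(w, w)
  }
  list(mat = M, bins = cm$bins[bin_id %in% idx])
}

#' Iterative-correction balancing
#'
#' Standard iterative correction: multiplicative per-bin weights are adjusted
#' until every unmasked row sum of the weighted matrix agrees with the mean
#' within `tol` (coefficient of variation). Zero-coverage bins are masked
#' (weight NA). Weights are scaled so balanced row sums are ~1.
#'
#' @param cm a `contact_matrix`.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the row-sum coefficient of variation.
#' @return the `contact_matrix` with `weights` filled in.
#' @export
balance_ic <- function(cm, max_iter = 200, tol = 1e-5) {
  M <- as.matrix(cm$mat)
  M <- M + t(M); diag(M) <- diag(M) / 2
  n <- nrow(M)
  mask <- rowSums(M) == 0
  b <- rep(1, n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- rowSums(M)
    su <- s[!mask]
    cv <- stats::sd(su) / mean(su)
    if (is.na(cv) || cv < tol) { converged <- TRUE; break }
    d <- s / mean(su)
    d[mask | d == 0] <- 1
    M <- M / outer(d, d)
    b <- b * d
  }
  if (!converged) warning("balancing did not converge; returning last iterate")
  m0 <- mean(rowSums(M)[!mask])
  w <- 1 / (b * sqrt(m0))
  w[mask] <- NA_real_
  cm$weights <- w
  cm
}

# log-spaced distance strata for O/E (bin-index distance d >= 0)
.dist_stratum <- function(d) {
  s <- numeric(length(d))
  nz <- d > 0
  s[nz] <- 1 + floor(log2(d[nz]) * 2)
  s
}

#' Compartment eigenvector from the O/E correlation matrix
#'
#' Per chromosome: balance-weighted cis matrix, observed/expected with the
#' expected taken as the per-stratum mean over log-spaced distance bins,
#' Pearson correlation matrix, leading eigenvector. The sign is oriented so
#' that bins with the higher mean of the active-chromatin `marker` track are
#' positive (compartment A).
#'
#' @param cm a balanced `contact_matrix` (cis contacts).
#' @param marker numeric marker value per global bin (e.g. H3K27ac density).
#' @param min_bins chromosomes with fewer usable bins are skipped.
#' @return data.table (bin_id, chrom, start, end, score, degenerate flag).
#' @export
eigenvector_compartments <- function(cm, marker = NULL, min_bins = 10) {
  if (is.null(cm$weights)) cm <- balance_ic(cm)
  res <- list()
  for (ch in unique(cm$bins$chrom)) {
    d <- dense_matrix(cm, ch, balanced = TRUE)
    n <- nrow(d$mat)
    score <- rep(NA_real_, n)
    degen <- FALSE
    usable <- !is.na(cm$weights[d$bins$bin_id]) & rowSums(d$mat, na.rm = TRUE) > 0
    if (sum(usable) < min_bins) {
      warning("chromosome ", ch, " skipped (fewer than ", min_bins,
              " usable bins)")
    } else {
      M <- d$mat[usable, usable, drop = FALSE]
      m <- nrow(M)
      dd <- abs(outer(seq_len(m), seq_len(m), "-"))
      st <- .dist_stratum(dd)
      E <- ave(as.vector(M), as.vector(st), FUN = function(x) mean(x, na.rm = TRUE))
      OE <- as.vector(M) / E
      OE[!is.finite(OE)] <- NA
      OE <- matrix(OE, m, m)
      C <- suppressWarnings(stats::cor(OE, use = "pairwise.complete.obs"))
      if (all(is.na(C)) || all(abs(C[!is.na(C)] - 1) < 1e-12)) {
        degen <- TRUE
      } else {
        C[is.na(C)] <- 0
        ev <- eigen(C, symmetric = TRUE)$vectors[, 1]
        if (!is.null(marker)) {
          mk <- marker[d$bins$bin_id][usable]
          hi <- mean(mk[ev > 0]); lo <- mean(mk[ev < 0])
          if (!is.na(hi) && !is.na(lo) && hi < lo) ev <- -ev
        }
        score[usable] <- ev
      }
    }
    res[[ch]] <- data.table(d$bins[, list(bin_id, chrom, start, end)],
                            score = score, degenerate = degen)
  }
  rbindlist(res)
}

#' Diamond insulation scores
#'
#' Per bin, the mean balanced signal in the `w`-bin diamond window crossing
#' the bin, log2-normalised to the chromosome mean of those window means.
#' Edge bins (window out of range) are NA.
#'
#' @param cm a balanced `contact_matrix`.
#' @param windows window sizes in bins (default 2, 5, 10).
#' @return data.table (bin_id, chrom, start, end, window, score).
#' @export
insulation_scores <- function(cm, windows = c(2, 5, 10)) {
  if (is.null(cm$weights)) cm <- balance_ic(cm)
  res <- list()
  for (ch in unique(cm$bins$chrom)) {
    d <- dense_matrix(cm, ch, balanced = TRUE)
    n <- nrow(d$mat)
    for (w in windows) {
      raw <- rep(NA_real_, n)
      if (n >= 2 * w + 1) {
        for (i in (w + 1):(n - w)) {
          raw[i] <- mean(d$mat[(i - w):(i - 1), (i + 1):(i + w)], na.rm = TRUE)
        }
      }
      mu <- mean(raw, na.rm = TRUE)
      score <- if (is.na(mu) || mu == 0) rep(NA_real_, n) else log2(raw / mu)
      res[[length(res) + 1L]] <- data.table(
        d$bins[, list(bin_id, chrom, start, end)], window = as.integer(w),
        score = score)
    }
  }
  rbindlist(res)
}

#' Per-read contact distance profiles
#'
#' Cover distance = maximum span of same-chromosome fragment midpoints;
#' adjacent distances = |mid_i - mid_(i+1)| for read-order neighbours on the
#' same chromosome; separated distances = the non-adjacent same-chromosome
#' pairs. Reads are stratified by order: lw (2-3), md (4-9), hg (>= 10).
#'
#' @param mw multiway fragment data.table.
#' @return list with `reads` (read_id, n, stratum, cover) and `distances`
#'   (read_id, type in cover/adjacent/separated, distance).
#' @export
distance_profiles <- function(mw) {
  mw <- as.data.table(mw)
  setorder(mw, read_id, frag_index)
  mw[, mid := .mid(start, end)]
  dist_one <- function(chrom, mid) {
    m <- length(mid)
    adj <- sep <- numeric()
    if (m >= 2L) {
      for (i in 1:(m - 1L)) for (j in (i + 1L):m) {
        if (chrom[i] == chrom[j]) {
          dd <- abs(mid[j] - mid[i])
          if (j == i + 1L) adj <- c(adj, dd) else sep <- c(sep, dd)
        }
      }
    }
    cov <- NA_real_
    for (ch in unique(chrom)) {
      mm <- mid[chrom == ch]
      if (length(mm) >= 2L) cov <- max(cov, diff(range(mm)), na.rm = TRUE)
    }
    list(cover = cov, adj = list(adj), sep = list(sep))
  }
  prof <- mw[, dist_one(chrom, mid), by = read_id]
  nn <- mw[, list(n = .N), by = read_id]
  reads <- merge(nn, prof[, list(read_id, cover)], by = "read_id")
  reads[, stratum := ifelse(n <= 3L, "lw", ifelse(n <= 9L, "md", "hg"))]
  dists <- rbind(
    prof[, list(distance = unlist(adj)), by = read_id][, type := "adjacent"],
    prof[, list(distance = unlist(sep)), by = read_id][, type := "separated"],
    reads[!is.na(cover), list(read_id, distance = cover)][, type := "cover"])
  list(reads = reads[], distances = dists[])
}
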