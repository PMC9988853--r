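# Independent oracle implementations used to cross-check the package's
# merge/filter/binning rules. These are deliberately written as plain-R
# loops over data.frames, independent of the package internals.

# genomic projection of read interval [os, oe) through a fragment row
oracle_project <- function(f, os, oe) {
  if (f$strand == "+") {
    c(f$start + (os - f$read_start), f$start + (oe - f$read_start))
  } else {
    c(f$end - (oe - f$read_start), f$end - (os - f$read_start))
  }
}

# brute-force fixed-point application of the overlap merge/drop rule on one
# read's fragments (data.frame rows)
oracle_merge_one_read <- function(df, tol = 50) {
  df <- as.data.frame(df)
  repeat {
    df <- df[order(df$read_start, df$read_end), , drop = FALSE]
    n <- nrow(df)
    found <- NULL
    if (n >= 2) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (df$read_start[j] < df$read_end[i]) { found <- c(i, j); break }
        }
        if (!is.null(found)) break
      }
    }
    if (is.null(found)) return(df)
    i <- found[1]; j <- found[2]
    fi <- df[i, ]; fj <- df[j, ]
    os <- max(fi$read_start, fj$read_start)
    oe <- min(fi$read_end, fj$read_end)
    coincident <- FALSE
    if (fi$chrom == fj$chrom && fi$strand == fj$strand) {
      pi_ <- oracle_project(fi, os, oe)
      pj_ <- oracle_project(fj, os, oe)
      coincident <- abs(pi_[1] - pj_[1]) <= tol && abs(pi_[2] - pj_[2]) <= tol
    }
    if (coincident) {
      fi$read_start <- min(fi$read_start, fj$read_start)
      fi$read_end <- max(fi$read_end, fj$read_end)
      fi$start <- min(fi$start, fj$start)
      fi$end <- max(fi$end, fj$end)
      fi$mapq <- max(fi$mapq, fj$mapq)
      df <- rbind(df[-c(i, j), , drop = FALSE], fi)
    } else {
      si <- fi$read_end - fi$read_start
      sj <- fj$read_end - fj$read_start
      drop <- if (si != sj) {
        if (si < sj) i else j
      } else if (fi$mapq != fj$mapq) {
        if (fi$mapq < fj$mapq) i else j
      } else j
      df <- df[-drop, , drop = FALSE]
    }
  }
}

# random fragment set for one read, engineered to contain read-coordinate
# overlaps, strand flips and cross-chromosome conflicts
random_read_frags <- function(read_id, n_frags, chroms = c("chrA", "chrB")) {
  rs <- sort(sample.int(900, n_frags))
  len <- sample(30:400, n_frags, replace = TRUE)
  data.frame(read_id = read_id,
             read_start = rs, read_end = rs + len,
             chrom = sample(chroms, n_frags, replace = TRUE),
             start = sample.int(5000, n_frags),
             end = 0L, strand = sample(c("+", "-"), n_frags, replace = TRUE),
             mapq = sample(c(0L, 5L, 30L, 60L), n_frags, replace = TRUE),
             frag_class = NA_character_, pass = "primary",
             stringsAsFactors = FALSE) |>
    transform(end = start + (read_end - read_start))
}

# nearest-site classification oracle (linear scan)
oracle_frag_class <- function(start, end, boundaries, tol = 30) {
  m1 <- min(abs(boundaries - start)) <= tol
  m2 <- min(abs(boundaries - end)) <= tol
  if (m1 && m2) "both_ends_matched" else if (m1 || m2) "one_end_matched" else "unmatched"
}

# exact NB upper tail by direct pmf summation (for small counts)
oracle_nb_upper <- function(q, size, mu, upto = 10000) {
  p <- mu / (size + mu)
  k <- 0:upto
  pmf <- exp(lgamma(k + size) - lgamma(size) - lfactorial(k) +
               size * log(1 - p) + k * log(p))
  sum(pmf[k >= q])
}

# a small multiway fragment table built by hand from (read, chrom, mid) spec
mw_from_mids <- function(spec) {
  # spec: list of list(read_id, chrom = vector, mid = vector)
  rows <- lapply(spec, function(s) {
    k <- length(s$mid)
    data.frame(read_id = s$read_id, frag_index = seq_len(k), n = k,
               chrom = s$chrom,
               start = as.integer(s$mid - 50), end = as.integer(s$mid + 50),
               strand = "+", mapq = 60L,
               read_start = (seq_len(k) - 1L) * 100L,
               read_end = seq_len(k) * 100L,
               stringsAsFactors = FALSE)
  })
  data.table::rbindlist(rows)
}

# agreement of two label vectors up to label swap (two groups)
swap_agreement <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  max(mean(a == b), mean(a == 3L - b))
}
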